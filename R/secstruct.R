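# Per-frame secondary-structure assignment. Hydrogen bonds are scored with
# the Kabsch-Sander electrostatic term and the standard -0.5 kcal/mol cutoff;
# labels are reduced to the five classes used for activation-domain
# timelines: H (alpha-helix), G (3-10 helix), E (beta), T (turn), C (coil).

KS_Q1Q2_F <- 0.42 * 0.20 * 332  # partial charges times electrostatic factor
KS_CUTOFF <- -0.5               # kcal/mol

ss_levels <- c("H", "G", "E", "T", "C")

# backbone atom index matrix (n_residues x N/CA/C/O), NA where missing
backbone_index <- function(topology) {
  res <- topology$residues
  out <- matrix(NA_integer_, nrow(res), 4,
                dimnames = list(NULL, c("N", "CA", "C", "O")))
  at <- topology$atoms
  for (nm in colnames(out)) {
    rows <- which(at$name == nm)
    out[match(at$residue_index[rows], res$residue_index), nm] <- rows
  }
  out
}

#' Assign secondary structure for one frame
#'
#' Backbone hydrogen bonds are detected with the Kabsch-Sander electrostatic
#' energy `E = q1*q2*(1/rON + 1/rCH - 1/rOH - 1/rCN)*f` (kcal/mol; bond iff
#' `E < -0.5`). Two consecutive i->i+4 bonds yield H, i->i+3 patterns G,
#' beta-bridge ladders E, isolated n-turns T, everything else C. Amide
#' hydrogens are taken from the structure when present and otherwise
#' reconstructed on the bisector-opposed direction of N at 1.01 Angstrom.
#' Residues with missing backbone atoms are labelled C with a warning
#' rather than failing.
#'
#' @param coords `N x 3` coordinate matrix (Angstrom).
#' @param topology Matching [topology()].
#' @return Character vector of labels (one per residue) in
#'   `c("H","G","E","T","C")`.
#' @export
assign_ss_frame <- function(coords, topology) {
  stopifnot(is_topology(topology))
  res <- topology$residues
  n <- nrow(res)
  bb <- backbone_index(topology)
  incomplete <- which(apply(bb, 1, anyNA))
  if (length(incomplete) > 0) {
    warn(sprintf("%d residue(s) with missing backbone atoms labelled C",
                 length(incomplete)))
  }

  # amide hydrogens: use explicit H atom when present, else reconstruct
  h_xyz <- amide_hydrogens(coords, topology)
  at <- topology$atoms
  h_rows <- which(at$name == "H")
  if (length(h_rows) > 0) {
    ri <- match(at$residue_index[h_rows], res$residue_index)
    h_xyz[ri, ] <- coords[h_rows, , drop = FALSE]
  }

  ok <- !apply(bb, 1, anyNA)
  has_h <- ok & !is.na(h_xyz[, 1])

  # hbond[d, a]: TRUE when NH of donor residue d bonds C=O of acceptor a
  hb <- matrix(FALSE, n, n)
  don <- which(has_h)
  acc <- which(ok)
  if (length(don) > 0 && length(acc) > 0) {
    nd <- coords[bb[don, "N"], , drop = FALSE]
    hd <- h_xyz[don, , drop = FALSE]
    ca_ <- coords[bb[acc, "C"], , drop = FALSE]
    oa <- coords[bb[acc, "O"], , drop = FALSE]
    dist2 <- function(p, q) {
      outer(rowSums(p^2), rowSums(q^2), "+") - 2 * p %*% t(q)
    }
    r_on <- sqrt(pmax(dist2(nd, oa), 1e-6))
    r_ch <- sqrt(pmax(dist2(hd, ca_), 1e-6))
    r_oh <- sqrt(pmax(dist2(hd, oa), 1e-6))
    r_cn <- sqrt(pmax(dist2(nd, ca_), 1e-6))
    e <- KS_Q1Q2_F * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    bond <- e < KS_CUTOFF
    sep_ok <- abs(outer(don, acc, "-")) >= 2
    hb[cbind(rep(don, times = length(acc))[as.vector(bond & sep_ok)],
             rep(acc, each = length(don))[as.vector(bond & sep_ok)])] <- TRUE
  }

  same_chain <- function(i, j) res$chain_id[i] == res$chain_id[j]
  turn_at <- function(i, nlen) {
    j <- i + nlen
    !is.na(j) && j <= n && same_chain(i, j) && hb[j, i]
  }
  turn3 <- vapply(seq_len(n), turn_at, logical(1), nlen = 3L)
  turn4 <- vapply(seq_len(n), turn_at, logical(1), nlen = 4L)
  turn5 <- vapply(seq_len(n), turn_at, logical(1), nlen = 5L)

  lab <- rep("C", n)
  # alpha helix: two consecutive i->i+4 turns cover residues i..i+3
  for (i in 2:n) {
    if (i + 3 <= n && turn4[i - 1] && turn4[i]) lab[i:(i + 3)] <- "H"
  }
  # 3-10 helix on residues not already alpha
  for (i in 2:n) {
    if (i + 2 <= n && turn3[i - 1] && turn3[i]) {
      idx <- i:(i + 2)
      lab[idx][lab[idx] == "C"] <- "G"
    }
  }
  # beta bridges (parallel/antiparallel), folded into a single E class
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    js <- which(abs(seq_len(n) - i) >= 3)
    for (j in js[js > 1 & js < n]) {
      par <- (hb[i, j - 1] && hb[j + 1, i]) || (hb[j, i - 1] && hb[i + 1, j])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) {
        bridge[i] <- TRUE
        bridge[j] <- TRUE
      }
    }
  }
  lab[bridge & lab == "C"] <- "E"
  # turns: interior residues of any n-turn not claimed by a helix/sheet
  for (i in seq_len(n)) {
    for (nlen in 3:5) {
      tt <- switch(as.character(nlen), "3" = turn3, "4" = turn4, "5" = turn5)
      if (tt[i] && i + nlen - 1 >= i + 1) {
        idx <- (i + 1):min(i + nlen - 1, n)
        lab[idx][lab[idx] == "C"] <- "T"
      }
    }
  }
  lab[incomplete] <- "C"
  lab
}

#' Secondary-structure timeline over a trajectory
#'
#' Applies [assign_ss_frame()] to every frame and returns a long tibble, the
#' tabular form of the timeline plots used for activation-domain helicity.
#'
#' @param frames A [frame_series()].
#' @param topology Matching [topology()].
#' @param residues Optional 0-based residue indices to keep (default all);
#'   an empty selection is an error.
#' @return Tibble of class `ss_timeline` with columns `frame`, `time_ns`,
#'   `run`, `residue_index`, `ss` (factor over H, G, E, T, C).
#' @export
ss_timeline <- function(frames, topology, residues = NULL) {
  check_frames_topology(frames, topology)
  res_idx <- topology$residues$residue_index
  if (!is.null(residues)) {
    res_idx <- intersect(res_idx, residues)
    if (length(res_idx) == 0) abort("empty residue selection")
  }
  keep <- match(res_idx, topology$residues$residue_index)
  nf <- frames$n_frames
  labs <- withCallingHandlers(
    lapply(seq_len(nf), function(i) {
      assign_ss_frame(frame_coords(frames, i), topology)[keep]
    }),
    warning = function(w) invokeRestart("muffleWarning")
  )
  out <- tibble(
    frame = rep(seq_len(nf), each = length(res_idx)),
    time_ns = rep(frame_times(frames), each = length(res_idx)),
    run = rep(run_labels(frames), each = length(res_idx)),
    residue_index = rep(res_idx, times = nf),
    ss = factor(unlist(labs), levels = ss_levels)
  )
  class(out) <- c("ss_timeline", class(out))
  out
}

#' Per-residue helical occupancy
#'
#' Fraction of frames in which each residue is helical. The default counts
#' only alpha-helix (H); `include_310 = TRUE` counts H and G, since timeline
#' summaries in the literature are ambiguous about 3-10 stretches.
#'
#' @param timeline An [ss_timeline()].
#' @param residues Optional 0-based residue indices to restrict to.
#' @param include_310 Count 3-10 helix (G) as helical.
#' @return Tibble with `residue_index` and `occupancy` in `[0, 1]`; the mean
#'   over the residue set is attached as attribute `mean_occupancy`.
#' @export
helical_occupancy <- function(timeline, residues = NULL, include_310 = FALSE) {
  stopifnot(inherits(timeline, "ss_timeline"))
  tl <- timeline
  if (!is.null(residues)) tl <- filter(tl, .data$residue_index %in% residues)
  helical <- if (include_310) c("H", "G") else "H"
  out <- summarise(group_by(tl, .data$residue_index),
                   occupancy = mean(.data$ss %in% helical), .groups = "drop")
  attr(out, "mean_occupancy") <- mean(out$occupancy)
  out
}

#' Modal helix boundaries and persistence
#'
#' Identifies consensus helical blocks (contiguous residues whose helical
#' occupancy reaches `min_persistence`), then reports, for each block, the
#' modal N- and C-terminal boundary residues among the per-frame helical
#' segments overlapping it, and the fraction of frames in which such a
#' segment exists. Modal ties break toward the N-terminus.
#'
#' @param timeline An [ss_timeline()].
#' @param min_persistence Occupancy threshold defining a consensus block.
#' @param include_310 Count G labels as helical.
#' @return Tibble with columns `start_res`, `end_res` (modal boundaries,
#'   0-based residue indices), `persistence`.
#' @export
helix_boundaries <- function(timeline, min_persistence = 0.5,
                             include_310 = FALSE) {
  stopifnot(inherits(timeline, "ss_timeline"))
  if (nrow(timeline) == 0) abort("empty timeline")
  helical <- if (include_310) c("H", "G") else "H"
  occ <- helical_occupancy(timeline, include_310 = include_310)
  res_sorted <- sort(unique(timeline$residue_index))
  hot <- occ$residue_index[occ$occupancy >= min_persistence]
  if (length(hot) == 0) return(tibble(start_res = integer(0),
                                      end_res = integer(0),
                                      persistence = numeric(0)))
  # contiguous consensus blocks
  hot <- sort(hot)
  block_id <- cumsum(c(1, diff(hot) != 1))
  blocks <- lapply(split(hot, block_id), range)

  frames <- unique(timeline$frame)
  # per-frame helical segments as (start, end) pairs
  seg_by_frame <- lapply(split(timeline, timeline$frame), function(fr) {
    fr <- fr[order(fr$residue_index), ]
    is_h <- fr$ss %in% helical
    if (!any(is_h)) return(NULL)
    r <- rle(is_h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    cbind(start = fr$residue_index[starts[keep]],
          end = fr$residue_index[ends[keep]])
  })

  out <- lapply(blocks, function(b) {
    starts <- integer(0)
    ends <- integer(0)
    covered <- 0L
    for (segs in seg_by_frame) {
      if (is.null(segs)) next
      ov <- segs[, "start"] <= b[2] & segs[, "end"] >= b[1]
      if (any(ov)) {
        covered <- covered + 1L
        # widest overlapping segment represents the helix in this frame
        w <- which(ov)[which.max(segs[ov, "end"] - segs[ov, "start"])]
        starts <- c(starts, segs[w, "start"])
        ends <- c(ends, segs[w, "end"])
      }
    }
    modal <- function(x) {
      tab <- table(x)
      cand <- as.integer(names(tab)[tab == max(tab)])
      min(cand)  # ties toward the N-terminus
    }
    tibble(start_res = modal(starts), end_res = modal(ends),
           persistence = covered / length(frames))
  })
  bind_rows(out)
}

#' Wide label matrix from a timeline
#'
#' @param timeline An [ss_timeline()].
#' @return Character matrix `frames x residues` with residue indices as
#'   column names.
#' @export
ss_matrix <- function(timeline) {
  stopifnot(inherits(timeline, "ss_timeline"))
  wide <- tidyr::pivot_wider(
    select(as_tibble(timeline), "frame", "residue_index", "ss"),
    names_from = "residue_index", values_from = "ss")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$frame
  m
}
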