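# Geometric observables of fuzzy-complex trajectories: pocket distances,
# switch-like occupancy states, helix-orientation angles, superposition and
# RMSD/RMSF. Superposition and RMSF computations are backed by bio3d, the
# standard structural-bioinformatics toolkit in R.

frames_to_xyz <- function(frames) {
  nf <- frames$n_frames
  out <- matrix(NA_real_, nf, 3 * frames$n_atoms)
  for (i in seq_len(nf)) out[i, ] <- as.vector(t(frames$coords[i, , ]))
  out
}

xyz_to_frames <- function(mat, template) {
  coords <- array(NA_real_, dim = c(nrow(mat), ncol(mat) / 3, 3))
  for (i in seq_len(nrow(mat))) {
    coords[i, , ] <- matrix(mat[i, ], ncol = 3, byrow = TRUE)
  }
  frame_series(coords, frame_interval_ns = template$frame_interval_ns,
               source = template$source, run_lengths = template$run_lengths)
}

#' Per-frame distance between two atom groups
#'
#' Euclidean distance between reductions of two atom selections, per frame.
#' The pocket-occupancy observable uses the coactivator pocket-floor CA as
#' one group and the anchor residue's side-chain heavy atoms as the other
#' (see [pocket_distance_series()]).
#'
#' @param frames A [frame_series()].
#' @param topology Matching [topology()].
#' @param sel_a,sel_b Integer atom indices (rows of the atom table), e.g.
#'   from [select_atoms()].
#' @param mode `"centroid"` (distance between group centroids) or `"min"`
#'   (minimum inter-atomic distance).
#' @return Tibble with columns `frame`, `time_ns`, `run`, `distance` (Angstrom).
#' @export
distance_series <- function(frames, topology, sel_a, sel_b,
                            mode = c("centroid", "min")) {
  mode <- match.arg(mode)
  check_frames_topology(frames, topology)
  if (length(sel_a) == 0 || length(sel_b) == 0) {
    abort("selection error: empty atom selection")
  }
  nf <- frames$n_frames
  d <- numeric(nf)
  for (i in seq_len(nf)) {
    xa <- frames$coords[i, sel_a, , drop = FALSE]
    xb <- frames$coords[i, sel_b, , drop = FALSE]
    if (mode == "centroid") {
      ca <- colMeans(matrix(xa, ncol = 3))
      cb <- colMeans(matrix(xb, ncol = 3))
      d[i] <- vnorm(ca - cb)
    } else {
      ma <- matrix(xa, ncol = 3)
      mb <- matrix(xb, ncol = 3)
      dd <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * ma %*% t(mb)
      d[i] <- sqrt(max(0, min(dd)))
    }
  }
  tibble(frame = seq_len(nf), time_ns = frame_times(frames),
         run = run_labels(frames), distance = d)
}

#' Pocket-occupancy distance of an anchor residue
#'
#' The binding-pocket observable: distance from the CA of the pocket-floor
#' residue on the coactivator to the side-chain heavy-atom centroid of a
#' candidate anchor residue on the activation domain. The centroid reduction
#' is robust to aromatic ring flips; glycine-like residues fall back to CA.
#'
#' @param frames A [frame_series()].
#' @param topology Matching [topology()].
#' @param pocket_residue 0-based residue index of the pocket-floor residue.
#' @param anchor_residue 0-based residue index of the candidate anchor.
#' @return Tibble as in [distance_series()].
#' @export
pocket_distance_series <- function(frames, topology, pocket_residue,
                                   anchor_residue) {
  sel_p <- select_atoms(topology, residue_index = pocket_residue,
                        atom_name = "CA")
  sel_a <- sidechain_or_ca(topology, anchor_residue)
  distance_series(frames, topology, sel_p, sel_a, mode = "centroid")
}

#' Helix-orientation angle between two residue-endpoint vectors
#'
#' The orientation observable: the unsigned angle between the CA(i)->CA(j)
#' vectors of two helices, each defined literally by its stated endpoint
#' residues (not a fitted axis). Reported in degrees in [0, 180].
#'
#' @param frames A [frame_series()].
#' @param topology Matching [topology()].
#' @param vec1,vec2 Length-2 integer vectors of 0-based residue indices
#'   `(from, to)` defining each helix vector by its CA endpoints.
#' @return Tibble with columns `frame`, `time_ns`, `run`, `angle` (degrees).
#' @export
helix_angle_series <- function(frames, topology, vec1, vec2) {
  check_frames_topology(frames, topology)
  ca_idx <- function(ri) {
    idx <- select_atoms(topology, residue_index = ri, atom_name = "CA")
    if (length(idx) != 1) {
      abort(sprintf("residue %d has no unique CA atom", ri))
    }
    idx
  }
  i1 <- ca_idx(vec1[1]); j1 <- ca_idx(vec1[2])
  i2 <- ca_idx(vec2[1]); j2 <- ca_idx(vec2[2])
  nf <- frames$n_frames
  ang <- numeric(nf)
  for (f in seq_len(nf)) {
    v1 <- frames$coords[f, j1, ] - frames$coords[f, i1, ]
    v2 <- frames$coords[f, j2, ] - frames$coords[f, i2, ]
    ang[f] <- angle_deg(v1, v2)
  }
  tibble(frame = seq_len(nf), time_ns = frame_times(frames),
         run = run_labels(frames), angle = ang)
}

#' Classify switch-like pocket-occupancy states
#'
#' Two-threshold (hysteresis) state machine over the distance traces of two
#' candidate anchor residues. An anchor is counted "in" once its distance
#' drops below `d_in` and remains so until it exceeds `d_out`; the band
#' between the thresholds suppresses label chatter from thermal noise.
#' Latches reset at run boundaries so no state carries over between
#' concatenated independent simulations.
#'
#' @param d_a,d_b Numeric distance traces (Angstrom) of the two anchors, or
#'   tibbles from [pocket_distance_series()] (their `distance` column is used
#'   and `run` taken from `d_a` unless given explicitly).
#' @param d_in In-threshold (Angstrom), default 6.5.
#' @param d_out Out-threshold (Angstrom), default 8.5; must exceed `d_in`.
#' @param run Optional integer run label per frame.
#' @return Tibble of class `occupancy_states` with columns `frame`, `run`,
#'   `d_a`, `d_b`, `state` (factor with levels `A_IN`, `B_IN`, `BOTH`,
#'   `NONE`); thresholds stored as attributes.
#' @export
classify_occupancy <- function(d_a, d_b, d_in = 6.5, d_out = 8.5, run = NULL) {
  if (is.data.frame(d_a)) {
    if (is.null(run) && "run" %in% names(d_a)) run <- d_a$run
    d_a <- d_a$distance
  }
  if (is.data.frame(d_b)) d_b <- d_b$distance
  if (length(d_a) != length(d_b)) {
    abort("distance traces differ in length")
  }
  if (d_in >= d_out) {
    abort("configuration error: d_in must be smaller than d_out")
  }
  nf <- length(d_a)
  if (is.null(run)) run <- rep(1L, nf)
  in_a <- FALSE
  in_b <- FALSE
  state <- character(nf)
  for (t in seq_len(nf)) {
    if (t == 1 || run[t] != run[t - 1]) {
      in_a <- FALSE
      in_b <- FALSE
    }
    in_a <- if (in_a) d_a[t] <= d_out else d_a[t] < d_in
    in_b <- if (in_b) d_b[t] <= d_out else d_b[t] < d_in
    state[t] <- if (in_a && in_b) "BOTH" else if (in_a) "A_IN"
      else if (in_b) "B_IN" else "NONE"
  }
  out <- tibble(frame = seq_len(nf), run = run, d_a = d_a, d_b = d_b,
                state = factor(state, levels = c("A_IN", "B_IN", "BOTH",
                                                 "NONE")))
  attr(out, "d_in") <- d_in
  attr(out, "d_out") <- d_out
  class(out) <- c("occupancy_states", class(out))
  out
}

#' Superpose trajectory frames onto a reference
#'
#' Least-squares optimal (Kabsch) rigid-body superposition of every frame
#' onto a reference structure over a selection, via `bio3d::fit.xyz`;
#' returns the aligned frames and the per-frame RMSD over the selection.
#'
#' @param frames A [frame_series()].
#' @param topology Matching [topology()].
#' @param reference Frame index used as reference (default 1) or an `N x 3`
#'   coordinate matrix.
#' @param selection Integer atom indices to fit on; default all CA atoms.
#' @return List with `frames` (aligned [frame_series()]) and `rmsd`
#'   (tibble: `frame`, `time_ns`, `run`, `rmsd` in Angstrom).
#' @export
superpose <- function(frames, topology, reference = 1, selection = NULL) {
  check_frames_topology(frames, topology)
  if (is.null(selection)) {
    selection <- select_atoms(topology, atom_name = "CA")
  }
  if (length(selection) < 3) {
    abort("degenerate superposition: need at least 3 atoms in selection")
  }
  ref <- if (is.matrix(reference)) reference else
    frame_coords(frames, reference)
  refsel <- ref[selection, , drop = FALSE]
  sv <- svd(scale(refsel, scale = FALSE))$d
  if (sum(sv > 1e-8) < 2) {
    abort("degenerate superposition: selection atoms are collinear")
  }
  xyz <- frames_to_xyz(frames)
  xyz_inds <- bio3d::atom2xyz(selection)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)), mobile = xyz,
                           fixed.inds = xyz_inds, mobile.inds = xyz_inds)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  aligned <- xyz_to_frames(fitted, frames)
  rmsd <- vapply(seq_len(frames$n_frames), function(i) {
    dif <- aligned$coords[i, selection, , drop = FALSE] -
      array(refsel, dim = c(1, length(selection), 3))
    sqrt(mean(rowSums(matrix(dif, ncol = 3)^2)))
  }, numeric(1))
  list(frames = aligned,
       rmsd = tibble(frame = seq_len(frames$n_frames),
                     time_ns = frame_times(frames),
                     run = run_labels(frames), rmsd = rmsd))
}

#' Per-residue RMSF of CA atoms
#'
#' Root-mean-square fluctuation of each selected residue's CA about its mean
#' position. Frames must already be superposed (see [superpose()]); a single
#' frame has no defined fluctuation and is an error.
#'
#' @param frames A superposed [frame_series()].
#' @param topology Matching [topology()].
#' @param residues 0-based residue indices; default all residues with a CA.
#' @return Tibble with columns `residue_index`, `residue_name`, `rmsf`
#'   (Angstrom).
#' @export
rmsf_profile <- function(frames, topology, residues = NULL) {
  check_frames_topology(frames, topology)
  if (frames$n_frames < 2) {
    abort("RMSF is undefined for a single frame")
  }
  res <- topology$residues
  if (!is.null(residues)) res <- res[res$residue_index %in% residues, ]
  ca_idx <- vapply(res$residue_index, function(ri) {
    idx <- select_atoms(topology, residue_index = ri, atom_name = "CA")
    if (length(idx) == 1) idx else NA_integer_
  }, integer(1))
  keep <- !is.na(ca_idx)
  res <- res[keep, ]
  ca_idx <- ca_idx[keep]
  if (length(ca_idx) == 0) abort("no CA atoms in requested residues")
  rmsf <- vapply(ca_idx, function(ai) {
    pos <- matrix(frames$coords[, ai, ], ncol = 3)
    dev <- sweep(pos, 2, colMeans(pos))
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1))
  tibble(residue_index = res$residue_index,
         residue_name = res$residue_name, rmsf = rmsf)
}
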