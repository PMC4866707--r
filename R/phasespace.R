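# Three-coordinate phase space (helix angle, two anchor distances): binned
# occupancy density of trajectory snapshots and placement of reference NMR
# model coordinates within or outside highly populated regions.

#' Zip phase-space points from observable series
#'
#' Combines a helix-angle series and the two anchor-distance series into
#' per-frame phase-space triples.
#'
#' @param angle Numeric angle trace (degrees) or tibble from
#'   [helix_angle_series()].
#' @param d_a,d_b Numeric distance traces (Angstrom) or tibbles from
#'   [pocket_distance_series()].
#' @return Tibble with columns `frame`, `angle`, `d_a`, `d_b`.
#' @export
phase_points <- function(angle, d_a, d_b) {
  if (is.data.frame(angle)) angle <- angle$angle
  if (is.data.frame(d_a)) d_a <- d_a$distance
  if (is.data.frame(d_b)) d_b <- d_b$distance
  n <- length(angle)
  if (length(d_a) != n || length(d_b) != n) {
    abort("alignment error: series lengths differ")
  }
  tibble(frame = seq_len(n), angle = angle, d_a = d_a, d_b = d_b)
}

#' 3-D phase-space histogram
#'
#' Bins phase points on a regular grid. Bin edges start at the floor of the
#' data minimum in units of the bin width, so the grid is stable under
#' subsetting of the data.
#'
#' @param points Tibble from [phase_points()].
#' @param bin_widths Numeric length-3: bin widths for (angle, d_a, d_b);
#'   default 10 degrees x 1 A x 1 A.
#' @return Object of class `phase_density`: list with `edges` (list of 3
#'   edge vectors), `counts` (3-D array), `n` (total points), `bin_widths`.
#' @export
phase_density <- function(points, bin_widths = c(10, 1, 1)) {
  if (nrow(points) == 0) abort("no phase points to bin")
  if (any(bin_widths <= 0)) abort("bin widths must be > 0")
  vals <- list(points$angle, points$d_a, points$d_b)
  edges <- vector("list", 3)
  idx <- vector("list", 3)
  for (k in 1:3) {
    w <- bin_widths[k]
    lo <- floor(min(vals[[k]]) / w) * w
    hi <- ceiling(max(vals[[k]]) / w) * w
    if (hi <= lo) hi <- lo + w
    edges[[k]] <- seq(lo, hi, by = w)
    # right-open bins [e_i, e_{i+1}); top edge closed
    idx[[k]] <- pmin(findInterval(vals[[k]], edges[[k]]),
                     length(edges[[k]]) - 1L)
  }
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  counts <- array(0L, dim = dims)
  flat <- (idx[[3]] - 1L) * dims[1] * dims[2] +
    (idx[[2]] - 1L) * dims[1] + idx[[1]]
  tab <- table(flat)
  counts[as.integer(names(tab))] <- as.integer(tab)
  structure(list(edges = edges, counts = counts, n = nrow(points),
                 bin_widths = bin_widths),
            class = "phase_density")
}

#' @export
print.phase_density <- function(x, ...) {
  cat(sprintf("<phase_density> %d points in %s grid (widths %s)\n", x$n,
              paste(dim(x$counts), collapse = " x "),
              paste(x$bin_widths, collapse = ", ")))
  invisible(x)
}

# bin index (length-3 integer, NA outside the grid) of a single point
density_bin <- function(density, p) {
  out <- integer(3)
  for (k in 1:3) {
    e <- density$edges[[k]]
    i <- findInterval(p[k], e)
    if (p[k] == e[length(e)]) i <- length(e) - 1L  # closed top edge
    if (i < 1 || i > length(e) - 1L) return(rep(NA_integer_, 3))
    out[k] <- i
  }
  out
}

#' Marginal 2-D projection of a phase density
#'
#' @param density A [phase_density()].
#' @param axes Integer length-2: which axes to keep (1 = angle, 2 = d_a,
#'   3 = d_b).
#' @return Matrix of counts over the two kept axes.
#' @export
project_density <- function(density, axes = c(1, 2)) {
  stopifnot(inherits(density, "phase_density"))
  drop_axis <- setdiff(1:3, axes)
  m <- apply(density$counts, axes, sum)
  if (!identical(sort(axes), axes)) m <- t(m)
  m
}

#' Fraction of reference points inside highly populated regions
#'
#' A reference point lies in a highly populated region when its bin - or any
#' bin in the 1-bin Chebyshev neighborhood, when `neighborhood = TRUE` -
#' holds at least `min_frac` of all samples. Used to ask whether reference
#' NMR ensemble models fall inside the conformational space an MD ensemble
#' actually visits.
#'
#' @param density A [phase_density()] built from trajectory snapshots.
#' @param reference_points Tibble with columns `angle`, `d_a`, `d_b` (and
#'   optionally `model`), e.g. observables of each NMR model evaluated as a
#'   one-frame trajectory.
#' @param min_frac Population threshold as a fraction of total samples,
#'   default 0.001.
#' @param neighborhood Include the 26 surrounding bins, default `TRUE`.
#' @return List with `fraction` (hits / references) and `placements`
#'   (tibble: `model`, `angle`, `d_a`, `d_b`, `in_region`).
#' @export
populated_fraction <- function(density, reference_points, min_frac = 0.001,
                               neighborhood = TRUE) {
  stopifnot(inherits(density, "phase_density"))
  if (nrow(reference_points) == 0) abort("no reference points supplied")
  if (min_frac <= 0 || min_frac >= 1) abort("min_frac must be in (0, 1)")
  threshold <- min_frac * density$n
  dims <- dim(density$counts)
  hit <- logical(nrow(reference_points))
  for (i in seq_len(nrow(reference_points))) {
    p <- c(reference_points$angle[i], reference_points$d_a[i],
           reference_points$d_b[i])
    b <- density_bin(density, p)
    if (anyNA(b)) next
    if (neighborhood) {
      rng <- lapply(1:3, function(k) max(1, b[k] - 1):min(dims[k], b[k] + 1))
      block <- density$counts[rng[[1]], rng[[2]], rng[[3]]]
      hit[i] <- any(block >= threshold)
    } else {
      hit[i] <- density$counts[b[1], b[2], b[3]] >= threshold
    }
  }
  placements <- mutate(as_tibble(reference_points), in_region = hit)
  if (!"model" %in% names(placements)) {
    placements$model <- seq_len(nrow(placements))
  }
  list(fraction = mean(hit),
       placements = select(placements, "model", "angle", "d_a", "d_b",
                           "in_region"))
}

#' Sensitivity sweep of the populated-region threshold
#'
#' Reports the reference-inclusion fraction over a grid of `min_frac`
#' values; the fraction is monotone non-increasing in the threshold.
#'
#' @param density A [phase_density()].
#' @param reference_points As in [populated_fraction()].
#' @param min_fracs Thresholds to sweep.
#' @param neighborhood As in [populated_fraction()].
#' @return Tibble with columns `min_frac`, `fraction`.
#' @export
populated_fraction_sweep <- function(density, reference_points,
                                     min_fracs = c(5e-4, 1e-3, 2e-3, 5e-3,
                                                   1e-2),
                                     neighborhood = TRUE) {
  res <- vapply(min_fracs, function(mf) {
    populated_fraction(density, reference_points, min_frac = mf,
                       neighborhood = neighborhood)$fraction
  }, numeric(1))
  tibble(min_frac = min_fracs, fraction = res)
}
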