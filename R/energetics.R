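# Simplified per-residue decomposition of intermolecular nonbonded energies.
# Lennard-Jones with Lorentz-Berthelot combination plus screened Coulomb
# (distance-dependent dielectric eps(r) = 4r by default) replaces the full
# MM-GBSA treatment: absolute kcal/mol values are not comparable to solvated
# estimates, but the per-residue rank order and temporal switching pattern -
# the quantities of interest for fuzzy anchoring - are preserved.

COULOMB_KE <- 332.0636  # kcal * Angstrom / (mol * e^2)

#' Nonbonded pair energy
#'
#' Van der Waals and electrostatic energy of one atom pair:
#' `vdw = 4*eps_ij*((sig_ij/r)^12 - (sig_ij/r)^6)` with Lorentz-Berthelot
#' combination (`eps_ij = sqrt(eps_i*eps_j)`, `sig_ij = (sig_i+sig_j)/2`),
#' and `elec = ke*q_i*q_j/(eps(r)*r)` with `ke = 332.0636` kcal A/(mol e^2).
#' The default dielectric is distance-dependent, `eps(r) = 4r`; `"vacuum"`
#' uses `eps = 1`.
#'
#' @param r Distance(s), Angstrom; must be positive.
#' @param q_i,q_j Partial charges (e).
#' @param eps_i,eps_j LJ well depths (kcal/mol).
#' @param sig_i,sig_j LJ diameters (Angstrom).
#' @param dielectric `"distance"` or `"vacuum"`.
#' @return Tibble with columns `vdw` and `elec` (kcal/mol).
#' @examples
#' # LJ minimum: r = 2^(1/6) * sigma gives vdw = -eps exactly
#' pair_energy(2^(1/6) * 3.4, 0, 0, 0.1, 0.1, 3.4, 3.4)
#' @export
pair_energy <- function(r, q_i, q_j, eps_i, eps_j, sig_i, sig_j,
                        dielectric = c("distance", "vacuum")) {
  dielectric <- match.arg(dielectric)
  if (any(r <= 0)) abort("singularity: pair distance must be > 0")
  eps_ij <- sqrt(eps_i * eps_j)
  sig_ij <- (sig_i + sig_j) / 2
  sr6 <- (sig_ij / r)^6
  vdw <- 4 * eps_ij * (sr6^2 - sr6)
  elec <- if (dielectric == "distance") {
    COULOMB_KE * q_i * q_j / (4 * r^2)
  } else {
    COULOMB_KE * q_i * q_j / r
  }
  tibble(vdw = vdw, elec = elec)
}

#' Per-residue intermolecular energy decomposition
#'
#' For each sampled frame and each activation-domain residue, sums the
#' nonbonded pair energies between that residue's atoms and all coactivator
#' atoms within the cutoff. Only intermolecular pairs are evaluated, so no
#' intramolecular 1-4 scaling is involved.
#'
#' @param frames A [frame_series()].
#' @param topology Parameterized [topology()] (see [assign_params()]).
#' @param group_ad 0-based residue indices of the activation domain.
#' @param group_coact 0-based residue indices of the coactivator; must be
#'   disjoint from `group_ad`.
#' @param sample_interval_ns Snapshot spacing in ns (default: every frame).
#' @param cutoff Pair cutoff, Angstrom; `Inf` evaluates all pairs (used by
#'   the brute-force cross-checks).
#' @param dielectric Passed to [pair_energy()].
#' @return Tibble of class `energy_decomposition` with columns `frame`,
#'   `time_ns`, `run`, `residue_index`, `vdw`, `elec` (kcal/mol).
#' @export
decomposition_matrix <- function(frames, topology, group_ad, group_coact,
                                 sample_interval_ns = NULL, cutoff = 12,
                                 dielectric = c("distance", "vacuum")) {
  dielectric <- match.arg(dielectric)
  check_frames_topology(frames, topology)
  if (length(intersect(group_ad, group_coact)) > 0) {
    abort("selection error: AD and coactivator residue groups overlap")
  }
  at <- topology$atoms
  if (is.null(at$charge)) {
    abort("topology has no parameters; run assign_params() first")
  }
  ad_idx <- which(at$residue_index %in% group_ad)
  co_idx <- which(at$residue_index %in% group_coact)
  if (length(ad_idx) == 0 || length(co_idx) == 0) {
    abort("selection error: empty residue group")
  }
  step <- if (is.null(sample_interval_ns)) 1L else
    max(1L, as.integer(round(sample_interval_ns / frames$frame_interval_ns)))
  sel_frames <- seq(1L, frames$n_frames, by = step)

  ad_res <- at$residue_index[ad_idx]
  q_ad <- at$charge[ad_idx]; e_ad <- at$epsilon[ad_idx]
  s_ad <- at$sigma[ad_idx]
  q_co <- at$charge[co_idx]; e_co <- at$epsilon[co_idx]
  s_co <- at$sigma[co_idx]
  eps_ij <- sqrt(outer(e_ad, e_co))
  sig_ij <- outer(s_ad, s_co, function(a, b) (a + b) / 2)
  qq <- outer(q_ad, q_co)
  times <- frame_times(frames)
  runs <- run_labels(frames)
  res_levels <- sort(unique(ad_res))

  rows <- vector("list", length(sel_frames))
  for (k in seq_along(sel_frames)) {
    f <- sel_frames[k]
    xa <- matrix(frames$coords[f, ad_idx, ], ncol = 3)
    xc <- matrix(frames$coords[f, co_idx, ], ncol = 3)
    r2 <- outer(rowSums(xa^2), rowSums(xc^2), "+") - 2 * xa %*% t(xc)
    r <- sqrt(pmax(r2, 1e-12))
    if (any(r2 <= 1e-12)) abort("singularity: coincident intermolecular atoms")
    within <- r <= cutoff
    sr6 <- (sig_ij / r)^6
    vdw_m <- 4 * eps_ij * (sr6^2 - sr6) * within
    elec_m <- if (dielectric == "distance") {
      COULOMB_KE * qq / (4 * r^2) * within
    } else {
      COULOMB_KE * qq / r * within
    }
    vdw_res <- rowsum(rowSums(vdw_m), ad_res)
    elec_res <- rowsum(rowSums(elec_m), ad_res)
    rows[[k]] <- tibble(frame = f, time_ns = times[f], run = runs[f],
                        residue_index = as.integer(rownames(vdw_res)),
                        vdw = as.numeric(vdw_res),
                        elec = as.numeric(elec_res))
  }
  out <- bind_rows(rows)
  attr(out, "cutoff") <- cutoff
  attr(out, "dielectric") <- dielectric
  class(out) <- c("energy_decomposition", class(out))
  out
}

#' Total interaction-energy time series
#'
#' Per-frame sum over residues of `vdw + elec`; by construction the series
#' equals the residue-wise row sums of the decomposition (additivity).
#'
#' @param decomposition An [decomposition_matrix()] result.
#' @return Tibble with columns `frame`, `time_ns`, `run`, `energy` (kcal/mol).
#' @export
binding_series <- function(decomposition) {
  stopifnot(inherits(decomposition, "energy_decomposition"))
  if (nrow(decomposition) == 0) abort("empty decomposition")
  summarise(group_by(decomposition, .data$frame, .data$time_ns, .data$run),
            energy = sum(.data$vdw + .data$elec), .groups = "drop")
}
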