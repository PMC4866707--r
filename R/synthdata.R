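# Synthetic fuzzy-complex trajectories with ground truth. The generator
# emulates the statistical structure of the study system - a rigid ~80
# residue coactivator domain whose surface pocket is occupied, switch-like,
# by one of two anchor side chains of a 25-35 residue peptide whose helical
# block forms and melts as a two-state Markov chain - without claiming
# physical realism: output is geometric (no sterics, no energetics), which
# is exactly what the analyses under test consume.

#' Specification of a synthetic fuzzy-complex trajectory
#'
#' Defaults describe the study conditions the generator emulates: a
#' 27-residue activation-domain peptide with tryptophan/phenylalanine
#' anchors four residues apart, a central cooperative helix block formed
#' ~90% of the time, switch-like pocket occupancy favouring single
#' occupancy with occasional double and vacant states, four concatenated
#' 100-frame runs at 10 ns spacing (the layout of deposited trajectory
#' sets) all starting with the F-anchor in the pocket, and 0.1 Angstrom
#' coordinate noise (measurement-scale jitter; see the vignette for the
#' assigner's sensitivity to larger, uncorrelated noise).
#'
#' @param peptide_sequence One-letter peptide sequence.
#' @param anchor_a,anchor_b 1-based positions of the two candidate anchor
#'   residues within the peptide (defaults: the W and F of the bundled
#'   variant scaffold).
#' @param helix_blocks Tibble with columns `start`, `end` (1-based peptide
#'   positions), `p` (stationary probability the block is formed) and
#'   `breathe` (probability that a block end shifts by one residue in a
#'   formed frame; split evenly between -1 and +1).
#' @param helix_mixing Markov mixing parameter in (0, 1]: per-frame flip
#'   probabilities are `mixing * (1 - p)` out of the formed state and
#'   `mixing * p` into it.
#' @param occupancy_stationary Stationary distribution over the occupancy
#'   states `A_IN`, `B_IN`, `BOTH`, `NONE`.
#' @param occupancy_mixing Mixing parameter: the transition matrix is
#'   `(1 - m) I + m 1 pi^T`, which has stationary distribution `pi`.
#' @param start_state Occupancy state at the start of every run
#'   (`"stationary"` draws it instead).
#' @param orientation_mean,orientation_sd Mean and spread (degrees) of the
#'   per-frame helix-orientation angle between peptide and coactivator.
#' @param coact_length Residues in the rigid coactivator helix.
#' @param pocket_site 1-based residue position of the pocket floor on the
#'   coactivator.
#' @param dock_distance Distance (Angstrom) from the pocket-floor CA to the
#'   docked anchor's side-chain centroid. The default 5.5 reflects that the
#'   CB pseudo-side-chain stands in for a full side chain whose centroid
#'   reaches ~4 Angstrom further into a pocket; it keeps backbones of the
#'   two chains clear of each other while staying inside the default
#'   6.5 Angstrom in-threshold.
#' @param noise_sd Isotropic Gaussian coordinate noise, Angstrom.
#' @param n_frames Total frames; must be divisible by `n_runs`.
#' @param n_runs Number of concatenated independent runs.
#' @param frame_interval_ns Frame spacing, ns.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(peptide_sequence = "MKTVLPIPELDDAVWESLFSSGSGSGS",
                       anchor_a = 15, anchor_b = 19,
                       helix_blocks = tibble(start = 10, end = 21, p = 0.9,
                                             breathe = 0.2),
                       helix_mixing = 0.3,
                       occupancy_stationary = c(A_IN = 0.5, B_IN = 0.3,
                                                BOTH = 0.1, NONE = 0.1),
                       occupancy_mixing = 0.2,
                       start_state = "B_IN",
                       orientation_mean = 90, orientation_sd = 35,
                       coact_length = 80, pocket_site = 50,
                       dock_distance = 5.5,
                       noise_sd = 0.1, n_frames = 400, n_runs = 4,
                       frame_interval_ns = 10) {
  check_sequence(peptide_sequence)
  n_pep <- nchar(peptide_sequence)
  if (anchor_a == anchor_b || anchor_a > n_pep || anchor_b > n_pep) {
    abort("anchors must be distinct positions within the peptide")
  }
  hb <- as_tibble(helix_blocks)
  if (any(hb$start > hb$end) || any(hb$end > n_pep) ||
      any(hb$p < 0 | hb$p > 1)) {
    abort("invalid helix_blocks specification")
  }
  pi0 <- occupancy_stationary
  if (length(pi0) != 4 || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-8) {
    abort("spec error: occupancy_stationary must be 4 probabilities summing to 1")
  }
  names(pi0) <- c("A_IN", "B_IN", "BOTH", "NONE")
  if (occupancy_mixing <= 0 || occupancy_mixing > 1 ||
      helix_mixing <= 0 || helix_mixing > 1) {
    abort("mixing parameters must lie in (0, 1]")
  }
  if (!start_state %in% c(names(pi0), "stationary")) {
    abort("start_state must be an occupancy state or 'stationary'")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (dock_distance <= 0) abort("dock_distance must be > 0")
  if (n_frames %% n_runs != 0) abort("n_frames must be divisible by n_runs")
  structure(
    list(peptide_sequence = peptide_sequence, anchor_a = anchor_a,
         anchor_b = anchor_b, helix_blocks = hb,
         helix_mixing = helix_mixing, occupancy_stationary = pi0,
         occupancy_mixing = occupancy_mixing, start_state = start_state,
         orientation_mean = orientation_mean,
         orientation_sd = orientation_sd, coact_length = coact_length,
         pocket_site = pocket_site, dock_distance = dock_distance,
         noise_sd = noise_sd,
         n_frames = n_frames, n_runs = n_runs,
         frame_interval_ns = frame_interval_ns),
    class = "synth_spec")
}

#' Occupancy transition matrix implied by a spec
#'
#' `(1 - m) I + m 1 pi^T`: rows sum to 1 and the stationary distribution is
#' exactly `pi`.
#'
#' @param spec A [synth_spec()].
#' @return 4 x 4 row-stochastic matrix with state names.
#' @export
occupancy_transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  pi0 <- spec$occupancy_stationary
  m <- spec$occupancy_mixing
  tm <- (1 - m) * diag(4) + m * matrix(pi0, 4, 4, byrow = TRUE)
  dimnames(tm) <- list(names(pi0), names(pi0))
  tm
}

#' Simulate a discrete-state Markov chain
#'
#' @param transition Row-stochastic transition matrix with state names.
#' @param n_steps Chain length.
#' @param start Starting state name, or `"stationary"` to draw the first
#'   state from the stationary distribution (computed by eigenvector).
#' @return Character vector of states. Uses the current RNG stream.
#' @export
simulate_markov_chain <- function(transition, n_steps, start = "stationary") {
  states <- rownames(transition)
  if (is.null(states) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    abort("spec error: transition matrix must be row-stochastic with names")
  }
  out <- character(n_steps)
  if (start == "stationary") {
    ev <- eigen(t(transition))
    v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
    p0 <- v / sum(v)
    out[1] <- sample(states, 1, prob = pmax(p0, 0))
  } else {
    if (!start %in% states) abort("unknown start state")
    out[1] <- start
  }
  for (t in seq_len(n_steps - 1)) {
    out[t + 1] <- sample(states, 1, prob = transition[out[t], ])
  }
  out
}

# coil dihedrals drawn from the broad beta/PPII basin so that coil stretches
# never score as helix
draw_coil_phi <- function(n) runif(n, -180, -60)
draw_coil_psi <- function(n) runif(n, 60, 180)

# Rigid coactivator domain: an up-down-up-down four-helix bundle (the shape
# of activator-binding coactivator domains), built from ideal helices packed
# on a square lattice. Rigidity is the point; inter-helix backbone breaks
# are bookkeeping-only and never scored by the analyses.
build_coactivator_bundle <- function(n_res, chain_id = "G") {
  n_helix <- 4L
  per <- n_res %/% n_helix
  lengths <- rep(per, n_helix)
  lengths[n_helix] <- n_res - per * (n_helix - 1)
  seq8 <- "LEALKAQA"
  offsets <- list(c(0, 0), c(11, 0), c(11, 11), c(0, 11))
  atoms <- NULL
  coords <- NULL
  res_offset <- 0L
  for (h in seq_len(n_helix)) {
    seq_h <- substr(strrep(seq8, ceiling(lengths[h] / 8)), 1, lengths[h])
    part <- build_peptide(seq_h, phi = -57, psi = -47, chain_id = chain_id,
                          author_start = res_offset + 1L)
    # align the helix axis with +z (or -z for antiparallel neighbors)
    ca_idx <- select_atoms(part$topology, atom_name = "CA")
    axis <- part$coords[ca_idx[length(ca_idx)], ] - part$coords[ca_idx[1], ]
    target <- if (h %% 2 == 1) c(0, 0, 1) else c(0, 0, -1)
    rot <- rotation_between(axis, target)
    xyz <- part$coords %*% t(rot)
    xyz <- sweep(xyz, 2, colMeans(xyz[ca_idx, , drop = FALSE]))
    xyz <- sweep(xyz, 2, -c(offsets[[h]], 0))
    a <- part$topology$atoms
    a$residue_index <- a$residue_index + res_offset
    atoms <- bind_rows(atoms, a)
    coords <- rbind(coords, xyz)
    res_offset <- res_offset + lengths[h]
  }
  list(topology = topology(atoms), coords = coords,
       helix4_range = c(res_offset - lengths[n_helix], res_offset - 1L))
}

#' Generate a synthetic fuzzy-complex trajectory with ground truth
#'
#' Builds, frame by frame: the peptide from ideal helical dihedrals
#' (-57, -47) on residues whose cooperative block is formed and random
#' beta/PPII-basin dihedrals elsewhere; the rigid coactivator helix, placed
#' so that the anchor dictated by the occupancy chain sits ~3.5 Angstrom
#' from the pocket-floor CA (the rejected anchor beyond the out-threshold,
#' both anchors close for `BOTH`, the whole domain displaced for `NONE`)
#' and so that the coactivator axis makes the drawn orientation angle with
#' the peptide helix axis; then adds isotropic Gaussian noise. Deterministic
#' given `seed`.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; recorded in the output.
#' @return List with `topology`, `frames` (a [frame_series()]), `truth`
#'   (per-frame occupancy states, per-frame per-residue helix states, drawn
#'   orientation angles, stationary distribution, spec, seed) and
#'   `observables` (0-based residue indices of the pocket site, anchors and
#'   suggested helix-vector endpoints for downstream analyses).
#' @export
generate_trajectory <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  n_pep <- nchar(spec$peptide_sequence)
  n_co <- spec$coact_length
  run_len <- spec$n_frames / spec$n_runs

  # rigid coactivator: compact four-helix bundle, built once
  co <- build_coactivator_bundle(n_co, chain_id = "G")
  co_xyz0 <- co$coords

  # peptide topology from a template build (coordinates replaced per frame)
  pep <- build_peptide(spec$peptide_sequence, phi = -57, psi = -47,
                       chain_id = "P", author_start = 1L)
  pep_atoms <- pep$topology$atoms
  pep_atoms$residue_index <- pep_atoms$residue_index + n_co
  top <- topology(bind_rows(co$topology$atoms, pep_atoms))

  pocket_res_global <- spec$pocket_site - 1L          # coactivator chain first
  anchor_a_global <- n_co + spec$anchor_a - 1L
  anchor_b_global <- n_co + spec$anchor_b - 1L
  pocket_ca_local <- select_atoms(co$topology,
                                  residue_index = spec$pocket_site - 1L,
                                  atom_name = "CA")
  # orientation reference: axis of the bundle's last helix ("helix 4"),
  # measured CA-to-CA like the downstream angle observable
  h4 <- co$helix4_range
  co_ca_h4a <- co_xyz0[select_atoms(co$topology, residue_index = h4[1],
                                    atom_name = "CA"), ]
  co_ca_h4b <- co_xyz0[select_atoms(co$topology, residue_index = h4[2],
                                    atom_name = "CA"), ]
  co_axis <- vunit(co_ca_h4b - co_ca_h4a)
  co_ca_all <- select_atoms(co$topology, atom_name = "CA")
  co_cacb_all <- select_atoms(co$topology, atom_name = c("CA", "CB"))
  # outward normal of the pocket site in the bundle frame: from the bundle
  # centroid through the pocket CA; the bundle is kept behind this normal
  co_centroid <- colMeans(co_xyz0[co_ca_all, , drop = FALSE])
  pocket_normal0 <- vunit(co_xyz0[pocket_ca_local, ] - co_centroid)

  # occupancy chain, restarted per run
  tm <- occupancy_transition_matrix(spec)
  occ <- unlist(lapply(seq_len(spec$n_runs), function(r) {
    simulate_markov_chain(tm, run_len, start = spec$start_state)
  }))

  # cooperative helix-block chains, restarted per run
  hb <- spec$helix_blocks
  block_formed <- matrix(FALSE, spec$n_frames, nrow(hb))
  for (b in seq_len(nrow(hb))) {
    p <- hb$p[b]
    m <- spec$helix_mixing
    tmb <- matrix(c(1 - m * p, m * p, m * (1 - p), 1 - m * (1 - p)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("coil", "helix"), c("coil", "helix")))
    for (r in seq_len(spec$n_runs)) {
      idx <- ((r - 1) * run_len + 1):(r * run_len)
      block_formed[idx, b] <-
        simulate_markov_chain(tmb, run_len, start = "stationary") == "helix"
    }
  }

  helix_state <- matrix(FALSE, spec$n_frames, n_pep)
  n_atoms <- top$n_atoms
  coords <- array(NA_real_, dim = c(spec$n_frames, n_atoms, 3))
  theta_drawn <- pmin(pmax(rnorm(spec$n_frames, spec$orientation_mean,
                                 spec$orientation_sd), 1), 179)
  theta_realized <- numeric(spec$n_frames)
  n_co_atoms <- nrow(co_xyz0)
  pep_sel_a_local <- sidechain_or_ca(pep$topology, spec$anchor_a - 1L)
  pep_sel_b_local <- sidechain_or_ca(pep$topology, spec$anchor_b - 1L)
  pep_vec_res <- c(min(hb$start), max(hb$end))  # peptide helix axis endpoints

  for (f in seq_len(spec$n_frames)) {
    # per-residue helix state from formed blocks with end breathing
    h <- rep(FALSE, n_pep)
    for (b in seq_len(nrow(hb))) {
      if (!block_formed[f, b]) next
      s <- hb$start[b]
      e <- hb$end[b]
      if (hb$breathe[b] > 0) {
        if (runif(1) < hb$breathe[b]) s <- s + sample(c(-1L, 1L), 1)
        if (runif(1) < hb$breathe[b]) e <- e + sample(c(-1L, 1L), 1)
      }
      h[max(1, s):min(n_pep, e)] <- TRUE
    }
    helix_state[f, ] <- h
    phi <- ifelse(h, -57, draw_coil_phi(n_pep))
    psi <- ifelse(h, -47, draw_coil_psi(n_pep))
    pep_f <- build_peptide(spec$peptide_sequence, phi = phi, psi = psi,
                           chain_id = "P", author_start = 1L)
    pep_xyz <- pep_f$coords

    cen_a <- colMeans(pep_xyz[pep_sel_a_local, , drop = FALSE])
    cen_b <- colMeans(pep_xyz[pep_sel_b_local, , drop = FALSE])
    mid <- (cen_a + cen_b) / 2
    u_ab <- vunit(cen_b - cen_a)
    d_ab <- vnorm(cen_b - cen_a)
    pep_ca_idx <- select_atoms(pep_f$topology, atom_name = "CA")
    pep_ca_xyz <- pep_xyz[pep_ca_idx, , drop = FALSE]
    pep_cacb_xyz <- pep_xyz[select_atoms(pep_f$topology,
                                         atom_name = c("CA", "CB")), ,
                            drop = FALSE]
    # approach direction: perpendicular to the anchor axis, away from the
    # peptide body, so the domain docks onto the anchor face
    away <- mid - colMeans(pep_ca_xyz)
    away <- away - sum(away * u_ab) * u_ab
    out_dir <- if (vnorm(away) > 1e-6) vunit(away) else
      perpendicular_of(u_ab)
    # pocket-floor CA target by occupancy state: the selected anchor ends
    # up dock_distance from the pocket CA, the rejected one beyond the
    # out-threshold, both within the in-threshold for BOTH
    dk <- spec$dock_distance
    # mostly radial approach (clear of the peptide cylinder) with enough
    # axial lean to keep the rejected anchor beyond the out-threshold
    x_p <- switch(occ[f],
      A_IN = cen_a + vunit(-0.3 * u_ab + 0.954 * out_dir) * dk,
      B_IN = cen_b + vunit(0.3 * u_ab + 0.954 * out_dir) * dk,
      BOTH = mid + out_dir * sqrt(max(dk^2 - (d_ab / 2)^2, 1)),
      NONE = mid + vunit(2 * out_dir + random_unit()) * 25
    )
    # orient the coactivator axis at the drawn angle to the peptide helix
    # axis, tilting about the approach direction: the bundle helices then
    # stay displaced from the peptide along out_dir for every tilt, instead
    # of slicing through it when the tilt plane contains the approach
    ca_i <- pep_xyz[select_atoms(pep_f$topology,
                                 residue_index = pep_vec_res[1] - 1L,
                                 atom_name = "CA"), ]
    ca_j <- pep_xyz[select_atoms(pep_f$topology,
                                 residue_index = pep_vec_res[2] - 1L,
                                 atom_name = "CA"), ]
    pep_axis <- vunit(ca_j - ca_i)
    axis_candidates <- list(
      as.vector(rotation_about(out_dir, theta_drawn[f]) %*% pep_axis),
      as.vector(rotation_about(out_dir, -theta_drawn[f]) %*% pep_axis))
    # bundle azimuth: closed form pointing the pocket's outward normal at
    # the peptide (bundle bulk behind the pocket), plus grid fallbacks;
    # the candidate maximizing the minimum CA/CB separation wins
    u_pf <- vunit(mid - x_p)
    best_d <- -Inf
    co_xyz <- NULL
    realized_axis <- NULL
    for (target_axis in axis_candidates) {
      rot <- rotation_between(co_axis, target_axis)
      n_rot <- as.vector(rot %*% pocket_normal0)
      n_perp <- n_rot - sum(n_rot * target_axis) * target_axis
      az_star <- if (vnorm(n_perp) > 1e-6) {
        atan2(sum(vcross(target_axis, n_perp) * u_pf),
              sum(n_perp * u_pf)) * 180 / pi
      } else 0
      for (az in c(az_star, az_star + 120, az_star - 120)) {
        rot_az <- rotation_about(target_axis, az) %*% rot
        xyz_try <- co_xyz0 %*% t(rot_az)
        xyz_try <- sweep(xyz_try, 2, -(x_p - xyz_try[pocket_ca_local, ]))
        co_cb_xyz <- xyz_try[co_cacb_all, , drop = FALSE]
        dd <- outer(rowSums(co_cb_xyz^2), rowSums(pep_cacb_xyz^2), "+") -
          2 * co_cb_xyz %*% t(pep_cacb_xyz)
        dmin <- sqrt(max(0, min(dd)))
        if (dmin > best_d) {
          best_d <- dmin
          co_xyz <- xyz_try
          realized_axis <- target_axis
        }
      }
    }
    theta_realized[f] <- angle_deg(realized_axis, pep_axis)

    frame_xyz <- rbind(co_xyz, pep_xyz)
    if (spec$noise_sd > 0) {
      frame_xyz <- frame_xyz + matrix(rnorm(length(frame_xyz),
                                            sd = spec$noise_sd),
                                      ncol = 3)
    }
    coords[f, , ] <- frame_xyz
  }

  frames <- frame_series(coords, frame_interval_ns = spec$frame_interval_ns,
                         source = sprintf("synthetic seed %d", seed),
                         run_lengths = rep(run_len, spec$n_runs))
  truth <- list(
    occupancy = factor(occ, levels = c("A_IN", "B_IN", "BOTH", "NONE")),
    helix_state = helix_state,
    block_formed = block_formed,
    orientation_deg = theta_realized,
    orientation_drawn_deg = theta_drawn,
    stationary = spec$occupancy_stationary,
    spec = spec, seed = seed
  )
  observables <- list(
    pocket_residue = pocket_res_global,
    anchor_a = anchor_a_global, anchor_b = anchor_b_global,
    coact_vec = co$helix4_range,
    peptide_vec = n_co + pep_vec_res - 1L,
    peptide_residues = n_co + seq_len(n_pep) - 1L,
    coact_residues = seq_len(n_co) - 1L
  )
  list(topology = top, frames = frames, truth = truth,
       observables = observables)
}

# unit vector perpendicular to u (deterministic construction)
perpendicular_of <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vunit(vcross(u, ref))
}

random_unit <- function() {
  v <- rnorm(3)
  vunit(v)
}

# rotation mapping unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- vunit(a)
  b <- vunit(b)
  ax <- vcross(a, b)
  s <- vnorm(ax)
  if (s < 1e-9) {
    if (sum(a * b) > 0) return(diag(3))
    return(rotation_about(perpendicular_of(a), 180))
  }
  rotation_about(ax, atan2(s, sum(a * b)) * 180 / pi)
}


#' Generate a synthetic variant activity panel
#'
#' Draws random substitutions at mutable positions of a base sequence,
#' computes each variant's mean helicity under the supplied helix-coil
#' parameters, and simulates fold-activation as a linear function of
#' helicity plus Gaussian noise. The generating parameters are returned so
#' regression recovery can be tested.
#'
#' @param n Number of variants (>= 3).
#' @param seed Integer seed.
#' @param slope,intercept,noise_sd Generating model:
#'   `activity = slope * helicity + intercept + N(0, noise_sd)`.
#' @param base_sequence Scaffold sequence.
#' @param mutable_positions 1-based positions where substitutions may occur.
#' @param alphabet Amino acids substitutions are drawn from.
#' @param params [lr_params()] used for helicity.
#' @return List with `panel` (tibble: `id`, `sequence`, `helicity`,
#'   `fold_activation`) and `truth` (slope, intercept, noise_sd, seed).
#' @export
generate_activity_panel <- function(n = 24, seed = 1, slope = 7,
                                    intercept = 5, noise_sd = 10,
                                    base_sequence =
                                      "MKTVLPIPELDDAVWESLFSSGSGSGS",
                                    mutable_positions = 13:20,
                                    alphabet = c("A", "V", "L", "W", "F",
                                                 "S", "E"),
                                    params = lr_params(nterm_acetyl = TRUE,
                                                       cterm_amide = TRUE)) {
  if (n < 3) abort("need n >= 3 variants")
  if (length(mutable_positions) == 0) {
    abort("spec error: no mutable positions")
  }
  set.seed(seed)
  base <- check_sequence(base_sequence)
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    for (p in mutable_positions) {
      if (runif(1) < 0.5) s[p] <- sample(alphabet, 1)
    }
    paste(s, collapse = "")
  }, character(1))
  hel <- vapply(seqs, function(s) mean_helicity(helicity(s, params)),
                numeric(1))
  act <- slope * hel + intercept + rnorm(n, sd = noise_sd)
  panel <- tibble(id = sprintf("variant%02d", seq_len(n)), sequence = seqs,
                  helicity = unname(hel), fold_activation = act)
  list(panel = panel,
       truth = list(slope = slope, intercept = intercept,
                    noise_sd = noise_sd, seed = seed))
}
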