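# Synthetic-trajectory generator: determinism, spec validation, round trips
# and ground-truth closure.

test_that("specs validate their invariants", {
  expect_error(synth_spec(occupancy_stationary = c(0.5, 0.5, 0.5, -0.5)),
               "spec error")
  expect_error(synth_spec(occupancy_mixing = 0), "mixing")
  expect_error(synth_spec(start_state = "SIDEWAYS"), "start_state")
  expect_error(synth_spec(noise_sd = -1), "noise_sd")
  expect_error(synth_spec(n_frames = 10, n_runs = 3), "divisible")
  expect_error(synth_spec(anchor_a = 15, anchor_b = 15), "distinct")
  expect_error(
    synth_spec(helix_blocks = tibble::tibble(start = 5, end = 4, p = 1,
                                             breathe = 0)),
    "helix_blocks")
  tm <- occupancy_transition_matrix(synth_spec())
  expect_equal(rowSums(tm), setNames(rep(1, 4), rownames(tm)))
  # stationarity: pi P = pi exactly by construction
  pi0 <- synth_spec()$occupancy_stationary
  expect_equal(as.numeric(pi0 %*% tm), as.numeric(pi0), tolerance = 1e-12)
  expect_error(simulate_markov_chain(matrix(c(1, 1, 0, 0), 2, 2), 10),
               "spec error")
})

test_that("generation is bit-reproducible given a seed", {
  spec <- synth_spec(n_frames = 20, n_runs = 2)
  g1 <- generate_trajectory(spec, seed = 99)
  g2 <- generate_trajectory(spec, seed = 99)
  expect_identical(g1$frames$coords, g2$frames$coords)
  expect_identical(g1$truth$occupancy, g2$truth$occupancy)
  g3 <- generate_trajectory(spec, seed = 100)
  expect_false(identical(g1$frames$coords, g3$frames$coords))
})

test_that("generated artifacts round-trip through the writers and readers", {
  spec <- synth_spec(n_frames = 6, n_runs = 2)
  g <- generate_trajectory(spec, seed = 7)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_pdb(g$topology, frame_coords(g$frames, 1), pdb)
  write_dcd(g$frames, dcd)
  back_top <- read_pdb_models(pdb)
  expect_equal(back_top$topology$n_atoms, g$topology$n_atoms)
  expect_lt(max(abs(back_top$models[[1]] - frame_coords(g$frames, 1))), 1e-3)
  back_fr <- read_dcd(dcd, g$topology, frame_interval_ns = 10,
                      run_lengths = c(3, 3))
  expect_equal(back_fr$n_frames, 6)
  expect_lt(max(abs(back_fr$coords - g$frames$coords)), 1e-4)
})

test_that("noise-free fully-helical generation satisfies the closure example", {
  # sigma = 0, helix probability 1 everywhere in the block, occupancy
  # pinned to the tryptophan anchor
  spec <- synth_spec(
    n_frames = 40, n_runs = 1, noise_sd = 0,
    helix_blocks = tibble::tibble(start = 10, end = 21, p = 1, breathe = 0),
    occupancy_stationary = c(A_IN = 1, B_IN = 0, BOTH = 0, NONE = 0),
    start_state = "A_IN")
  g <- generate_trajectory(spec, seed = 3)
  ob <- g$observables
  tl <- ss_timeline(g$frames, g$topology, residues = ob$peptide_residues)
  interior <- 80 + (11:19)
  occ <- helical_occupancy(tl, residues = interior)
  expect_gte(attr(occ, "mean_occupancy"), 0.95)
  d_a <- pocket_distance_series(g$frames, g$topology, ob$pocket_residue,
                                ob$anchor_a)
  d_b <- pocket_distance_series(g$frames, g$topology, ob$pocket_residue,
                                ob$anchor_b)
  states <- classify_occupancy(d_a, d_b)
  expect_true(all(states$state == "A_IN"))
})

test_that("occupancy chains reach their stationary distribution", {
  spec <- synth_spec()
  tm <- occupancy_transition_matrix(spec)
  set.seed(123)
  chain <- simulate_markov_chain(tm, 5000, start = "stationary")
  freq <- table(factor(chain, levels = rownames(tm))) / 5000
  pi0 <- spec$occupancy_stationary
  # 3 standard errors, inflated for autocorrelation of the chain
  m <- spec$occupancy_mixing
  ess <- 5000 * m / (2 - m)
  for (s in names(pi0)) {
    se <- sqrt(pi0[[s]] * (1 - pi0[[s]]) / ess)
    expect_lt(abs(freq[[s]] - pi0[[s]]), 3 * se)
  }
})

test_that("activity panels encode the generating regression", {
  # zero noise -> perfect linearity
  gp <- generate_activity_panel(n = 12, seed = 5, noise_sd = 0)
  fit <- correlate_activity(gp$panel)
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1, tolerance = 1e-9)
  expect_equal(suppressWarnings(tidy(fit))$estimate[2], gp$truth$slope,
               tolerance = 1e-6)
  # determinism and distinctness across seeds
  expect_identical(generate_activity_panel(n = 8, seed = 2)$panel,
                   generate_activity_panel(n = 8, seed = 2)$panel)
  expect_false(identical(generate_activity_panel(n = 8, seed = 2)$panel,
                         generate_activity_panel(n = 8, seed = 3)$panel))
  expect_error(generate_activity_panel(n = 2), "n >= 3")
  expect_error(generate_activity_panel(mutable_positions = integer(0)),
               "spec error")
})

test_that("orientation ground truth matches the measured angle observable", {
  spec <- synth_spec(n_frames = 30, n_runs = 1, noise_sd = 0.05)
  g <- generate_trajectory(spec, seed = 14)
  ang <- helix_angle_series(g$frames, g$topology, g$observables$coact_vec,
                            g$observables$peptide_vec)
  expect_lt(median(abs(ang$angle - g$truth$orientation_deg)), 2)
})
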