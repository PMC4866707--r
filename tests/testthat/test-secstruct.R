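# DSSP-style assignment on constructed geometries, timelines, occupancies
# and boundary statistics.

test_that("constructed geometries receive the expected labels", {
  helix <- ideal_helix(15)
  lab <- assign_ss_frame(helix$coords, helix$topology)
  expect_true(all(lab[3:13] == "H"))
  ext <- extended_chain(10)
  lab_e <- assign_ss_frame(ext$coords, ext$topology)
  expect_false(any(lab_e %in% c("H", "G")))
  g310 <- build_peptide(strrep("A", 8), phi = -49, psi = -26)
  lab_g <- assign_ss_frame(g310$coords, g310$topology)
  expect_true(any(lab_g == "G"))
  expect_false(any(lab_g == "H"))
  # polyproline-II-like chain stays coil
  ppii <- build_peptide(strrep("A", 10), phi = -75, psi = 145)
  expect_false(any(assign_ss_frame(ppii$coords, ppii$topology) %in%
                     c("H", "G")))
})

test_that("assignment is invariant under rigid-body motion", {
  set.seed(11)
  helix <- ideal_helix(12)
  rot <- random_rotation()
  moved <- sweep(helix$coords %*% t(rot), 2, -rnorm(3, sd = 50))
  expect_equal(assign_ss_frame(helix$coords, helix$topology),
               assign_ss_frame(moved, helix$topology))
})

test_that("missing backbone atoms degrade to coil with a warning, not failure", {
  helix <- ideal_helix(8)
  keep <- !(helix$topology$atoms$residue_index == 3 &
              helix$topology$atoms$name == "O")
  top2 <- topology(helix$topology$atoms[keep, ])
  expect_warning(lab <- assign_ss_frame(helix$coords[keep, ], top2),
                 "missing backbone")
  expect_equal(lab[4], "C")
  expect_length(lab, 8)
})

test_that("timelines are time-resolved assignments with run annotation", {
  helix <- ideal_helix(12)
  fr <- frames_from(list(helix$coords, helix$coords, helix$coords,
                         helix$coords), interval = 2,
                    run_lengths = c(2, 2))
  tl <- ss_timeline(fr, helix$topology)
  expect_s3_class(tl, "ss_timeline")
  expect_equal(nrow(tl), 4 * 12)
  expect_equal(unique(tl$run), c(1L, 2L))
  expect_equal(unique(tl$time_ns), c(2, 4, 6, 8))
  # static ideal helix: interior helical in every frame
  interior <- dplyr::filter(tl, .data$residue_index %in% 3:8)
  expect_true(all(interior$ss == "H"))
  expect_error(ss_timeline(fr, helix$topology, residues = 99L), "empty")
})

test_that("helical occupancy summarises H (and optionally G) fractions", {
  helix <- ideal_helix(12)
  ext <- extended_chain(12)
  # alternating helix/coil frames -> occupancy 0.5 for interior residues
  fr <- frames_from(list(helix$coords, ext$coords, helix$coords, ext$coords))
  tl <- ss_timeline(fr, helix$topology)
  occ <- helical_occupancy(tl, residues = 4:8)
  expect_equal(occ$occupancy, rep(0.5, 5))
  expect_equal(attr(occ, "mean_occupancy"), 0.5)
  # all-helix timeline -> 1 in the interior
  tl_h <- ss_timeline(frames_from(list(helix$coords, helix$coords)),
                      helix$topology)
  expect_equal(helical_occupancy(tl_h, residues = 4:8)$occupancy, rep(1, 5))
  # counting 3-10 as helical can only increase occupancy
  g310 <- build_peptide(strrep("A", 12), phi = -49, psi = -26)
  tl_g <- ss_timeline(frames_from(list(g310$coords)), g310$topology)
  occ_a <- helical_occupancy(tl_g, include_310 = FALSE)
  occ_ag <- helical_occupancy(tl_g, include_310 = TRUE)
  expect_true(all(occ_ag$occupancy >= occ_a$occupancy))
  expect_gt(attr(occ_ag, "mean_occupancy"), attr(occ_a, "mean_occupancy"))
})

test_that("helix boundaries report modal borders and persistence", {
  spec <- synth_spec(n_frames = 60, n_runs = 1,
                     helix_blocks = tibble::tibble(start = 10, end = 21,
                                                   p = 1, breathe = 0),
                     noise_sd = 0)
  g <- generate_trajectory(spec, seed = 21)
  tl <- ss_timeline(g$frames, g$topology,
                    residues = g$observables$peptide_residues)
  b <- helix_boundaries(tl, min_persistence = 0.5)
  expect_equal(nrow(b), 1)
  expect_equal(b$persistence, 1)
  # assigner trims one residue at each end of a geometric helix block
  expect_lte(abs(b$start_res - (80 + 9)), 1)
  expect_lte(abs(b$end_res - (80 + 20)), 1)

  # partial persistence: block formed ~60% of frames
  spec2 <- synth_spec(n_frames = 200, n_runs = 1,
                      helix_blocks = tibble::tibble(start = 10, end = 21,
                                                    p = 0.6, breathe = 0),
                      helix_mixing = 0.8, noise_sd = 0)
  g2 <- generate_trajectory(spec2, seed = 22)
  tl2 <- ss_timeline(g2$frames, g2$topology,
                     residues = g2$observables$peptide_residues)
  b2 <- helix_boundaries(tl2, min_persistence = 0.3)
  truth_frac <- mean(g2$truth$block_formed[, 1])
  expect_equal(b2$persistence[1], truth_frac, tolerance = 0.05)

  # breathing ends: modal bounds equal the central bounds (ends shift +/- 1
  # in a minority of formed frames)
  spec3 <- synth_spec(n_frames = 150, n_runs = 1,
                      helix_blocks = tibble::tibble(start = 10, end = 21,
                                                    p = 1, breathe = 0.3),
                      noise_sd = 0)
  g3 <- generate_trajectory(spec3, seed = 23)
  tl3 <- ss_timeline(g3$frames, g3$topology,
                     residues = g3$observables$peptide_residues)
  b3 <- helix_boundaries(tl3, min_persistence = 0.5)
  b3c <- helix_boundaries(tl3, min_persistence = 0.5)  # deterministic
  expect_identical(b3, b3c)
  expect_lte(abs(b3$start_res - (80 + 9)), 1)
  expect_lte(abs(b3$end_res - (80 + 20)), 1)
})

test_that("generator helix schedule is recovered in the timeline", {
  spec <- synth_spec(n_frames = 150, n_runs = 1)
  g <- generate_trajectory(spec, seed = 31)
  tl <- ss_timeline(g$frames, g$topology,
                    residues = g$observables$peptide_residues)
  # interior block residues (positions 12..19 of the 10..21 block)
  interior_pos <- 12:19
  m <- ss_matrix(tl)
  agree <- 0
  total <- 0
  for (p in interior_pos) {
    assigned <- m[, as.character(80 + p - 1)] == "H"
    truth <- g$truth$helix_state[, p]
    agree <- agree + sum(assigned == truth)
    total <- total + length(truth)
  }
  expect_gte(agree / total, 0.95)
})
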