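# Geometric observables: distances, angles, occupancy hysteresis,
# superposition, RMSF.

test_that("distance series reduce groups as documented", {
  top <- point_topology(3)
  # coincident atoms -> 0; 3-4-5 triangle -> 5
  co <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0))
  fr <- frames_from(list(co, co))
  expect_equal(distance_series(fr, top, 1, 1)$distance, c(0, 0))
  expect_equal(distance_series(fr, top, 1, 2)$distance, c(5, 5))
  # centroid of a 2-atom group at (0,0,0),(2,0,0) vs point (1,4,0) -> 4
  co2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 4, 0))
  fr2 <- frames_from(list(co2))
  expect_equal(distance_series(fr2, top, c(1, 2), 3)$distance, 4)
  # minimum mode picks the closest pair
  expect_equal(distance_series(fr2, top, c(1, 2), 3, mode = "min")$distance,
               sqrt(17))
  expect_error(distance_series(fr2, top, integer(0), 3), "selection")
})

test_that("helix-axis angles cover the [0, 180] range with symmetries", {
  top <- point_topology(4)
  # CA chain: vectors 1->2 and 3->4
  mk <- function(v1, v2) {
    frames_from(list(rbind(c(0, 0, 0), v1, c(10, 10, 10), c(10, 10, 10) + v2)))
  }
  expect_equal(helix_angle_series(mk(c(0, 0, 1), c(0, 0, 1)), top,
                                  c(0, 1), c(2, 3))$angle, 0)
  expect_equal(helix_angle_series(mk(c(0, 0, 1), c(0, 1, 0)), top,
                                  c(0, 1), c(2, 3))$angle, 90)
  expect_equal(helix_angle_series(mk(c(0, 0, 1), c(0, 0, -1)), top,
                                  c(0, 1), c(2, 3))$angle, 180)
  # swapping the vectors leaves theta unchanged; negating one maps to 180 - theta
  set.seed(4)
  v1 <- rnorm(3)
  v2 <- rnorm(3)
  a12 <- helix_angle_series(mk(v1, v2), top, c(0, 1), c(2, 3))$angle
  a21 <- helix_angle_series(mk(v2, v1), top, c(0, 1), c(2, 3))$angle
  aneg <- helix_angle_series(mk(v1, -v2), top, c(0, 1), c(2, 3))$angle
  expect_equal(a12, a21)
  expect_equal(aneg, 180 - a12)
  # zero-length vector is degenerate
  expect_error(helix_angle_series(mk(c(0, 0, 0), v2), top,
                                  c(0, 1), c(2, 3)), "degenerate")
})

test_that("angles and distances are invariant under rigid motion", {
  set.seed(5)
  top <- point_topology(4)
  co <- matrix(rnorm(12, sd = 5), 4, 3)
  rot <- random_rotation()
  shift <- rnorm(3, sd = 20)
  co2 <- sweep(co %*% t(rot), 2, -shift)
  fr <- frames_from(list(co))
  fr2 <- frames_from(list(co2))
  expect_equal(distance_series(fr, top, c(1, 2), c(3, 4))$distance,
               distance_series(fr2, top, c(1, 2), c(3, 4))$distance,
               tolerance = 1e-10)
  expect_equal(helix_angle_series(fr, top, c(0, 1), c(2, 3))$angle,
               helix_angle_series(fr2, top, c(0, 1), c(2, 3))$angle,
               tolerance = 1e-10)
})

test_that("occupancy classification applies hysteresis and matches the replay oracle", {
  # constant traces
  n <- 20
  all_a <- classify_occupancy(rep(3, n), rep(15, n))
  expect_true(all(all_a$state == "A_IN"))
  expect_true(all(classify_occupancy(rep(3, n), rep(3, n))$state == "BOTH"))
  expect_true(all(classify_occupancy(rep(15, n), rep(15, n))$state == "NONE"))
  # in-band fluctuation keeps the latched state until d_out is crossed
  d_a <- c(10, 6.0, 7.5, 8.4, 7.0, 8.6, 7.5, 6.0)
  st <- classify_occupancy(d_a, rep(20, 8))$state
  expect_equal(as.character(st),
               c("NONE", "A_IN", "A_IN", "A_IN", "A_IN", "NONE", "NONE",
                 "A_IN"))
  # random walks against the brute-force state machine, with run boundaries
  for (seed in 1:5) {
    set.seed(seed)
    da <- cumsum(rnorm(300, sd = 1.2)) + 7.5
    db <- cumsum(rnorm(300, sd = 1.2)) + 7.5
    run <- rep(1:3, each = 100)
    got <- classify_occupancy(da, db, run = run)
    expect_equal(as.character(got$state),
                 replay_occupancy(da, db, 6.5, 8.5, run))
  }
  expect_error(classify_occupancy(1:5, 1:5, d_in = 9, d_out = 8),
               "configuration")
  expect_error(classify_occupancy(1:5, 1:4), "length")
})

test_that("run boundaries reset the occupancy latch", {
  # anchor enters in run 1 and its distance stays in the band into run 2:
  # without a reset the label would carry over
  d_a <- c(5, 7.5, 7.5, 7.5)
  run <- c(1, 1, 2, 2)
  st <- classify_occupancy(d_a, rep(20, 4), run = run)$state
  expect_equal(as.character(st), c("A_IN", "A_IN", "NONE", "NONE"))
})

test_that("superposition recovers rigid motions and matches the quaternion oracle", {
  set.seed(6)
  helix <- ideal_helix(10)
  top <- helix$topology
  ref <- helix$coords
  rot <- rotation_about(c(0, 0, 1), 90)
  moved <- sweep(ref %*% t(rot), 2, -c(5, -3, 8))
  fr <- frames_from(list(ref, moved))
  fit <- superpose(fr, top, reference = 1)
  expect_equal(fit$rmsd$rmsd[1], 0, tolerance = 1e-8)
  expect_equal(fit$rmsd$rmsd[2], 0, tolerance = 1e-8)
  # random deformed pair: Kabsch RMSD equals the quaternion-method value
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(30, sd = 4), 10, 3)
    y <- x + matrix(rnorm(30, sd = 0.8), 10, 3)
    topp <- point_topology(10)
    frp <- frames_from(list(x, y))
    got <- superpose(frp, topp, reference = 1, selection = 1:10)
    expect_equal(got$rmsd$rmsd[2], quaternion_rmsd(x, y), tolerance = 1e-8)
  }
  # degenerate selections
  expect_error(superpose(fr, top, selection = 1:2), "at least 3")
  lin <- frames_from(list(cbind(1:5, 0, 0), cbind(1:5, 0, 0)))
  expect_error(superpose(lin, point_topology(5)), "collinear")
})

test_that("RMSF matches closed forms and refuses single frames", {
  top <- point_topology(2)
  # static trajectory -> all zeros
  co <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(rmsf_profile(frames_from(list(co, co, co)), top)$rmsf,
               c(0, 0))
  # one atom alternating +/- 1 A on x around its mean -> RMSF exactly 1
  up <- rbind(c(1, 0, 0), c(5, 0, 0))
  dn <- rbind(c(-1, 0, 0), c(5, 0, 0))
  expect_equal(rmsf_profile(frames_from(list(up, dn, up, dn)), top)$rmsf,
               c(1, 0))
  expect_error(rmsf_profile(frames_from(list(co)), top), "single frame")
  # isotropic Gaussian jitter sigma_i per residue -> RMSF ~= sigma * sqrt(3)
  set.seed(7)
  sig <- c(0.2, 0.5, 1.0)
  base <- cbind(seq(0, 20, length.out = 3), 0, 0)
  n_fr <- 2000
  frames <- lapply(seq_len(n_fr), function(i) {
    base + matrix(rnorm(9, sd = rep(sig, 3)), 3, 3)
  })
  prof <- rmsf_profile(frames_from(frames), point_topology(3))
  expect_equal(prof$rmsf, sig * sqrt(3), tolerance = 0.05)
})
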