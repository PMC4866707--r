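# Lifson-Roig helicity, variant bookkeeping and the activity regression.

test_that("transfer-matrix helicity equals exhaustive enumeration", {
  params_plain <- lr_params()
  params_caps <- lr_params(nterm_acetyl = TRUE, cterm_amide = TRUE)
  seqs <- c("AAAA", "MKTVLPIP", "WWWWLFWS", "GGGGGG", "PAPAPA", "KWIKWYE")
  for (sq in seqs) {
    for (p in list(params_plain, params_caps)) {
      got <- helicity(sq, p)
      oracle <- enum_lr(sq, p)
      expect_equal(exp(attr(got, "log_z")), oracle$z, tolerance = 1e-12)
      expect_equal(got$p_helix, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("helicity behaves as the model dictates at its limits", {
  # all w = 0: no residue can occupy a regular helical state
  zero_tab <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(aa = c("A", "R", "N", "D", "C", "Q", "E",
                                         "G", "H", "I", "L", "K", "M", "F",
                                         "P", "S", "T", "W", "Y", "V"),
                                  w300 = 0, dh = -0.9), zero_tab)
  h0 <- helicity("AAAAAAA", lr_params(path = zero_tab))
  expect_equal(h0$p_helix, rep(0, 7))
  expect_equal(mean_helicity(h0), 0)
  # probabilities live in [0, 1] and the partition function is positive
  h <- helicity(strrep("A", 30), lr_params())
  expect_true(all(h$p_helix >= 0 & h$p_helix <= 1))
  expect_true(is.finite(attr(h, "log_z")))
  # homopolymer helicity strictly increases with w
  mh <- vapply(c(0.8, 1.2, 1.6, 2.0), function(w) {
    tab <- withr::local_tempfile(fileext = ".tsv")
    readr::write_tsv(tibble::tibble(aa = names(fuzzytraj:::aa_three),
                                    w300 = w, dh = -0.9), tab)
    mean_helicity(helicity(strrep("A", 20), lr_params(path = tab)))
  }, numeric(1))
  expect_true(all(diff(mh) > 0))
  # terminal blocking never decreases homopolymer helicity (bundled set)
  base <- mean_helicity(helicity(strrep("A", 15), lr_params()))
  nc <- mean_helicity(helicity(strrep("A", 15),
                               lr_params(nterm_acetyl = TRUE)))
  both <- mean_helicity(helicity(strrep("A", 15),
                                 lr_params(nterm_acetyl = TRUE,
                                           cterm_amide = TRUE)))
  expect_gte(nc, base)
  expect_gte(both, nc)
  expect_error(helicity("AXB", lr_params()), "unknown amino-acid")
})

test_that("temperature rescales weights through the enthalpy term", {
  cold <- mean_helicity(helicity(strrep("A", 20),
                                 lr_params(temperature = 280)))
  warm <- mean_helicity(helicity(strrep("A", 20),
                                 lr_params(temperature = 320)))
  expect_gt(cold, warm)  # helix formation is exothermic in the bundled set
})

test_that("variant substitutions are positional with author numbering", {
  tab <- table2_sequences()
  s07 <- tab$sequence[tab$id == "cAD-like07"]
  s96 <- tab$sequence[tab$id == "cAD-like96"]
  subs <- variant_substitutions(s07, s96, author_start = 80L)
  expect_equal(nrow(subs), 4)
  expect_true(all(subs$to == "W"))
  expect_equal(subs$author_number, c(93L, 95L, 96L, 99L))
  expect_equal(nrow(variant_substitutions(s07, s07)), 0)
  one <- variant_substitutions("AAAA", "AAWA")
  expect_equal(one$position, 3L)
  expect_equal(one$from, "A")
  expect_equal(one$to, "W")
  expect_error(variant_substitutions("AAA", "AAAA"), "alignment")
})

test_that("bundled variant helicities follow the activity ordering", {
  tab <- table2_sequences()
  params <- lr_params(nterm_acetyl = TRUE, cterm_amide = TRUE)
  mh <- vapply(tab$sequence, function(s) mean_helicity(helicity(s, params)),
               numeric(1))
  names(mh) <- tab$id
  expect_gt(mh[["cAD-like96"]], mh[["cAD-like07"]])
  expect_gt(mh[["cAD-like07"]], mh[["GCN4_81_100"]])
  # the strong variant is not marginally stronger: several-fold difference
  expect_gt(mh[["cAD-like96"]] / mh[["cAD-like07"]], 2)
})

test_that("the activity regression handles exact, degenerate and noisy panels", {
  # exactly collinear points -> r^2 = 1
  d <- tibble::tibble(helicity = c(1, 2, 3, 4), fold_activation = c(3, 5, 7, 9))
  fit <- correlate_activity(d)
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1,
               tolerance = 1e-12)
  expect_equal(suppressWarnings(tidy(fit))$estimate, c(1, 2),
               tolerance = 1e-10)
  # prediction intervals bracket the data for a perfect fit
  expect_true(all(fit$data$.pi_lower <= d$fold_activation + 1e-9))
  expect_true(all(fit$data$.pi_upper >= d$fold_activation - 1e-9))
  expect_error(correlate_activity(d[1:2, ]), "at least 3")
  expect_error(correlate_activity(
    tibble::tibble(helicity = rep(2, 5), fold_activation = 1:5)),
    "zero variance")
  # slope-zero panel with noise: r^2 near zero, slope CI covers zero
  set.seed(17)
  null_d <- tibble::tibble(helicity = runif(40, 0, 20),
                           fold_activation = rnorm(40, 10, 3))
  null_fit <- correlate_activity(null_d)
  expect_lt(glance(null_fit)$r.squared, 0.2)
  ci <- tidy(null_fit)
  expect_true(ci$conf.low[2] < 0 && ci$conf.high[2] > 0)
})
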