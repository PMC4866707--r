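# Sequence-based alpha-helical propensity via the Lifson-Roig helix-coil
# model, evaluated exactly by a transfer matrix over (previous, current)
# residue-state pairs, plus the propensity-vs-transactivation regression.
#
# Statistical weights follow the Lifson-Roig convention: a residue in the
# helical state bordered by helical residues on both sides carries its helix
# weight w; helical residues at helix ends carry the nucleation weight v;
# coil residues carry 1. "Helicity" of a residue is the probability of being
# in a w-state (regular helix interior), the quantity that tracks measurable
# helix content.

#' Helix-coil model parameters
#'
#' Loads the bundled literature-informed weight table (a short-helix scale
#' in which tryptophan is a strong helix former) and applies a van 't Hoff
#' temperature correction `w(T) = w(300) * exp((dh/R)(1/300 - 1/T))` with a
#' per-residue helix-formation enthalpy `dh` (kcal/mol). pH and ionic
#' strength are accepted and recorded for provenance but do not modify the
#' weights; only temperature does (documented limitation).
#'
#' @param temperature Kelvin, default 300.
#' @param v Nucleation weight, default 0.048.
#' @param nterm_acetyl,cterm_amide Terminal-blocking flags; a blocked
#'   terminus multiplies the nucleation weight of a helix reaching that
#'   terminus by the corresponding cap factor (>= 1).
#' @param ncap_factor,ccap_factor Cap modifiers for blocked termini.
#' @param path Optional TSV overriding the bundled table (columns `aa`,
#'   `w300`, `dh`).
#' @param ph,ionic_strength Recorded, not used.
#' @return Object of class `helix_coil_params`.
#' @export
lr_params <- function(temperature = 300, v = 0.048,
                      nterm_acetyl = FALSE, cterm_amide = FALSE,
                      ncap_factor = 1.6, ccap_factor = 1.3,
                      path = NULL, ph = 7.0, ionic_strength = 0.15) {
  if (is.null(path)) {
    path <- system.file("extdata", "helix_weights_synthetic.tsv",
                        package = "fuzzytraj", mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("aa", "w300", "dh") %in% names(tab))) {
    abort("weight table needs columns aa, w300, dh")
  }
  if (any(tab$w300 < 0) || v < 0) abort("helix weights must be >= 0")
  missing <- setdiff(names(aa_three), tab$aa)
  if (length(missing) > 0) {
    abort(paste0("weight table lacks amino acid(s): ",
                 paste(missing, collapse = ", ")))
  }
  R <- 0.0019872  # kcal / (mol K)
  w <- tab$w300 * exp((tab$dh / R) * (1 / 300 - 1 / temperature))
  structure(
    list(w = setNames(w, tab$aa), v = v,
         nterm_acetyl = nterm_acetyl, cterm_amide = cterm_amide,
         ncap_factor = ncap_factor, ccap_factor = ccap_factor,
         temperature = temperature, ph = ph,
         ionic_strength = ionic_strength),
    class = "helix_coil_params")
}

#' @export
print.helix_coil_params <- function(x, ...) {
  cat(sprintf(
    "<helix_coil_params> T = %g K, v = %g, caps: N%s/C%s\n",
    x$temperature, x$v,
    if (x$nterm_acetyl) "+ (acetyl)" else "-",
    if (x$cterm_amide) "+ (amide)" else "-"))
  invisible(x)
}

# Lifson-Roig statistical weight of residue i given the state triple
# (prev, cur, next); states TRUE = helical. Cap factors apply to helical
# residues at blocked termini.
lr_weight <- function(i, n, prev, cur, nxt, w_i, params) {
  if (!cur) return(1)
  u <- if (prev && nxt) w_i else params$v
  if (i == 1 && params$nterm_acetyl) u <- u * params$ncap_factor
  if (i == n && params$cterm_amide) u <- u * params$ccap_factor
  u
}

#' Per-residue helicity of a sequence
#'
#' Exact Lifson-Roig evaluation by a transfer matrix over the four
#' (previous, current) state pairs with coil boundary states. The
#' per-residue helix probability is the probability of the residue being in
#' a regular (w-state) helical conformation; mean helicity is its average
#' over the sequence, in percent.
#'
#' @param sequence One-letter amino-acid string.
#' @param params A [lr_params()] object.
#' @return Tibble of class `helicity` with columns `position` (1-based),
#'   `aa`, `p_helix`; attributes `mean_helicity_pct` and `log_z`.
#' @examples
#' h <- helicity("MKTVLPIPELDDAWWWWLFWSGSGSGS", lr_params(nterm_acetyl = TRUE,
#'                                                        cterm_amide = TRUE))
#' mean_helicity(h)
#' @export
helicity <- function(sequence, params = lr_params()) {
  stopifnot(inherits(params, "helix_coil_params"))
  letters1 <- check_sequence(sequence)
  n <- length(letters1)
  w <- unname(params$w[letters1])
  # pair states: 1 = cc, 2 = ch, 3 = hc, 4 = hh as (s_{i-1}, s_i)
  pair_prev <- c(FALSE, FALSE, TRUE, TRUE)
  pair_cur <- c(FALSE, TRUE, FALSE, TRUE)
  mat_at <- function(i) {
    m <- matrix(0, 4, 4)
    for (a in 1:4) {
      for (b in 1:4) {
        if (pair_cur[a] != pair_prev[b]) next  # chain consistency
        m[a, b] <- lr_weight(i, n, pair_prev[a], pair_cur[a], pair_cur[b],
                             w[i], params)
      }
    }
    m
  }
  # forward: f[[i]] over pairs (s_i, s_{i+1}); f[[0]] fixes s_0 = coil
  f <- vector("list", n + 1)
  f[[1]] <- c(1, 1, 0, 0)  # (s_0 = c, s_1 in {c, h}), weights applied later
  for (i in seq_len(n)) f[[i + 1]] <- as.vector(f[[i]] %*% mat_at(i))
  # backward: b[[i]] over pairs (s_i, s_{i+1}) completing i+1..n, s_{n+1} = c
  b <- vector("list", n + 1)
  b[[n + 1]] <- c(1, 0, 1, 0)  # s_{n+1} must be coil
  for (i in rev(seq_len(n))) b[[i]] <- as.vector(mat_at(i) %*% b[[i + 1]])
  z <- sum(f[[n + 1]] * b[[n + 1]])
  if (z <= 0) abort("degenerate partition function")
  # P(residue i in w-state) = f_{i-1}[hh] * w_i * b_i[hh] / Z
  p <- numeric(n)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      p[i] <- f[[i]][4] * w[i] * b[[i + 1]][4] / z
    }
  }
  out <- tibble(position = seq_len(n), aa = letters1, p_helix = p)
  attr(out, "mean_helicity_pct") <- 100 * mean(p)
  attr(out, "log_z") <- log(z)
  class(out) <- c("helicity", class(out))
  out
}

#' Mean helicity in percent
#'
#' @param x A [helicity()] result.
#' @return Numeric scalar (percent).
#' @export
mean_helicity <- function(x) {
  stopifnot(inherits(x, "helicity"))
  attr(x, "mean_helicity_pct")
}

#' Positional substitutions between two equal-length variants
#'
#' No alignment is attempted: unequal lengths are an error.
#'
#' @param seq_a,seq_b One-letter sequences of equal length.
#' @param author_start Author number of position 1 (for reporting in
#'   deposited numbering), default 1.
#' @return Tibble with columns `position`, `author_number`, `from`, `to`.
#' @export
variant_substitutions <- function(seq_a, seq_b, author_start = 1L) {
  a <- check_sequence(seq_a)
  b <- check_sequence(seq_b)
  if (length(a) != length(b)) {
    abort("alignment error: sequences differ in length")
  }
  pos <- which(a != b)
  tibble(position = pos, author_number = author_start + pos - 1L,
         from = a[pos], to = b[pos])
}

#' Load a variant activity table
#'
#' @param path TSV with columns `id`, `sequence`, `fold_activation`;
#'   `NULL` loads the bundled table of cAD-like variants with their
#'   reporter-gene fold-induction values.
#' @return Tibble of class `activity_table`.
#' @export
load_activity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cad_variants.tsv",
                        package = "fuzzytraj", mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "sequence", "fold_activation") %in% names(tab))) {
    abort("activity table needs columns id, sequence, fold_activation")
  }
  if (any(tab$fold_activation <= 0)) abort("fold_activation must be > 0")
  if (length(unique(nchar(tab$sequence))) != 1) {
    abort("sequences in one panel must have equal length")
  }
  class(tab) <- c("activity_table", class(tab))
  tab
}

#' Regress transactivation potential on helical propensity
#'
#' Ordinary least squares of fold-activation on mean helicity across a
#' variant panel, with the 95% prediction interval (t-distribution, n - 2
#' degrees of freedom) per point.
#'
#' @param data Data frame with one row per variant.
#' @param helicity_col,activity_col Column names (strings) holding mean
#'   helicity (%) and fold-activation.
#' @param level Prediction-interval level, default 0.95.
#' @return Object of class `activity_fit`: list with `model` (the `lm`),
#'   `data` (input plus `.fitted`, `.pi_lower`, `.pi_upper`), `level`.
#' @export
correlate_activity <- function(data, helicity_col = "helicity",
                               activity_col = "fold_activation",
                               level = 0.95) {
  data <- as_tibble(data)
  if (nrow(data) < 3) abort("need at least 3 variants for a regression")
  x <- data[[helicity_col]]
  y <- data[[activity_col]]
  if (is.null(x) || is.null(y)) abort("helicity/activity column not found")
  if (sd(x) < 1e-12) {
    abort("degenerate regression: helicity has zero variance")
  }
  df <- tibble(helicity = x, activity = y)
  fit <- lm(activity ~ helicity, data = df)
  pred <- suppressWarnings(
    predict(fit, interval = "prediction", level = level))
  out_data <- mutate(data, .fitted = pred[, "fit"],
                     .pi_lower = pred[, "lwr"], .pi_upper = pred[, "upr"])
  structure(list(model = fit, data = out_data, level = level,
                 helicity_col = helicity_col, activity_col = activity_col),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<activity_fit> n = %d, slope = %.4g, intercept = %.4g, r^2 = %.3f\n",
    g$nobs, coef(x$model)[2], coef(x$model)[1], g$r.squared))
  invisible(x)
}

#' Tidy an activity regression
#'
#' @param x An [correlate_activity()] fit.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, statistic,
#'   p-value and confidence bounds.
#' @export
tidy.activity_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  ci <- stats::confint(x$model, level = x$level)
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std.error = unname(s[, 2]), statistic = unname(s[, 3]),
         p.value = unname(s[, 4]),
         conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]))
}

#' Model-level summary of an activity regression
#'
#' @param x An [correlate_activity()] fit.
#' @param ... Unused.
#' @return One-row tibble with `r.squared`, `adj.r.squared`, `sigma`,
#'   `nobs`, `df.residual`.
#' @export
glance.activity_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, nobs = length(s$residuals),
         df.residual = x$model$df.residual)
}
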