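# Independent oracles used to cross-check the package's implementations.
# Each is written directly from the defining formula or by brute force and
# shares no code with the implementation it checks.

# --- exhaustive Lifson-Roig enumeration (2^n states) ---------------------
enum_lr <- function(sequence, params) {
  l <- strsplit(sequence, "")[[1]]
  n <- length(l)
  w <- unname(params$w[l])
  z <- 0
  ph <- numeric(n)
  for (mask in 0:(2^n - 1)) {
    s <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    wt <- 1
    for (i in seq_len(n)) {
      if (!s[i]) next
      prev <- if (i == 1) FALSE else s[i - 1]
      nxt <- if (i == n) FALSE else s[i + 1]
      u <- if (prev && nxt) w[i] else params$v
      if (i == 1 && params$nterm_acetyl) u <- u * params$ncap_factor
      if (i == n && params$cterm_amide) u <- u * params$ccap_factor
      wt <- wt * u
    }
    z <- z + wt
    for (i in seq_len(n)) {
      prev <- if (i == 1) FALSE else s[i - 1]
      nxt <- if (i == n) FALSE else s[i + 1]
      if (s[i] && prev && nxt) ph[i] <- ph[i] + wt
    }
  }
  list(z = z, p = ph / z)
}

# --- naive per-point 3-D binning loop ------------------------------------
naive_bin3d <- function(points, edges) {
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  counts <- array(0L, dim = dims)
  vals <- cbind(points$angle, points$d_a, points$d_b)
  for (r in seq_len(nrow(vals))) {
    idx <- integer(3)
    for (k in 1:3) {
      e <- edges[[k]]
      i <- NA_integer_
      for (b in seq_len(length(e) - 1)) {
        closed_top <- b == length(e) - 1
        if (vals[r, k] >= e[b] &&
            (vals[r, k] < e[b + 1] ||
             (closed_top && vals[r, k] <= e[b + 1]))) {
          i <- b
          break
        }
      }
      idx[k] <- i
    }
    if (!anyNA(idx)) counts[idx[1], idx[2], idx[3]] <-
        counts[idx[1], idx[2], idx[3]] + 1L
  }
  counts
}

# --- naive two-threshold occupancy replay --------------------------------
replay_occupancy <- function(d_a, d_b, d_in, d_out, run = NULL) {
  n <- length(d_a)
  if (is.null(run)) run <- rep(1L, n)
  a_in <- FALSE
  b_in <- FALSE
  out <- character(n)
  for (t in seq_len(n)) {
    if (t == 1 || run[t] != run[t - 1]) {
      a_in <- FALSE
      b_in <- FALSE
    }
    if (a_in) {
      if (d_a[t] > d_out) a_in <- FALSE
    } else {
      if (d_a[t] < d_in) a_in <- TRUE
    }
    if (b_in) {
      if (d_b[t] > d_out) b_in <- FALSE
    } else {
      if (d_b[t] < d_in) b_in <- TRUE
    }
    out[t] <- if (a_in && b_in) "BOTH" else if (a_in) "A_IN" else
      if (b_in) "B_IN" else "NONE"
  }
  out
}

# --- quaternion-method optimal RMSD (Horn 1987) --------------------------
quaternion_rmsd <- function(x, y) {
  # x, y: N x 3; returns minimal RMSD of y onto x over rigid motions
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  S <- t(yc) %*% xc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda_max <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lambda_max) / nrow(x)
  sqrt(max(0, msd))
}

# --- brute-force all-pairs intermolecular energy sum ---------------------
brute_pair_sum <- function(coords, atoms, idx_a, idx_b,
                           dielectric = "distance") {
  vdw <- 0
  elec <- 0
  for (i in idx_a) {
    for (j in idx_b) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      eps <- sqrt(atoms$epsilon[i] * atoms$epsilon[j])
      sig <- (atoms$sigma[i] + atoms$sigma[j]) / 2
      vdw <- vdw + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      elec <- elec + if (dielectric == "distance") {
        332.0636 * atoms$charge[i] * atoms$charge[j] / (4 * r^2)
      } else {
        332.0636 * atoms$charge[i] * atoms$charge[j] / r
      }
    }
  }
  c(vdw = vdw, elec = elec)
}
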