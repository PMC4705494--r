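# Independent brute-force oracles. Deliberately dumb double loops over
# explicit index windows, sharing no code with the package implementations.

oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    nt <- length(x) - mm + 1
    cnt <- numeric(nt)
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) {
          cnt[i] <- cnt[i] + 1
        }
      }
    }
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in seq(i + 1, nt)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A > 0 && B > 0) -log(A / B) else NA_real_
}

oracle_rqa <- function(x, m, tau, r_factor, lmin) {
  n <- length(x)
  M <- n - (m - 1) * tau
  r <- r_factor * sqrt(m) * sd(x)
  R <- matrix(FALSE, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      vi <- x[i + (seq_len(m) - 1) * tau]
      vj <- x[j + (seq_len(m) - 1) * tau]
      R[i, j] <- sqrt(sum((vi - vj)^2)) <= r
    }
  }
  n_rec <- sum(R) - M
  rec <- 100 * n_rec / (M^2 - M)
  if (n_rec == 0) {
    return(list(RPLmean = NA_real_, RPLmax = NA_real_, RPREC = 0,
                RPDET = NA_real_, RPShan = NA_real_))
  }
  lens <- integer(0)
  for (k in seq_len(M - 1)) {          # upper diagonals, scanned element-wise
    run <- 0L
    for (i in seq_len(M - k)) {
      if (R[i, i + k]) {
        run <- run + 1L
      } else {
        if (run > 0L) lens <- c(lens, run)
        run <- 0L
      }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  dl <- lens[lens >= lmin]
  det <- 100 * 2 * sum(dl) / n_rec
  if (length(dl) == 0) {
    return(list(RPLmean = NA_real_, RPLmax = NA_real_, RPREC = rec,
                RPDET = det, RPShan = NA_real_))
  }
  tb <- table(dl)
  p <- as.numeric(tb) / length(dl)
  list(RPLmean = mean(dl), RPLmax = max(dl), RPREC = rec, RPDET = det,
       RPShan = -sum(p * log(p)))
}

# R-native IRLS mirroring the documented algorithm, to pin down the
# compiled fitter exactly.
oracle_irls <- function(X, y, tune = 4.685, tol = 1e-8, maxit = 50) {
  p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  b <- XtXinv %*% crossprod(X, y)
  h <- pmin(pmax(rowSums((X %*% XtXinv) * X), 0), 0.9999)
  adj <- 1 / sqrt(1 - h)
  for (it in seq_len(maxit)) {
    radj <- as.numeric(y - X %*% b) * adj
    a <- sort(abs(radj))
    s <- median(a[min(p, length(a)):length(a)]) / 0.6745
    if (s < 1e-12) break
    u <- radj / (tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) < 1e-10) break
    bnew <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    delta <- max(abs(bnew - b))
    b <- bnew
    if (delta < tol) break
  }
  as.numeric(b)
}

# Small synthetic predictive data.frame with named feature columns (no HRV
# extraction involved) for fast regression/selection tests.
make_pred_frame <- function(n_sub, n_reps, features, gen_y, seed = 1) {
  set.seed(seed)
  n <- n_sub * n_reps
  df <- data.frame(sub_id = rep(seq_len(n_sub), each = n_reps),
                   test_id = rep(seq_len(n_reps), n_sub))
  for (f in features) df[[f]] <- rnorm(n, mean = 10, sd = 3)
  df$delta_sys <- gen_y(df)
  df
}
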