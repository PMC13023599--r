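# Shared fixtures and independent oracles used across the suite.

# A cosine tone as a sampled_signal.
make_tone <- function(f0 = 0.25, amp = 1, duration = 120, fs = 100,
                      phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  sampled_signal(amp * cos(2 * pi * f0 * t + phase), fs = fs)
}

interior_idx <- function(n, fs, guard_s = 10) {
  g <- round(guard_s * fs)
  seq.int(g + 1, n - g)
}

# Independent natural cubic spline: solve the tridiagonal second-derivative
# system directly (natural boundary: M_1 = M_n = 0), then evaluate.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i] <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    b[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  M <- solve(A, b)
  vapply(xout, function(xx) {
    j <- max(which(x <= xx)); j <- min(j, n - 1)
    hj <- h[j]; a <- (x[j + 1] - xx) / hj; bq <- (xx - x[j]) / hj
    a * y[j] + bq * y[j + 1] +
      ((a^3 - a) * M[j] + (bq^3 - bq) * M[j + 1]) * hj^2 / 6
  }, numeric(1))
}

# Rank-then-Pearson Spearman oracle with average ranks, from the raw
# product-moment sums.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(rx)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Brute-force one-way within-subject ANOVA from explicit grand/row/column
# means.
oracle_rm_anova <- function(z) {
  n <- nrow(z); k <- ncol(z)
  g <- mean(z)
  ss_m <- n * sum((colMeans(z) - g)^2)
  ss_s <- k * sum((rowMeans(z) - g)^2)
  ss_t <- sum((z - g)^2)
  ss_e <- ss_t - ss_m - ss_s
  f <- (ss_m / (k - 1)) / (ss_e / ((k - 1) * (n - 1)))
  list(F = f,
       p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE),
       eta = ss_m / (ss_m + ss_e))
}

# Paired t test from the explicit difference-vector formulas.
oracle_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  se <- sd(d) / sqrt(n)
  tv <- mean(d) / se
  list(mean = mean(d), se = se, t = tv,
       p = 2 * pt(-abs(tv), n - 1))
}

# Match detected peaks to true beats within a tolerance; returns
# sensitivity, positive predictivity and worst matched timing error.
match_beats <- function(true_t, det_t, tol_s = 0.05) {
  used <- logical(length(det_t))
  err <- rep(NA_real_, length(true_t))
  for (i in seq_along(true_t)) {
    j <- which(!used & abs(det_t - true_t[i]) <= tol_s)
    if (length(j) > 0) {
      j <- j[which.min(abs(det_t[j] - true_t[i]))]
      used[j] <- TRUE
      err[i] <- abs(det_t[j] - true_t[i])
    }
  }
  tp <- sum(!is.na(err))
  list(sensitivity = tp / length(true_t),
       ppv = tp / length(det_t),
       max_err_s = if (tp > 0) max(err, na.rm = TRUE) else NA_real_)
}
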