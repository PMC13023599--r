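# Within-participant Spearman correlations between respiratory measures
# and parasympathetic indices, Fisher z, and the group-level
# repeated-measures comparison with Bonferroni pairwise tests.

#' Align a respiratory measure with an HRV grid
#'
#' Evaluates a uniformly sampled respiratory measure at the HRV grid
#' times.  When each grid time falls exactly on a sample (the usual case:
#' a 0.1 s grid against a 500 Hz channel) the sample is picked directly;
#' otherwise linear interpolation is used (the measures are band-limited
#' far below the sampling rate, so the two paths agree to rounding).
#'
#' @param values respiratory measure samples.
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample, seconds.
#' @param grid_times HRV grid times, seconds.
#' @return measure values on the grid (`NA` outside the sample support).
#' @export
align_measure <- function(values, fs, t0, grid_times) {
  pos <- (grid_times - t0) * fs + 1
  idx <- round(pos)
  out <- rep(NA_real_, length(grid_times))
  exact <- abs(pos - idx) < 1e-6 & idx >= 1 & idx <= length(values)
  out[exact] <- values[idx[exact]]
  if (any(!exact)) {
    t_samp <- t0 + (seq_along(values) - 1) / fs
    out[!exact] <- stats::approx(t_samp, values, xout = grid_times[!exact],
                                 rule = 1, ties = "ordered")$y
  }
  out
}

#' Pairwise-complete alignment of one measure/index pair
#'
#' Drops guard-band grid points and any point where either series is
#' missing; both outputs share one index set.
#'
#' @param measure_on_grid measure values on the HRV grid (from
#'   [align_measure()]).
#' @param index_values HRV index values on the same grid.
#' @param grid_times the grid, seconds.
#' @param guard_lo,guard_hi time bounds of the usable interior, seconds.
#' @return list `x`, `y`, `n_pairs`.
#' @export
align_pairs <- function(measure_on_grid, index_values, grid_times,
                        guard_lo = -Inf, guard_hi = Inf) {
  keep <- grid_times >= guard_lo & grid_times <= guard_hi &
    !is.na(measure_on_grid) & !is.na(index_values)
  list(x = measure_on_grid[keep], y = index_values[keep],
       n_pairs = sum(keep))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (tie-aware).  Constant
#' input has no defined rank correlation and returns `NA`.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return rho in `[-1, 1]`, or `NA`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Fisher z transform
#'
#' `atanh(rho)`, variance-stabilizing for group statistics.  `|rho| = 1`
#' (possible on short or perfectly monotone series) is clipped to
#' `1 - 1e-7` with a warning so z stays finite.
#'
#' @param rho correlation(s).
#' @return z value(s).
#' @export
fisher_z <- function(rho) {
  hit <- !is.na(rho) & abs(rho) >= 1 - 1e-7
  if (any(hit)) {
    warning("|rho| >= 1 - 1e-7 clipped before Fisher z")
    rho[hit] <- sign(rho[hit]) * (1 - 1e-7)
  }
  atanh(rho)
}

#' Per-subject correlation matrix between respiratory measures and
#' parasympathetic indices
#'
#' Spearman rho and Fisher z for each of the 3 x 3 cells
#' (waveform, amplitude, inverted rate) x (log HF, RMSSD, CVI), computed
#' on the pairwise-complete interior grid.  Cells with fewer than
#' `min_pairs` usable points are set `NA`.
#'
#' @param decomp a `resp_decomposition`.
#' @param track an `hrv_track` from the same recording.
#' @param min_pairs minimum usable grid points per cell (default 100).
#' @param thin use every `thin`-th grid point (default 1 = all points;
#'   the grid is heavily autocorrelated, so thinning changes effective
#'   resolution, not the estimand).
#' @return object of class `subject_correlations`: matrices `rho` and
#'   `z` (3 x 3, dimnames measures x indices) and `n_pairs`.
#' @export
subject_correlations <- function(decomp, track, min_pairs = 100, thin = 1) {
  stopifnot(inherits(decomp, "resp_decomposition"),
            inherits(track, "hrv_track"))
  n <- length(decomp$preprocessed)
  lo <- decomp$t0 + decomp$guard_s
  hi <- decomp$t0 + (n - 1) / decomp$fs - decomp$guard_s
  grid <- track$grid_times
  sel <- seq(1, length(grid), by = thin)
  measures <- list(
    waveform = align_measure(decomp$preprocessed, decomp$fs, decomp$t0,
                             grid[sel]),
    amplitude = align_measure(decomp$amplitude, decomp$fs, decomp$t0,
                              grid[sel]),
    rate = align_measure(decomp$rate_inverted, decomp$fs, decomp$t0,
                         grid[sel]))
  indices <- list(hf = track$hf_log[sel], rmssd = track$rmssd_ms[sel],
                  cvi = track$cvi[sel])
  rho <- z <- np <- matrix(NA_real_, 3, 3,
                           dimnames = list(names(measures), names(indices)))
  for (m in seq_along(measures)) {
    for (k in seq_along(indices)) {
      pr <- align_pairs(measures[[m]], indices[[k]], grid[sel],
                        guard_lo = lo, guard_hi = hi)
      np[m, k] <- pr$n_pairs
      if (pr$n_pairs >= min_pairs) {
        rho[m, k] <- spearman_corr(pr$x, pr$y)
        z[m, k] <- fisher_z(rho[m, k])
      }
    }
  }
  structure(list(rho = rho, z = z, n_pairs = np),
            class = "subject_correlations")
}

#' @export
print.subject_correlations <- function(x, ...) {
  cat("<subject_correlations> Spearman rho (n_pairs in first cell:",
      x$n_pairs[1, 1], ")\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA on a subjects x measures matrix (here: Fisher z
#' correlations for the three respiratory measures).  Sums of squares are
#' decomposed directly: `SS_error = SS_total - SS_measure - SS_subject`,
#' `F = MS_measure / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom, and `partial eta^2 = SS_measure / (SS_measure + SS_error)`.
#' No sphericity correction is applied by default (the uncorrected df are
#' the conventional report for k = 3); `gg = TRUE` applies the
#' Greenhouse-Geisser epsilon.
#'
#' @param z_matrix numeric matrix, subjects in rows, measures (>= 2) in
#'   columns; rows with any `NA` are dropped listwise.
#' @param gg apply the Greenhouse-Geisser correction?
#' @return object of class `rm_anova`: `F`, `df`, `p`,
#'   `partial_eta_sq`, `means`, `n`, `n_dropped`, and (if `gg`)
#'   `epsilon`.
#' @examples
#' set.seed(1)
#' rm_anova(matrix(rnorm(24), 8, 3))
#' @export
rm_anova <- function(z_matrix, gg = FALSE) {
  z <- as.matrix(z_matrix)
  drop <- apply(z, 1, function(r) any(!is.finite(r)))
  n_dropped <- sum(drop)
  z <- z[!drop, , drop = FALSE]
  n <- nrow(z); k <- ncol(z)
  if (n < 3) stop("repeated-measures ANOVA needs >= 3 complete subjects")
  g <- mean(z)
  col_m <- colMeans(z)
  row_m <- rowMeans(z)
  ss_measure <- n * sum((col_m - g)^2)
  ss_subject <- k * sum((row_m - g)^2)
  ss_total <- sum((z - g)^2)
  ss_error <- ss_total - ss_measure - ss_subject
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_m <- ss_measure / df1
  ms_e <- ss_error / df2
  if (ms_e <= 0) {
    f <- if (ms_m > 0) Inf else 0
    p <- if (ms_m > 0) 0 else 1
  } else {
    f <- ms_m / ms_e
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  eta <- if (ss_measure + ss_error > 0) ss_measure / (ss_measure + ss_error)
         else 0
  out <- list(F = f, df = c(df1, df2), p = p, partial_eta_sq = eta,
              means = col_m, n = n, n_dropped = n_dropped)
  if (gg) {
    # Greenhouse-Geisser epsilon from the double-centred covariance
    s <- stats::cov(z)
    dc <- s - outer(rowMeans(s), rep(1, k)) -
      outer(rep(1, k), colMeans(s)) + mean(s)
    eps <- sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
    out$epsilon <- eps
    out$df <- out$df * eps
    out$p <- if (is.finite(f)) stats::pf(f, out$df[1], out$df[2],
                                         lower.tail = FALSE) else out$p
  }
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%g, %g) = %.3f, p = %.4g, partial eta^2 = %.3f (n = %d%s)\n",
              x$df[1], x$df[2], x$F, x$p, x$partial_eta_sq, x$n,
              if (x$n_dropped > 0)
                paste0(", ", x$n_dropped, " dropped") else ""))
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t tests on the column differences of a subjects x measures
#' matrix, each p multiplied by the number of pairs (capped at 1).  The
#' sign convention is first-listed minus second.
#'
#' @param z_matrix subjects x measures matrix (complete rows used).
#' @return data frame: `pair`, `mean_difference`, `SE`, `t`, `df`,
#'   `p_raw`, `p_bonferroni`.
#' @export
bonferroni_pairwise <- function(z_matrix) {
  z <- as.matrix(z_matrix)
  z <- z[!apply(z, 1, function(r) any(!is.finite(r))), , drop = FALSE]
  k <- ncol(z); n <- nrow(z)
  if (n < 3) stop("pairwise comparisons need >= 3 complete subjects")
  nm <- colnames(z)
  if (is.null(nm)) nm <- paste0("m", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(pair = character(m), mean_difference = numeric(m),
                    SE = numeric(m), t = numeric(m), df = numeric(m),
                    p_raw = numeric(m), p_bonferroni = numeric(m),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- z[, a] - z[, b]
    md <- mean(d)
    se <- stats::sd(d) / sqrt(n)
    if (se == 0) {
      tv <- if (md == 0) 0 else sign(md) * Inf
      p <- if (md == 0) 1 else 0
    } else {
      tv <- md / se
      p <- 2 * stats::pt(-abs(tv), n - 1)
    }
    out[j, ] <- list(paste(nm[a], "vs", nm[b]), md, se, tv, n - 1,
                     p, min(1, m * p))
  }
  out
}

#' Validate the sliding-window length against whole-record indices
#'
#' For each candidate window length, the time-averaged windowed index of
#' every subject is correlated (Pearson, across subjects) with the same
#' index computed once from the whole recording -- the usual
#' justification for an ultra-short analysis window.  A window spanning
#' the whole record reduces to the whole-record index itself (r = 1).
#'
#' @param rr_list list of `rr_series`, one per subject (>= 3).
#' @param windows candidate window lengths, seconds; `Inf` means the
#'   whole record.
#' @param grid_s sliding grid spacing, seconds.
#' @param hf_band HF band, Hz.
#' @return data frame: `window_s`, `r_hf`, `r_rmssd`, `r_cvi`.
#' @export
validate_window_choice <- function(rr_list, windows = c(5, 15, 30, 60, Inf),
                                   grid_s = 0.1, hf_band = c(0.15, 0.40)) {
  if (length(rr_list) < 3)
    stop("window validation needs at least 3 subjects")
  whole <- function(rr) {
    v <- rr$rr_repaired_ms
    c(hf = hf_power_window(rr$interval_times, v, band = hf_band),
      rmssd = rmssd_window(v), cvi = cvi_window(v)$cvi)
  }
  w_idx <- t(vapply(rr_list, whole, numeric(3)))
  out <- data.frame(window_s = windows, r_hf = NA_real_,
                    r_rmssd = NA_real_, r_cvi = NA_real_)
  for (i in seq_along(windows)) {
    w <- windows[i]
    avg <- t(vapply(rr_list, function(rr) {
      span <- diff(range(rr$beat_times))
      # a window the sliding estimator cannot fit reduces to the
      # whole-record index
      if (!is.finite(w) || 2 * w > span) return(whole(rr))
      trk <- sliding_hrv(rr, window_s = w, grid_s = grid_s,
                         hf_band = hf_band)
      c(hf = mean(trk$hf_log, na.rm = TRUE),
        rmssd = mean(trk$rmssd_ms, na.rm = TRUE),
        cvi = mean(trk$cvi, na.rm = TRUE))
    }, numeric(3)))
    out$r_hf[i] <- stats::cor(avg[, 1], w_idx[, 1])
    out$r_rmssd[i] <- stats::cor(avg[, 2], w_idx[, 2])
    out$r_cvi[i] <- stats::cor(avg[, 3], w_idx[, 3])
  }
  out
}
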