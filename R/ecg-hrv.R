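# R-peak detection (Pan-Tompkins), R-R cleaning/repair, tachogram
# resampling, and continuous parasympathetic indices (log HF, RMSSD,
# CVI) on a sliding window.

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic stages: 5-15 Hz band-pass, five-point derivative, squaring,
#' 150 ms moving-window integration, then adaptive dual thresholds on
#' the integrated and band-passed signals with running signal/noise peak
#' estimates, a 200 ms refractory period, and search-back at 1.66 times
#' the running R-R mean when a beat is missed.  Band-pass and integration
#' are zero-phase/centred here, so each accepted integrated peak is
#' refined to the local maximum of the band-passed signal within
#' +/- 75 ms -- the reported peak time has no systematic group delay.
#'
#' @param ecg a `sampled_signal`, `fs >= 100` Hz, at least 2 s long.
#' @param refractory_s detector refractory period, seconds.
#' @return object of class `rpeak_series`: `peak_times` (seconds,
#'   strictly increasing), `peak_indices` (sample indices), `fs`.
#' @examples
#' cfg <- sim_config(duration_s = 60, fs = 250, noise_sd_ecg = 0, seed = 3)
#' sub <- simulate_subject(cfg)
#' pk <- detect_r_peaks(sub$ecg)
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.2) {
  stopifnot(inherits(ecg, "sampled_signal"))
  fs <- ecg$fs
  if (fs < 100) stop("detect_r_peaks needs fs >= 100 Hz (got ", fs, ")")
  n <- length(ecg$values)
  if (n < 2 * fs) stop("ECG record shorter than 2 s: cannot initialize ",
                       "detector thresholds")
  x <- ecg$values - mean(ecg$values)
  bp <- zerophase_filter(x, fs, high_pass = 5, low_pass = 15, order = 2)
  # five-point derivative, centred (zero-lag)
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) * fs / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  wl <- max(3L, round(0.150 * fs))
  if (wl %% 2 == 0) wl <- wl + 1L
  mwi <- stats::filter(sq, rep(1 / wl, wl), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate fiducial points: strict local maxima of the integrated signal
  cand <- which(mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                mwi[2:(n - 1)] >= mwi[3:n]) + 1L
  if (length(cand) == 0) {
    warning("no candidate peaks found in ECG")
    return(structure(list(peak_times = numeric(0),
                          peak_indices = integer(0), fs = fs),
                     class = "rpeak_series"))
  }

  init <- seq_len(round(2 * fs))
  spki <- max(mwi[init]); npki <- mean(mwi[init]) / 2
  spkf <- max(abs(bp[init])); npkf <- mean(abs(bp[init])) / 2
  thr1 <- function() npki + 0.25 * (spki - npki)
  thrf <- function() npkf + 0.25 * (spkf - npkf)

  half <- round(0.075 * fs)
  refine <- function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(bp[lo:hi]) - 1L
  }
  refr <- round(refractory_s * fs)

  peaks <- integer(0)
  rr_recent <- numeric(0)
  last_i <- -Inf
  noise_cand <- integer(0)   # rejected candidates since the last beat

  accept <- function(j) {
    peaks <<- c(peaks, j)
    if (length(peaks) >= 2) {
      rr_recent <<- c(rr_recent, diff(utils::tail(peaks, 2)))
      if (length(rr_recent) > 8) rr_recent <<- utils::tail(rr_recent, 8)
    }
    last_i <<- j
    noise_cand <<- integer(0)
  }

  for (i in cand) {
    if (i - last_i <= refr) next
    pk <- mwi[i]
    j <- refine(i)
    if (pk >= thr1() && abs(bp[j]) >= thrf()) {
      if (length(peaks) > 0 && j - last_i <= refr) next
      spki <- 0.125 * pk + 0.875 * spki
      spkf <- 0.125 * abs(bp[j]) + 0.875 * spkf
      accept(j)
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      npkf <- 0.125 * abs(bp[j]) + 0.875 * npkf
      noise_cand <- c(noise_cand, i)
      # search-back: have we overrun 1.66x the running R-R?
      if (length(rr_recent) >= 2 && length(noise_cand) > 0 &&
          (i - last_i) > 1.66 * mean(rr_recent)) {
        sb <- noise_cand[mwi[noise_cand] >= thr1() / 2]
        sb <- sb[sb - last_i > refr]
        if (length(sb) > 0) {
          ib <- sb[which.max(mwi[sb])]
          jb <- refine(ib)
          if (jb - last_i > refr) {
            spki <- 0.25 * mwi[ib] + 0.75 * spki
            spkf <- 0.25 * abs(bp[jb]) + 0.75 * spkf
            accept(jb)
          }
        }
      }
    }
  }
  if (length(peaks) == 0)
    warning("zero R peaks detected")
  peaks <- peaks[!duplicated(peaks)]
  structure(list(peak_times = ecg$t0 + (peaks - 1) / fs,
                 peak_indices = peaks, fs = fs),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  np <- length(x$peak_times)
  if (np >= 2) {
    rr <- diff(x$peak_times)
    cat(sprintf("<rpeak_series: %d peaks, mean HR %.1f bpm, RR %.0f +/- %.0f ms>\n",
                np, 60 / mean(rr), 1000 * mean(rr), 1000 * stats::sd(rr)))
  } else cat(sprintf("<rpeak_series: %d peaks>\n", np))
  invisible(x)
}

#' Gate R-R intervals and repair outliers by natural cubic spline
#'
#' Intervals outside the physiological range (inclusive bounds, default
#' 250-1500 ms) are flagged missing and replaced by a natural cubic
#' spline over beat index fitted through the valid intervals.  Invalid
#' runs at the record edges (no bracketing support) take the
#' nearest-valid value, with a warning.
#'
#' @param peaks an `rpeak_series`, or a numeric vector of beat times in
#'   seconds.
#' @param bounds_ms inclusive validity range, ms.
#' @return object of class `rr_series`: `beat_times` (all beats),
#'   `interval_times` (time of the second beat of each interval),
#'   `rr_ms`, `valid`, `rr_repaired_ms`.
#' @export
clean_and_interpolate_rr <- function(peaks, bounds_ms = c(250, 1500)) {
  bt <- if (inherits(peaks, "rpeak_series")) peaks$peak_times
        else as.numeric(peaks)
  if (length(bt) < 5) stop("need at least 5 beats (4 intervals)")
  if (any(diff(bt) <= 0)) stop("beat times must be strictly increasing")
  rr <- diff(bt) * 1000
  valid <- rr >= bounds_ms[1] & rr <= bounds_ms[2]
  if (sum(valid) < 4)
    stop("fewer than 4 valid R-R intervals (", sum(valid),
         "): cannot support spline repair")
  rep_ms <- rr
  if (any(!valid)) {
    idx <- seq_along(rr)
    vi <- idx[valid]
    inner <- idx[!valid & idx > min(vi) & idx < max(vi)]
    if (length(inner) > 0)
      rep_ms[inner] <- stats::spline(vi, rr[vi], xout = inner,
                                     method = "natural", ties = "ordered")$y
    outer_idx <- idx[!valid & (idx < min(vi) | idx > max(vi))]
    if (length(outer_idx) > 0) {
      warning("invalid R-R run at record edge: nearest-valid extrapolation ",
              "applied to ", length(outer_idx), " interval(s)")
      rep_ms[outer_idx[outer_idx < min(vi)]] <- rr[min(vi)]
      rep_ms[outer_idx[outer_idx > max(vi)]] <- rr[max(vi)]
    }
  }
  structure(list(beat_times = bt, interval_times = bt[-1], rr_ms = rr,
                 valid = valid, rr_repaired_ms = rep_ms),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series: %d intervals (%d gated out), %.0f +/- %.0f ms>\n",
              length(x$rr_ms), sum(!x$valid), mean(x$rr_repaired_ms),
              stats::sd(x$rr_repaired_ms)))
  invisible(x)
}

#' Tachogram plot
#' @param x an `rr_series`.
#' @param ... passed to `plot`.
#' @export
plot.rr_series <- function(x, ...) {
  graphics::plot(x$interval_times, x$rr_ms, type = "p", pch = 20,
                 col = ifelse(x$valid, "black", "red"),
                 xlab = "time (s)", ylab = "R-R (ms)", ...)
  graphics::lines(x$interval_times, x$rr_repaired_ms, col = "grey50")
  invisible(x)
}

#' Resample a tachogram to a uniform grid
#'
#' Shape-preserving (monotone, Fritsch-Carlson) piecewise cubic Hermite
#' interpolation of the repaired R-R series as a function of beat time,
#' evaluated on a uniform grid spanning the beats; never overshoots the
#' local data range.
#'
#' @param rr an `rr_series`.
#' @param grid_s grid spacing, seconds (default 0.1).
#' @return list with `grid_times` and `rr_ms`.
#' @export
resample_rr <- function(rr, grid_s = 0.1) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$interval_times
  if (any(!is.finite(rr$rr_repaired_ms)))
    stop("repaired R-R series contains non-finite values")
  t0 <- ceiling(x[1] / grid_s) * grid_s
  t1 <- floor(x[length(x)] / grid_s) * grid_s
  if (t1 <= t0) stop("beat support shorter than one grid step")
  grid <- seq(t0, t1, by = grid_s)
  f <- stats::splinefun(x, rr$rr_repaired_ms, method = "monoH.FC")
  list(grid_times = grid, rr_ms = f(grid))
}

#' RMSSD of an R-R window
#'
#' Root mean square of successive differences; needs at least two
#' intervals (three beats).
#'
#' @param rr_values R-R intervals, ms.
#' @return RMSSD in ms, or `NA` if under-populated.
#' @export
rmssd_window <- function(rr_values) {
  if (length(rr_values) < 2) return(NA_real_)
  sqrt(mean(diff(rr_values)^2))
}

#' Poincare SD1/SD2 and the cardiac vagal index of an R-R window
#'
#' Poincare pairs (rr_k, rr_{k+1}); SD1 is the population SD of the
#' rotated coordinate `(rr_{k+1} - rr_k)/sqrt(2)` (dispersion across the
#' identity line), SD2 of `(rr_{k+1} + rr_k)/sqrt(2)` (along it).
#' `CVI = log10(SD1 * SD2)`, floored at `log10(eps)` for degenerate
#' windows (flagged via the `floored` field).
#'
#' @param rr_values R-R intervals, ms (>= 3, i.e. >= 4 beats).
#' @param eps floor, ms^2.
#' @return list: `cvi`, `sd1`, `sd2`, `floored`.
#' @export
cvi_window <- function(rr_values, eps = 1e-6) {
  if (length(rr_values) < 3)
    return(list(cvi = NA_real_, sd1 = NA_real_, sd2 = NA_real_,
                floored = NA))
  d <- diff(rr_values)
  s <- rr_values[-1] + rr_values[-length(rr_values)]
  sd1 <- pop_sd(d) / sqrt(2)
  sd2 <- pop_sd(s) / sqrt(2)
  prod <- sd1 * sd2
  list(cvi = log10(max(prod, eps)), sd1 = sd1, sd2 = sd2,
       floored = prod < eps)
}

#' Log HF power of an R-R window by Lomb-Scargle
#'
#' Lomb-Scargle spectral density of the mean-subtracted R-R values at
#' their (irregular) beat times, integrated by trapezoid over the HF band
#' on a fixed frequency grid, returned as `log10(power + eps)`.
#'
#' @param times beat times of the intervals, seconds.
#' @param rr_values R-R intervals, ms (>= 4 beats, i.e. >= 3 intervals;
#'   the windowing caller enforces its own beat minimum).
#' @param band HF band, Hz.
#' @param freq_step evaluation grid step, Hz (<= 0.01).
#' @param eps floor, ms^2.
#' @return `log10(ms^2)` band power, or `NA` if under-populated.
#' @export
hf_power_window <- function(times, rr_values, band = c(0.15, 0.40),
                            freq_step = 0.005, eps = 1e-6) {
  if (length(rr_values) < 3 || length(times) != length(rr_values))
    return(NA_real_)
  if (stats::sd(rr_values) == 0) return(log10(eps))  # degenerate: floor
  freqs <- seq(band[1], band[2], by = freq_step)
  psd <- lomb_psd(times, rr_values, freqs)
  log10(trapz(freqs, psd) + eps)
}

# Vectorized sliding-window Lomb-Scargle HF power: the same algebra as
# lomb_psd()/hf_power_window(), but every per-window sum is a
# contiguous-range difference of per-interval cumulative sums, so all
# windows are evaluated at once.  `lo`/`hi` index the intervals of each
# window; out-of-range windows yield garbage the caller must mask.
sliding_hf_lomb <- function(times, values, lo, hi, freqs, eps) {
  nI <- length(times)
  lo <- pmin(pmax(lo, 1L), nI)
  hi <- pmin(pmax(hi, lo), nI)
  w <- 2 * pi * freqs
  W <- outer(times, w)
  S <- sin(W); C <- cos(W)
  cum2 <- function(M) rbind(0, apply(M, 2, cumsum))
  cC <- cum2(C); cS <- cum2(S)
  cvC <- cum2(values * C); cvS <- cum2(values * S)
  cSC <- cum2(S * C); cC2S2 <- cum2(C * C - S * S)
  rs <- function(M) M[hi + 1L, , drop = FALSE] - M[lo, , drop = FALSE]
  cv <- c(0, cumsum(values)); cv2 <- c(0, cumsum(values^2))
  n <- hi - lo + 1
  mu <- (cv[hi + 1L] - cv[lo]) / n
  varv <- pmax((cv2[hi + 1L] - cv2[lo]) / n - mu^2, 0)
  # NB: vectors of length n_windows recycle down matrix columns, i.e.
  # along windows (rows) -- exactly the per-window scaling needed.
  xc <- rs(cvC) - mu * rs(cC)
  xs <- rs(cvS) - mu * rs(cS)
  s2 <- 2 * rs(cSC)
  c2 <- rs(cC2S2)
  wtau <- 0.5 * atan2(s2, c2)
  cw <- cos(wtau); sw <- sin(wtau)
  num_c <- (cw * xc + sw * xs)^2
  num_s <- (cw * xs - sw * xc)^2
  cc <- 0.5 * (cw^2 * (n + c2) + 2 * cw * sw * s2 + sw^2 * (n - c2))
  ss <- 0.5 * (sw^2 * (n + c2) - 2 * cw * sw * s2 + cw^2 * (n - c2))
  p <- 0.5 * (num_c / ifelse(cc <= 0, Inf, cc) +
              num_s / ifelse(ss <= 0, Inf, ss))
  span <- times[hi] - times[lo]
  psd <- p * (2 * span / n)
  df <- freqs[2] - freqs[1]
  wts <- rep(df, length(freqs)); wts[c(1, length(wts))] <- df / 2
  power <- as.numeric(psd %*% wts)
  out <- log10(power + eps)
  out[varv <= 1e-12 * pmax(mu^2, 1)] <- log10(eps)   # degenerate window
  out
}

#' Continuous HRV track on a sliding window
#'
#' For every grid time t (0.1 s spacing by default) the three
#' parasympathetic indices are computed from the beats falling in the
#' centred window `[t - w/2, t + w/2]`.  Windows overlapping the record
#' edges, or holding fewer beats than the per-index minimum (3 for
#' RMSSD, 4 for HF and CVI), are missing (`NA`), never zero.
#'
#' @param rr an `rr_series`.
#' @param window_s window length, seconds (default 5).
#' @param grid_s grid spacing, seconds (default 0.1).
#' @param hf_band HF band, Hz.
#' @param hf_input `"beats"` (Lomb-Scargle on the irregular beat-domain
#'   R-R values; the estimator's reason for being) or `"resampled"`
#'   (Lomb on the uniform 0.1 s Hermite-resampled series within the
#'   window).
#' @param hf_freq_step,hf_eps,cvi_eps see the per-window functions.
#' @return object of class `hrv_track`: `grid_times`, `hf_log`,
#'   `rmssd_ms`, `cvi`, `n_beats_per_window`, `window_s`, `grid_s`.
#' @examples
#' bt <- cumsum(c(1, rep(0.8, 120)))
#' trk <- sliding_hrv(clean_and_interpolate_rr(bt))
#' @export
sliding_hrv <- function(rr, window_s = 5, grid_s = 0.1,
                        hf_band = c(0.15, 0.40),
                        hf_input = c("beats", "resampled"),
                        hf_freq_step = 0.005, hf_eps = 1e-6,
                        cvi_eps = 1e-6) {
  stopifnot(inherits(rr, "rr_series"))
  hf_input <- match.arg(hf_input)
  bt <- rr$beat_times
  span <- bt[length(bt)] - bt[1]
  if (span < 2 * window_s)
    stop("record (", format(span, digits = 3), " s) shorter than twice ",
         "the window length")
  it <- rr$interval_times
  rv <- rr$rr_repaired_ms
  t0 <- ceiling(bt[1] / grid_s) * grid_s
  t1 <- floor(bt[length(bt)] / grid_s) * grid_s
  grid <- seq(t0, t1, by = grid_s)
  ng <- length(grid)
  h <- window_s / 2
  eps_t <- 1e-9

  # window membership by binary search on the sorted interval/beat times
  lo_i <- findInterval(grid - h - eps_t, it) + 1L
  hi_i <- findInterval(grid + h + eps_t, it)
  lo_b <- findInterval(grid - h - eps_t, bt) + 1L
  hi_b <- findInterval(grid + h + eps_t, bt)
  inside <- grid - h >= bt[1] - eps_t & grid + h <= bt[length(bt)] + eps_t

  nb <- hi_b - lo_b + 1L
  freqs <- seq(hf_band[1], hf_band[2], by = hf_freq_step)
  nw <- pmax(hi_i - lo_i + 1L, 0L)           # intervals per window

  # Every per-window statistic is a contiguous-range sum over the sorted
  # intervals, so the whole track is computed from cumulative sums with
  # no per-window loop.
  cum <- function(v) c(0, cumsum(v))
  rsum <- function(cv, lo, hi) cv[hi + 1L] - cv[lo]
  nI <- length(rv)
  dd <- diff(rv)
  sums <- rv[-1] + rv[-nI]
  ok1 <- inside & nw >= 2 & nb >= 3           # >= 1 successive difference
  ok2 <- inside & nw >= 3 & nb >= 4           # HF / CVI minimum

  rmssd <- rep(NA_real_, ng)
  np <- nw - 1L                               # Poincare pairs per window
  sd2sum <- rsum(cum(dd^2), lo_i, pmax(hi_i - 1L, 0L))
  rmssd[ok1] <- sqrt(sd2sum[ok1] / np[ok1])

  cvi <- rep(NA_real_, ng)
  m_d <- rsum(cum(dd), lo_i, hi_i - 1L) / np
  v_d <- pmax(sd2sum / np - m_d^2, 0)
  m_s <- rsum(cum(sums), lo_i, hi_i - 1L) / np
  v_s <- pmax(rsum(cum(sums^2), lo_i, hi_i - 1L) / np - m_s^2, 0)
  prod_sd <- sqrt(v_d / 2) * sqrt(v_s / 2)    # population SD1 * SD2
  cvi[ok2] <- log10(pmax(prod_sd[ok2], cvi_eps))

  hf <- rep(NA_real_, ng)
  if (hf_input == "beats") {
    hf_all <- sliding_hf_lomb(it, rv, lo_i, hi_i, freqs, hf_eps)
    hf[ok2] <- hf_all[ok2]
  } else {
    res <- resample_rr(rr, grid_s)
    for (g in which(ok2)) {
      sel <- which(res$grid_times >= grid[g] - h - eps_t &
                   res$grid_times <= grid[g] + h + eps_t)
      hf[g] <- hf_power_window(res$grid_times[sel], res$rr_ms[sel],
                               band = hf_band, freq_step = hf_freq_step,
                               eps = hf_eps)
    }
  }
  nb[!inside] <- NA_integer_
  structure(list(grid_times = grid, hf_log = hf, rmssd_ms = rmssd,
                 cvi = cvi, n_beats_per_window = nb, window_s = window_s,
                 grid_s = grid_s, hf_band = hf_band, hf_input = hf_input),
            class = "hrv_track")
}

#' @export
print.hrv_track <- function(x, ...) {
  ok <- !is.na(x$rmssd_ms)
  cat(sprintf(paste0("<hrv_track: %d grid points @ %g s, window %g s, ",
                     "%d missing\n  RMSSD %.1f ms, log HF %.2f, CVI %.2f ",
                     "(medians)>\n"),
              length(x$grid_times), x$grid_s, x$window_s, sum(!ok),
              stats::median(x$rmssd_ms, na.rm = TRUE),
              stats::median(x$hf_log, na.rm = TRUE),
              stats::median(x$cvi, na.rm = TRUE)))
  invisible(x)
}

#' Plot an HRV track (three index panels)
#' @param x an `hrv_track`.
#' @param ... ignored.
#' @export
plot.hrv_track <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$grid_times, x$hf_log, type = "l",
                 xlab = "", ylab = "log HF (log10 ms^2)")
  graphics::plot(x$grid_times, x$rmssd_ms, type = "l", lty = 2,
                 xlab = "", ylab = "RMSSD (ms)")
  graphics::plot(x$grid_times, x$cvi, type = "l", lty = 3,
                 xlab = "time (s)", ylab = "CVI")
  invisible(x)
}

#' Write an HRV track CSV
#' @param x an `hrv_track`.
#' @param path destination.
#' @export
write_hrv_csv <- function(x, path) {
  stopifnot(inherits(x, "hrv_track"))
  utils::write.csv(data.frame(time_s = x$grid_times, hf_log = x$hf_log,
                              rmssd_ms = x$rmssd_ms, cvi = x$cvi,
                              n_beats = x$n_beats_per_window),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an R-R table CSV
#' @param x an `rr_series`.
#' @param path destination.
#' @export
write_rr_csv <- function(x, path) {
  stopifnot(inherits(x, "rr_series"))
  utils::write.csv(data.frame(beat_time_s = x$interval_times,
                              rr_ms = x$rr_ms, valid = x$valid,
                              rr_repaired_ms = x$rr_repaired_ms),
                   path, row.names = FALSE)
  invisible(path)
}
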