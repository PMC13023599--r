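# Low-level numerical helpers: zero-phase band-limiting, the discrete
# analytic signal, phase unwrapping, Lomb-Scargle spectral estimation.

#' Zero-phase Butterworth-response filtering
#'
#' Applies the magnitude-squared response of an order-`order` Butterworth
#' filter (the response a forward-backward `filtfilt` pass realises) with
#' exactly zero phase, by frequency-domain multiplication on an
#' even-extended copy of the record.  The even extension removes the
#' endpoint discontinuity (the classic reflect-padding used before
#' `filtfilt`), and the spectral construction is numerically stable at
#' arbitrarily small normalized cutoffs -- the regime of a 0.01 Hz
#' high-pass on 500 Hz data, where transfer-function coefficients are
#' unusable.
#'
#' @param x numeric vector, uniformly sampled.
#' @param fs sampling rate, Hz.
#' @param high_pass optional high-pass cutoff, Hz.
#' @param low_pass optional low-pass cutoff(s), Hz; a vector applies the
#'   cutoffs in cascade.
#' @param order Butterworth order of each single (one-directional) pass;
#'   the realised rolloff is that of `2 * order` poles.
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
zerophase_filter <- function(x, fs, high_pass = NULL, low_pass = NULL,
                             order = 4) {
  n <- length(x)
  if (n < 4) stop("signal too short to filter (length ", n, ")")
  # edge-replicate up to a 5-smooth length so the FFT stays O(n log n)
  # for any record length, then extend evenly (no discontinuity).
  nf <- stats::nextn(n, c(2, 3, 5))
  xp <- if (nf > n) c(x, rep(x[n], nf - n)) else x
  xe <- c(xp, rev(xp))                     # even extension, period 2*nf
  m <- length(xe)
  f <- (seq_len(m) - 1) / m * fs
  f <- pmin(f, fs - f)                     # folded (physical) frequencies
  g <- rep(1, m)
  # |H|^2 of an order-k Butterworth has exponent 2k; forward-backward
  # squares it again, hence exponent 2*order applied as amplitude gain.
  if (!is.null(high_pass)) {
    r <- (f / high_pass)^(2 * order)
    g <- g * r / (1 + r)                   # zero at DC: removes the mean
  }
  for (fc in low_pass) {
    g <- g / (1 + (f / fc)^(2 * order))
  }
  y <- Re(stats::fft(stats::fft(xe) * g, inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Discrete analytic signal via the frequency domain
#'
#' Standard construction: double the positive frequencies, zero the
#' negative ones, keep DC (and Nyquist for even length).
#'
#' @param x numeric vector.
#' @return complex vector `x + i H[x]`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Unwrap a phase sequence
#'
#' Adds multiples of 2*pi so successive differences lie in (-pi, pi].
#'
#' @param p phase, radians.
#' @return unwrapped phase, radians.
#' @keywords internal
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  dw <- (d + pi) %% (2 * pi) - pi
  dw[dw == -pi & d > 0] <- pi
  p[1] + c(0, cumsum(dw))
}

#' Trapezoidal integral
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Population standard deviation (divisor n)
#' @keywords internal
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Lomb-Scargle power spectral density of an irregular series
#'
#' Classic Lomb periodogram with the time-offset tau that makes the
#' sine/cosine regressors orthogonal, rescaled to a one-sided spectral
#' density: for a sinusoid of amplitude `a` inside the evaluated band the
#' band-integrated density is `a^2 / 2` (its variance), the convention
#' needed to report HF power in ms^2.
#'
#' @param times sample times, seconds (need not be uniform).
#' @param values sample values (mean is removed internally).
#' @param freqs evaluation frequencies, Hz (all > 0).
#' @return numeric vector of spectral density values, `units(values)^2`
#'   per Hz.
#' @keywords internal
lomb_psd <- function(times, values, freqs) {
  n <- length(times)
  stopifnot(length(values) == n, n >= 2)
  x <- values - mean(values)
  span <- diff(range(times))
  if (span <= 0) return(rep(0, length(freqs)))
  w <- 2 * pi * freqs
  # outer products: rows = times, cols = frequencies
  wt <- outer(times, w)
  swt <- sin(wt)
  cwt <- cos(wt)
  s2 <- 2 * colSums(swt * cwt)          # sum sin(2wt)
  c2 <- colSums(cwt^2 - swt^2)          # sum cos(2wt)
  wtau <- 0.5 * atan2(s2, c2)
  cw <- cos(wtau); sw <- sin(wtau)
  # the tau-shifted sums follow from angle subtraction, so the shifted
  # regressors never need to be formed:
  #   sum x cos(wt - wtau) = cw * xc + sw * xs, etc.
  xc <- colSums(x * cwt)
  xs <- colSums(x * swt)
  num_c <- (cw * xc + sw * xs)^2
  num_s <- (cw * xs - sw * xc)^2
  cc <- 0.5 * (cw^2 * (n + c2) + 2 * cw * sw * s2 + sw^2 * (n - c2))
  ss <- 0.5 * (sw^2 * (n + c2) - 2 * cw * sw * s2 + cw^2 * (n - c2))
  cc[cc <= 0] <- Inf                    # degenerate regressor -> no power
  ss[ss <= 0] <- Inf
  p <- 0.5 * (num_c / cc + num_s / ss)
  p * 2 * span / n
}

# Deterministic derived seeds: exact in double arithmetic, below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + k * 104729) %%
               2147483629)
}
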