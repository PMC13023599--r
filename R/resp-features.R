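# Respiratory preprocessing and Hilbert decomposition into instantaneous
# amplitude (depth), corrected monotone phase, and sign-inverted
# instantaneous frequency (rate).

#' Band-limit a respiratory waveform
#'
#' Removes low-frequency drift (< 0.01 Hz) and high-frequency noise
#' (> 2 Hz), then low-passes at 0.75 Hz, yielding the quasi-monocomponent
#' waveform required by the analytic-signal decomposition.  All three
#' stages are zero-phase order-4 Butterworth responses applied in cascade,
#' so event timing is preserved and the output mean is (numerically) zero.
#'
#' @param raw a `sampled_signal`.
#' @param high_pass drift cutoff, Hz.
#' @param low_pass_noise noise cutoff, Hz.
#' @param low_pass_final monocomponent cutoff, Hz.
#' @return a `sampled_signal` of the same length and rate.
#' @examples
#' t <- seq(0, 120, by = 0.01)
#' s <- sampled_signal(cos(2 * pi * 0.25 * t) + 3, fs = 100)
#' p <- preprocess_respiration(s)
#' @export
preprocess_respiration <- function(raw, high_pass = 0.01,
                                   low_pass_noise = 2,
                                   low_pass_final = 0.75) {
  stopifnot(inherits(raw, "sampled_signal"))
  if (signal_duration(raw) < 30)
    stop("respiration record too short (",
         format(signal_duration(raw), digits = 3),
         " s): at least 30 s is needed for the 0.01 Hz high-pass to settle")
  y <- zerophase_filter(raw$values, raw$fs, high_pass = high_pass,
                        low_pass = c(low_pass_noise, low_pass_final),
                        order = 4)
  sampled_signal(y, fs = raw$fs, t0 = raw$t0, channel = raw$channel)
}

#' Instantaneous amplitude and raw phase of the analytic signal
#'
#' The analytic signal `s + i H[s]` is formed in the frequency domain;
#' its modulus is the instantaneous amplitude and its unwrapped argument
#' the raw instantaneous phase.  A degenerate all-zero input yields zero
#' amplitude and, by convention, zero phase (with a message).
#'
#' @param signal a preprocessed (quasi-monocomponent) `sampled_signal`.
#' @return list with `amplitude` (>= 0) and `raw_phase` (radians,
#'   unwrapped), both the length of the input.
#' @export
compute_analytic <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  x <- signal$values
  if (all(x == 0)) {
    message("all-zero signal: amplitude and phase set to 0 by convention")
    return(list(amplitude = numeric(length(x)),
                raw_phase = numeric(length(x))))
  }
  a <- analytic_signal(x)
  list(amplitude = Mod(a), raw_phase = unwrap_phase(Arg(a)))
}

# Replace every run of samples below the running maximum by linear
# interpolation between the bracketing record highs (the local maximum
# where the phase stopped increasing and the recovery point where it
# resumes).  Output is non-decreasing by construction.
monotone_interp <- function(p) {
  cm <- cummax(p)
  keep <- p >= cm - 1e-12
  if (all(keep)) return(p)
  idx <- which(keep)
  stats::approx(idx, p[idx], xout = seq_along(p), rule = 2,
                ties = "ordered")$y
}

#' Correct the instantaneous phase to a monotone time course
#'
#' Spurious decreases of the raw instantaneous phase (where the analytic
#' trajectory loops near the origin) are repaired by up to ten rounds of:
#' linearly interpolate each decreasing segment between its bracketing
#' extrema, then low-pass the phase increments at 0.75 Hz (filtering the
#' increments rather than the absolute phase avoids re-introducing
#' drift).  Ten rounds is the cap that guarantees monotonicity; the loop
#' exits as soon as the phase is monotone, which makes the corrected
#' phase a true fixed point (further iterations are no-ops -- the
#' repeated low-pass would otherwise keep eroding in-band content).  A
#' terminal monotone repair enforces the non-decreasing contract
#' exactly; it moves the phase by less than the residual tolerance.
#'
#' @param raw_phase unwrapped phase, radians.
#' @param fs sampling rate, Hz.
#' @param iterations maximum repair/filter rounds (default 10).
#' @param low_pass increment low-pass cutoff, Hz.
#' @return corrected phase; forward differences >= -1e-6 rad.  A
#'   `convergence` attribute carries the RMS change of the last active
#'   round, and `iterations_used` the number of rounds run.
#' @export
correct_phase <- function(raw_phase, fs, iterations = 10, low_pass = 0.75) {
  p <- raw_phase
  last_change <- 0
  used <- 0
  for (it in seq_len(iterations)) {
    if (min(diff(p)) >= -1e-9) break      # monotone: fixed point reached
    prev <- p
    p <- monotone_interp(p)
    d <- diff(p)
    d <- zerophase_filter(d, fs, low_pass = low_pass, order = 4)
    p <- p[1] + c(0, cumsum(d))
    last_change <- sqrt(mean((p - prev)^2))
    used <- it
  }
  p <- monotone_interp(p)
  attr(p, "convergence") <- last_change
  attr(p, "iterations_used") <- used
  p
}

#' Instantaneous frequency from a corrected phase
#'
#' Central-difference derivative divided by 2*pi (one-sided at the
#' endpoints); exact for linear phase.
#'
#' @param phase corrected (monotone) phase, radians.
#' @param fs sampling rate, Hz.
#' @return instantaneous frequency, Hz.
#' @export
instantaneous_frequency <- function(phase, fs) {
  phase <- as.numeric(phase)
  n <- length(phase)
  stopifnot(n >= 3)
  f <- numeric(n)
  f[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) * fs / (4 * pi)
  f[1] <- (phase[2] - phase[1]) * fs / (2 * pi)
  f[n] <- (phase[n] - phase[n - 1]) * fs / (2 * pi)
  f
}

#' Full respiratory decomposition
#'
#' Composes [preprocess_respiration()], [compute_analytic()],
#' [correct_phase()] and [instantaneous_frequency()], and inverts the
#' sign of the frequency so that, like depth, larger values are the
#' direction expected to accompany greater parasympathetic activity
#' (slower breathing).
#'
#' @param raw a `sampled_signal` (raw belt trace).
#' @param guard_s guard band, seconds, excluded at each end by downstream
#'   correlation steps (filter and Hilbert edge effects live there).
#' @param preprocess set `FALSE` if `raw` is already band-limited.
#' @return object of class `resp_decomposition`: `preprocessed`,
#'   `amplitude`, `phase`, `frequency`, `rate_inverted` (all length of
#'   input), `fs`, `t0`, `guard_s`.
#' @examples
#' cfg <- sim_config(duration_s = 90, fs = 50, seed = 2)
#' d <- decompose_respiration(simulate_respiration(cfg)$signal)
#' d
#' @export
decompose_respiration <- function(raw, guard_s = 10, preprocess = TRUE) {
  pre <- if (preprocess) preprocess_respiration(raw) else raw
  an <- compute_analytic(pre)
  ph <- correct_phase(an$raw_phase, pre$fs)
  fr <- instantaneous_frequency(ph, pre$fs)
  structure(list(preprocessed = pre$values, amplitude = an$amplitude,
                 phase = as.numeric(ph), frequency = fr,
                 rate_inverted = -fr, fs = pre$fs, t0 = pre$t0,
                 guard_s = guard_s,
                 phase_convergence = attr(ph, "convergence")),
            class = "resp_decomposition")
}

#' @export
print.resp_decomposition <- function(x, ...) {
  n <- length(x$amplitude)
  g <- round(x$guard_s * x$fs)
  core <- seq.int(g + 1, n - g)
  cat(sprintf(paste0("<resp_decomposition: %d samples @ %g Hz, guard %g s\n",
                     "  interior amplitude %.3g (mean), frequency %.3g Hz ",
                     "(mean), phase span %.1f rad>\n"),
              n, x$fs, x$guard_s, mean(x$amplitude[core]),
              mean(x$frequency[core]), x$phase[n] - x$phase[1]))
  invisible(x)
}

#' Plot a respiratory decomposition
#'
#' Three stacked panels: preprocessed waveform with its amplitude
#' envelope, corrected instantaneous phase, and instantaneous frequency.
#'
#' @param x a `resp_decomposition`.
#' @param ... passed to the waveform panel.
#' @export
plot.resp_decomposition <- function(x, ...) {
  t <- x$t0 + (seq_along(x$preprocessed) - 1) / x$fs
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, x$preprocessed, type = "l", col = "darkgreen",
                 xlab = "", ylab = "waveform (a.u.)", ...)
  graphics::lines(t, x$amplitude, col = "red", lwd = 1.5)
  graphics::plot(t, x$phase, type = "l", xlab = "", ylab = "phase (rad)")
  graphics::plot(t, x$frequency, type = "l", col = "blue",
                 xlab = "time (s)", ylab = "frequency (Hz)")
  invisible(x)
}

#' Write a decomposition as a tidy CSV
#'
#' Columns: `time_s, preprocessed, amplitude, phase, frequency,
#' rate_inverted`.
#'
#' @param x a `resp_decomposition`.
#' @param path destination CSV.
#' @export
write_decomposition_csv <- function(x, path) {
  stopifnot(inherits(x, "resp_decomposition"))
  t <- x$t0 + (seq_along(x$preprocessed) - 1) / x$fs
  utils::write.csv(data.frame(time_s = t, preprocessed = x$preprocessed,
                              amplitude = x$amplitude, phase = x$phase,
                              frequency = x$frequency,
                              rate_inverted = x$rate_inverted),
                   path, row.names = FALSE)
  invisible(path)
}
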