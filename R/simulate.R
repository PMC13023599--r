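# Synthetic cardiorespiratory cohorts: respiration with controlled depth
# and rate dynamics, an IPFM beat generator whose vagal modulation can be
# coupled to depth and/or rate, and template-based ECG morphology.

# Slow unit-variance process: white noise low-passed at `cutoff` Hz, then
# standardized per record (exactly zero mean, unit SD).
slow_process <- function(n, fs, cutoff = 0.05) {
  z <- zerophase_filter(stats::rnorm(n), fs, low_pass = cutoff)
  s <- stats::sd(z)
  if (s == 0) return(rep(0, n))
  (z - mean(z)) / s
}

clip <- function(x, lim) pmin(pmax(x, -lim), lim)

#' Simulate a spontaneous respiration record
#'
#' Generates `resp(t) = depth(t) cos(phase(t)) + drift + noise` where the
#' depth envelope and breathing rate are independent slowly varying
#' (< 0.05 Hz) positive processes, sighs add transient envelope boosts,
#' and a 0.005 Hz drift exercises the preprocessing high-pass.  The
#' instantaneous phase integrates the rate, so ground truth for the
#' Hilbert decomposition is known exactly on the sample grid.
#'
#' @param config a [sim_config()].
#' @return list with `signal` (a `sampled_signal`) and `truth`, a list of
#'   per-sample ground truth: `t`, `true_depth` (a.u., >= 10% of
#'   `base_depth`), `true_rate` (Hz, floored at 0.05), `true_phase`
#'   (radians), plus `fs`.
#' @examples
#' r <- simulate_respiration(sim_config(duration_s = 60, fs = 50, seed = 1))
#' @export
simulate_respiration <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs

  rate <- config$base_breath_rate_hz
  if (config$breath_rate_sd_hz > 0)
    rate <- rate + config$breath_rate_sd_hz * slow_process(n, config$fs)
  rate <- pmax(rate, 0.05)
  if (length(rate) == 1) rate <- rep(rate, n)

  depth <- config$base_depth
  if (config$depth_sd > 0)
    depth <- depth + config$depth_sd * slow_process(n, config$fs)
  if (length(depth) == 1) depth <- rep(depth, n)
  n_sigh <- stats::rpois(1, config$sigh_rate_per_min * config$duration_s / 60)
  if (n_sigh > 0) {
    at <- sort(stats::runif(n_sigh, 0, config$duration_s))
    for (tc in at)
      depth <- depth + config$base_depth * exp(-(t - tc)^2 / (2 * 2^2))
  }
  depth <- pmax(depth, 0.1 * config$base_depth)  # envelope never degenerate

  phase <- 2 * pi * cumsum(rate) / config$fs
  drift <- if (config$drift_amp > 0)
    config$drift_amp * sin(2 * pi * 0.005 * t + stats::runif(1, 0, 2 * pi))
  else 0
  noise <- if (config$noise_sd_resp > 0)
    stats::rnorm(n, 0, config$noise_sd_resp) else 0

  values <- depth * cos(phase) + drift + noise
  list(signal = sampled_signal(values, fs = config$fs, channel = "resp"),
       truth = list(t = t, true_depth = depth, true_rate = rate,
                    true_phase = phase, fs = config$fs))
}

#' Generate beat times by integral pulse frequency modulation
#'
#' IPFM: a beat is emitted at each time where
#' `integral_0^t (1 + m(u)) HR0/60 du` crosses a successive integer.  The
#' vagal modulation is
#' `m(t) = [g_d norm(depth) + g_r norm(rate)] sin(phase) + noise`, with
#' `norm(x) = min(x / mean(x), 2.5)` a positive mean-normalized envelope
#' (clipped for physiological saturation) so the within-breath RSA
#' amplitude grows monotonically with depth and/or rate, `sin(phase)`
#' locking the modulation within the breath, and `noise` a band-limited
#' (0.04-0.40 Hz) component of amplitude `hrv_noise_gain` independent of
#' respiration.  `|m|` must stay below 1 (the mean rate never reverses);
#' the configured gains are rejected otherwise.
#'
#' @param truth the `truth` element returned by [simulate_respiration()].
#' @param config the same [sim_config()].
#' @return list with `beat_times` (seconds, strictly increasing) and
#'   `modulation` (the per-sample m(t)).
#' @export
simulate_beat_times <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"),
            is.list(truth), !is.null(truth$true_depth),
            !is.null(truth$true_rate), !is.null(truth$true_phase))
  set.seed(derive_seed(config$seed, 2L))
  n <- length(truth$true_depth)
  fs <- config$fs

  norm_env <- function(x) pmin(x / mean(x), 2.5)
  m <- (config$rsa_gain_depth * norm_env(truth$true_depth) +
        config$rsa_gain_rate * norm_env(truth$true_rate)) *
    sin(truth$true_phase)
  if (config$hrv_noise_gain > 0) {
    z <- zerophase_filter(stats::rnorm(n), fs,
                          high_pass = 0.04, low_pass = 0.40, order = 2)
    s <- stats::sd(z)
    if (s > 0) m <- m + config$hrv_noise_gain * clip((z - mean(z)) / s, 3.5)
  }
  if (max(abs(m)) >= 1)
    stop("IPFM modulation cap exceeded (max |m| = ",
         format(max(abs(m)), digits = 3),
         "): reduce rsa_gain_depth (", config$rsa_gain_depth,
         ") / rsa_gain_rate (", config$rsa_gain_rate,
         ") / hrv_noise_gain (", config$hrv_noise_gain, ")")

  r <- (1 + m) * config$mean_hr_bpm / 60
  # cumulative trapezoid of the instantaneous beat rate
  integ <- c(0, cumsum((r[-1] + r[-n]) / 2)) / fs
  k <- seq_len(floor(integ[n]))
  beat_times <- stats::approx(integ, truth$t, xout = k, ties = "ordered")$y
  list(beat_times = beat_times, modulation = m)
}

#' Synthesize a template-based ECG from beat times
#'
#' Places a fixed QRS-like template (narrow Gaussian, SD 10 ms, amplitude
#' `amplitude`) at each beat time, plus smaller P- and T-like bumps, and
#' adds white noise of SD `noise_sd_ecg`.  Morphology is deliberately
#' simple: the record exists to exercise the detector, not to mimic a
#' 12-lead ECG.
#'
#' @param beat_times strictly increasing beat times, seconds, within
#'   `[0, duration_s]`.
#' @param config a [sim_config()] (supplies `fs`, `duration_s`,
#'   `noise_sd_ecg`, `seed`).
#' @param amplitude R-wave amplitude, a.u.
#' @param pt_waves add the small P/T bumps? (default TRUE)
#' @return a `sampled_signal` of the ECG channel.
#' @export
synthesize_ecg <- function(beat_times, config, amplitude = 1,
                           pt_waves = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (length(beat_times) > 0) {
    if (any(diff(beat_times) <= 0))
      stop("beat_times must be strictly increasing")
    if (min(beat_times) < 0 || max(beat_times) > config$duration_s)
      stop("beat_times must lie within [0, duration_s]")
    if (any(diff(beat_times) < 0.2))
      warning("beat spacing below the 200 ms detector refractory period")
  }
  set.seed(derive_seed(config$seed, 3L))
  n <- round(config$duration_s * config$fs)
  fs <- config$fs
  x <- numeric(n)
  add_bump <- function(x, centre, amp, sd) {
    i0 <- max(1L, floor((centre - 4 * sd) * fs) + 1L)
    i1 <- min(n, ceiling((centre + 4 * sd) * fs) + 1L)
    if (i0 > n || i1 < 1) return(x)
    idx <- i0:i1
    tt <- (idx - 1) / fs
    x[idx] <- x[idx] + amp * exp(-(tt - centre)^2 / (2 * sd^2))
    x
  }
  for (tb in beat_times) {
    x <- add_bump(x, tb, amplitude, 0.010)
    if (pt_waves) {
      x <- add_bump(x, tb - 0.18, 0.10 * amplitude, 0.030)  # P
      x <- add_bump(x, tb + 0.28, 0.20 * amplitude, 0.050)  # T
    }
  }
  if (config$noise_sd_ecg > 0)
    x <- x + stats::rnorm(n, 0, config$noise_sd_ecg)
  sampled_signal(x, fs = fs, channel = "ecg")
}

#' Simulate one subject (respiration + beats + optional ECG)
#'
#' @param config a [sim_config()].
#' @param ecg synthesize the ECG channel?  `FALSE` gives the fast path
#'   where downstream analysis consumes the true IPFM beat times.
#' @return list with `resp` (`sampled_signal`), `ecg` (`sampled_signal`
#'   or NULL), `truth` (ground truth including `true_beat_times` and
#'   `true_vagal_modulation`), and `config`.
#' @export
simulate_subject <- function(config, ecg = TRUE) {
  r <- simulate_respiration(config)
  b <- simulate_beat_times(r$truth, config)
  truth <- r$truth
  truth$true_beat_times <- b$beat_times
  truth$true_vagal_modulation <- b$modulation
  list(resp = r$signal,
       ecg = if (ecg) synthesize_ecg(b$beat_times, config) else NULL,
       truth = truth, config = config)
}

#' Simulate a cohort of subjects under a coupling scenario
#'
#' Per-subject seeds derive deterministically from the template's seed
#' (counter-based), and per-subject physiology is jittered around the
#' template: heart rate (SD 6 bpm), breathing rate (SD 0.03 Hz), depth
#' scale and depth variability (log-normal, SD 0.2).  The scenario fixes
#' the coupling gains: `depth-coupled` sets `(g, 0)`, `rate-coupled`
#' `(0, g)`, `null` `(0, 0)`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param config_template a [sim_config()]; its `seed` is the cohort
#'   master seed.
#' @param scenario `"depth-coupled"`, `"rate-coupled"` or `"null"`.
#' @param coupling_gain the scenario gain g (shipped default 0.25).
#' @param ecg synthesize ECG channels? (`FALSE` = fast path)
#' @return object of class `cardioresp_cohort`: list of subjects (each as
#'   [simulate_subject()] returns) with attributes `scenario` and
#'   `master_seed`.
#' @examples
#' coh <- simulate_cohort(3, sim_config(duration_s = 60, fs = 50, seed = 5),
#'                        scenario = "null", ecg = FALSE)
#' @export
simulate_cohort <- function(n_subjects, config_template,
                            scenario = c("depth-coupled", "rate-coupled",
                                         "null"),
                            coupling_gain = 0.25, ecg = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config_template, "sim_config"))
  if (n_subjects < 2) stop("a cohort needs at least 2 subjects")
  gains <- switch(scenario,
                  "depth-coupled" = c(coupling_gain, 0),
                  "rate-coupled" = c(0, coupling_gain),
                  "null" = c(0, 0))
  master <- config_template$seed
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sseed <- derive_seed(master, 1000L + i)
    set.seed(sseed)
    jit <- stats::rnorm(4)
    cfg <- config_template
    cfg$mean_hr_bpm <- min(max(cfg$mean_hr_bpm + 6 * jit[1], 45), 110)
    cfg$base_breath_rate_hz <-
      min(max(cfg$base_breath_rate_hz + 0.03 * jit[2], 0.15), 0.35)
    cfg$base_depth <- cfg$base_depth * exp(0.2 * jit[3])
    cfg$depth_sd <- cfg$depth_sd * exp(0.2 * jit[4])
    cfg$rsa_gain_depth <- gains[1]
    cfg$rsa_gain_rate <- gains[2]
    cfg$seed <- derive_seed(sseed, 9L)
    subjects[[i]] <- simulate_subject(cfg, ecg = ecg)
    subjects[[i]]$id <- sprintf("s%02d", i)
  }
  structure(subjects, scenario = scenario, master_seed = master,
            class = "cardioresp_cohort")
}

#' @export
print.cardioresp_cohort <- function(x, ...) {
  cat(sprintf("<cardioresp_cohort: %d subjects, scenario '%s', master seed %d>\n",
              length(x), attr(x, "scenario"), attr(x, "master_seed")))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One `time_s,value` CSV per channel per subject plus JSON sidecars
#' (fs, channel, seed, scenario).
#'
#' @param cohort a `cardioresp_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cardioresp_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scen <- attr(cohort, "scenario")
  for (s in cohort) {
    write_signal_csv(s$resp, file.path(dir, paste0(s$id, "_resp.csv")),
                     seed = s$config$seed, scenario = scen)
    if (!is.null(s$ecg))
      write_signal_csv(s$ecg, file.path(dir, paste0(s$id, "_ecg.csv")),
                       seed = s$config$seed, scenario = scen)
  }
  invisible(dir)
}
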