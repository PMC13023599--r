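# Configuration for the synthetic cardiorespiratory generator.

#' Simulation configuration
#'
#' Parameters of one synthetic subject.  Defaults emulate 5 min of quiet
#' seated rest recorded at 500 Hz: spontaneous breathing around 0.25 Hz
#' with slow, independent drifts of depth and rate, occasional sighs
#' (transient deep breaths), a resting heart rate of 70 bpm, and a
#' baseline of respiration-independent vagal modulation so the R-R series
#' varies even when no respiratory coupling is configured.
#'
#' @param duration_s record length, seconds.
#' @param fs sampling rate, Hz.
#' @param base_breath_rate_hz mean breathing rate, Hz; must lie in
#'   (0.05, 0.75) so the rhythm survives the 0.75 Hz low-pass.
#' @param breath_rate_sd_hz SD of the slow (< 0.05 Hz) breathing-rate
#'   drift, Hz.
#' @param base_depth mean respiratory depth, arbitrary units.
#' @param depth_sd SD of the slow depth drift, same units.
#' @param sigh_rate_per_min expected sigh events per minute; each sigh is
#'   a transient (~2 s SD Gaussian) boost of the depth envelope by one
#'   `base_depth`.
#' @param mean_hr_bpm mean heart rate, beats/min, in (30, 200).
#' @param rsa_gain_depth dimensionless gain coupling the vagal modulation
#'   amplitude to instantaneous depth (mean-normalized, clipped at 2.5x
#'   the mean so saturation bounds the modulation).
#' @param rsa_gain_rate as above, for instantaneous rate.
#' @param hrv_noise_gain amplitude of band-limited (0.04-0.40 Hz) vagal
#'   modulation independent of respiration; keeps R-R variability alive
#'   in the uncoupled (null) scenario.
#' @param drift_amp amplitude of a 0.005 Hz baseline drift added to the
#'   respiration channel (exercises the high-pass), same units as depth.
#' @param noise_sd_resp,noise_sd_ecg white measurement noise SDs.
#' @param seed integer RNG seed; identical seed + config gives
#'   bit-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(duration_s = 60, fs = 100, seed = 7)
#' @export
sim_config <- function(duration_s = 300, fs = 500,
                       base_breath_rate_hz = 0.25, breath_rate_sd_hz = 0.02,
                       base_depth = 1, depth_sd = 0.25,
                       sigh_rate_per_min = 0.5, mean_hr_bpm = 70,
                       rsa_gain_depth = 0, rsa_gain_rate = 0,
                       hrv_noise_gain = 0.08, drift_amp = 0.3,
                       noise_sd_resp = 0.02, noise_sd_ecg = 0.02,
                       seed = 1) {
  cfg <- list(duration_s = duration_s, fs = fs,
              base_breath_rate_hz = base_breath_rate_hz,
              breath_rate_sd_hz = breath_rate_sd_hz,
              base_depth = base_depth, depth_sd = depth_sd,
              sigh_rate_per_min = sigh_rate_per_min,
              mean_hr_bpm = mean_hr_bpm,
              rsa_gain_depth = rsa_gain_depth,
              rsa_gain_rate = rsa_gain_rate,
              hrv_noise_gain = hrv_noise_gain, drift_amp = drift_amp,
              noise_sd_resp = noise_sd_resp, noise_sd_ecg = noise_sd_ecg,
              seed = seed)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("sim_config field '", nm, "' must be a single finite number")
  }
  if (duration_s <= 0) stop("sim_config field 'duration_s' must be > 0")
  if (fs <= 0) stop("sim_config field 'fs' must be > 0")
  if (mean_hr_bpm <= 30 || mean_hr_bpm >= 200)
    stop("sim_config field 'mean_hr_bpm' must lie in (30, 200)")
  if (base_breath_rate_hz <= 0.05 || base_breath_rate_hz >= 0.75)
    stop("sim_config field 'base_breath_rate_hz' must lie in (0.05, 0.75)")
  neg <- c("breath_rate_sd_hz", "depth_sd", "sigh_rate_per_min",
           "hrv_noise_gain", "drift_amp", "noise_sd_resp", "noise_sd_ecg")
  for (nm in neg) if (cfg[[nm]] < 0)
    stop("sim_config field '", nm, "' must be >= 0")
  if (base_depth <= 0) stop("sim_config field 'base_depth' must be > 0")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config: %.0f s @ %g Hz, breathing %.2f Hz (sd %.3f), ",
    "depth %.2f (sd %.2f), HR %.0f bpm,\n  gains depth %.2f rate %.2f ",
    "noise %.2f, seed %d>\n"),
    x$duration_s, x$fs, x$base_breath_rate_hz, x$breath_rate_sd_hz,
    x$base_depth, x$depth_sd, x$mean_hr_bpm, x$rsa_gain_depth,
    x$rsa_gain_rate, x$hrv_noise_gain, x$seed))
  invisible(x)
}
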