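test_that("degenerate config collapses to a pure sinusoid with constant envelope", {
  cfg <- sim_config(duration_s = 60, fs = 100, breath_rate_sd_hz = 0,
                    depth_sd = 0, sigh_rate_per_min = 0, drift_amp = 0,
                    noise_sd_resp = 0, base_depth = 1.5, seed = 1)
  r <- simulate_respiration(cfg)
  expect_equal(r$truth$true_depth, rep(1.5, length(r$signal$values)))
  expect_equal(r$truth$true_rate, rep(0.25, length(r$signal$values)))
  expect_equal(r$signal$values, 1.5 * cos(r$truth$true_phase),
               tolerance = 1e-12)
})

test_that("same seed and config give bit-identical subjects", {
  cfg <- sim_config(duration_s = 40, fs = 100, rsa_gain_depth = 0.2,
                    seed = 99)
  a <- simulate_subject(cfg)
  b <- simulate_subject(cfg)
  expect_identical(a$resp$values, b$resp$values)
  expect_identical(a$ecg$values, b$ecg$values)
  expect_identical(a$truth$true_beat_times, b$truth$true_beat_times)
})

test_that("invalid config fields are rejected with the field named", {
  expect_error(sim_config(fs = NaN), "fs")
  expect_error(sim_config(mean_hr_bpm = 250), "mean_hr_bpm")
  expect_error(sim_config(base_breath_rate_hz = 0.9), "base_breath_rate_hz")
  expect_error(sim_config(depth_sd = -1), "depth_sd")
})

test_that("mean simulated breathing rate is centred on the configured base", {
  means <- vapply(1:100, function(s) {
    cfg <- sim_config(duration_s = 300, fs = 20, breath_rate_sd_hz = 0.01,
                      seed = s)
    mean(simulate_respiration(cfg)$truth$true_rate)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.25), 2 * se + 1e-12)
  # the slow drift is standardized per record, so each record mean is
  # already the base rate unless the positivity floor engages
  expect_lt(max(abs(means - 0.25)), 1e-10)
})

test_that("unmodulated IPFM emits beats at exactly the mean period", {
  cfg <- sim_config(duration_s = 120, fs = 100, mean_hr_bpm = 60,
                    breath_rate_sd_hz = 0, depth_sd = 0,
                    sigh_rate_per_min = 0, hrv_noise_gain = 0, seed = 3)
  r <- simulate_respiration(cfg)
  b <- simulate_beat_times(r$truth, cfg)
  expect_equal(diff(b$beat_times), rep(1, length(b$beat_times) - 1),
               tolerance = 1e-9)
  # beat count equals the floor of the total integrated rate; the last
  # sample sits at duration - 1/fs
  expect_equal(length(b$beat_times), floor((120 - 1 / 100) * 60 / 60))
})

test_that("depth coupling raises windowed RMSSD where true depth is larger", {
  cfg <- sim_config(duration_s = 300, fs = 50, rsa_gain_depth = 0.3,
                    hrv_noise_gain = 0, seed = 8)
  sub <- simulate_subject(cfg, ecg = FALSE)
  bt <- sub$truth$true_beat_times
  rr <- diff(bt) * 1000
  # brute-force 20 s windows
  edges <- seq(0, 300, by = 20)
  win_rmssd <- win_depth <- numeric(length(edges) - 1)
  for (i in seq_len(length(edges) - 1)) {
    sel <- bt[-1] > edges[i] & bt[-1] <= edges[i + 1]
    win_rmssd[i] <- sqrt(mean(diff(rr[sel])^2))
    dsel <- sub$truth$t > edges[i] & sub$truth$t <= edges[i + 1]
    win_depth[i] <- mean(sub$truth$true_depth[dsel])
  }
  expect_gt(cor(win_depth, win_rmssd, method = "spearman"), 0)
})

test_that("doubling the depth gain strictly increases whole-record RMSSD", {
  rmssd_at <- function(g) {
    cfg <- sim_config(duration_s = 180, fs = 50, rsa_gain_depth = g,
                      hrv_noise_gain = 0, seed = 21)
    sub <- simulate_subject(cfg, ecg = FALSE)
    sqrt(mean(diff(diff(sub$truth$true_beat_times) * 1000)^2))
  }
  expect_gt(rmssd_at(0.3), rmssd_at(0.15))
})

test_that("excessive modulation gain is rejected naming the gain", {
  cfg <- sim_config(duration_s = 60, fs = 50, rsa_gain_depth = 0.9,
                    seed = 5)
  r <- simulate_respiration(cfg)
  expect_error(simulate_beat_times(r$truth, cfg), "rsa_gain_depth")
})

test_that("ECG template peaks at the beat time and scales linearly", {
  cfg <- sim_config(duration_s = 20, fs = 500, noise_sd_ecg = 0, seed = 2)
  e1 <- synthesize_ecg(10, cfg, pt_waves = FALSE)
  t <- signal_times(e1)
  expect_lt(abs(t[which.max(e1$values)] - 10), 0.002)
  e3 <- synthesize_ecg(10, cfg, amplitude = 3, pt_waves = FALSE)
  expect_equal(e3$values, 3 * e1$values, tolerance = 1e-12)
})

test_that("ECG synthesis warns on sub-refractory beat spacing", {
  cfg <- sim_config(duration_s = 10, fs = 200, seed = 2)
  expect_warning(synthesize_ecg(c(5, 5.1), cfg), "refractory")
  expect_error(synthesize_ecg(c(5, 4), cfg), "increasing")
  expect_error(synthesize_ecg(c(5, 12), cfg), "duration")
})

test_that("cohort generation is reproducible with distinct per-subject seeds", {
  cfgt <- sim_config(duration_s = 40, fs = 50, seed = 7)
  coh <- simulate_cohort(33, cfgt, scenario = "depth-coupled", ecg = FALSE)
  expect_length(coh, 33)
  seeds <- vapply(coh, function(s) s$config$seed, numeric(1))
  expect_length(unique(seeds), 33)
  lens <- vapply(coh, function(s) length(s$resp$values), numeric(1))
  expect_true(all(lens == 40 * 50))
  gains <- vapply(coh, function(s) s$config$rsa_gain_depth, numeric(1))
  expect_true(all(gains == 0.25))
  coh2 <- simulate_cohort(33, cfgt, scenario = "depth-coupled", ecg = FALSE)
  expect_identical(coh[[17]]$resp$values, coh2[[17]]$resp$values)
})

test_that("null scenario zeroes both coupling gains", {
  cfgt <- sim_config(duration_s = 40, fs = 50, seed = 7)
  coh <- simulate_cohort(2, cfgt, scenario = "null", ecg = FALSE)
  for (s in coh) {
    expect_identical(s$config$rsa_gain_depth, 0)
    expect_identical(s$config$rsa_gain_rate, 0)
  }
})

test_that("coupled R-R spectrum peaks at the mean breathing rate", {
  cfg <- sim_config(duration_s = 300, fs = 50, rsa_gain_depth = 0.3,
                    hrv_noise_gain = 0, breath_rate_sd_hz = 0.005,
                    seed = 13)
  sub <- simulate_subject(cfg, ecg = FALSE)
  bt <- sub$truth$true_beat_times
  rr <- diff(bt) * 1000
  freqs <- seq(0.05, 0.45, by = 1 / 300)
  psd <- resphrv:::lomb_psd(bt[-1], rr, freqs)
  f_peak <- freqs[which.max(psd)]
  expect_lt(abs(f_peak - mean(sub$truth$true_rate)), 2 / 300)
})

test_that("cohort writer round-trips signals through CSV + sidecar", {
  dir <- withr::local_tempdir()
  cfgt <- sim_config(duration_s = 35, fs = 40, seed = 31)
  coh <- simulate_cohort(2, cfgt, scenario = "null", ecg = TRUE)
  write_cohort(coh, dir)
  back <- read_signal_csv(file.path(dir, "s01_resp.csv"))
  expect_equal(back$values, coh[[1]]$resp$values, tolerance = 1e-12)
  expect_identical(back$fs, coh[[1]]$resp$fs)
})
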