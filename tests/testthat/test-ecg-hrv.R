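test_that("detector recovers every clean template beat within 10 ms", {
  cfg <- sim_config(duration_s = 120, fs = 250, mean_hr_bpm = 65,
                    rsa_gain_depth = 0.2, noise_sd_ecg = 0, seed = 11)
  sub <- simulate_subject(cfg)
  pk <- detect_r_peaks(sub$ecg)
  m <- match_beats(sub$truth$true_beat_times, pk$peak_times, tol_s = 0.05)
  expect_identical(m$sensitivity, 1)
  expect_identical(m$ppv, 1)
  expect_lt(m$max_err_s, 0.010)
})

test_that("flat or too-short input is handled explicitly", {
  flat <- sampled_signal(rep(1, 2000), fs = 200)
  expect_warning(pk <- detect_r_peaks(flat), "peak")
  expect_length(pk$peak_times, 0)
  expect_error(detect_r_peaks(sampled_signal(rnorm(100), fs = 200)), "2 s")
  expect_error(detect_r_peaks(sampled_signal(rnorm(500), fs = 50)), "100 Hz")
})

test_that("detector keeps sensitivity and PPV above 0.99 under noise", {
  cfg <- sim_config(duration_s = 180, fs = 250, mean_hr_bpm = 100,
                    rsa_gain_depth = 0.2, noise_sd_ecg = 0.1, seed = 23)
  sub <- simulate_subject(cfg)
  pk <- detect_r_peaks(sub$ecg)
  m <- match_beats(sub$truth$true_beat_times, pk$peak_times, tol_s = 0.05)
  expect_gte(m$sensitivity, 0.99)
  expect_gte(m$ppv, 0.99)
})

test_that("detected peaks respect the refractory period", {
  cfg <- sim_config(duration_s = 60, fs = 250, noise_sd_ecg = 0.05,
                    seed = 31)
  sub <- simulate_subject(cfg)
  pk <- detect_r_peaks(sub$ecg)
  expect_true(all(diff(pk$peak_times) > 0.2))
})

test_that("R-R gating leaves a fully valid series untouched", {
  bt <- cumsum(c(0, rep(0.8, 50)))
  rr <- clean_and_interpolate_rr(bt)
  expect_true(all(rr$valid))
  expect_identical(rr$rr_repaired_ms, rr$rr_ms)
  expect_equal(rr$rr_ms, rep(800, 50), tolerance = 1e-9)
})

test_that("an out-of-range interval is repaired by the natural spline", {
  # intervals 800, 800, 2000, 800, 800 ms: the third is gated out
  bt <- cumsum(c(0, 0.8, 0.8, 2.0, 0.8, 0.8))
  rr <- clean_and_interpolate_rr(bt)
  expect_identical(which(!rr$valid), 3L)
  oracle <- oracle_natural_spline(c(1, 2, 4, 5), rr$rr_ms[c(1, 2, 4, 5)], 3)
  expect_equal(rr$rr_repaired_ms[3], oracle, tolerance = 1e-9)
  expect_identical(rr$rr_repaired_ms[-3], rr$rr_ms[-3])
})

test_that("gating bounds are inclusive at 250 and 1500 ms", {
  bt <- cumsum(c(0, 0.8, 0.25, 0.8, 1.5, 0.8))
  rr <- clean_and_interpolate_rr(bt)
  expect_true(all(rr$valid))
})

test_that("edge-invalid runs take the nearest valid value with a warning", {
  bt <- cumsum(c(0, 2.0, 0.8, 0.82, 0.78, 0.8, 2.0))
  expect_warning(rr <- clean_and_interpolate_rr(bt), "edge")
  expect_equal(rr$rr_repaired_ms[1], rr$rr_ms[2], tolerance = 1e-9)
  expect_equal(rr$rr_repaired_ms[6], rr$rr_ms[5], tolerance = 1e-9)
})

test_that("too few valid intervals are rejected", {
  expect_error(clean_and_interpolate_rr(cumsum(c(0, 2, 2, 2, 2, 0.8))),
               "valid")
})

test_that("Hermite resampling preserves constants, shape and sinusoids", {
  bt <- cumsum(c(0, rep(0.8, 100)))
  rr <- clean_and_interpolate_rr(bt)
  res <- resample_rr(rr)
  expect_equal(diff(res$grid_times), rep(0.1, length(res$grid_times) - 1),
               tolerance = 1e-12)
  expect_equal(res$rr_ms, rep(800, length(res$rr_ms)), tolerance = 1e-9)

  # monotone data stay monotone (no overshoot between knots)
  bt2 <- cumsum(c(0, seq(0.6, 1.2, length.out = 40)))
  res2 <- resample_rr(clean_and_interpolate_rr(bt2))
  expect_true(all(diff(res2$rr_ms) >= -1e-9))

  # sinusoidal modulation is tracked within 5 ms
  n <- 200
  gaps <- numeric(n); tcur <- 0
  for (i in 1:n) {
    gaps[i] <- (800 + 50 * sin(2 * pi * 0.25 * tcur)) / 1000
    tcur <- tcur + gaps[i]
  }
  bt3 <- cumsum(c(0, gaps))
  res3 <- resample_rr(clean_and_interpolate_rr(bt3))
  # each interval value is the sinusoid sampled at the interval start
  truth_fun <- approxfun(bt3[-length(bt3)],
                         800 + 50 * sin(2 * pi * 0.25 * bt3[-length(bt3)]))
  keep <- res3$grid_times > 2 & res3$grid_times < max(bt3) - 2
  rmse <- sqrt(mean((res3$rr_ms[keep] - truth_fun(res3$grid_times[keep] - 0.8))^2,
                    na.rm = TRUE))
  expect_lt(rmse, 5)
})

test_that("RMSSD matches hand computations", {
  expect_equal(rmssd_window(c(800, 850, 800)), 50)
  expect_equal(rmssd_window(rep(800, 10)), 0)
  expect_equal(rmssd_window(c(700, 900, 700, 900)), 200)
  expect_true(is.na(rmssd_window(800)))
})

test_that("CVI components match the hand-computed Poincare transform", {
  # linear ramp: constant successive difference, SD1 = 0 -> floored
  ramp <- cvi_window(seq(700, 900, by = 50))
  expect_equal(ramp$sd1, 0)
  expect_true(ramp$floored)
  expect_equal(ramp$cvi, log10(1e-6))

  # alternating 700/900: sums constant -> SD2 = 0, SD1 = 200/sqrt(2)
  alt <- cvi_window(c(700, 900, 700, 900, 700))
  expect_equal(alt$sd1, 200 / sqrt(2), tolerance = 1e-12)
  expect_equal(alt$sd2, 0)
  expect_true(alt$floored)
})

test_that("SD1 tracks RMSSD/sqrt(2) when successive differences are centred", {
  set.seed(4)
  for (r in 1:5) {
    v <- 800 + cumsum(rnorm(200, 0, 10))
    got <- cvi_window(v)
    d <- diff(v)
    if (abs(mean(d)) < 2) {
      expect_equal(got$sd1, rmssd_window(v) / sqrt(2), tolerance = 0.05)
    }
    # exact oracle re-derivation
    expect_equal(got$sd1, sqrt(mean((d - mean(d))^2) / 2), tolerance = 1e-12)
  }
})

test_that("Lomb HF power matches the sinusoid closed form on a long window", {
  n <- 75
  gaps <- numeric(n); tcur <- 0.8
  for (i in 1:n) {
    gaps[i] <- (800 + 50 * sin(2 * pi * 0.25 * tcur)) / 1000
    tcur <- tcur + gaps[i]
  }
  bt <- cumsum(c(0.8, gaps))
  rrv <- diff(bt) * 1000
  hf <- hf_power_window(bt[-1], rrv)
  expect_lt(abs(10^hf - 50^2 / 2), 0.10 * 50^2 / 2)

  # out-of-band modulation leaks under 5% of the in-band case
  gaps2 <- numeric(n); tcur <- 0.8
  for (i in 1:n) {
    gaps2[i] <- (800 + 50 * sin(2 * pi * 0.05 * tcur)) / 1000
    tcur <- tcur + gaps2[i]
  }
  bt2 <- cumsum(c(0.8, gaps2))
  hf2 <- hf_power_window(bt2[-1], diff(bt2) * 1000)
  expect_lt(10^hf2, 0.05 * 10^hf)
})

test_that("constant R-R window floors the HF estimate", {
  expect_equal(hf_power_window(seq(1, 5, by = 0.8), rep(800, 6)),
               log10(1e-6))
})

test_that("sliding track is constant-stationary on a metronomic record", {
  bt <- cumsum(c(0, rep(0.8, 150)))
  trk <- sliding_hrv(clean_and_interpolate_rr(bt))
  ok <- !is.na(trk$rmssd_ms)
  expect_true(any(ok))
  # beat times built by cumsum carry ~1e-13 ms float dust
  expect_lt(max(trk$rmssd_ms[ok]), 1e-9)
  expect_true(all(trk$hf_log[!is.na(trk$hf_log)] == log10(1e-6)))
})

test_that("grid arithmetic and edge missingness follow the window definition", {
  bt <- cumsum(c(0, rep(0.8, 150)))   # beats 0 .. 120 s
  trk <- sliding_hrv(clean_and_interpolate_rr(bt))
  span <- floor(120 / 0.1) * 0.1
  expect_length(trk$grid_times, span / 0.1 + 1)
  edge <- trk$grid_times < 2.5 | trk$grid_times > 120 - 2.5
  expect_true(all(is.na(trk$rmssd_ms[edge])))
  expect_true(all(is.na(trk$n_beats_per_window[edge])))
})

test_that("sliding HF equals the per-window estimator on every grid point", {
  set.seed(9)
  bt <- cumsum(c(1, 0.8 + 0.05 * sin(2 * pi * 0.25 * (1:120)) +
                   rnorm(120, 0, 0.02)))
  rr <- clean_and_interpolate_rr(bt)
  trk <- sliding_hrv(rr)
  it <- rr$interval_times; rv <- rr$rr_repaired_ms
  for (g in which(!is.na(trk$hf_log))[seq(1, sum(!is.na(trk$hf_log)), by = 97)]) {
    t <- trk$grid_times[g]
    sel <- it >= t - 2.5 - 1e-9 & it <= t + 2.5 + 1e-9
    expect_equal(trk$hf_log[g], hf_power_window(it[sel], rv[sel]),
                 tolerance = 1e-9)
    expect_equal(trk$rmssd_ms[g], rmssd_window(rv[sel]), tolerance = 1e-9)
    expect_equal(trk$cvi[g], cvi_window(rv[sel])$cvi, tolerance = 1e-9)
  }
})

test_that("RMSSD is scale-equivariant and CVI shifts by 2 log10 c", {
  set.seed(12)
  v <- 800 + cumsum(rnorm(50, 0, 15))
  c0 <- 1.7
  expect_equal(rmssd_window(c0 * v), c0 * rmssd_window(v), tolerance = 1e-12)
  expect_equal(cvi_window(c0 * v)$cvi, cvi_window(v)$cvi + 2 * log10(c0),
               tolerance = 1e-12)
})

test_that("in-band modulation never decreases long-window band power", {
  n <- 120
  make_rr <- function(amp) {
    gaps <- numeric(n); tcur <- 0.8
    for (i in 1:n) {
      gaps[i] <- (850 + amp * sin(2 * pi * 0.3 * tcur)) / 1000
      tcur <- tcur + gaps[i]
    }
    bt <- cumsum(c(0.8, gaps))
    hf_power_window(bt[-1], diff(bt) * 1000)
  }
  pows <- vapply(c(0, 10, 25, 50), make_rr, numeric(1))
  expect_true(all(diff(pows) > 0))
})

test_that("depth-coupled simulation shows RMSSD tracking true depth end-to-end", {
  cfg <- sim_config(duration_s = 240, fs = 50, rsa_gain_depth = 0.3,
                    seed = 41)
  sub <- simulate_subject(cfg, ecg = FALSE)
  rr <- clean_and_interpolate_rr(sub$truth$true_beat_times)
  trk <- sliding_hrv(rr)
  depth_on_grid <- align_measure(sub$truth$true_depth, 50, 0,
                                 trk$grid_times)
  ok <- !is.na(trk$rmssd_ms) & !is.na(depth_on_grid)
  expect_gt(cor(depth_on_grid[ok], trk$rmssd_ms[ok], method = "spearman"),
            0)
})

test_that("resampled-input HF option runs and stays close in rank to beat-domain HF", {
  set.seed(5)
  bt <- cumsum(c(1, 0.8 + 0.06 * sin(2 * pi * 0.25 * (1:150)) +
                   rnorm(150, 0, 0.01)))
  rr <- clean_and_interpolate_rr(bt)
  t1 <- sliding_hrv(rr, hf_input = "beats")
  t2 <- sliding_hrv(rr, hf_input = "resampled")
  ok <- !is.na(t1$hf_log) & !is.na(t2$hf_log)
  expect_gt(cor(t1$hf_log[ok], t2$hf_log[ok], method = "spearman"), 0.7)
})
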