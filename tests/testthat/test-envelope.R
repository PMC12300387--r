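test_that("rate of change of a line is its slope; tone envelope is flat", {
  fs <- 1000
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ramp <- fpi_trace(tt, 0.3 * tt)
  env <- compute_envelope(ramp, trim_s = 0.5)
  mid <- seq(500, length(env$rate_of_change) - 500)
  expect_equal(env$rate_of_change[mid], rep(0.3, length(mid)),
               tolerance = 1e-6)

  tone <- fpi_trace(tt, cos(2 * pi * 10 * tt))
  env2 <- compute_envelope(tone, trim_s = 0.5)
  mid2 <- seq(1000, length(env2$envelope) - 1000)
  # analytic envelope of a pure tone is constant: flat within 5% mid-span
  expect_lt(diff(range(env2$envelope[mid2])), 0.05)
  expect_equal(max(env2$envelope), 1)
  expect_true(all(env2$envelope >= 0))
})

test_that("envelope preconditions are enforced", {
  fs <- 100
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  tr <- fpi_trace(tt, sin(2 * pi * 3 * tt))
  expect_error(compute_envelope(tr, trim_s = 0.6), "trim_s")
  expect_error(compute_envelope(tr, trim_s = 0, band = c(10, 5)), "band")
  expect_error(compute_envelope(tr, trim_s = 0, band = c(0.5, 60)), "band")
})

test_that("envelope peak detection honours height and greedy distance", {
  fs <- 1000
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  bumps <- exp(-(tt - 1)^2 / (2 * 0.05^2)) +
    0.8 * exp(-(tt - 2)^2 / (2 * 0.05^2))
  sig <- list(time_s = tt, values = bumps, sampling_rate_hz = fs)
  p2 <- detect_envelope_peaks(sig, min_height = 0.3, min_distance_s = 0.5)
  expect_length(p2, 2L)
  expect_equal(p2, c(1, 2), tolerance = 2 / fs)
  # under a wider exclusion zone only the taller bump survives
  p1 <- detect_envelope_peaks(sig, min_height = 0.3, min_distance_s = 1.5)
  expect_equal(p1, 1, tolerance = 2 / fs)
  # flat envelope: nothing to find
  flat <- list(time_s = tt, values = rep(0.5, length(tt)),
               sampling_rate_hz = fs)
  expect_length(detect_envelope_peaks(flat), 0L)
})

test_that("epoch averaging reproduces degenerate and stochastic cases", {
  fs <- 100
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  template <- sin(2 * pi * 2 * tt[1:100])
  x <- rep(template, 60)
  sig <- list(time_s = tt, values = x, sampling_rate_hz = fs)
  peaks <- seq(5, 55, by = 1)
  avg <- epoch_average(sig, peaks, window = c(-0.2, 0.2))
  # identical epochs: zero-width CI, mean equals the epoch
  expect_equal(avg$ci_upper, avg$ci_lower, tolerance = 1e-12)
  expect_equal(avg$epoch_count, length(peaks))
  expect_true(all(avg$ci_lower <= avg$mean_signal + 1e-12))

  # two pointwise-opposite epochs average to zero
  y <- c(rep(1, 100), rep(-1, 100))
  sig2 <- list(time_s = tt[1:200], values = y, sampling_rate_hz = fs)
  avg2 <- epoch_average(sig2, c(0.5, 1.5), window = c(-0.2, 0.2))
  expect_equal(avg2$mean_signal, rep(0, length(avg2$mean_signal)))

  # k = 100 i.i.d. N(0,1) epochs: CI half-width ~ 1.96 / 10
  set.seed(7)
  noise <- list(time_s = seq(0, 110 - 1 / fs, by = 1 / fs),
                values = rnorm(110 * fs), sampling_rate_hz = fs)
  avg3 <- epoch_average(noise, seq(5, 104, by = 1), window = c(-0.2, 0.2))
  half <- mean((avg3$ci_upper - avg3$ci_lower) / 2)
  expect_equal(half, 0.196, tolerance = 0.2)

  # windows beyond the extent are dropped; none usable is an error
  avg4 <- epoch_average(sig, c(0.05, 5), window = c(-0.2, 0.2))
  expect_equal(avg4$dropped_count, 1L)
  expect_error(epoch_average(sig, 0.05, window = c(-0.2, 0.2)), "usable")
})

test_that("epoch minima map to absolute times for every peak", {
  fs <- 1000
  t_rel <- seq(-0.5, 0.5, by = 1 / fs)
  avg <- structure(
    list(epoch_time_s = t_rel,
         mean_signal = -cos(2 * pi * t_rel),
         ci_lower = -cos(2 * pi * t_rel), ci_upper = -cos(2 * pi * t_rel),
         epoch_count = 5L, dropped_count = 0L, sampling_rate_hz = fs),
    class = "epoch_average"
  )
  cat1 <- detect_epoch_minima(avg, peak_times = c(2, 3))
  expect_equal(cat1$absolute_time_s, c(2, 3), tolerance = 1e-9)
  expect_equal(unique(cat1$epoch_rel_time_s), 0, tolerance = 1e-9)

  # monotonic mean: no interior trough
  avg$mean_signal <- t_rel
  expect_equal(nrow(detect_epoch_minima(avg, peak_times = c(2, 3))), 0L)

  # two troughs map to every peak
  avg$mean_signal <- -exp(-(t_rel - 0.1)^2 / (2 * 0.03^2)) -
    exp(-(t_rel - 0.4)^2 / (2 * 0.03^2))
  cat2 <- detect_epoch_minima(avg, peak_times = c(2, 3))
  expect_equal(cat2$absolute_time_s, c(2.1, 2.4, 3.1, 3.4),
               tolerance = 1e-3)
  # manual truncation mirrors the drop-first / drop-last controls
  cat3 <- detect_epoch_minima(avg, peak_times = c(2, 3),
                              drop_first = 1, drop_last = 2)
  expect_equal(cat3$absolute_time_s, 2.4, tolerance = 1e-3)
})

test_that("minima catalog round-trips through CSV", {
  run <- fx_roundtrip(noise_sd = 0.01, seed = 1)
  env <- compute_envelope(preprocess_trace(run$recording$trace))
  peaks <- detect_envelope_peaks(env)
  minima <- detect_epoch_minima(epoch_average(env, peaks), peaks)
  expect_gt(nrow(minima), 0L)
  expect_true(all(diff(minima$absolute_time_s) > 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_minima(minima, path)
  back <- read_minima(path)
  expect_equal(back$absolute_time_s, minima$absolute_time_s,
               tolerance = 1e-9)
})

test_that("envelope peaks track systolic upstrokes within 100 ms up to 5% noise", {
  for (noise in c(0.01, 0.05)) {
    rec <- fx_recording(noise_sd = noise, seed = 1)
    pre <- preprocess_trace(rec$trace)
    peaks <- detect_envelope_peaks(compute_envelope(pre))
    onsets <- rec$events$time_s[rec$events$label == "systole_start"]
    for (p in peaks) {
      expect_lt(min(abs(onsets - p)), 0.1)
    }
    expect_gte(length(peaks), 10L)
  }
})
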