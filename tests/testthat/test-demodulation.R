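test_that("the halfwave quantum matches lambda/(4n)", {
  expect_equal(halfwave_quantum(optical_config()), 386.7, tolerance = 0.05 / 386.7)
  expect_equal(halfwave_quantum(optical_config(refractive_index = 1)),
               387.825, tolerance = 1e-9)
  expect_lt(halfwave_quantum(optical_config(refractive_index = 1e9)), 1e-3)
})

test_that("halfwave numbers follow the count-up / flip-at-breakpoint rule", {
  ann <- fx_annotations(c("MAX", "BP", "MIN", "MAX", "MIN", "BP",
                          "MAX", "MIN"))
  hw <- assign_halfwave(ann)
  expect_identical(hw$anchors$m, c(1L, 2L, 3L, 2L, 1L))
  expect_length(hw$breakpoint_times_s, 2L)

  # zero before baseline: annotation inconsistent
  expect_error(assign_halfwave(fx_annotations(c("MAX", "BP", "MIN", "BP",
                                                "MAX"))),
               "reached 0")
  # below zero is always an error
  expect_error(
    assign_halfwave(fx_annotations(c("MAX", "BP", "MIN", "BP", "MAX",
                                     "MIN"))),
    "0")
  expect_error(assign_halfwave(fx_annotations(c("MAX", "MIN", "MAX"))),
               "no breakpoint")
})

test_that("a baseline touch immediately before a breakpoint is legitimate", {
  ann <- fx_annotations(c("MAX", "BP", "MIN", "BP", "MAX", "BP", "MIN"))
  hw <- assign_halfwave(ann)
  expect_identical(hw$anchors$m, c(1L, 0L, 1L))
})

test_that("anchor displacements are exact multiples of the quantum", {
  ann <- fx_annotations(c("MAX", "BP", "MIN", "MAX", "MIN", "BP",
                          "MAX", "MIN"))
  hw <- assign_halfwave(ann)
  opt <- optical_config()
  anchors <- delta_z_at_anchors(hw, opt)
  q <- halfwave_quantum(opt)
  expect_equal(anchors$delta_z_nm, anchors$m * q)
  expect_equal(anchors$delta_z_nm[anchors$m == 1][1], 386.7,
               tolerance = 0.1 / 386.7)
  expect_equal(sort(unique(anchors$delta_z_nm)),
               c(386.7, 773.3, 1160.0), tolerance = 0.1 / 386.7)
})

test_that("reconstruction interpolates anchors and refuses bad input", {
  anchors <- data.frame(time_s = 1:6 / 10, m = 1:6,
                        delta_z_nm = (1:6) * 100)
  grid <- seq(0, 1, by = 0.01)
  disp <- reconstruct_displacement(anchors, numeric(0), grid)
  # anchors on a line: the cubic reproduces the line everywhere
  inside <- disp$time_s >= 0.1 & disp$time_s <= 0.6
  expect_equal(disp$delta_z_nm, disp$time_s * 1000, tolerance = 1e-9)
  expect_true(all(inside))  # no extrapolation beyond the anchor span

  expect_error(reconstruct_displacement(anchors[1:3, ], numeric(0), grid),
               "at least 4 anchors")
  bad <- anchors; bad$time_s[3] <- bad$time_s[2]
  expect_error(reconstruct_displacement(bad, numeric(0), grid),
               "strictly increasing")

  # breakpoint displacements come from the anchor spline
  disp2 <- reconstruct_displacement(anchors, 0.35, grid)
  bp <- attr(disp2, "breakpoints")
  expect_equal(bp$delta_z_nm, 350, tolerance = 1e-9)
})

test_that("per-sample m is the last anchor's halfwave number", {
  anchors <- data.frame(time_s = c(0.1, 0.2, 0.3, 0.4), m = c(1L, 2L, 3L, 2L),
                        delta_z_nm = c(1, 2, 3, 2) * 386.7)
  disp <- reconstruct_displacement(anchors, numeric(0), seq(0, 1, by = 0.05))
  expect_identical(disp$m[disp$time_s < 0.2], rep(1L, sum(disp$time_s < 0.2)))
  expect_identical(disp$m[disp$time_s >= 0.4], 2L)
})

test_that("noise-free round trip reconstructs displacement to one quantum", {
  run <- fx_roundtrip(noise_sd = 0, seed = 1)
  q <- halfwave_quantum(optical_config())
  resid <- fx_truth_residual(run)
  expect_lte(sqrt(mean(resid^2)), q)
  expect_lte(max(abs(resid)), 2 * q)
  # quantization law on the anchors actually used
  anch <- attr(run$displacement, "anchors")
  expect_equal(anch$delta_z_nm, anch$m * q, tolerance = 1e-12)
})

test_that("demodulated CSV carries time, m, delta_z and I2_t", {
  run <- fx_roundtrip(noise_sd = 0.01, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_displacement(run$displacement, path)
  expect_identical(readLines(path, n = 1),
                   "\"time\",\"m\",\"delta_z\",\"I2_t\"")
  back <- read_displacement(path)
  expect_equal(back$delta_z_nm, run$displacement$delta_z_nm,
               tolerance = 1e-9)
  expect_true(all(is.finite(back$I2_t)))
})

test_that("demodulate rejects annotations from a different time axis", {
  run <- fx_roundtrip(noise_sd = 0.01, seed = 1)
  pre <- preprocess_trace(run$recording$trace)
  ann <- run$annotations
  shifted <- ann$points
  shifted$time_s <- shifted$time_s + 0.31
  shifted_ann <- annotation_set(shifted, ann$analysis_window + 0.31)
  expect_error(demodulate(pre, shifted_ann), "time axis")
})

test_that("the cavity-shortening sign is unrecoverable: both signs demodulate alike", {
  tmpl <- apw_template(n_cycles = 6L)
  runs <- lapply(c(-1, 1), function(s) {
    prof <- make_apw(tmpl, 10000, seed = 2)
    rec <- render_interferogram(prof, noise_sd = 0, seed = 2, sign = s)
    pre <- preprocess_trace(rec$trace)
    env <- compute_envelope(pre)
    peaks <- detect_envelope_peaks(env)
    minima <- detect_epoch_minima(epoch_average(env, peaks), peaks)
    ext <- detect_extrema(pre)
    ann <- enforce_bp_parity(
      build_annotations(ext, propose_breakpoints(ext, minima)), peaks)
    demodulate(pre, ann)
  })
  common <- intersect(round(runs[[1]]$time_s * 1e4),
                      round(runs[[2]]$time_s * 1e4))
  z1 <- runs[[1]]$delta_z_nm[match(common, round(runs[[1]]$time_s * 1e4))]
  z2 <- runs[[2]]$delta_z_nm[match(common, round(runs[[2]]$time_s * 1e4))]
  # magnitude-from-baseline reporting maps both physical signs onto the
  # same curve up to a constant offset
  resid <- (z1 - z2) - mean(z1 - z2)
  expect_lte(max(abs(resid)), 2 * halfwave_quantum(optical_config()))
})
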