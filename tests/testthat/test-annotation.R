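test_that("fringe extrema of a pure tone alternate at the analytic positions", {
  fs <- 1000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  tr <- fpi_trace(tt, (cos(2 * pi * 5 * tt) + 1) / 2)
  ext <- detect_extrema(tr, prominence = 0.05)
  n_max <- sum(ext$status == "MAX")
  n_min <- sum(ext$status == "MIN")
  expect_lte(abs(n_max - 5L), 1L)
  expect_lte(abs(n_min - 5L), 1L)
  expect_true(all(ext$status[-1] != ext$status[-nrow(ext)]))
  # analytic extrema of cos(2 pi 5 t) sit on the k/10 grid
  expect_true(all(abs(ext$time_s * 10 - round(ext$time_s * 10)) < 0.02))
})

test_that("a monotonic ramp carries no fringes and errors", {
  tt <- seq(0, 1, by = 1e-3)
  expect_error(detect_extrema(fpi_trace(tt, tt), prominence = 0.05),
               "fewer than 2 extrema")
})

test_that("alternation repair keeps the more extreme of close same-type peaks", {
  fs <- 1000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  # two maxima split by a dip shallower than the excursion threshold
  key_t <- c(0, 0.30, 0.36, 0.42, 0.60, 0.80, 1 - 1 / fs)
  key_v <- c(0, 1.00, 0.97, 0.99, 0.20, 0.80, 0)
  x <- stats::approx(key_t, key_v, xout = tt)$y
  ext <- detect_extrema(fpi_trace(tt, x), prominence = 0.05, smooth_hz = 0)
  # the 1.00 / 0.97 / 0.99 cluster collapses onto the taller maximum
  expect_identical(ext$status, c("MAX", "MIN", "MAX"))
  expect_lt(abs(ext$time_s[1] - 0.30), 0.01)
})

test_that("breakpoint proposal picks candidates within the search radius", {
  ext <- data.frame(sample_index = c(100L, 200L), time_s = c(2.35, 2.52),
                    value = c(0.98, 0.03), status = c("MAX", "MIN"))
  minima <- structure(data.frame(absolute_time_s = 2.40, amplitude = 0.1,
                                 epoch_rel_time_s = 0.1),
                      class = c("minima_catalog", "data.frame"))
  bp <- propose_breakpoints(ext, minima, search_radius_s = 0.1)
  expect_equal(bp$time_s, 2.35)
  expect_identical(bp$status, "BP")

  expect_equal(nrow(propose_breakpoints(ext, minima[0, ],
                                        search_radius_s = 0.1)), 0L)
  # degenerate radius: only exact coincidences qualify
  expect_warning(
    bp0 <- propose_breakpoints(ext, minima, search_radius_s = 0),
    "skipped")
  expect_equal(nrow(bp0), 0L)
  minima2 <- structure(data.frame(absolute_time_s = 2.35, amplitude = 0.1,
                                  epoch_rel_time_s = 0.1),
                       class = c("minima_catalog", "data.frame"))
  expect_equal(propose_breakpoints(ext, minima2, search_radius_s = 0)$time_s,
               2.35)
})

test_that("the reversal rule prefers partial-fringe extrema over nearer rails", {
  ext <- data.frame(sample_index = c(1L, 2L, 3L),
                    time_s = c(0.98, 1.00, 1.02),
                    value = c(0.02, 0.97, 0.60),
                    status = c("MIN", "MAX", "MIN"))
  minima <- structure(data.frame(absolute_time_s = 0.995, amplitude = 0,
                                 epoch_rel_time_s = 0),
                      class = c("minima_catalog", "data.frame"))
  bp_rev <- propose_breakpoints(ext, minima, search_radius_s = 0.15,
                                method = "reversal")
  expect_equal(bp_rev$time_s, 1.02)   # the mid-scale extremum
  bp_near <- propose_breakpoints(ext, minima, search_radius_s = 0.15,
                                 method = "nearest")
  expect_equal(bp_near$time_s, 1.00)  # the closest one
})

test_that("annotation sets enforce ordering, tokens and the window", {
  pts <- data.frame(sample_index = 0:2, time_s = c(0.1, 0.2, 0.3),
                    value = c(1, 0, 1), status = c("MAX", "BP", "MIN"))
  ann <- annotation_set(pts, c(0, 1))
  expect_s3_class(ann, "annotation_set")
  expect_error(annotation_set(transform(pts, status = c("MAX", "XX", "MIN")),
                              c(0, 1)), "status")
  expect_error(annotation_set(transform(pts, time_s = c(0.1, 0.1, 0.3)),
                              c(0, 1)), "strictly increasing")
  expect_error(annotation_set(pts, c(0.15, 1)), "window")
})

test_that("scripted edits mutate the set and leave an audit trail", {
  pts <- data.frame(sample_index = c(0L, 10L, 20L, 30L),
                    time_s = c(0.0, 0.1, 0.2, 0.3),
                    value = c(1, 0.5, 0, 1),
                    status = c("MAX", "BP", "MIN", "MAX"))
  ann <- annotation_set(pts, c(-0.1, 1))

  rel <- apply_edits(ann, list(list(op = "relabel", index = 20L,
                                    status = "BP")))
  expect_identical(sum(rel$points$status == "BP"), 2L)

  # remove-then-add restores the set; audit log keeps both commands
  back <- apply_edits(ann, list(
    list(op = "remove", index = 20L),
    list(op = "add", index = 20L, time = 0.2, value = 0, status = "MIN")
  ))
  expect_equal(back$points, ann$points)
  expect_length(back$audit_log, 2L)

  expect_error(apply_edits(ann, list(list(op = "move", index = 30L,
                                          new_time = 5))),
               "outside the analysis window")
  expect_error(apply_edits(ann, list(list(op = "remove", index = 99L))),
               "edit #1")
  expect_error(apply_edits(ann, list(list(op = "teleport", index = 0L))),
               "unknown op")
})

test_that("edits files round-trip through JSON and CSV", {
  edits <- list(list(op = "relabel", index = 20L, status = "BP"),
                list(op = "remove", index = 30L))
  jp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(edits, jp, auto_unbox = TRUE)
  got <- read_edits(jp)
  expect_identical(got[[1]]$op, "relabel")
  expect_identical(got[[2]]$index, 30L)
  cp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(op = "relabel", index = 20, status = "BP"),
                   cp, row.names = FALSE)
  got2 <- read_edits(cp)
  expect_identical(got2[[1]]$status, "BP")
})

test_that("physiological ordering and parity rules are validated per cycle", {
  ok <- fx_annotations(c("MAX", "BP", "MIN", "MAX", "BP", "MIN"))
  rep1 <- validate_annotations(ok, cycle_bounds = c(-0.05, 0.65))
  expect_true(rep1$ordering_pass)
  expect_true(all(rep1$per_cycle$parity_pass))
  expect_true(rep1$overall_pass)

  bad_order <- fx_annotations(c("BP", "MAX", "MIN", "BP"))
  rep2 <- validate_annotations(bad_order, cycle_bounds = c(-0.05, 0.65))
  expect_false(rep2$ordering_pass)
  expect_false(rep2$overall_pass)

  odd <- fx_annotations(c("MAX", "BP", "MIN", "BP", "MAX", "BP"))
  rep3 <- validate_annotations(odd, cycle_bounds = c(-0.05, 0.65))
  expect_false(all(rep3$per_cycle$parity_pass))
  expect_false(rep3$overall_pass)
})

test_that("parity repair promotes partial-fringe extrema or demotes rail BPs", {
  pts <- data.frame(
    sample_index = seq(0L, 60L, by = 10L),
    time_s = seq(0, 0.6, by = 0.1),
    value = c(1, 0.5, 0, 1, 0.55, 0, 1),
    status = c("MAX", "BP", "MIN", "MAX", "MIN", "MIN", "MAX")
  )
  ann <- annotation_set(pts, c(-0.1, 1))
  fixed <- enforce_bp_parity(ann, cycle_bounds = c(0, 0.65))
  # the mid-scale extremum at 0.4 s is promoted to even out the count
  expect_identical(fixed$points$status[5], "BP")
  expect_match(fixed$audit_log[1], "promoted")

  # no mid-scale candidate: the least reversal-like BP is demoted
  pts2 <- data.frame(
    sample_index = seq(0L, 60L, by = 10L),
    time_s = seq(0, 0.6, by = 0.1),
    value = c(1, 0.5, 0, 0.99, 0, 0.45, 1),
    status = c("MAX", "BP", "MIN", "BP", "MIN", "BP", "MAX")
  )
  ann2 <- annotation_set(pts2, c(-0.1, 1))
  fixed2 <- enforce_bp_parity(ann2, cycle_bounds = c(0, 0.65))
  expect_identical(fixed2$points$status[4], "MAX")
  expect_match(fixed2$audit_log[1], "demoted")
})

test_that("annotation CSV round-trip is lossless", {
  run <- fx_roundtrip(noise_sd = 0.01, seed = 1)
  ann <- run$annotations
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "\"index\",\"time\",\"value\",\"Status\"")
  back <- read_annotations(path)
  expect_identical(back$points$status, ann$points$status)
  expect_identical(back$points$sample_index, ann$points$sample_index)
  expect_equal(back$points$time_s, ann$points$time_s, tolerance = 1e-9)
})

test_that("automatic annotations on clean simulations obey the rules", {
  run <- fx_roundtrip(noise_sd = 0, seed = 1)
  ann <- run$annotations
  pre_peaks <- detect_envelope_peaks(
    compute_envelope(preprocess_trace(run$recording$trace)))
  report <- validate_annotations(ann, pre_peaks)
  expect_true(report$ordering_pass)
  expect_true(all(report$per_cycle$parity_pass))
  # breakpoints land on the true reversal times of peak and notch
  truth <- run$recording$events
  bp_times <- ann$points$time_s[ann$points$status == "BP"]
  for (lbl in c("systolic_peak", "dicrotic_notch")) {
    for (tv in truth$time_s[truth$label == lbl]) {
      if (tv > min(bp_times) && tv < max(bp_times)) {
        expect_lt(min(abs(bp_times - tv)), 0.03)
      }
    }
  }
})
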