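# Shared fixtures and independent oracles. Heavy simulations are cached per
# (noise, seed) so several test files can reuse the same run.

.fx_cache <- new.env(parent = emptyenv())

fx_template <- function(...) apw_template(n_cycles = 12L, ...)

fx_roundtrip <- function(noise_sd = 0.01, seed = 1L) {
  key <- paste0("rt_", noise_sd, "_", seed)
  if (!exists(key, envir = .fx_cache)) {
    assign(key,
           roundtrip_validate(fx_template(), noise_sd = noise_sd, seed = seed),
           envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

fx_recording <- function(noise_sd = 0.01, seed = 1L) {
  key <- paste0("rec_", noise_sd, "_", seed)
  if (!exists(key, envir = .fx_cache)) {
    prof <- make_apw(fx_template(), sampling_rate_hz = 10000, seed = seed)
    assign(key, render_interferogram(prof, noise_sd = noise_sd, seed = seed),
           envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

# Brute-force extremum counter on a dense grid: counts sign changes of the
# (zero-skipping) discrete derivative. Independent of the package's
# extremum machinery.
brute_extrema_count <- function(x) {
  d <- diff(x)
  d <- d[d != 0]
  sum(diff(sign(d)) != 0)
}

# Residual of a reconstruction against ground truth after removing the
# constant offset (the absolute displacement baseline is unobservable from
# a single-wavelength interferogram).
fx_truth_residual <- function(run) {
  d <- run$displacement
  gt <- run$recording$ground_truth
  fs <- 1 / stats::median(diff(gt$time_s))
  sel <- match(round(d$time_s * fs), round(gt$time_s * fs))
  resid <- d$delta_z_nm - gt$delta_z_nm[sel]
  resid - mean(resid)
}

# Minimal annotation set builder for rule-level tests.
fx_annotations <- function(statuses, dt = 0.1) {
  n <- length(statuses)
  annotation_set(
    data.frame(sample_index = seq_len(n) - 1L,
               time_s = (seq_len(n) - 1L) * dt,
               value = rep(c(1, 0), length.out = n),
               status = statuses),
    analysis_window = c(-dt, n * dt)
  )
}
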