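#' Optical configuration of the low-finesse Fabry-Perot cavity
#'
#' Constants of the two-beam interference law
#' \deqn{I(t) = I_1 + I_2 + 2\sqrt{I_1 I_2}\cos\!\big(\tfrac{4\pi n}{\lambda}(z \pm \Delta z(t)) + \pi\big)}
#' where \eqn{I_1} is the intensity reflected from the fiber end, \eqn{I_2}
#' the intensity reflected from the elastic membrane (treated as constant in
#' the low-finesse, small-variation regime), \eqn{n} the refractive index of
#' the medium inside the cavity, \eqn{\lambda} the laser wavelength and
#' \eqn{z} the static cavity length.
#'
#' The derived quantity \eqn{\lambda/(4n)} -- the cavity-length change between
#' two successive intensity extrema -- is available via [halfwave_quantum()].
#'
#' @param wavelength_nm laser wavelength in nm (default 1551.3).
#' @param refractive_index refractive index of the cavity medium (>= 1,
#'   default 1.003 for air).
#' @param static_cavity_length_nm static cavity length z in nm.
#' @param intensity_fiber reflected intensity I1 (> 0, arbitrary units).
#' @param intensity_membrane reflected intensity I2 (> 0, arbitrary units).
#' @return object of class `optical_config`.
#' @examples
#' halfwave_quantum(optical_config())  # ~386.7 nm
#' @export
optical_config <- function(wavelength_nm = 1551.3,
                           refractive_index = 1.003,
                           static_cavity_length_nm = 1e5,
                           intensity_fiber = 1,
                           intensity_membrane = 0.25) {
  if (wavelength_nm <= 0) stop("wavelength_nm must be positive")
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  if (static_cavity_length_nm <= 0) stop("static_cavity_length_nm must be positive")
  if (intensity_fiber <= 0 || intensity_membrane <= 0) {
    stop("reflected intensities I1 and I2 must be positive")
  }
  structure(
    list(wavelength_nm = wavelength_nm,
         refractive_index = refractive_index,
         static_cavity_length_nm = static_cavity_length_nm,
         intensity_fiber = intensity_fiber,
         intensity_membrane = intensity_membrane),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config> lambda = ", x$wavelength_nm, " nm, n = ",
      x$refractive_index, ", z = ", x$static_cavity_length_nm,
      " nm, I1 = ", x$intensity_fiber, ", I2 = ", x$intensity_membrane,
      "\n  halfwave quantum lambda/(4n) = ",
      format(halfwave_quantum(x), digits = 6), " nm\n", sep = "")
  invisible(x)
}

#' Peak-to-peak amplitude of the interference fringe
#'
#' The cosine term of the interference law has amplitude
#' \eqn{2\sqrt{I_1 I_2}}; noise levels in the simulator are conveniently
#' expressed as a fraction of this value.
#'
#' @param optics an [optical_config()].
#' @return fringe amplitude in intensity units.
#' @export
fringe_amplitude <- function(optics) {
  stopifnot(inherits(optics, "optical_config"))
  2 * sqrt(optics$intensity_fiber * optics$intensity_membrane)
}

#' Parametric arterial pulse waveform template
#'
#' Analytic ground-truth displacement profile for one cardiac cycle, used by
#' the simulator and by the timing-accuracy evaluation. The cycle shape is a
#' sum of a gamma-variate systolic wave (exactly zero at the foot), a
#' Gaussian dicrotic (reflected) wave and an exponentially decaying
#' diastolic baseline, linearly corrected so the waveform starts and ends
#' each cycle exactly at zero displacement with a strictly negative
#' end-diastolic slope. The composite is rescaled numerically so its maximum
#' equals `peak_amplitude_um`. With `dicrotic_notch_depth > 0` the valley
#' between the systolic and dicrotic waves is the dicrotic notch (exactly
#' one local minimum between the systolic peak and end of cycle).
#'
#' @param heart_rate_hz cardiac frequency in Hz (default 1.0).
#' @param peak_amplitude_um systolic peak displacement in micrometers
#'   (default 17.5; physiological radial-artery recordings span 15-20 um).
#' @param systolic_fraction fraction of the cycle at which the systolic peak
#'   occurs, in (0,1) (default 0.15).
#' @param dicrotic_notch_depth relative amplitude of the dicrotic wave in
#'   `[0,1)`; 0 removes the notch entirely (default 0.35).
#' @param dicrotic_notch_time_fraction fraction of the cycle at which the
#'   notch region is centered, in (0,1) (default 0.40).
#' @param diastolic_decay_rate exponential decay rate (per cycle) of the
#'   diastolic baseline; keeps a non-zero downward slope up to the cycle
#'   boundary so the end-diastolic reversal is well defined (default 3).
#' @param cycle_jitter_sd_s standard deviation (seconds) of Gaussian
#'   perturbations of individual cycle lengths (default 0).
#' @param n_cycles number of cardiac cycles to generate (default 10).
#' @return object of class `apw_template`.
#' @export
apw_template <- function(heart_rate_hz = 1.0,
                         peak_amplitude_um = 17.5,
                         systolic_fraction = 0.15,
                         dicrotic_notch_depth = 0.35,
                         dicrotic_notch_time_fraction = 0.40,
                         diastolic_decay_rate = 3,
                         cycle_jitter_sd_s = 0,
                         n_cycles = 10L) {
  if (heart_rate_hz <= 0) stop("heart_rate_hz must be positive")
  if (peak_amplitude_um <= 0) stop("peak_amplitude_um must be positive")
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("systolic_fraction must lie in (0,1)")
  }
  if (dicrotic_notch_depth < 0 || dicrotic_notch_depth >= 1) {
    stop("dicrotic_notch_depth must lie in [0,1)")
  }
  if (dicrotic_notch_time_fraction <= 0 || dicrotic_notch_time_fraction >= 1) {
    stop("dicrotic_notch_time_fraction must lie in (0,1)")
  }
  if (dicrotic_notch_depth > 0 &&
      dicrotic_notch_time_fraction <= systolic_fraction) {
    stop("the dicrotic notch must come after the systolic peak")
  }
  if (diastolic_decay_rate <= 0) stop("diastolic_decay_rate must be positive")
  if (cycle_jitter_sd_s < 0) stop("cycle_jitter_sd_s must be nonnegative")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be a positive integer")
  structure(
    list(heart_rate_hz = heart_rate_hz,
         peak_amplitude_um = peak_amplitude_um,
         systolic_fraction = systolic_fraction,
         dicrotic_notch_depth = dicrotic_notch_depth,
         dicrotic_notch_time_fraction = dicrotic_notch_time_fraction,
         diastolic_decay_rate = diastolic_decay_rate,
         cycle_jitter_sd_s = cycle_jitter_sd_s,
         n_cycles = n_cycles),
    class = "apw_template"
  )
}

#' @export
print.apw_template <- function(x, ...) {
  cat("<apw_template> ", x$n_cycles, " cycles @ ", x$heart_rate_hz,
      " Hz, peak ", x$peak_amplitude_um, " um, notch depth ",
      x$dicrotic_notch_depth, "\n", sep = "")
  invisible(x)
}

# Normalized single-cycle shape on phase u in [0,1]. Three components: a
# gamma-variate systolic wave (exactly zero at the foot, peaking at
# systolic_fraction), a Gaussian dicrotic wave after the notch, and a
# decaying baseline that keeps a strictly negative slope into the cycle
# boundary so the end-diastolic foot is a well-defined reversal. A linear
# correction pins the cycle to exactly zero at both boundaries; the
# derivative kink at the foot models the sharp onset of the next upstroke.
apw_cycle_shape <- function(template) {
  u_s <- template$systolic_fraction
  gamma <- 4
  u_d <- template$dicrotic_notch_time_fraction + 0.12
  sigma_d <- 0.10
  a_d <- 0.8 * template$dicrotic_notch_depth
  k <- template$diastolic_decay_rate
  base <- function(u) {
    gv <- ifelse(u <= 0, 0, (u / u_s)^gamma * exp(gamma * (1 - u / u_s)))
    gv + a_d * exp(-(u - u_d)^2 / (2 * sigma_d^2)) +
      0.25 * (1 - exp(-20 * u)) * (exp(-k * u) - exp(-k))
  }
  g0 <- base(0)
  g1 <- base(1)
  function(u) base(u) - ((1 - u) * g0 + u * g1)
}

#' Generate a synthetic arterial pulse waveform displacement profile
#'
#' Samples the template's cycle shape on a uniform time grid and emits the
#' ground-truth event times for each cycle: systole start, systolic peak,
#' dicrotic notch (when present) and diastole end. With non-zero cycle
#' jitter, individual cycle durations are perturbed by Gaussian noise
#' (reproducibly via `seed`).
#'
#' @param template an [apw_template()].
#' @param sampling_rate_hz sampling rate in Hz (>= 100; default 10000 so that
#'   fringe oscillations during the systolic upstroke are well resolved).
#' @param seed integer seed for the cycle-length jitter.
#' @return object of class `apw_profile`: list with `time_s`, `delta_z_nm`
#'   (the displacement profile), `events` (data.frame `time_s`, `label` with
#'   labels `systole_start`, `systolic_peak`, `dicrotic_notch`,
#'   `diastole_end`), `sampling_rate_hz`, `cycle_bounds_s` and the template.
#' @examples
#' prof <- make_apw(apw_template(n_cycles = 2), sampling_rate_hz = 500, seed = 1)
#' max(prof$delta_z_nm)  # ~17500 nm
#' @export
make_apw <- function(template, sampling_rate_hz = 10000, seed = 1L) {
  stopifnot(inherits(template, "apw_template"))
  if (sampling_rate_hz < 100) {
    stop("sampling_rate_hz must be >= 100 to resolve interference fringes")
  }
  period <- 1 / template$heart_rate_hz
  durations <- rep(period, template$n_cycles)
  if (template$cycle_jitter_sd_s > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    durations <- durations +
      stats::rnorm(template$n_cycles, sd = template$cycle_jitter_sd_s)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    durations <- pmax(durations, 0.2 * period)
  }
  bounds <- c(0, cumsum(durations))
  total <- bounds[length(bounds)]
  dt <- 1 / sampling_rate_hz
  n <- round(total / dt)
  time_s <- (seq_len(n) - 1L) * dt

  shape <- apw_cycle_shape(template)
  u_dense <- seq(0, 1, length.out = 4096L)
  g_dense <- shape(u_dense)
  g_max <- max(g_dense)
  amp_nm <- template$peak_amplitude_um * 1000

  # Nyquist guard: peak fringe frequency = max|dz/dt| / (2 * lambda/(4n)),
  # evaluated for the default optical configuration.
  q <- halfwave_quantum(optical_config())
  max_slope_nm_s <- amp_nm / g_max *
    max(abs(diff(g_dense))) / (u_dense[2] - u_dense[1]) / min(durations)
  peak_fringe_hz <- max_slope_nm_s / (2 * q)
  if (peak_fringe_hz > 0.45 * sampling_rate_hz) {
    stop("sampling rate too low to resolve the requested amplitude: ",
         "expected peak fringe rate ", round(peak_fringe_hz), " Hz vs ",
         "sampling rate ", sampling_rate_hz, " Hz")
  }

  cyc <- pmin(findInterval(time_s, bounds, rightmost.closed = TRUE),
              template$n_cycles)
  u <- (time_s - bounds[cyc]) / durations[cyc]
  delta_z <- amp_nm * shape(u) / g_max

  # ground-truth events from the dense per-cycle shape
  i_peak <- which.max(g_dense)
  u_peak <- u_dense[i_peak]
  u_notch <- NA_real_
  if (template$dicrotic_notch_depth > 0) {
    post <- g_dense[i_peak:length(g_dense)]
    ext <- local_extrema(post)
    mins <- ext$index[ext$type == "MIN"]
    if (length(mins) > 0L) {
      u_notch <- u_dense[i_peak + mins[1L] - 1L]
    }
  }
  events <- do.call(rbind, lapply(seq_len(template$n_cycles), function(i) {
    t0 <- bounds[i]; Ti <- durations[i]
    ev <- data.frame(
      time_s = c(t0, t0 + u_peak * Ti),
      label = c("systole_start", "systolic_peak"),
      stringsAsFactors = FALSE
    )
    if (!is.na(u_notch)) {
      ev <- rbind(ev, data.frame(time_s = t0 + u_notch * Ti,
                                 label = "dicrotic_notch"))
    }
    rbind(ev, data.frame(time_s = t0 + Ti, label = "diastole_end"))
  }))
  events <- events[order(events$time_s), ]
  rownames(events) <- NULL

  structure(
    list(time_s = time_s,
         delta_z_nm = delta_z,
         events = events,
         sampling_rate_hz = sampling_rate_hz,
         cycle_bounds_s = bounds,
         template = template,
         seed = as.integer(seed)),
    class = "apw_profile"
  )
}

#' @export
print.apw_profile <- function(x, ...) {
  cat("<apw_profile> ", length(x$time_s), " samples @ ", x$sampling_rate_hz,
      " Hz, ", x$template$n_cycles, " cycles, peak ",
      format(max(x$delta_z_nm) / 1000, digits = 4), " um\n", sep = "")
  invisible(x)
}

#' Render a displacement profile into an interferometric recording
#'
#' Evaluates the two-beam interference law
#' \eqn{I(t) = I_1 + I_2 + 2\sqrt{I_1 I_2}\cos(4\pi n/\lambda\,(z + s\,\Delta z(t)) + \pi)}
#' on the profile's time grid and adds white Gaussian noise. The sign
#' \eqn{s = -1} by default: systolic membrane deflection shortens the cavity.
#'
#' @param profile an [apw_profile()], or any list with numeric `time_s` and
#'   `delta_z_nm` of equal length on a uniform grid.
#' @param optics an [optical_config()].
#' @param noise_sd standard deviation of additive white Gaussian intensity
#'   noise, in intensity units (compare [fringe_amplitude()]).
#' @param seed integer seed; identical arguments give bit-identical output.
#' @param sign direction of the cavity-length change, `-1` or `+1`.
#' @return object of class `fpi_recording`: list with `trace`
#'   ([fpi_trace()]), `ground_truth` (data.frame `time_s`, `delta_z_nm`),
#'   `events`, `noise_sd`, `sign`, `seed` and `optics`.
#' @export
render_interferogram <- function(profile, optics = optical_config(),
                                 noise_sd = 0, seed = 1L, sign = -1) {
  stopifnot(inherits(optics, "optical_config"))
  if (!all(c("time_s", "delta_z_nm") %in% names(profile))) {
    stop("profile must contain time_s and delta_z_nm")
  }
  if (length(profile$time_s) != length(profile$delta_z_nm)) {
    stop("time_s and delta_z_nm must have equal length")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!sign %in% c(-1, 1)) stop("sign must be -1 or +1")
  z <- optics$static_cavity_length_nm + sign * profile$delta_z_nm
  phase <- 4 * pi * optics$refractive_index / optics$wavelength_nm * z + pi
  i1 <- optics$intensity_fiber
  i2 <- optics$intensity_membrane
  intensity <- i1 + i2 + 2 * sqrt(i1 * i2) * cos(phase)
  if (noise_sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    intensity <- intensity + stats::rnorm(length(intensity), sd = noise_sd)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  structure(
    list(trace = fpi_trace(profile$time_s, intensity),
         ground_truth = data.frame(time_s = profile$time_s,
                                   delta_z_nm = profile$delta_z_nm),
         events = if (!is.null(profile$events)) profile$events else NULL,
         noise_sd = noise_sd,
         sign = sign,
         seed = as.integer(seed),
         optics = optics),
    class = "fpi_recording"
  )
}

#' @export
print.fpi_recording <- function(x, ...) {
  cat("<fpi_recording> ", length(x$trace$time_s), " samples @ ",
      x$trace$sampling_rate_hz, " Hz, noise sd ", x$noise_sd,
      ", sign ", x$sign, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic recording and its ground truth to CSV files
#'
#' Writes the interferogram (`time,intensity`), a companion ground-truth file
#' (`time,delta_z_nm`) and, when present, the event table (`time,label`).
#'
#' @param recording an `fpi_recording`.
#' @param path output path for the interferogram CSV; the ground truth and
#'   events are written next to it with suffixes `_truth.csv` / `_events.csv`.
#' @return named character vector of the files written, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "fpi_recording"))
  write_trace(recording$trace, path)
  stem <- sub("\\.csv$", "", path)
  truth_path <- paste0(stem, "_truth.csv")
  utils::write.csv(
    data.frame(time = recording$ground_truth$time_s,
               delta_z_nm = recording$ground_truth$delta_z_nm),
    truth_path, row.names = FALSE
  )
  out <- c(trace = path, truth = truth_path)
  if (!is.null(recording$events)) {
    events_path <- paste0(stem, "_events.csv")
    utils::write.csv(
      data.frame(time = recording$events$time_s,
                 label = recording$events$label),
      events_path, row.names = FALSE
    )
    out <- c(out, events = events_path)
  }
  invisible(out)
}
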