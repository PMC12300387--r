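#' Halfwave quantum: cavity-length change between successive extrema
#'
#' Successive extrema of the interference intensity are separated by a phase
#' difference of pi, i.e. a cavity-length change of \eqn{\lambda/(4n)}
#' (about 386.7 nm for a 1551.3 nm source in air, n = 1.003). This quantum
#' is the displacement resolution of the fringe-counting reconstruction.
#'
#' @param optics an [optical_config()].
#' @return length in nm.
#' @examples
#' halfwave_quantum(optical_config())           # 386.665
#' halfwave_quantum(optical_config(refractive_index = 1))  # 387.825
#' @export
halfwave_quantum <- function(optics = optical_config()) {
  stopifnot(inherits(optics, "optical_config"))
  optics$wavelength_nm / (4 * optics$refractive_index)
}

#' Assign halfwave numbers to annotated fringe extrema
#'
#' The integer halfwave number m starts at 1 at the first extremum after the
#' first breakpoint (the beginning of a heart-pulse period, systole) and
#' then increases by 1 per extremum until a breakpoint is reached, where the
#' direction flips; points before the first breakpoint are excluded.
#'
#' A halfwave number below zero indicates an inconsistent annotation (a
#' missed or spurious breakpoint) and is an error. m may touch 0 only when
#' the immediately following labeled point is a breakpoint -- the waveform
#' grazing its diastolic baseline just before reversing -- otherwise a zero
#' mid-cycle is likewise an error.
#'
#' @param annotations an [annotation_set()] containing at least one BP.
#' @return object of class `halfwave_assignment`: list with `anchors`
#'   (data.frame `sample_index`, `time_s`, `value`, `status`, `m`),
#'   `breakpoint_times_s`, and `direction` (the +-1 direction in force after
#'   each labeled point).
#' @examples
#' pts <- data.frame(sample_index = 0:7, time_s = (0:7) / 10, value = 0,
#'                   status = c("MAX","BP","MIN","MAX","MIN","BP","MAX","MIN"))
#' ann <- annotation_set(pts, c(0, 1))
#' assign_halfwave(ann)$anchors$m  # 1 2 3 2 1
#' @export
assign_halfwave <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  pts <- annotations$points
  bp_pos <- which(pts$status == "BP")
  if (length(bp_pos) == 0L) {
    stop("no breakpoint present: cannot anchor the halfwave count")
  }
  first_bp <- bp_pos[1L]
  active <- pts[seq_len(nrow(pts)) > first_bp, , drop = FALSE]
  direction <- 1L
  m <- NA_integer_
  ms <- integer(0)
  dirs <- integer(0)
  status_seq <- active$status
  for (i in seq_len(nrow(active))) {
    if (status_seq[i] == "BP") {
      direction <- -direction
      dirs <- c(dirs, direction)
      ms <- c(ms, NA_integer_)
      next
    }
    m <- if (is.na(m)) 1L else m + direction
    if (m < 0L) {
      stop("halfwave number fell below 0 at t = ",
           format(active$time_s[i], digits = 6),
           " s: inconsistent annotation (missed or spurious breakpoint)")
    }
    if (m == 0L) {
      nxt <- if (i < nrow(active)) status_seq[i + 1L] else NA_character_
      if (!identical(nxt, "BP")) {
        stop("halfwave number reached 0 mid-cycle at t = ",
             format(active$time_s[i], digits = 6),
             " s: inconsistent annotation (missed or spurious breakpoint)")
      }
    }
    ms <- c(ms, m)
    dirs <- c(dirs, direction)
  }
  anchors <- active[active$status != "BP", , drop = FALSE]
  anchors$m <- ms[!is.na(ms)]
  rownames(anchors) <- NULL
  structure(
    list(anchors = anchors,
         # the anchoring first BP (start of systole) is itself a reversal
         # and belongs to the reconstruction's knots
         breakpoint_times_s = pts$time_s[bp_pos],
         direction = dirs),
    class = "halfwave_assignment"
  )
}

#' @export
print.halfwave_assignment <- function(x, ...) {
  cat("<halfwave_assignment> ", nrow(x$anchors), " anchors, ",
      length(x$breakpoint_times_s), " breakpoints, m in [",
      min(x$anchors$m), ", ", max(x$anchors$m), "]\n", sep = "")
  invisible(x)
}

#' Displacement at the fringe-extremum anchors
#'
#' Each anchor's cavity-length change is `m * lambda/(4n)` -- an exact
#' integer multiple of the halfwave quantum.
#'
#' @param assignment a `halfwave_assignment`.
#' @param optics an [optical_config()].
#' @return data.frame with columns `time_s`, `m`, `delta_z_nm`.
#' @export
delta_z_at_anchors <- function(assignment, optics = optical_config()) {
  stopifnot(inherits(assignment, "halfwave_assignment"))
  q <- halfwave_quantum(optics)
  data.frame(time_s = assignment$anchors$time_s,
             m = assignment$anchors$m,
             delta_z_nm = assignment$anchors$m * q)
}

#' Reconstruct the displacement curve by cubic-spline interpolation
#'
#' A natural cubic spline is fit through the extremum anchors; the
#' breakpoint displacements are obtained by evaluating this spline at the
#' breakpoint times (the spline's momentum across a reversal recovers the
#' turning value between the two quantized fringe levels). The breakpoints
#' are added to the anchor set and the final curve is a shape-preserving
#' monotone cubic interpolant through the combined set sampled on
#' `time_grid`. Grid points outside the anchored span are excluded (no
#' extrapolation). The curve interpolates every anchor.
#'
#' @param anchors data.frame from [delta_z_at_anchors()] (needs `time_s`,
#'   `delta_z_nm`, optionally `m`); at least 4 anchors, strictly increasing
#'   times.
#' @param breakpoint_times numeric vector of breakpoint times (may be
#'   empty); breakpoints outside the anchored span are ignored.
#' @param time_grid numeric vector of output sample times.
#' @return object of class `displacement_trace`: data.frame with columns
#'   `time_s`, `m` (piecewise constant: the last extremum anchor's halfwave
#'   number), `delta_z_nm`, plus attributes `anchors` and
#'   `breakpoints` (data.frame `time_s`, `delta_z_nm`).
#' @export
reconstruct_displacement <- function(anchors, breakpoint_times = numeric(0),
                                     time_grid) {
  if (nrow(anchors) < 4L) {
    stop("at least 4 anchors are required for cubic-spline reconstruction")
  }
  if (any(diff(anchors$time_s) <= 0)) {
    stop("anchor times must be strictly increasing")
  }
  span <- range(anchors$time_s)
  bp <- breakpoint_times[breakpoint_times >= span[1] &
                           breakpoint_times <= span[2]]
  bp <- setdiff(bp, anchors$time_s)
  bp_dz <- if (length(bp) > 0L) {
    stats::spline(anchors$time_s, anchors$delta_z_nm, xout = bp,
                  method = "natural")$y
  } else {
    numeric(0)
  }
  knots_t <- c(anchors$time_s, bp)
  knots_z <- c(anchors$delta_z_nm, bp_dz)
  ord <- order(knots_t)
  knots_t <- knots_t[ord]
  knots_z <- knots_z[ord]
  keep <- time_grid >= span[1] & time_grid <= span[2]
  tt <- time_grid[keep]
  # monotone cubic Hermite through the knots: in sparse low-velocity
  # stretches (late diastole) anchor gaps are long and a C2 spline's
  # momentum overshoots by several halfwave quanta; the shape-preserving
  # cubic interpolates every knot without oscillating between them
  fcurve <- stats::splinefun(knots_t, knots_z, method = "monoH.FC")
  zz <- fcurve(tt)
  m_col <- if (!is.null(anchors$m)) {
    idx <- findInterval(tt, anchors$time_s)
    anchors$m[pmax(idx, 1L)]
  } else {
    rep(NA_integer_, length(tt))
  }
  out <- data.frame(time_s = tt, m = m_col, delta_z_nm = zz)
  attr(out, "anchors") <- anchors
  attr(out, "breakpoints") <- data.frame(time_s = bp, delta_z_nm = bp_dz)
  class(out) <- c("displacement_trace", "data.frame")
  out
}

#' Demodulate an annotated recording into a displacement curve
#'
#' Composition of [assign_halfwave()], [delta_z_at_anchors()] and
#' [reconstruct_displacement()] on the preprocessed trace's time grid. The
#' `I2_t` column carries the processed intensity at each output sample.
#'
#' @param pre an `fpi_preprocessed` object (same time axis the annotations
#'   were made on).
#' @param annotations an [annotation_set()].
#' @param optics an [optical_config()].
#' @return a `displacement_trace` data.frame with columns `time_s`, `m`,
#'   `delta_z_nm`, `I2_t`.
#' @export
demodulate <- function(pre, annotations, optics = optical_config()) {
  stopifnot(inherits(pre, "fpi_preprocessed"),
            inherits(annotations, "annotation_set"))
  pts <- annotations$points
  idx <- pts$sample_index + 1L
  if (any(idx < 1L) || any(idx > length(pre$time_s)) ||
      max(abs(pre$time_s[idx] - pts$time_s)) > 0.5 / pre$sampling_rate_hz) {
    stop("annotation times do not match the preprocessed time axis")
  }
  assignment <- assign_halfwave(annotations)
  anchors <- delta_z_at_anchors(assignment, optics)
  disp <- reconstruct_displacement(anchors, assignment$breakpoint_times_s,
                                   pre$time_s)
  sel <- match(round(disp$time_s * pre$sampling_rate_hz),
               round(pre$time_s * pre$sampling_rate_hz))
  disp$I2_t <- pre$processed[sel]
  disp
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat("<displacement_trace> ", nrow(x), " samples, delta_z ",
      format(min(x$delta_z_nm), digits = 5), " to ",
      format(max(x$delta_z_nm), digits = 5), " nm\n", sep = "")
  invisible(x)
}

#' @export
plot.displacement_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$delta_z_nm / 1000, type = "l",
                 xlab = "time (s)", ylab = expression(Delta * z ~ (mu * m)),
                 ...)
  invisible(x)
}

#' Write / read the displacement CSV (`time,m,delta_z,I2_t`)
#'
#' `time` in seconds, `delta_z` in nm, `I2_t` in processed-intensity units.
#'
#' @param disp a `displacement_trace`.
#' @param path CSV path (conventionally `displacement.csv`).
#' @return `path` invisibly (write); a `displacement_trace` (read).
#' @export
write_displacement <- function(disp, path) {
  utils::write.csv(
    data.frame(time = disp$time_s, m = disp$m, delta_z = disp$delta_z_nm,
               I2_t = if (!is.null(disp$I2_t)) disp$I2_t else NA_real_),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_displacement
#' @export
read_displacement <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  d <- utils::read.csv(path)
  if (!all(c("time", "m", "delta_z") %in% names(d))) {
    stop("expected columns time, m, delta_z in ", path)
  }
  out <- data.frame(time_s = d$time, m = d$m, delta_z_nm = d$delta_z,
                    I2_t = if ("I2_t" %in% names(d)) d$I2_t else NA_real_)
  class(out) <- c("displacement_trace", "data.frame")
  out
}
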