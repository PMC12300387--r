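#' Preprocessing configuration
#'
#' Parameters of the raw-signal conditioning stage: z-score outlier repair,
#' zero-phase Butterworth high-pass drift removal, and segment-wise min-max
#' normalization.
#'
#' @param zscore_threshold flag samples whose global z-score magnitude
#'   exceeds this value (default 3.0).
#' @param highpass_cutoff_hz high-pass cutoff in Hz (default 0.5).
#' @param filter_order Butterworth order (default 4).
#' @param segment_length_s normalization segment length in seconds
#'   (default 1.0).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(zscore_threshold = 3.0,
                              highpass_cutoff_hz = 0.5,
                              filter_order = 4L,
                              segment_length_s = 1.0) {
  if (zscore_threshold <= 0) stop("zscore_threshold must be positive")
  if (highpass_cutoff_hz <= 0) stop("highpass_cutoff_hz must be positive")
  if (filter_order < 1) stop("filter_order must be a positive integer")
  if (segment_length_s <= 0) stop("segment_length_s must be positive")
  structure(
    list(zscore_threshold = zscore_threshold,
         highpass_cutoff_hz = highpass_cutoff_hz,
         filter_order = as.integer(filter_order),
         segment_length_s = segment_length_s),
    class = "preprocess_config"
  )
}

#' Repair outliers by z-score flagging and interpolation
#'
#' Samples whose deviation from the global mean exceeds
#' `zscore_threshold` standard deviations are replaced by linear
#' interpolation between the nearest non-flagged neighbours; flagged samples
#' at the edges take the nearest valid value (backward/forward fill). A
#' constant trace (zero standard deviation) has no outliers by convention.
#'
#' @param trace an [fpi_trace()].
#' @param zscore_threshold positive threshold (default 3.0).
#' @return the repaired [fpi_trace()] with attribute `outlier_indices`
#'   (1-based indices of the replaced samples).
#' @examples
#' tr <- fpi_trace(seq(0, 0.9, by = 0.1), c(0, 0, 0, 100, 0, 0, 0, 0, 0, 0))
#' attr(repair_outliers(tr, 2), "outlier_indices")
#' @export
repair_outliers <- function(trace, zscore_threshold = 3.0) {
  stopifnot(inherits(trace, "fpi_trace"))
  if (zscore_threshold <= 0) stop("zscore_threshold must be positive")
  x <- trace$intensity
  s <- stats::sd(x)
  if (s == 0 || !is.finite(s)) {
    attr(trace, "outlier_indices") <- integer(0)
    return(trace)
  }
  z <- abs(x - mean(x)) / s
  bad <- which(z > zscore_threshold)
  if (length(bad) == length(x)) {
    stop("all samples flagged as outliers; signal unusable")
  }
  if (length(bad) > 0L) {
    good <- setdiff(seq_along(x), bad)
    # rule = 2: nearest-valid-value fill beyond the first/last good sample
    x[bad] <- stats::approx(good, x[good], xout = bad,
                            method = "linear", rule = 2)$y
  }
  out <- fpi_trace(trace$time_s, x)
  attr(out, "outlier_indices") <- bad
  out
}

#' Zero-phase Butterworth high-pass filter
#'
#' Removes low-frequency drift with a forward-backward (zero-phase)
#' Butterworth high-pass, so waveform timing is not shifted. The effective
#' magnitude response is the square of the single-pass Butterworth response.
#'
#' @param trace an [fpi_trace()].
#' @param cutoff_hz cutoff frequency in Hz, strictly below Nyquist.
#' @param order filter order (default 4).
#' @return the filtered [fpi_trace()].
#' @export
highpass_trace <- function(trace, cutoff_hz = 0.5, order = 4L) {
  stopifnot(inherits(trace, "fpi_trace"))
  y <- zero_phase_butter(trace$intensity, trace$sampling_rate_hz,
                         cutoff_hz, order, type = "high")
  fpi_trace(trace$time_s, y)
}

#' Segment-wise min-max normalization
#'
#' Splits the trace into half-open segments `[k*L, (k+1)*L)` seconds
#' (relative to the first sample) and affinely maps each segment's values
#' onto `[0, 1]`. A degenerate (constant) segment maps to 0.5. The final
#' partial segment is normalized over its own extent.
#'
#' @param trace an [fpi_trace()].
#' @param segment_length_s segment length L in seconds (default 1.0).
#' @return the normalized [fpi_trace()].
#' @examples
#' tr <- fpi_trace(seq(0, 0.2, by = 0.1), c(2, 4, 6))
#' segment_normalize(tr, 1)$intensity  # 0, 0.5, 1
#' @export
segment_normalize <- function(trace, segment_length_s = 1.0) {
  stopifnot(inherits(trace, "fpi_trace"))
  if (segment_length_s <= 0) stop("segment_length_s must be positive")
  rel <- trace$time_s - trace$time_s[1L]
  # guard against floating-point time axes putting a boundary sample in the
  # wrong bin: work on integer sample counts per segment
  n_per <- round(segment_length_s * trace$sampling_rate_hz)
  if (n_per < 1L) stop("segment shorter than one sample")
  seg <- (seq_along(rel) - 1L) %/% n_per
  x <- trace$intensity
  y <- unlist(lapply(split(x, seg), function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0.5, length(v)) else (v - r[1]) / (r[2] - r[1])
  }), use.names = FALSE)
  fpi_trace(trace$time_s, y)
}

#' Run the full preprocessing stage
#'
#' Composition of [validate_input()] (when given a raw table),
#' [repair_outliers()], [highpass_trace()] and [segment_normalize()], in that
#' order. The high-passed-then-normalized signal is the `processed` column.
#'
#' @param x an [fpi_trace()], or a raw two-column table passed through
#'   [validate_input()].
#' @param config a [preprocess_config()].
#' @return object of class `fpi_preprocessed`: list with `time_s`, `raw`,
#'   `processed`, `sampling_rate_hz`, `outlier_indices` and `config`.
#' @export
preprocess_trace <- function(x, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  trace <- if (inherits(x, "fpi_trace")) x else validate_input(x)
  repaired <- repair_outliers(trace, config$zscore_threshold)
  filtered <- highpass_trace(repaired, config$highpass_cutoff_hz,
                             config$filter_order)
  normalized <- segment_normalize(filtered, config$segment_length_s)
  structure(
    list(time_s = trace$time_s,
         raw = trace$intensity,
         processed = normalized$intensity,
         sampling_rate_hz = trace$sampling_rate_hz,
         outlier_indices = attr(repaired, "outlier_indices"),
         config = config),
    class = "fpi_preprocessed"
  )
}

#' @export
print.fpi_preprocessed <- function(x, ...) {
  cat("<fpi_preprocessed> ", length(x$time_s), " samples @ ",
      format(x$sampling_rate_hz, digits = 6), " Hz, ",
      length(x$outlier_indices), " outliers repaired\n", sep = "")
  invisible(x)
}

#' Write / read the preprocessed trace CSV (`time,raw,processed`)
#'
#' @param pre an `fpi_preprocessed` object.
#' @param path CSV path (conventionally `preprocessed.csv`).
#' @return `path` invisibly (write); an `fpi_preprocessed` (read).
#' @export
write_preprocessed <- function(pre, path) {
  stopifnot(inherits(pre, "fpi_preprocessed"))
  utils::write.csv(
    data.frame(time = pre$time_s, raw = pre$raw, processed = pre$processed),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_preprocessed
#' @export
read_preprocessed <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  d <- utils::read.csv(path)
  if (!all(c("time", "raw", "processed") %in% names(d))) {
    stop("expected columns time, raw, processed in ", path)
  }
  tr <- fpi_trace(d$time, d$processed)  # validates the grid
  structure(
    list(time_s = tr$time_s,
         raw = as.numeric(d$raw),
         processed = tr$intensity,
         sampling_rate_hz = tr$sampling_rate_hz,
         outlier_indices = integer(0),
         config = NULL),
    class = "fpi_preprocessed"
  )
}
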