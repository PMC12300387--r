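#' Uniformly sampled interferogram trace
#'
#' Container for a single-channel Fabry-Perot interference recording: a
#' strictly increasing, uniformly spaced time axis (seconds) and the measured
#' intensity (arbitrary units). The sampling rate is derived from the time
#' step and stored alongside the data.
#'
#' @param time_s numeric vector of sample times in seconds, strictly
#'   increasing with a constant step (relative tolerance `1e-6`).
#' @param intensity numeric vector of intensities, same length as `time_s`.
#' @return an object of class `fpi_trace`: a list with elements `time_s`,
#'   `intensity` and `sampling_rate_hz`.
#' @examples
#' tr <- fpi_trace(seq(0, 1, by = 1e-3), sin(2 * pi * 5 * seq(0, 1, by = 1e-3)))
#' tr$sampling_rate_hz
#' @export
fpi_trace <- function(time_s, intensity) {
  if (length(time_s) < 2L) {
    stop("a trace needs at least 2 samples")
  }
  if (length(time_s) != length(intensity)) {
    stop("time and intensity must have the same length")
  }
  if (anyNA(time_s) || anyNA(intensity)) {
    stop("trace contains missing values")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    stop("time axis must be strictly increasing (first violation at index ",
         which(dt <= 0)[1L] + 1L, ")")
  }
  dt0 <- stats::median(dt)
  bad <- which(abs(dt - dt0) > 1e-6 * dt0)
  if (length(bad) > 0L) {
    stop("non-uniform sampling step at index ", bad[1L] + 1L,
         " (dt = ", signif(dt[bad[1L]], 6), ", expected ", signif(dt0, 6), ")")
  }
  structure(
    list(time_s = as.numeric(time_s),
         intensity = as.numeric(intensity),
         sampling_rate_hz = 1 / dt0),
    class = "fpi_trace"
  )
}

#' Validate a raw two-column table as an interferogram trace
#'
#' Checks that the table has at least two columns interpretable as time and
#' intensity, that all cells are numeric, and that the time grid is uniform,
#' then returns a verified [fpi_trace()].
#'
#' @param raw_table a data.frame (or object coercible to one) whose first two
#'   columns are time in seconds and intensity.
#' @return an [fpi_trace()].
#' @examples
#' validate_input(data.frame(time = c(0, 0.001, 0.002), intensity = 1:3))
#' @export
validate_input <- function(raw_table) {
  raw_table <- as.data.frame(raw_table)
  if (nrow(raw_table) == 0L) {
    stop("input table is empty")
  }
  if (ncol(raw_table) < 2L) {
    stop("input table needs at least two columns (time, intensity)")
  }
  tm <- raw_table[[1L]]
  iv <- raw_table[[2L]]
  check_numeric <- function(x, what) {
    if (!is.numeric(x)) {
      xx <- suppressWarnings(as.numeric(as.character(x)))
      bad <- which(is.na(xx) & !is.na(x))
      if (length(bad) > 0L) {
        stop("non-numeric ", what, " value at row ", bad[1L],
             " (\"", as.character(x[bad[1L]]), "\")")
      }
      x <- xx
    }
    if (anyNA(x)) {
      stop("missing ", what, " value at row ", which(is.na(x))[1L])
    }
    x
  }
  tm <- check_numeric(tm, "time")
  iv <- check_numeric(iv, "intensity")
  fpi_trace(tm, iv)
}

#' Read an interferogram recording from CSV
#'
#' Expects a header with at least two columns (`time,intensity`); extra
#' columns are ignored. The table is validated with [validate_input()].
#'
#' @param path path to a CSV file.
#' @return an [fpi_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  validate_input(utils::read.csv(path, colClasses = NA))
}

#' Write a trace to CSV with header `time,intensity`
#' @param trace an [fpi_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fpi_trace"))
  utils::write.csv(
    data.frame(time = trace$time_s, intensity = trace$intensity),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @export
print.fpi_trace <- function(x, ...) {
  cat("<fpi_trace> ", length(x$time_s), " samples @ ",
      format(x$sampling_rate_hz, digits = 6), " Hz, ",
      format(x$time_s[1], digits = 4), "-",
      format(x$time_s[length(x$time_s)], digits = 4), " s\n", sep = "")
  invisible(x)
}

#' @export
plot.fpi_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$intensity, type = "l",
                 xlab = "time (s)", ylab = "intensity (a.u.)", ...)
  invisible(x)
}
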