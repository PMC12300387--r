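#' Rate-of-change envelope of a preprocessed trace
#'
#' Computes the discrete gradient (central differences, one-sided at the
#' ends) of the processed signal, derives its analytic signal via the
#' Hilbert transform, and takes the magnitude as the instantaneous
#' amplitude. The envelope is max-normalized to 1 and smoothed with a
#' zero-phase Butterworth band-pass; the smoothed envelope is max-normalized
#' again so the peak-detection height criterion works in normalized units.
#' Initial and final samples (`trim_s` on each side) are discarded to
#' mitigate edge effects.
#'
#' The instantaneous amplitude of the interferogram's rate of change tracks
#' the fringe frequency, i.e. the magnitude of the membrane velocity: it is
#' maximal during the systolic upstroke and dips towards zero at every
#' displacement reversal, which is what makes it the carrier of both the
#' cycle-onset (peak) and the breakpoint-candidate (minima) information.
#'
#' @param pre an `fpi_preprocessed` object (see [preprocess_trace()]), or an
#'   [fpi_trace()].
#' @param trim_s seconds trimmed from each end (default 0.5); `2 * trim_s`
#'   must be smaller than the trace duration.
#' @param band two-element numeric, band-pass corners in Hz for envelope
#'   smoothing (default `c(0.5, 10)`), strictly inside `(0, Nyquist)`.
#' @param smooth_order Butterworth order of the smoothing band-pass
#'   (default 2).
#' @param smooth_hz anti-noise low-pass applied before differentiation
#'   (differencing amplifies wide-band noise proportionally to frequency);
#'   `NULL` (default) means a tenth of the sampling rate -- far above the
#'   fringe band, so signal content is untouched -- and `0` disables it.
#' @return object of class `envelope_result`: list with `time_s`,
#'   `rate_of_change`, `envelope` (nonnegative, max 1), `smoothed_envelope`
#'   (max 1) and `sampling_rate_hz`.
#' @export
compute_envelope <- function(pre, trim_s = 0.5, band = c(0.5, 10),
                             smooth_order = 2L, smooth_hz = NULL) {
  sig <- as_signal(pre)
  fs <- sig$sampling_rate_hz
  dur <- sig$time_s[length(sig$time_s)] - sig$time_s[1L]
  if (trim_s < 0) stop("trim_s must be nonnegative")
  if (2 * trim_s >= dur) {
    stop("trim_s too large: 2 * trim_s must be below the trace duration (",
         format(dur, digits = 4), " s)")
  }
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    stop("band must satisfy 0 < low < high < Nyquist (", fs / 2, " Hz)")
  }
  keep <- sig$time_s >= sig$time_s[1L] + trim_s &
    sig$time_s <= sig$time_s[length(sig$time_s)] - trim_s
  tt <- sig$time_s[keep]
  xx <- sig$values[keep]
  if (is.null(smooth_hz)) smooth_hz <- fs / 10
  if (smooth_hz > 0) {
    xx <- zero_phase_butter(xx, fs, smooth_hz, 2L, type = "low")
  }
  roc <- pracma::gradient(xx, 1 / fs)
  env <- Mod(analytic_signal(roc))
  m <- max(env)
  if (m > 0) env <- env / m
  sm <- zero_phase_butter(env, fs, band, smooth_order, type = "pass")
  ms <- max(sm)
  if (ms > 0) sm <- sm / ms
  structure(
    list(time_s = tt,
         rate_of_change = roc,
         envelope = env,
         smoothed_envelope = sm,
         sampling_rate_hz = fs),
    class = "envelope_result"
  )
}

#' @export
print.envelope_result <- function(x, ...) {
  cat("<envelope_result> ", length(x$time_s), " samples, ",
      format(x$time_s[1], digits = 4), "-",
      format(x$time_s[length(x$time_s)], digits = 4), " s\n", sep = "")
  invisible(x)
}

# Coerce supported containers to a plain (time, values) signal.
as_signal <- function(x) {
  if (inherits(x, "envelope_result")) {
    list(time_s = x$time_s, values = x$smoothed_envelope,
         sampling_rate_hz = x$sampling_rate_hz)
  } else if (inherits(x, "fpi_preprocessed")) {
    list(time_s = x$time_s, values = x$processed,
         sampling_rate_hz = x$sampling_rate_hz)
  } else if (inherits(x, "fpi_trace")) {
    list(time_s = x$time_s, values = x$intensity,
         sampling_rate_hz = x$sampling_rate_hz)
  } else if (is.list(x) && all(c("time_s", "values") %in% names(x))) {
    if (is.null(x$sampling_rate_hz)) {
      x$sampling_rate_hz <- 1 / stats::median(diff(x$time_s))
    }
    x
  } else {
    stop("unsupported signal container: ", paste(class(x), collapse = "/"))
  }
}

#' Detect peaks of the smoothed envelope
#'
#' Local maxima of the smoothed envelope at least `min_height` high,
#' retained greedily in descending height order subject to a minimum
#' pairwise separation. Each retained peak marks one cardiac cycle onset.
#'
#' @param env an `envelope_result` (or any container accepted by the epoch
#'   functions; the smoothed envelope is used).
#' @param min_height minimum peak height in normalized units (default 0.3).
#' @param min_distance_s minimum separation between peaks in seconds
#'   (default 0.5, capping the detected rate at 120 bpm).
#' @return numeric vector of peak times (seconds), sorted; may be empty.
#' @export
detect_envelope_peaks <- function(env, min_height = 0.3,
                                  min_distance_s = 0.5) {
  if (min_distance_s <= 0) stop("min_distance_s must be positive")
  sig <- as_signal(env)
  idx <- greedy_peaks(sig$values, min_height,
                      round(min_distance_s * sig$sampling_rate_hz))
  sig$time_s[idx]
}

#' Epoch-average a signal around event onsets
#'
#' Extracts a fixed window around each peak time, averages the epochs
#' pointwise and attaches the normal-approximation 95% confidence band
#' (`mean +- 1.96 * sd / sqrt(k)`). Peaks whose window would exceed the
#' signal extent are dropped (and counted).
#'
#' @param x signal container ([compute_envelope()] result, preprocessed
#'   trace, or plain `list(time_s=, values=)`).
#' @param peak_times event onset times in seconds.
#' @param window two-element numeric `c(pre_s, post_s)` relative window,
#'   `pre_s < post_s` (default `c(-0.2, 1.0)`).
#' @return object of class `epoch_average`: list with `epoch_time_s`
#'   (relative axis), `mean_signal`, `ci_lower`, `ci_upper`, `epoch_count`,
#'   `dropped_count` and `sampling_rate_hz`.
#' @export
epoch_average <- function(x, peak_times, window = c(-0.2, 1.0)) {
  sig <- as_signal(x)
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("window must be c(pre_s, post_s) with pre_s < post_s")
  }
  if (length(peak_times) == 0L) stop("no peaks supplied")
  fs <- sig$sampling_rate_hz
  rel_idx <- seq(round(window[1] * fs), round(window[2] * fs))
  n <- length(sig$values)
  t0 <- sig$time_s[1L]
  centers <- round((peak_times - t0) * fs) + 1L
  ok <- centers + rel_idx[1L] >= 1L & centers + rel_idx[length(rel_idx)] <= n
  dropped <- sum(!ok)
  centers <- centers[ok]
  if (length(centers) == 0L) {
    stop("no usable epochs: every peak window exceeds the signal extent")
  }
  epochs <- vapply(centers, function(c0) sig$values[c0 + rel_idx],
                   numeric(length(rel_idx)))
  k <- length(centers)
  mu <- rowMeans(epochs)
  se <- if (k > 1L) apply(epochs, 1L, stats::sd) / sqrt(k) else rep(0, length(mu))
  structure(
    list(epoch_time_s = rel_idx / fs,
         mean_signal = mu,
         ci_lower = mu - 1.96 * se,
         ci_upper = mu + 1.96 * se,
         epoch_count = k,
         dropped_count = dropped,
         sampling_rate_hz = fs),
    class = "epoch_average"
  )
}

#' @export
print.epoch_average <- function(x, ...) {
  cat("<epoch_average> ", x$epoch_count, " epochs (",
      x$dropped_count, " dropped), window ",
      format(x$epoch_time_s[1], digits = 3), " to ",
      format(x$epoch_time_s[length(x$epoch_time_s)], digits = 3),
      " s\n", sep = "")
  invisible(x)
}

#' Locate epoch-averaged minima and map them to absolute times
#'
#' Minima of the epoch-averaged signal are found as peaks of the negated
#' mean signal (same height/distance machinery as
#' [detect_envelope_peaks()]). Each epoch-relative minimum is emitted at
#' `peak_time + t_rel` for every supplied peak; the pooled catalog is
#' sorted, de-duplicated and optionally truncated at either end (mirroring
#' the manual removal of spurious first/last minima in low-rate-of-change
#' diastolic regions).
#'
#' @param avg an `epoch_average`.
#' @param peak_times the absolute peak times the epochs were aligned on.
#' @param min_separation_s minimum separation between epoch-relative minima
#'   (default 0.05 s).
#' @param min_prominence minimum dip depth relative to the adjacent maxima
#'   of the mean signal (default 0.02 normalized units). Low-rate-of-change
#'   diastolic stretches carry shallow envelope wiggles that are not
#'   displacement reversals; pruning by dip prominence removes them, which
#'   is the automatic counterpart of the manual removal of spurious
#'   first/last minima.
#' @param min_depth minimum height of the negated mean signal for a minimum
#'   to count (default `-Inf`: every sufficiently prominent local minimum).
#' @param drop_first,drop_last number of leading/trailing catalog records to
#'   discard (default 0).
#' @return a `minima_catalog` data.frame with columns `absolute_time_s`,
#'   `amplitude` (mean-signal value at the minimum) and `epoch_rel_time_s`
#'   (the epoch-relative minimum each record maps from); may have zero rows.
#' @export
detect_epoch_minima <- function(avg, peak_times, min_separation_s = 0.05,
                                min_prominence = 0.02, min_depth = -Inf,
                                drop_first = 0L, drop_last = 0L) {
  stopifnot(inherits(avg, "epoch_average"))
  neg <- -avg$mean_signal
  ext <- local_extrema(neg)
  pruned <- prune_extrema(ext$index, ext$type, neg, min_prominence)
  cand <- pruned$index[pruned$type == "MAX"]
  cand <- cand[neg[cand] >= min_depth]
  # greedy retention by depth under the separation constraint
  cand <- cand[order(neg[cand], decreasing = TRUE)]
  min_sep_idx <- round(min_separation_s * avg$sampling_rate_hz)
  idx <- integer(0)
  for (i in cand) {
    if (all(abs(idx - i) >= min_sep_idx)) idx <- c(idx, i)
  }
  idx <- sort(idx)
  empty <- data.frame(absolute_time_s = numeric(0), amplitude = numeric(0),
                      epoch_rel_time_s = numeric(0))
  if (length(idx) == 0L) return(structure(empty, class = c("minima_catalog", "data.frame")))
  t_rel <- avg$epoch_time_s[idx]
  amp <- avg$mean_signal[idx]
  cat_df <- do.call(rbind, lapply(seq_along(peak_times), function(i) {
    data.frame(absolute_time_s = peak_times[i] + t_rel,
               amplitude = amp,
               epoch_rel_time_s = t_rel)
  }))
  cat_df <- cat_df[order(cat_df$absolute_time_s), ]
  # de-duplicate records mapped from adjacent epochs onto the same instant
  if (nrow(cat_df) > 1L) {
    keep <- c(TRUE, diff(cat_df$absolute_time_s) >= min_separation_s / 2)
    cat_df <- cat_df[keep, ]
  }
  n <- nrow(cat_df)
  drop_first <- min(as.integer(drop_first), n)
  drop_last <- min(as.integer(drop_last), n - drop_first)
  if (drop_first > 0L || drop_last > 0L) {
    cat_df <- cat_df[seq.int(drop_first + 1L, n - drop_last), , drop = FALSE]
  }
  rownames(cat_df) <- NULL
  structure(cat_df, class = c("minima_catalog", "data.frame"))
}

#' Write / read the minima catalog CSV (`absolute_time,amplitude`)
#'
#' @param catalog a `minima_catalog` data.frame.
#' @param path CSV path (conventionally `minima.csv`).
#' @return `path` invisibly (write); a `minima_catalog` (read).
#' @export
write_minima <- function(catalog, path) {
  utils::write.csv(
    data.frame(absolute_time = catalog$absolute_time_s,
               amplitude = catalog$amplitude),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_minima
#' @export
read_minima <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  d <- utils::read.csv(path)
  if (!all(c("absolute_time", "amplitude") %in% names(d))) {
    stop("expected columns absolute_time, amplitude in ", path)
  }
  structure(
    data.frame(absolute_time_s = d$absolute_time,
               amplitude = d$amplitude,
               epoch_rel_time_s = NA_real_),
    class = c("minima_catalog", "data.frame")
  )
}
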