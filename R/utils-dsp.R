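# Internal signal-processing primitives shared across the pipeline.

#' Zero-phase IIR filtering
#'
#' Applies a recursive filter forward and then backward so the output carries
#' no phase delay relative to the input. Edge transients are controlled by
#' odd-symmetric extension of the signal at both ends plus steady-state
#' (direct-form-I) initial conditions, so that a constant input produces a
#' constant output from the first sample.
#'
#' @param b,a numerator / denominator coefficients of the filter.
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @keywords internal
#' @noRd
zero_phase_filter <- function(b, a, x) {
  nb <- length(b)
  na <- length(a)
  n <- length(x)
  npad <- 3L * (max(na, nb) - 1L)
  if (n <= npad + 1L) {
    stop("signal too short for zero-phase filtering (need > ", npad + 1L, " samples)")
  }
  xe <- c(2 * x[1] - x[(npad + 1L):2L],
          x,
          2 * x[n] - x[(n - 1L):(n - npad)])
  dc <- sum(b) / sum(a)
  run_one <- function(z) {
    z0 <- z[1]
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z0, nb - 1L),
                              init = rep(z0 * dc, na - 1L)))
  }
  y <- run_one(xe)
  y <- rev(run_one(rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Butterworth zero-phase convenience wrappers
#' @keywords internal
#' @noRd
zero_phase_butter <- function(x, fs, cutoff_hz, order, type) {
  nyq <- fs / 2
  w <- cutoff_hz / nyq
  if (any(w <= 0) || any(w >= 1)) {
    stop("cutoff frequency must lie strictly between 0 and the Nyquist frequency (",
         nyq, " Hz)")
  }
  bf <- signal::butter(order, w, type = type)
  zero_phase_filter(bf$b, bf$a, x)
}

#' Analytic signal via the FFT
#'
#' Standard one-sided spectrum construction: the negative-frequency half of
#' the spectrum is zeroed and the positive half doubled, yielding
#' x + i * H(x) where H is the Hilbert transform.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Indices of strict local extrema of x, alternating by construction.
# Flat runs are compressed by carrying the last non-zero slope sign forward,
# so a plateau contributes (at most) one extremum at its trailing edge.
# Returns a data.frame with columns `index` and `type` ("MAX"/"MIN").
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(data.frame(index = integer(0), type = character(0)))
  }
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2L) {
    return(data.frame(index = integer(0), type = character(0)))
  }
  # carry last non-zero sign forward across flats; leading flats take the
  # first non-zero sign so they never spawn an extremum at the boundary
  s_filled <- stats::approx(nz, s[nz], xout = seq_along(s),
                            method = "constant", rule = 2, f = 0)$y
  chg <- which(diff(s_filled) != 0)
  if (length(chg) == 0L) {
    return(data.frame(index = integer(0), type = character(0)))
  }
  ext_idx <- chg + 1L
  type <- ifelse(s_filled[chg] > 0, "MAX", "MIN")
  data.frame(index = as.integer(ext_idx), type = type,
             stringsAsFactors = FALSE)
}

# Alternation-preserving pruning of an extrema sequence by minimum
# peak-to-valley excursion (single-pass turning-point / hysteresis rule):
# a candidate of the same type as the last retained extremum replaces it if
# more extreme; an opposite-type candidate is retained only once it differs
# from the last retained value by at least `min_excursion`. The surviving
# sequence strictly alternates MAX/MIN and every adjacent pair differs by
# at least `min_excursion`.
prune_extrema <- function(idx, type, values, min_excursion) {
  stopifnot(length(idx) == length(type))
  if (length(idx) < 2L || min_excursion <= 0) {
    return(list(index = idx, type = type))
  }
  v <- values[idx]
  n <- length(idx)
  keep_idx <- integer(n)
  keep_type <- character(n)
  keep_v <- numeric(n)
  top <- 1L
  keep_idx[1L] <- idx[1L]; keep_type[1L] <- type[1L]; keep_v[1L] <- v[1L]
  for (i in 2L:n) {
    if (type[i] == keep_type[top]) {
      more_extreme <- if (type[i] == "MAX") v[i] > keep_v[top] else v[i] < keep_v[top]
      if (more_extreme) {
        keep_idx[top] <- idx[i]; keep_v[top] <- v[i]
      }
    } else if (abs(v[i] - keep_v[top]) >= min_excursion) {
      top <- top + 1L
      keep_idx[top] <- idx[i]; keep_type[top] <- type[i]; keep_v[top] <- v[i]
    }
  }
  # a leading spurious extremum can survive with a sub-threshold gap to its
  # successor; drop it so the guarantee holds at the front too
  while (top >= 2L && abs(keep_v[2L] - keep_v[1L]) < min_excursion) {
    keep_idx <- keep_idx[-1L]; keep_type <- keep_type[-1L]; keep_v <- keep_v[-1L]
    top <- top - 1L
  }
  list(index = keep_idx[seq_len(top)], type = keep_type[seq_len(top)])
}

# Greedy peak selection: local maxima of `values` with height >= min_height,
# retained in descending height order subject to a minimum index distance.
greedy_peaks <- function(values, min_height, min_distance_idx) {
  ext <- local_extrema(values)
  cand <- ext$index[ext$type == "MAX"]
  cand <- cand[values[cand] >= min_height]
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(values[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(kept - i) >= min_distance_idx)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

rms <- function(x) sqrt(mean(x^2))
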