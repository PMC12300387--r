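#' Ordered set of labeled points on an interferogram
#'
#' Container for the segmentation skeleton of a recording: fringe extrema
#' (`MAX`/`MIN`) and breakpoints (`BP`, displacement reversals) ordered by
#' time within an analysis window. Points must have strictly increasing
#' times; physiological ordering/parity rules are checked separately by
#' [validate_annotations()] so that raw automatic detections can be held and
#' edited before they satisfy the rules.
#'
#' @param points data.frame with columns `sample_index` (0-based),
#'   `time_s`, `value` and `status` (one of `"MAX"`, `"MIN"`, `"BP"`).
#' @param analysis_window two-element numeric `c(start_s, end_s)`.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(points, analysis_window) {
  required <- c("sample_index", "time_s", "value", "status")
  if (!all(required %in% names(points))) {
    stop("points must have columns ", paste(required, collapse = ", "))
  }
  points <- as.data.frame(points)[required]
  if (!all(points$status %in% c("MAX", "MIN", "BP"))) {
    bad <- setdiff(unique(points$status), c("MAX", "MIN", "BP"))
    stop("invalid status token(s): ", paste(bad, collapse = ", "))
  }
  points <- points[order(points$time_s), ]
  rownames(points) <- NULL
  if (nrow(points) > 1L && any(diff(points$time_s) <= 0)) {
    stop("annotation times must be strictly increasing")
  }
  if (length(analysis_window) != 2L || analysis_window[2] <= analysis_window[1]) {
    stop("analysis_window must be c(start_s, end_s) with start < end")
  }
  if (nrow(points) > 0L &&
      (min(points$time_s) < analysis_window[1] ||
       max(points$time_s) > analysis_window[2])) {
    stop("annotation times must lie within the analysis window")
  }
  structure(
    list(points = points, analysis_window = as.numeric(analysis_window),
         audit_log = character(0)),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  tab <- table(factor(x$points$status, levels = c("MAX", "MIN", "BP")))
  cat("<annotation_set> ", nrow(x$points), " points (",
      tab[["MAX"]], " MAX, ", tab[["MIN"]], " MIN, ", tab[["BP"]], " BP), ",
      "window ", format(x$analysis_window[1], digits = 4), "-",
      format(x$analysis_window[2], digits = 4), " s\n", sep = "")
  invisible(x)
}

#' Detect interference-fringe extrema
#'
#' Finds the alternating local maxima and minima of the processed intensity
#' within a time window. Small oscillations are pruned by a minimum
#' peak-to-valley excursion (`prominence`); whenever pruning leaves two
#' same-type neighbours the more extreme one is kept, so the returned
#' sequence strictly alternates MAX/MIN.
#'
#' Sample-level white noise is attenuated before the extremum scan by a
#' gentle zero-phase Butterworth low-pass well above the fringe band
#' (default a tenth of the sampling rate), which does not shift extremum
#' times; set `smooth_hz = 0` to disable.
#'
#' @param pre an `fpi_preprocessed` object or [fpi_trace()].
#' @param window optional `c(start_s, end_s)`; default the full trace.
#' @param prominence minimum peak-to-valley excursion, in units of the
#'   analyzed signal (default 0.05, matching the `[0,1]` normalized scale).
#' @param smooth_hz anti-noise low-pass cutoff in Hz; `NULL` (default)
#'   means a tenth of the sampling rate, `0` disables smoothing.
#' @return data.frame of labeled points (`sample_index` 0-based w.r.t. the
#'   full trace, `time_s`, `value`, `status` in MAX/MIN).
#' @export
detect_extrema <- function(pre, window = NULL, prominence = 0.05,
                           smooth_hz = NULL) {
  sig <- as_signal(pre)
  if (is.null(window)) {
    window <- range(sig$time_s)
  }
  sel <- which(sig$time_s >= window[1] & sig$time_s <= window[2])
  if (length(sel) < 3L) stop("analysis window contains fewer than 3 samples")
  x <- sig$values[sel]
  if (is.null(smooth_hz)) smooth_hz <- sig$sampling_rate_hz / 10
  if (smooth_hz > 0) {
    x <- zero_phase_butter(x, sig$sampling_rate_hz, smooth_hz, 2L,
                           type = "low")
  }
  ext <- local_extrema(x)
  pruned <- prune_extrema(ext$index, ext$type, x, prominence)
  if (length(pruned$index) < 2L) {
    stop("fewer than 2 extrema found: no interference fringes in the window")
  }
  gi <- sel[pruned$index]            # 1-based index into the full trace
  data.frame(
    sample_index = gi - 1L,
    time_s = sig$time_s[gi],
    value = sig$values[gi],
    status = pruned$type,
    stringsAsFactors = FALSE
  )
}

#' Propose breakpoints from a minima catalog
#'
#' A breakpoint -- the instant at which membrane displacement reverses -- is
#' itself a local extremum of the interference intensity, so breakpoints are
#' constrained to coincide with detected fringe extrema. For each catalog
#' minimum the candidate extremum within `search_radius_s` is selected by
#' one of three rules:
#'
#' * `"reversal"` (default): prefer partial-fringe extrema. Ordinary fringe
#'   extrema sit at the full-scale levels of the normalized intensity
#'   (near 0 or 1), whereas the extremum created by a displacement reversal
#'   takes whatever intermediate value the interrupted cosine had reached,
#'   so a clearly mid-scale extremum (at least `partial_fringe_margin` away
#'   from both levels) is the reversal itself. Among such candidates the
#'   nearest is chosen; if none is mid-scale (the reversal happens to
#'   coincide with a fringe level and merges with its neighbouring
#'   extremum), the rule falls back to the nearest candidate.
#' * `"nearest"`: the candidate nearest in time.
#' * `"widest"`: the candidate with the largest summed gap to its
#'   neighbouring extrema (slowest local phase progression).
#'
#' Minima with no extremum in range are skipped with a warning; duplicates
#' collapse to one breakpoint.
#'
#' @param extrema data.frame from [detect_extrema()].
#' @param minima_catalog a `minima_catalog` (see [detect_epoch_minima()]).
#' @param search_radius_s search radius in seconds (default 0.15).
#' @param method candidate selection rule (see above).
#' @param partial_fringe_margin minimum distance from the 0/1 full-scale
#'   levels for an extremum to count as a partial fringe (default 0.15).
#' @return data.frame of the selected points relabeled `status = "BP"`
#'   (possibly zero rows).
#' @export
propose_breakpoints <- function(extrema, minima_catalog,
                                search_radius_s = 0.15,
                                method = c("reversal", "nearest", "widest"),
                                partial_fringe_margin = 0.15) {
  method <- match.arg(method)
  if (search_radius_s < 0) stop("search_radius_s must be nonnegative")
  empty <- extrema[0, ]
  if (is.null(minima_catalog) || nrow(minima_catalog) == 0L) {
    return(empty)
  }
  et <- extrema$time_s
  gaps <- if (length(et) >= 2L) {
    d <- diff(et)
    c(d[1], (d[-length(d)] + d[-1]) / 2, d[length(d)]) * 2
  } else {
    rep(0, length(et))
  }
  chosen <- integer(0)
  for (tm in minima_catalog$absolute_time_s) {
    d <- abs(et - tm)
    cand <- which(d <= search_radius_s)
    if (length(cand) == 0L) {
      warning("no fringe extremum within ", search_radius_s,
              " s of catalog minimum at ", format(tm, digits = 5),
              " s; skipped")
      next
    }
    pick <- if (method == "nearest") {
      cand[which.min(d[cand])]
    } else if (method == "reversal") {
      # prefer partial-fringe extrema, but only within half the radius:
      # neighbouring reversals are >= ~0.1 s apart, so a mid-scale extremum
      # much farther than the catalog estimate's own uncertainty belongs to
      # a different event (a reversal merged with a fringe rail shows up as
      # a near-rail extremum right at the estimate instead)
      score <- pmin(extrema$value[cand], 1 - extrema$value[cand])
      good <- cand[score >= partial_fringe_margin &
                     d[cand] <= search_radius_s / 2]
      if (length(good) > 0L) good[which.min(d[good])] else cand[which.min(d[cand])]
    } else {
      best <- cand[gaps[cand] == max(gaps[cand])]
      best[which.min(d[best])]
    }
    chosen <- c(chosen, pick)
  }
  chosen <- sort(unique(chosen))
  if (length(chosen) == 0L) return(empty)
  bp <- extrema[chosen, ]
  bp$status <- "BP"
  rownames(bp) <- NULL
  bp
}

#' Assemble an annotation set from extrema and proposed breakpoints
#'
#' Relabels the chosen extrema as BP, merges, and (optionally) trims the
#' sequence so that it starts with the extremum immediately preceding the
#' first breakpoint and ends at the last breakpoint -- the canonical
#' "extremum followed by breakpoint" start of an analysis period.
#'
#' @param extrema data.frame from [detect_extrema()].
#' @param breakpoints data.frame from [propose_breakpoints()].
#' @param analysis_window `c(start_s, end_s)`; default spans the points.
#' @param trim if `TRUE` (default) trim to the extremum-BP ... BP core.
#' @return an [annotation_set()].
#' @export
build_annotations <- function(extrema, breakpoints, analysis_window = NULL,
                              trim = TRUE) {
  pts <- extrema
  if (nrow(breakpoints) > 0L) {
    pts$status[pts$sample_index %in% breakpoints$sample_index] <- "BP"
  }
  pts <- pts[order(pts$time_s), ]
  if (trim && any(pts$status == "BP")) {
    bp_pos <- which(pts$status == "BP")
    first_bp <- bp_pos[1L]
    last_bp <- bp_pos[length(bp_pos)]
    start <- max(1L, first_bp - 1L)
    pts <- pts[start:last_bp, , drop = FALSE]
  }
  rownames(pts) <- NULL
  if (is.null(analysis_window)) {
    analysis_window <- range(pts$time_s) + c(-1e-9, 1e-9)
  }
  annotation_set(pts, analysis_window)
}

#' Enforce even breakpoint parity per cardiac cycle
#'
#' A cardiac cycle must contain an even number of breakpoints: every
#' excursion of the membrane away from its end-diastolic position reverses
#' an even number of times within one period. An odd count signals a missed
#' or spurious breakpoint. For each odd cycle this repair either promotes
#' the most reversal-like unlabeled extremum (the one with the strongest
#' partial-fringe character, see [propose_breakpoints()]) to BP, or -- when
#' no candidate is convincingly mid-scale -- demotes the least
#' reversal-like BP back to its extremum label.
#'
#' @param annotations an [annotation_set()].
#' @param cycle_bounds sorted numeric vector of cycle boundary times.
#' @param partial_fringe_margin minimum mid-scale score to promote an
#'   extremum (default 0.15).
#' @return the repaired [annotation_set()]; repairs are appended to the
#'   audit log.
#' @export
enforce_bp_parity <- function(annotations, cycle_bounds,
                              partial_fringe_margin = 0.15) {
  stopifnot(inherits(annotations, "annotation_set"))
  pts <- annotations$points
  log <- annotations$audit_log
  score <- pmin(pts$value, 1 - pts$value)
  for (j in seq_len(length(cycle_bounds) - 1L)) {
    in_cyc <- which(pts$time_s >= cycle_bounds[j] &
                      pts$time_s < cycle_bounds[j + 1L])
    is_bp <- pts$status[in_cyc] == "BP"
    if (sum(is_bp) %% 2L == 0L) next
    cand_add <- in_cyc[!is_bp]
    cand_add <- cand_add[score[cand_add] >= partial_fringe_margin]
    if (length(cand_add) > 0L) {
      pick <- cand_add[which.max(score[cand_add])]
      # a promoted extremum loses its MAX/MIN label, as in proposal
      old <- pts$status[pick]
      pts$status[pick] <- "BP"
      log <- c(log, paste0("parity repair cycle ", j, ": promoted ", old,
                           " at ", format(pts$time_s[pick], digits = 6),
                           " s to BP"))
    } else {
      bps <- in_cyc[is_bp]
      pick <- bps[which.min(score[bps])]
      # demote to the fringe level it sits on
      pts$status[pick] <- if (pts$value[pick] >= 0.5) "MAX" else "MIN"
      log <- c(log, paste0("parity repair cycle ", j, ": demoted BP at ",
                           format(pts$time_s[pick], digits = 6),
                           " s to ", pts$status[pick]))
    }
  }
  out <- annotation_set(pts, annotations$analysis_window)
  out$audit_log <- log
  out
}

#' Apply scripted edits to an annotation set
#'
#' The reproducible replacement for interactive point adjustment: a list of
#' add / remove / relabel / move commands applied in order, with an audit
#' log recording every command. Commands reference points by `sample_index`.
#'
#' Each command is a list (or one row of a data.frame) with fields:
#' * `op = "add"`: `index`, `time`, `value`, `status`
#' * `op = "remove"`: `index`
#' * `op = "relabel"`: `index`, `status`
#' * `op = "move"`: `index`, `new_time`, optional `new_index`, `new_value`
#'
#' @param annotations an [annotation_set()].
#' @param edits list of commands, or a data.frame with the union of the
#'   fields above (unused fields `NA`).
#' @return the edited [annotation_set()] with an extended `audit_log`.
#' @export
apply_edits <- function(annotations, edits) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (is.data.frame(edits)) {
    edits <- lapply(seq_len(nrow(edits)), function(i) {
      as.list(edits[i, , drop = FALSE])
    })
  }
  pts <- annotations$points
  win <- annotations$analysis_window
  log <- annotations$audit_log
  for (k in seq_along(edits)) {
    cmd <- edits[[k]]
    op <- cmd$op
    describe <- function() {
      paste0("edit #", k, " (", op, ")")
    }
    find_row <- function(index) {
      row <- which(pts$sample_index == index)
      if (length(row) != 1L) {
        stop(describe(), ": no point with sample_index ", index)
      }
      row
    }
    if (identical(op, "add")) {
      if (cmd$time < win[1] || cmd$time > win[2]) {
        stop(describe(), ": time ", cmd$time, " outside the analysis window")
      }
      if (!cmd$status %in% c("MAX", "MIN", "BP")) {
        stop(describe(), ": invalid status ", cmd$status)
      }
      pts <- rbind(pts, data.frame(sample_index = as.integer(cmd$index),
                                   time_s = cmd$time, value = cmd$value,
                                   status = cmd$status))
    } else if (identical(op, "remove")) {
      pts <- pts[-find_row(cmd$index), , drop = FALSE]
    } else if (identical(op, "relabel")) {
      if (!cmd$status %in% c("MAX", "MIN", "BP")) {
        stop(describe(), ": invalid status ", cmd$status)
      }
      pts$status[find_row(cmd$index)] <- cmd$status
    } else if (identical(op, "move")) {
      row <- find_row(cmd$index)
      if (cmd$new_time < win[1] || cmd$new_time > win[2]) {
        stop(describe(), ": new_time ", cmd$new_time,
             " outside the analysis window")
      }
      pts$time_s[row] <- cmd$new_time
      if (!is.null(cmd$new_index) && !is.na(cmd$new_index)) {
        pts$sample_index[row] <- as.integer(cmd$new_index)
      }
      if (!is.null(cmd$new_value) && !is.na(cmd$new_value)) {
        pts$value[row] <- cmd$new_value
      }
    } else {
      stop("edit #", k, ": unknown op \"", op, "\"")
    }
    log <- c(log, paste0(
      "edit #", k, ": ", op, " ",
      paste(names(cmd)[names(cmd) != "op"], "=",
            unlist(cmd[names(cmd) != "op"]), collapse = ", ")
    ))
  }
  out <- annotation_set(pts, win)
  out$audit_log <- log
  out
}

#' Read edit commands from a JSON or CSV file
#'
#' JSON: an array of command objects. CSV: one command per row with columns
#' for the union of fields (`op,index,time,value,status,new_time,new_index,
#' new_value`), empty cells ignored.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @return list of command lists suitable for [apply_edits()].
#' @export
read_edits <- function(path) {
  if (!file.exists(path)) stop("edits file does not exist: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(d)), function(i) {
      row <- as.list(d[i, , drop = FALSE])
      row[!vapply(row, function(v) is.na(v) || identical(v, ""), logical(1))]
    })
  }
}

#' Validate physiological ordering and parity rules
#'
#' Checks, per cardiac cycle, that the number of breakpoints falling in
#' `[start, end)` is even, and that the analysis period starts with an
#' extremum immediately followed by a breakpoint (the start of systole).
#'
#' @param annotations an [annotation_set()].
#' @param cycle_bounds sorted numeric vector of cycle boundary times
#'   (`length >= 2`); cycle `j` is `[cycle_bounds[j], cycle_bounds[j+1])`.
#' @return object of class `annotation_report`: list with `ordering_pass`,
#'   `per_cycle` (data.frame `cycle`, `start_s`, `end_s`, `n_bp`,
#'   `parity_pass`) and `overall_pass`.
#' @export
validate_annotations <- function(annotations, cycle_bounds) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (length(cycle_bounds) < 2L || is.unsorted(cycle_bounds)) {
    stop("cycle_bounds must be a sorted vector of length >= 2")
  }
  pts <- annotations$points
  ordering_pass <- nrow(pts) >= 2L &&
    pts$status[1L] %in% c("MAX", "MIN") &&
    pts$status[2L] == "BP"
  bp_times <- pts$time_s[pts$status == "BP"]
  n_cycles <- length(cycle_bounds) - 1L
  per_cycle <- data.frame(
    cycle = seq_len(n_cycles),
    start_s = cycle_bounds[-length(cycle_bounds)],
    end_s = cycle_bounds[-1L]
  )
  per_cycle$n_bp <- vapply(seq_len(n_cycles), function(j) {
    sum(bp_times >= per_cycle$start_s[j] & bp_times < per_cycle$end_s[j])
  }, integer(1))
  per_cycle$parity_pass <- per_cycle$n_bp %% 2L == 0L
  structure(
    list(ordering_pass = ordering_pass,
         per_cycle = per_cycle,
         overall_pass = ordering_pass && all(per_cycle$parity_pass)),
    class = "annotation_report"
  )
}

#' @export
print.annotation_report <- function(x, ...) {
  cat("<annotation_report> overall ",
      if (x$overall_pass) "PASS" else "FAIL",
      " (ordering ", if (x$ordering_pass) "ok" else "violated",
      "; parity failures in ",
      sum(!x$per_cycle$parity_pass), "/", nrow(x$per_cycle),
      " cycles)\n", sep = "")
  invisible(x)
}

#' Write / read the annotation CSV (`index,time,value,Status`)
#'
#' The `Status` column holds the tokens `MAX`, `MIN`, `BP` bit-exact;
#' `index` is the 0-based sample index. Round-trip is lossless.
#'
#' @param annotations an [annotation_set()].
#' @param path CSV path (conventionally `annotations.csv`).
#' @param analysis_window window to attach on read; default spans the points.
#' @return `path` invisibly (write); an [annotation_set()] (read).
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  pts <- annotations$points
  utils::write.csv(
    data.frame(index = pts$sample_index, time = pts$time_s,
               value = pts$value, Status = pts$status),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, analysis_window = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "time", "value", "Status") %in% names(d))) {
    stop("expected columns index, time, value, Status in ", path)
  }
  if (is.null(analysis_window)) {
    analysis_window <- range(d$time) + c(-1e-9, 1e-9)
  }
  annotation_set(
    data.frame(sample_index = as.integer(d$index), time_s = d$time,
               value = d$value, status = d$Status),
    analysis_window
  )
}
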