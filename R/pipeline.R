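#' Pipeline configuration
#'
#' Bundles every stage's parameters, the I/O paths and the seed into one
#' serializable object. Defaults match the per-stage defaults.
#'
#' @param input path to the raw recording CSV (`time,intensity`); `NULL`
#'   when the pipeline starts from a simulation.
#' @param out_dir directory for intermediate artifacts.
#' @param simulate `NULL`, or a list of [apw_template()] /
#'   [render_interferogram()] parameters (`heart_rate_hz`,
#'   `peak_amplitude_um`, `n_cycles`, `noise_sd`, `sampling_rate_hz`, ...)
#'   used to synthesize the input.
#' @param preprocess a [preprocess_config()] or list of its arguments.
#' @param envelope list of [compute_envelope()] / [detect_envelope_peaks()] /
#'   [epoch_average()] / [detect_epoch_minima()] parameters.
#' @param annotation list of [detect_extrema()] / [propose_breakpoints()]
#'   parameters, optionally with `edits` (path to an edits file) and
#'   `window`.
#' @param optics an [optical_config()] or list of its arguments.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = ".",
                            simulate = NULL,
                            preprocess = preprocess_config(),
                            envelope = list(),
                            annotation = list(),
                            optics = optical_config(),
                            seed = 1L) {
  if (is.list(preprocess) && !inherits(preprocess, "preprocess_config")) {
    preprocess <- do.call(preprocess_config, preprocess)
  }
  if (is.list(optics) && !inherits(optics, "optical_config")) {
    optics <- do.call(optical_config, optics)
  }
  env_defaults <- list(trim_s = 0.5, band = c(0.5, 10), min_height = 0.3,
                       min_distance_s = 0.5, epoch_window = c(-0.2, 1.0),
                       min_separation_s = 0.05, drop_first = 0L,
                       drop_last = 0L)
  ann_defaults <- list(prominence = 0.05, search_radius_s = 0.15,
                       bp_method = "reversal", edits = NULL, window = NULL)
  structure(
    list(input = input, out_dir = out_dir, simulate = simulate,
         preprocess = preprocess,
         envelope = utils::modifyList(env_defaults, envelope),
         annotation = utils::modifyList(ann_defaults, annotation),
         optics = optics, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return a [pipeline_config()] (read); `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y$preprocess <- unclass(y$preprocess)
  y$optics <- unclass(y$optics)
  yaml::write_yaml(y, path)
  invisible(path)
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the demodulation pipeline end to end
#'
#' Orchestrates simulate (optional) -> preprocess -> envelope -> annotate ->
#' demodulate, writing `preprocessed.csv`, `minima.csv`, `annotations.csv`
#' and `displacement.csv` into `config$out_dir` plus a `manifest.csv`
#' listing each artifact with its MD5 content hash. Stages are resumable:
#' any stage listed in `stages` reads its inputs from the artifacts already
#' present in `out_dir`. Stage errors abort with the failing stage named;
#' artifacts of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("preprocess", "envelope", "annotate", "demodulate")` to (re)run.
#' @return invisibly, the manifest data.frame (`file`, `md5`, `rows`).
#' @export
run_pipeline <- function(config,
                         stages = c("preprocess", "envelope", "annotate",
                                    "demodulate")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    preprocessed = file.path(config$out_dir, "preprocessed.csv"),
    minima = file.path(config$out_dir, "minima.csv"),
    annotations = file.path(config$out_dir, "annotations.csv"),
    displacement = file.path(config$out_dir, "displacement.csv")
  )
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage \"", stage, "\" failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  input_path <- config$input
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    tmpl_args <- sim[names(sim) %in% names(formals(apw_template))]
    tmpl <- do.call(apw_template, tmpl_args)
    fs <- if (!is.null(sim$sampling_rate_hz)) sim$sampling_rate_hz else 10000
    noise_sd <- if (!is.null(sim$noise_sd)) sim$noise_sd else 0
    prof <- make_apw(tmpl, fs, seed = config$seed)
    rec <- render_interferogram(prof, config$optics, noise_sd = noise_sd,
                                seed = config$seed)
    input_path <- file.path(config$out_dir, "simulated.csv")
    write_recording(rec, input_path)
    stage_log("simulate", length(prof$time_s), " samples @ ", fs, " Hz, ",
              "noise sd ", noise_sd, " -> ", input_path)
  }

  if ("preprocess" %in% stages) {
    if (is.null(input_path) || !file.exists(input_path)) {
      stop("pipeline stage \"preprocess\" failed: input file not found: ",
           if (is.null(input_path)) "<NULL>" else input_path, call. = FALSE)
    }
    in_stage("preprocess", {
      pre <- preprocess_trace(read_trace(input_path), config$preprocess)
      write_preprocessed(pre, paths$preprocessed)
      stage_log("preprocess", length(pre$time_s), " samples, ",
                length(pre$outlier_indices), " outliers repaired -> ",
                paths$preprocessed)
    })
  }

  ep <- config$envelope
  if ("envelope" %in% stages) {
    in_stage("envelope", {
      pre <- read_preprocessed(paths$preprocessed)
      env <- compute_envelope(pre, trim_s = ep$trim_s, band = ep$band)
      peaks <- detect_envelope_peaks(env, min_height = ep$min_height,
                                     min_distance_s = ep$min_distance_s)
      avg <- epoch_average(env, peaks, window = ep$epoch_window)
      minima <- detect_epoch_minima(avg, peaks,
                                    min_separation_s = ep$min_separation_s,
                                    drop_first = ep$drop_first,
                                    drop_last = ep$drop_last)
      write_minima(minima, paths$minima)
      stage_log("envelope", length(peaks), " envelope peaks, ",
                nrow(minima), " catalog minima -> ", paths$minima)
    })
  }

  ap <- config$annotation
  if ("annotate" %in% stages) {
    in_stage("annotate", {
      pre <- read_preprocessed(paths$preprocessed)
      minima <- read_minima(paths$minima)
      extrema <- detect_extrema(pre, window = ap$window,
                                prominence = ap$prominence)
      bps <- propose_breakpoints(extrema, minima,
                                 search_radius_s = ap$search_radius_s,
                                 method = ap$bp_method)
      ann <- build_annotations(extrema, bps)
      # cycle bounds for the parity repair come from the envelope peaks
      env <- compute_envelope(pre, trim_s = ep$trim_s, band = ep$band)
      cyc <- detect_envelope_peaks(env, min_height = ep$min_height,
                                   min_distance_s = ep$min_distance_s)
      if (length(cyc) >= 2L) {
        ann <- enforce_bp_parity(ann, cyc)
      }
      if (!is.null(ap$edits)) {
        ann <- apply_edits(ann, read_edits(ap$edits))
      }
      write_annotations(ann, paths$annotations)
      stage_log("annotate", nrow(ann$points), " points (",
                sum(ann$points$status == "BP"), " BP) -> ",
                paths$annotations)
    })
  }

  if ("demodulate" %in% stages) {
    in_stage("demodulate", {
      pre <- read_preprocessed(paths$preprocessed)
      ann <- read_annotations(paths$annotations)
      disp <- demodulate(pre, ann, config$optics)
      write_displacement(disp, paths$displacement)
      stage_log("demodulate", nrow(disp), " samples, delta_z ",
                format(max(disp$delta_z_nm) / 1000, digits = 4),
                " um peak -> ", paths$displacement)
    })
  }

  files <- unlist(paths)
  files <- files[file.exists(files)]
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    rows = vapply(files, function(f) length(readLines(f)) - 1L, integer(1)),
    row.names = NULL
  )
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
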