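#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML (or JSON) file with blocks `input`
#' (`tiff`, `voxel_size`, `n_z`, `frame_interval`, `head_direction`),
#' `preprocess` (`denoise`, `gain`, `dark_crop`, `order`), `detection`,
#' `tracking`, `roi`, `trace`, `identification` and `seed`. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML/JSON config file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- c("input", "preprocess", "detection", "tracking", "roi", "trace",
             "identification", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  block_keys <- list(
    input = c("tiff", "voxel_size", "n_z", "frame_interval",
              "head_direction"),
    preprocess = c("denoise", "gain", "dark_crop", "order"),
    detection = c("filter_size", "sigma", "threshold", "merge_distance"),
    tracking = c("max_link_distance", "max_time_gap", "gap_max_distance",
                 "restore_max_distance", "restore_max_gap", "n_neighbors",
                 "ref_fraction", "extend_to_end"),
    roi = c("sample_every", "extent"),
    trace = c("window"),
    identification = c("lambda_corr", "collinearity_tol", "axis_angle_tol",
                       "threshold_sds", "pool_size", "atlas"))
  for (b in names(block_keys)) {
    extra <- setdiff(names(cfg[[b]]), block_keys[[b]])
    if (length(extra))
      stop("unknown keys in config block '", b, "': ",
           paste(extra, collapse = ", "))
  }
  cfg
}

stage_paths <- function(run_dir) {
  list(inputs = file.path(run_dir, "inputs"),
       detections = file.path(run_dir, "detections", "spots.csv"),
       tracks = file.path(run_dir, "tracks", "tracks.csv"),
       shapes = file.path(run_dir, "shapes", "shapes.csv"),
       traces = file.path(run_dir, "traces", "traces.csv"),
       identities = file.path(run_dir, "identities", "identities.csv"),
       evaldir = file.path(run_dir, "eval"),
       manifest = file.path(run_dir, "manifest.json"))
}

require_stage_output <- function(path, stage) {
  if (!file.exists(path))
    stop("missing output of upstream stage '", stage, "' (", path,
         "); run that stage first")
  path
}

#' Run the full pipeline on a recording
#'
#' Stages: preprocess, detect, track, segment (ROI), extract (traces),
#' identify. Each stage writes its outputs under the run directory and can
#' be resumed individually via `stages`; a manifest with the configuration,
#' seed and per-stage timings is written at the end.
#'
#' @param config config list (see [read_pipeline_config()]).
#' @param run_dir output directory (created if needed).
#' @param rec optionally, an in-memory [recording()] instead of
#'   `config$input$tiff`.
#' @param stages subset of stages to run, in pipeline order.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config, run_dir, rec = NULL,
                         stages = c("detect", "track", "segment",
                                    "extract", "identify")) {
  config <- validate_pipeline_config(config)
  p <- stage_paths(run_dir)
  for (d in c(p$inputs, dirname(p$detections), dirname(p$tracks),
              dirname(p$shapes), dirname(p$traces), dirname(p$identities),
              p$evaldir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  timings <- list()
  clock <- function(expr) system.time(expr)[["elapsed"]]

  load_rec <- function() {
    if (!is.null(rec)) return(rec)
    inp <- config$input
    read_recording(inp$tiff, inp$voxel_size, inp$n_z,
                   inp$frame_interval %||% 1)
  }
  preprocess <- function(r) {
    pp <- config$preprocess
    if (is.null(pp)) return(r)
    order <- pp$order %||% c("denoise", "background")
    for (step in order) {
      if (step == "denoise" && !is.null(pp$denoise))
        r <- temporal_denoise(r, gain = pp$gain %||% 0.5, mode = pp$denoise)
      if (step == "background")
        r <- subtract_background(r, pp$dark_crop)
    }
    r
  }

  rec_pp <- NULL
  get_rec <- function() {
    if (is.null(rec_pp)) rec_pp <<- preprocess(load_rec())
    rec_pp
  }

  if ("detect" %in% stages) {
    timings$detect <- clock({
      dp <- do.call(detection_params, config$detection %||% list())
      spots <- detect_all_frames(get_rec(), dp)
      write_spots_csv(spots, p$detections)
    })
  }
  if ("track" %in% stages) {
    timings$track <- clock({
      spots <- read_spots_csv(require_stage_output(p$detections, "detect"))
      spots <- spot_table(spots$t, spots$x, spots$y, spots$z,
                          spots$intensity, spots$source)
      tp <- do.call(tracking_params, config$tracking %||% list())
      tracks <- track_neurons(spots, dim(get_rec()$frames)[1], tp)
      write_spots_csv(tracks, p$tracks)
    })
  }
  tracks <- NULL
  get_tracks <- function() {
    if (is.null(tracks)) {
      tr <- read_spots_csv(require_stage_output(p$tracks, "track"))
      tracks <<- tr
    }
    tracks
  }
  if ("segment" %in% stages) {
    timings$segment <- clock({
      shapes <- segment_all_rois(get_rec(), get_tracks(),
                                 sample_every =
                                   config$roi$sample_every %||% 10L)
      write_shapes_csv(shapes, p$shapes)
    })
  }
  if ("extract" %in% stages) {
    timings$extract <- clock({
      shapes <- read_shapes_csv(require_stage_output(p$shapes, "segment"))
      traces <- extract_all_traces(get_rec(), get_tracks(), shapes,
                                   window = config$trace$window %||% 5L)
      write_traces_csv(traces, dim(get_rec()$frames)[1], p$traces)
    })
  }
  if ("identify" %in% stages) {
    timings$identify <- clock({
      tm_csv <- read.csv(require_stage_output(p$traces, "extract"))
      m <- t(as.matrix(tm_csv[, -1]))
      colnames(m) <- tm_csv$track_id
      ip <- do.call(ident_params,
                    config$identification[setdiff(
                      names(config$identification), "atlas")] %||% list())
      atlas <- if (!is.null(config$identification$atlas))
        default_atlas(config$identification$atlas) else default_atlas()
      hd <- config$input$head_direction %||% c(1, 0, 0)
      res <- identify_neurons(get_tracks(),
                              apply(m, 2, smooth_trace,
                                    window = config$trace$window %||% 5L),
                              hd, atlas = atlas, params = ip)
      write.csv(res$assignments, p$identities, row.names = FALSE)
    })
  }
  manifest <- list(config = config, seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("nematrace")),
                   stages = stages, timings = timings,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(run_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
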