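#' Pipeline configuration
#'
#' Flat, serialisable configuration for the end-to-end pipeline
#' (simulate/load -> classify -> segment -> track -> filter -> measure ->
#' summarise -> heatmap). All parameters are validated against the
#' stage preconditions before any stage runs.
#'
#' @param regime `"open"` or `"vessel"` (synthetic input).
#' @param n_nuclei,n_frames,frame_interval_s,pixel_size_um,z_slices
#'   synthetic movie geometry, see [synth_movie_config()].
#' @param field_y,field_x field size in pixels.
#' @param noise_gaussian_sd,noise_poisson imaging noise.
#' @param prob_threshold,min_volume_vox segmentation parameters.
#' @param max_disp_um,max_gap tracking parameters.
#' @param min_timepoints,use_vessel_mask track filters.
#' @param sf_formula,sf_threshold shape-factor formula and squeezing
#'   threshold (must correspond; see [sf_threshold_for()]).
#' @param window_min migration standardisation window (minutes).
#' @param bin_size_px heatmap bin size.
#' @param seed master seed.
#' @param movie_path optional input movie TIFF (otherwise synthetic).
#' @param classifier_path optional classifier JSON (otherwise trained
#'   from automatic quantile scribbles on the first frame).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(regime = "vessel", n_nuclei = 3, n_frames = 40,
                            frame_interval_s = 30, pixel_size_um = 0.3,
                            z_slices = 5, field_y = 160, field_x = 200,
                            noise_gaussian_sd = 5, noise_poisson = TRUE,
                            prob_threshold = 0.5, min_volume_vox = 30,
                            max_disp_um = 10, max_gap = 1,
                            min_timepoints = 4, use_vessel_mask = TRUE,
                            sf_formula = "aspect_sum", sf_threshold = 0.4,
                            window_min = 15, bin_size_px = 17, seed = 1,
                            movie_path = NULL, classifier_path = NULL) {
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    abort("prob_threshold must be in (0, 1)")
  }
  if (sf_threshold <= 0 || sf_threshold >= 1) {
    abort("sf_threshold must be in (0, 1)")
  }
  if (max_disp_um < 0) abort("max_disp_um must be non-negative")
  if (min_timepoints < 1) abort("min_timepoints must be >= 1")
  if (bin_size_px < 1) abort("bin_size_px must be >= 1")
  if (window_min <= 0) abort("window_min must be positive")
  if (!regime %in% c("open", "vessel")) {
    abort("regime must be 'open' or 'vessel'")
  }
  structure(
    list(
      regime = regime, n_nuclei = n_nuclei, n_frames = n_frames,
      frame_interval_s = frame_interval_s, pixel_size_um = pixel_size_um,
      z_slices = z_slices, field_y = field_y, field_x = field_x,
      noise_gaussian_sd = noise_gaussian_sd, noise_poisson = noise_poisson,
      prob_threshold = prob_threshold, min_volume_vox = min_volume_vox,
      max_disp_um = max_disp_um, max_gap = max_gap,
      min_timepoints = min_timepoints, use_vessel_mask = use_vessel_mask,
      sf_formula = sf_formula, sf_threshold = sf_threshold,
      window_min = window_min, bin_size_px = bin_size_px, seed = seed,
      movie_path = movie_path, classifier_path = classifier_path
    ),
    class = "pipeline_config"
  )
}

#' Run the full quantification pipeline
#'
#' Executes segment -> track -> filter -> measure -> summarise ->
#' heatmap on a synthetic or supplied movie, writing every output plus
#' a config snapshot and run log into `out_dir`. Rerunning with an
#' identical config and seed reproduces byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the tracks and summaries tibbles, the
#'   heatmap, the ground truth (when synthetic) and the output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    abort("config must be a pipeline_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message("[nucleodyn] stage: ", name)
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAIL %s: %s", name, conditionMessage(e)), log_con)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    writeLines(sprintf("OK   %-10s %.2fs", name,
                       as.numeric(Sys.time() - t0, units = "secs")), log_con)
    res
  }

  writeLines(c("nucleodyn pipeline run",
               sprintf("seed: %s", config$seed)), log_con)
  write_config(config, file.path(out_dir, "config.yaml"))

  movie <- stage("input", {
    if (!is.null(config$movie_path)) {
      m <- read_movie_tiff(config$movie_path)
      structure(
        list(data = m$data, ground_truth = NULL, vessel_mask = NULL,
             pixel_size_um = m$pixel_size_um %||% config$pixel_size_um,
             z_step_um = m$z_step_um %||% 1,
             frame_interval_s = m$frame_interval_s %||%
               config$frame_interval_s),
        class = "synth_movie"
      )
    } else {
      render_movie(synth_movie_config(
        regime = synth_regime(config$regime),
        n_nuclei = config$n_nuclei, n_frames = config$n_frames,
        frame_interval_s = config$frame_interval_s,
        pixel_size_um = config$pixel_size_um, z_slices = config$z_slices,
        field_px = c(config$field_y, config$field_x),
        noise_gaussian_sd = config$noise_gaussian_sd,
        noise_poisson = config$noise_poisson, seed = config$seed
      ))
    }
  })

  classifier <- stage("train", {
    if (!is.null(config$classifier_path)) {
      read_classifier(config$classifier_path)
    } else {
      vol <- extract_volume(movie$data, 1)
      scr <- auto_scribbles(vol)
      train_pixel_classifier(vol, scr$fg, scr$bg)
    }
  })

  labels <- stage("segment", {
    segment_movie(movie, classifier,
                  prob_threshold = config$prob_threshold,
                  min_volume_vox = config$min_volume_vox)
  })

  detections <- stage("measure", {
    measure_detections(labels, pixel_size_um = movie$pixel_size_um,
                       sf_formula = config$sf_formula)
  })

  tracks <- stage("track", {
    linked <- link_tracks(detections, max_disp_um = config$max_disp_um,
                          max_gap = config$max_gap)
    filter_tracks(
      linked, min_timepoints = config$min_timepoints,
      region_mask = if (isTRUE(config$use_vessel_mask))
        movie$vessel_mask else NULL,
      pixel_size_um = movie$pixel_size_um
    )
  })
  tracks$time_s <- tracks$frame * movie$frame_interval_s

  summaries <- stage("summarize", {
    if (nrow(tracks)) {
      summarize_tracks(tracks,
                       frame_interval_s = movie$frame_interval_s,
                       window_min = config$window_min,
                       sf_threshold = config$sf_threshold)
    } else {
      tibble(track_id = integer(0))
    }
  })

  heatmap <- stage("heatmap", {
    sf_heatmap(tracks, bin_size_px = config$bin_size_px,
               field_shape = dim(movie$data)[3:4],
               pixel_size_um = movie$pixel_size_um)
  })

  paths <- list(
    tracks = file.path(out_dir, "tracks.csv"),
    summaries = file.path(out_dir, "summaries.csv"),
    heatmap = file.path(out_dir, "heatmap.tif"),
    labels = file.path(out_dir, "labels.tif"),
    config = file.path(out_dir, "config.yaml"),
    log = log_path
  )
  stage("write", {
    write_tracks_csv(tracks, paths$tracks,
                     frame_interval_s = movie$frame_interval_s)
    utils::write.csv(as.data.frame(summaries), paths$summaries,
                     row.names = FALSE, quote = FALSE)
    write_heatmap_tiff(heatmap, paths$heatmap)
    # labels written as per-frame max projections, one page per frame
    pages <- lapply(labels, function(l) {
      apply(l, c(2, 3), max) / 65535
    })
    tiff::writeTIFF(pages, paths$labels, bits.per.sample = 16L)
    if (!is.null(movie$ground_truth)) {
      utils::write.csv(as.data.frame(movie$ground_truth),
                       file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  })

  invisible(list(movie = movie, tracks = tracks, summaries = summaries,
                 heatmap = heatmap, classifier = classifier, paths = paths))
}
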