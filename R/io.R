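#' Write a movie (or volume) as multi-page TIFF
#'
#' Pages are ordered t-major, z-minor. Axis order, dimensions, intensity
#' scale and physical metadata are stored in a YAML sidecar file
#' (`<path>.yaml`) so the movie can be reconstructed exactly with
#' [read_movie_tiff()].
#'
#' @param x `synth_movie`, `(t, z, y, x)` array, or `(z, y, x)` volume.
#' @param path output file.
#' @param pixel_size_um,frame_interval_s,z_step_um physical metadata
#'   (taken from the movie object when available).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(x, path, pixel_size_um = NULL,
                             frame_interval_s = NULL, z_step_um = NULL) {
  if (inherits(x, "synth_movie")) {
    pixel_size_um <- pixel_size_um %||% x$pixel_size_um
    frame_interval_s <- frame_interval_s %||% x$frame_interval_s
    z_step_um <- z_step_um %||% x$z_step_um
    x <- x$data
  }
  if (length(dim(x)) == 3L) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 4L) abort("x must be a (t, z, y, x) array")
  d <- dim(x)
  scale <- max(x, 1)
  pages <- list()
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[length(pages) + 1L]] <- matrix(x[t, z, , ] / scale, d[3], d[4])
    }
  }
  yaml::write_yaml(list(
    axes = "tzyx", n_t = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
    intensity_scale = scale,
    pixel_size_um = pixel_size_um %||% NA,
    frame_interval_s = frame_interval_s %||% NA,
    z_step_um = z_step_um %||% NA
  ), paste0(path, ".yaml"))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF file.
#' @return list with `data` (`(t, z, y, x)` array) and the stored
#'   physical metadata.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) {
    abort("missing axis metadata sidecar (<path>.yaml)")
  }
  meta <- yaml::read_yaml(meta_path)
  d <- c(meta$n_t, meta$n_z, meta$n_y, meta$n_x)
  data <- array(0, dim = d)
  k <- 1L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      data[t, z, , ] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  list(data = data, pixel_size_um = meta$pixel_size_um,
       frame_interval_s = meta$frame_interval_s, z_step_um = meta$z_step_um)
}

#' Write a label image as single-page 16-bit TIFF
#' @param labels integer `(y, x)` matrix.
#' @param path output file.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) abort("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#' @param path TIFF file.
#' @export
read_label_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

tracks_csv_columns <- c(
  "track_id", "frame", "time_s", "nucleus_label", "x_um", "y_um", "z_um",
  "area_um2", "sf", "circularity", "min_feret_um", "max_feret_um", "gap"
)

#' Write the tracks CSV (fixed schema)
#'
#' Columns, in order: `track_id, frame, time_s, nucleus_label, x_um,
#' y_um, z_um, area_um2, sf, circularity, min_feret_um, max_feret_um,
#' gap`. Comma-separated, UTF-8, `.` decimal. Identical inputs produce
#' byte-identical files.
#'
#' @param tracks tracks tibble (extra columns are dropped).
#' @param path output file.
#' @param frame_interval_s used to fill `time_s` when absent.
#' @export
write_tracks_csv <- function(tracks, path, frame_interval_s = 30) {
  if (!"time_s" %in% names(tracks)) {
    tracks$time_s <- tracks$frame * frame_interval_s
  }
  missing <- setdiff(tracks_csv_columns, names(tracks))
  if (length(missing)) {
    abort(paste("tracks missing columns:", paste(missing, collapse = ", ")))
  }
  out <- as.data.frame(tracks[, tracks_csv_columns])
  out$gap <- as.logical(out$gap)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tracks CSV
#' @param path CSV file written by [write_tracks_csv()].
#' @return tibble.
#' @export
read_tracks_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write the heatmap as 32-bit float TIFF
#'
#' Writes `<stem>.tif` with per-bin mean SF and `<stem>_counts.tif`
#' with per-bin observation counts (16-bit). No-data bins are stored as
#' 0 in the mean image; the counts image (0 observations) is the
#' authoritative no-data flag, since the TIFF codec does not preserve
#' NaN.
#'
#' @param hm a [sf_heatmap()] object.
#' @param path output file for the mean heatmap; the counts file is
#'   derived from it.
#' @export
write_heatmap_tiff <- function(hm, path) {
  m <- hm$mean
  m[is.na(m)] <- NaN
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  counts_path <- sub("\\.tiff?$", "", path)
  counts_path <- paste0(counts_path, "_counts.tif")
  tiff::writeTIFF(hm$count / 65535, counts_path, bits.per.sample = 16L,
                  reduce = FALSE)
  invisible(c(path, counts_path))
}

#' Serialise a pixel classifier to JSON text
#'
#' Full double precision is preserved, so a reloaded classifier
#' reproduces probabilities bit-identically.
#'
#' @param classifier a [train_pixel_classifier()] model.
#' @param path output file.
#' @export
write_classifier <- function(classifier, path) {
  if (!inherits(classifier, "pixel_classifier")) {
    abort("classifier must be a pixel_classifier")
  }
  # doubles stored as 17-significant-digit strings: exact round trip
  num17 <- function(x) sprintf("%.17g", x)
  obj <- list(
    type = "nucleodyn_pixel_classifier", version = 1L,
    spec = unclass(classifier$spec),
    bias = num17(classifier$bias),
    weights = as.list(setNames(num17(classifier$weights),
                               names(classifier$weights))),
    lambda = classifier$lambda
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' Load a pixel classifier from JSON text
#' @param path file written by [write_classifier()].
#' @return `pixel_classifier`.
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  if (!identical(obj$type, "nucleodyn_pixel_classifier")) {
    abort("not a nucleodyn classifier file")
  }
  structure(
    list(
      spec = structure(
        list(gauss_sigmas = obj$spec$gauss_sigmas,
             grad_sigma = obj$spec$grad_sigma,
             log_sigmas = obj$spec$log_sigmas),
        class = "feature_spec"
      ),
      bias = as.numeric(obj$bias),
      weights = vapply(obj$weights, as.numeric, numeric(1)),
      lambda = obj$lambda
    ),
    class = "pixel_classifier"
  )
}

#' Write / read a pipeline configuration
#'
#' Configurations are serialised as YAML; a snapshot is written into
#' every pipeline output directory so any result can be traced to the
#' exact parameters and seed that produced it.
#'
#' @param config a [pipeline_config()] list.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
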