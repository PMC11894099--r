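#' Measure per-frame detections from label stacks
#'
#' Turns the per-frame label volumes into a detections table: one row
#' per (frame, label) with the 3D centroid and the 2D shape measures of
#' the label's maximum projection.
#'
#' @param label_stacks list of `(z, y, x)` integer label arrays, one per
#'   frame (frames are taken as 0-based `seq_along - 1`).
#' @param pixel_size_um in-plane pixel size.
#' @param sf_formula passed to [measure_shape()].
#' @return tibble with columns `frame`, `nucleus_label`, `x_px`, `y_px`,
#'   `z_px`, `x_um`, `y_um`, `z_um`, `area_um2`, `sf`, `circularity`,
#'   `min_feret_um`, `max_feret_um`.
#' @export
measure_detections <- function(label_stacks, pixel_size_um = 0.3,
                               sf_formula = "aspect_sum") {
  rows <- purrr::map_dfr(seq_along(label_stacks), function(t) {
    labels <- label_stacks[[t]]
    ids <- sort(unique(labels[labels > 0L]))
    purrr::map_dfr(ids, function(id) {
      idx <- which(labels == id, arr.ind = TRUE) # (z, y, x), 1-based
      mask <- project_mask_2d(labels, id)
      sh <- measure_shape(mask, pixel_size_um, sf_formula = sf_formula)
      tibble(
        frame = t - 1L, nucleus_label = id,
        x_px = mean(idx[, 3] - 1), y_px = mean(idx[, 2] - 1),
        z_px = mean(idx[, 1] - 1),
        x_um = mean(idx[, 3] - 1) * pixel_size_um,
        y_um = mean(idx[, 2] - 1) * pixel_size_um,
        z_um = mean(idx[, 1] - 1) * pixel_size_um,
        area_um2 = sh$area_um2, sf = sh$sf, circularity = sh$circularity,
        min_feret_um = sh$min_feret_um, max_feret_um = sh$max_feret_um
      )
    })
  })
  rows
}

#' Link detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking with gap closing:
#' for each frame, candidate (track, detection) pairs within
#' `max_disp_um` (scaled by the gap length when closing over missing
#' frames) are matched in order of ascending distance; ties are broken
#' by lower track id, then lower detection label, making the result
#' independent of the input order of detections within a frame.
#' Unmatched detections open new tracks.
#'
#' @param detections tibble with at least `frame`, `x_um`, `y_um`
#'   (optionally `z_um`, `nucleus_label`); additional columns are
#'   carried through.
#' @param max_disp_um maximum linking displacement per frame step.
#' @param max_gap maximum number of missing frames to close over.
#' @return the detections with `track_id` and `gap` columns, ordered by
#'   track and frame. `gap` marks a detection linked across missing
#'   frames.
#' @export
link_tracks <- function(detections, max_disp_um = 10, max_gap = 1) {
  if (max_disp_um < 0) abort("max_disp_um must be non-negative")
  if (max_gap < 0) abort("max_gap must be non-negative")
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(detections))) {
    abort("detections must have columns frame, x_um, y_um")
  }
  det <- as_tibble(detections)
  if (!"z_um" %in% names(det)) det$z_um <- 0
  if (!"nucleus_label" %in% names(det)) {
    det <- det |>
      dplyr::group_by(.data$frame) |>
      dplyr::mutate(nucleus_label = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  det$track_id <- NA_integer_
  det$gap <- FALSE

  frames <- sort(unique(det$frame))
  # per-track state: id, frame and position of the last linked detection
  last_frame <- integer(0)
  last_pos <- matrix(numeric(0), ncol = 3)
  next_id <- 1L

  for (f in frames) {
    di <- which(det$frame == f)
    di <- di[order(det$nucleus_label[di])]
    cand_tracks <- which(last_frame >= f - 1L - max_gap & last_frame < f)
    if (length(cand_tracks) && length(di)) {
      pairs <- expand.grid(ti = cand_tracks, dj = seq_along(di))
      gap_len <- f - last_frame[pairs$ti]
      dx <- last_pos[pairs$ti, 1] - det$x_um[di[pairs$dj]]
      dy <- last_pos[pairs$ti, 2] - det$y_um[di[pairs$dj]]
      dz <- last_pos[pairs$ti, 3] - det$z_um[di[pairs$dj]]
      dist <- sqrt(dx^2 + dy^2 + dz^2)
      ok <- dist <= max_disp_um * gap_len
      pairs <- pairs[ok, , drop = FALSE]
      dist <- dist[ok]
      ord <- order(dist, pairs$ti, det$nucleus_label[di[pairs$dj]])
      used_t <- logical(length(last_frame))
      used_d <- logical(length(di))
      for (k in ord) {
        ti <- pairs$ti[k]; dj <- pairs$dj[k]
        if (used_t[ti] || used_d[dj]) next
        used_t[ti] <- TRUE; used_d[dj] <- TRUE
        row <- di[dj]
        det$track_id[row] <- ti
        det$gap[row] <- (f - last_frame[ti]) > 1L
        last_frame[ti] <- f
        last_pos[ti, ] <- c(det$x_um[row], det$y_um[row], det$z_um[row])
      }
    }
    # open new tracks for unmatched detections, in label order
    for (row in di[is.na(det$track_id[di])]) {
      det$track_id[row] <- next_id
      last_frame <- c(last_frame, f)
      last_pos <- rbind(last_pos,
                        c(det$x_um[row], det$y_um[row], det$z_um[row]))
      next_id <- next_id + 1L
    }
  }
  dplyr::arrange(det, .data$track_id, .data$frame)
}

#' Apply the track-level inclusion filters
#'
#' Removes tracks observed at fewer than `min_timepoints` timepoints
#' and, when a region mask is supplied, tracks whose majority of
#' centroids fall outside the region (the operational reading of
#' excluding tracks outside vessels).
#'
#' @param tracks tibble with `track_id`, `frame`, `x_um`, `y_um`.
#' @param min_timepoints minimum detections per track (default 4).
#' @param region_mask optional `(y, x)` mask/label matrix; nonzero =
#'   inside.
#' @param pixel_size_um pixel size used to place centroids in the mask.
#' @return the surviving tracks, unmodified.
#' @export
filter_tracks <- function(tracks, min_timepoints = 4, region_mask = NULL,
                          pixel_size_um = 0.3) {
  if (min_timepoints < 1) abort("min_timepoints must be >= 1")
  keep <- tracks |>
    dplyr::count(.data$track_id) |>
    dplyr::filter(.data$n >= min_timepoints) |>
    dplyr::pull(.data$track_id)
  out <- dplyr::filter(tracks, .data$track_id %in% keep)
  if (!is.null(region_mask)) {
    ny <- nrow(region_mask); nx <- ncol(region_mask)
    inside_ids <- out |>
      dplyr::mutate(
        row = pmin(pmax(round(.data$y_um / pixel_size_um) + 1L, 1L), ny),
        col = pmin(pmax(round(.data$x_um / pixel_size_um) + 1L, 1L), nx),
        inside = region_mask[cbind(.data$row, .data$col)] > 0
      ) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(frac = mean(.data$inside), .groups = "drop") |>
      dplyr::filter(.data$frac > 0.5) |>
      dplyr::pull(.data$track_id)
    out <- dplyr::filter(out, .data$track_id %in% inside_ids)
  }
  out
}

#' Track purity against ground truth
#'
#' Assigns every detection to the nearest ground-truth nucleus in its
#' frame and reports, per track, the fraction of detections belonging
#' to the track's majority identity (1 = no identity swaps).
#'
#' @param tracks linked tracks tibble (`track_id`, `frame`, `x_px`,
#'   `y_px`).
#' @param ground_truth tibble from [render_movie()].
#' @return tibble with `track_id`, `n`, `purity`, `majority_id`.
#' @export
track_purity <- function(tracks, ground_truth) {
  gt <- dplyr::select(ground_truth, "frame", "nucleus_id", "x_px", "y_px")
  tracks |>
    dplyr::mutate(true_id = purrr::map2_int(
      .data$frame, seq_len(dplyr::n()),
      function(f, i) {
        g <- gt[gt$frame == f, ]
        if (!nrow(g)) return(NA_integer_)
        d <- (g$x_px - tracks$x_px[i])^2 + (g$y_px - tracks$y_px[i])^2
        g$nucleus_id[which.min(d)]
      }
    )) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      purity = max(table(.data$true_id)) / dplyr::n(),
      majority_id = as.integer(names(which.max(table(.data$true_id)))),
      .groups = "drop"
    )
}
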