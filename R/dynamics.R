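#' Detect squeezing events in a shape-factor time series
#'
#' A nucleus is squeezing in a frame when its shape factor is at or above
#' the threshold (0.4 by default, on the \eqn{(a-b)/(a+b)} scale). Events
#' are maximal runs of consecutive squeezing frames; missing frames (gap
#' closing during tracking) break runs rather than interpolating a
#' deformation measurement.
#'
#' @param sf numeric vector of shape-factor values, one per observed frame.
#' @param threshold squeezing threshold; a frame with SF exactly equal to
#'   the threshold counts as squeezing.
#' @param frame_interval_s time between consecutive frames in seconds.
#' @param frames optional integer frame numbers of the observations; runs
#'   are broken where consecutive observations are more than one frame
#'   apart. Defaults to consecutive frames.
#' @return list with `events`, a tibble (`start_frame`, `end_frame`,
#'   `n_frames`, `duration_min`), and `proportion`, the fraction of
#'   observed frames spent squeezing.
#' @examples
#' detect_squeezing(c(0.2, 0.5, 0.6, 0.3, 0.45), threshold = 0.4,
#'                  frame_interval_s = 30)
#' @export
detect_squeezing <- function(sf, threshold = 0.4, frame_interval_s = 30,
                             frames = NULL) {
  if (length(sf) == 0L) abort("sf series is empty")
  if (anyNA(sf)) abort("sf series contains NA values")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (frame_interval_s <= 0) abort("frame_interval_s must be positive")
  if (is.null(frames)) frames <- seq_along(sf) - 1L
  if (length(frames) != length(sf)) abort("frames must match sf in length")
  if (is.unsorted(frames, strictly = TRUE)) {
    abort("frames must be strictly increasing")
  }

  squeezing <- sf >= threshold
  if (!any(squeezing)) {
    return(list(
      events = tibble(start_frame = integer(0), end_frame = integer(0),
                      n_frames = integer(0), duration_min = numeric(0)),
      proportion = 0
    ))
  }
  # run id increments when the squeeze state changes or a frame is missing
  state_change <- c(TRUE, diff(squeezing) != 0 | diff(frames) != 1L)
  run_id <- cumsum(state_change)

  events <- tibble(
    run = run_id, frame = as.integer(frames), squeezing = squeezing
  ) |>
    dplyr::filter(.data$squeezing) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      start_frame = min(.data$frame),
      end_frame = max(.data$frame),
      n_frames = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$start_frame) |>
    dplyr::mutate(duration_min = .data$n_frames * frame_interval_s / 60) |>
    dplyr::select(-"run")

  list(events = events, proportion = mean(squeezing))
}

#' Summarise one nuclear track
#'
#' Produces the per-track statistics reported for nuclear dynamics and
#' migration: mean and maximum SF, squeezing proportion, event count and
#' mean event duration, mean instantaneous speed, and track length,
#' Euclidean distance and persistence standardised to a fixed window
#' (15 min by default).
#'
#' Path length and Euclidean distance are measured over the first
#' contiguous stretch of the track, truncated at the standard window.
#' Tracks shorter than the window are linearly rescaled by
#' `window / span` and flagged in the `rescaled` column. Persistence is
#' the Euclidean distance divided by the path length; it is undefined
#' (NA, not zero) for a stationary track.
#'
#' @param track tibble with one row per observation, columns `frame`,
#'   `x_um`, `y_um`, `sf` (as produced by the tracking stage).
#' @param frame_interval_s frame interval in seconds.
#' @param window_min standardisation window in minutes.
#' @param sf_threshold squeezing threshold passed to [detect_squeezing()].
#' @return one-row tibble (see [summarize_tracks()] for columns).
#' @export
summarize_track <- function(track, frame_interval_s = 30, window_min = 15,
                            sf_threshold = 0.4) {
  need <- c("frame", "x_um", "y_um", "sf")
  if (!all(need %in% names(track))) {
    abort(paste("track must have columns:", paste(need, collapse = ", ")))
  }
  track <- dplyr::arrange(track, .data$frame)
  sq <- detect_squeezing(track$sf, threshold = sf_threshold,
                         frame_interval_s = frame_interval_s,
                         frames = track$frame)

  # mean instantaneous speed over consecutive observations (um/min);
  # gap-spanning steps are divided by the elapsed, not nominal, time
  n <- nrow(track)
  if (n >= 2L) {
    step <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
    dt_min <- diff(track$frame) * frame_interval_s / 60
    mean_speed <- mean(step / dt_min)
  } else {
    mean_speed <- NA_real_
  }

  # first contiguous stretch, truncated at the standard window
  gaps <- which(diff(track$frame) != 1L)
  last <- if (length(gaps)) gaps[1] else n
  span_limit <- floor(window_min * 60 / frame_interval_s)
  last <- min(last, span_limit + 1L)
  seg <- track[seq_len(last), , drop = FALSE]
  span_min <- (nrow(seg) - 1L) * frame_interval_s / 60

  if (nrow(seg) >= 2L && span_min > 0) {
    path <- sum(sqrt(diff(seg$x_um)^2 + diff(seg$y_um)^2))
    eucl <- sqrt((seg$x_um[nrow(seg)] - seg$x_um[1])^2 +
                 (seg$y_um[nrow(seg)] - seg$y_um[1])^2)
    rescaled <- span_min < window_min
    scale <- if (rescaled) window_min / span_min else 1
    path <- path * scale
    eucl <- eucl * scale
  } else {
    path <- 0
    eucl <- 0
    rescaled <- TRUE
  }
  persistence <- if (path > 0) eucl / path else NA_real_

  tibble(
    n_timepoints = n,
    mean_sf = mean(track$sf),
    max_sf = max(track$sf),
    squeeze_prop = sq$proportion,
    n_events = nrow(sq$events),
    mean_event_min = if (nrow(sq$events)) mean(sq$events$duration_min)
                     else NA_real_,
    mean_speed_um_min = mean_speed,
    path_length_15 = path,
    euclidean_15 = eucl,
    persistence = persistence,
    rescaled = rescaled
  )
}

#' Summarise all tracks in a tracks table
#'
#' @param tracks long tibble with columns `track_id`, `frame`, `x_um`,
#'   `y_um`, `sf` (additional columns are ignored).
#' @inheritParams summarize_track
#' @return tibble with one row per track: `track_id`, `n_timepoints`,
#'   `mean_sf`, `max_sf`, `squeeze_prop`, `n_events`, `mean_event_min`,
#'   `mean_speed_um_min`, `path_length_15`, `euclidean_15`,
#'   `persistence`, `rescaled`.
#' @export
summarize_tracks <- function(tracks, frame_interval_s = 30, window_min = 15,
                             sf_threshold = 0.4) {
  if (!"track_id" %in% names(tracks)) abort("tracks must have track_id")
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(~ summarize_track(
      .x, frame_interval_s = frame_interval_s,
      window_min = window_min, sf_threshold = sf_threshold
    )) |>
    dplyr::ungroup()
}

#' Correlation matrix of track attributes
#'
#' Pairwise correlations between per-track summary attributes (e.g. mean
#' SF against migration persistence), with two-sided p-values from the
#' t approximation on n - 2 degrees of freedom. Spearman correlations
#' rank-transform with average ranks for ties, then take the
#' product-moment correlation of the ranks. Incomplete records are
#' handled pairwise.
#'
#' @param data tibble of per-track summaries.
#' @param attributes character vector of column names; defaults to all
#'   numeric columns except `track_id`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return object of class `nucleodyn_cor` with matrices `r`, `p`, `n`;
#'   see [generics::tidy()] and [ggplot2::autoplot()] methods.
#' @export
correlation_matrix <- function(data, attributes = NULL,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(attributes)) {
    attributes <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))], "track_id"
    )
  }
  missing_cols <- setdiff(attributes, names(data))
  if (length(missing_cols)) {
    abort(paste("attributes not in data:", paste(missing_cols, collapse = ", ")))
  }
  k <- length(attributes)
  r <- matrix(NA_real_, k, k, dimnames = list(attributes, attributes))
  p <- r
  nmat <- matrix(NA_integer_, k, k, dimnames = dimnames(r))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k)) {
    nmat[i, i] <- sum(!is.na(data[[attributes[i]]]))
    if (i == k) next
    for (j in seq((i + 1), k)) {
      x <- data[[attributes[i]]]
      y <- data[[attributes[j]]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 3L) {
        warn(sprintf("fewer than 3 complete pairs for %s vs %s",
                     attributes[i], attributes[j]))
        next
      }
      xv <- x[ok]; yv <- y[ok]
      if (sd(xv) == 0 || sd(yv) == 0) {
        warn(sprintf("zero variance in %s vs %s; correlation undefined",
                     attributes[i], attributes[j]))
        next
      }
      if (method == "spearman") {
        xv <- rank(xv)
        yv <- rank(yv)
      }
      rij <- stats::cor(xv, yv)
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        p[i, j] <- p[j, i] <- 2 * pt(-abs(tstat), df = n - 2)
      }
    }
  }
  structure(
    list(r = r, p = p, n = nmat, method = method, attributes = attributes),
    class = "nucleodyn_cor"
  )
}

#' @export
print.nucleodyn_cor <- function(x, digits = 3, ...) {
  cat("Correlation matrix (", x$method, ")\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Spatial heatmap of mean shape factor
#'
#' Bins track observations on a square grid (17 px, about 5 um, by
#' default) and reports the mean SF of all observations whose centroid
#' falls in each bin. Bins follow half-open intervals
#' \eqn{[k s, (k+1) s)}; a centroid exactly on a boundary belongs to the
#' higher-index bin. Bins with no observations are NA (no data).
#'
#' @param tracks tibble with `x_um`, `y_um`, `sf` columns.
#' @param bin_size_px bin edge length in pixels.
#' @param field_shape integer `(y, x)` extent of the field in pixels.
#' @param pixel_size_um pixel size used to convert centroids back to px.
#' @return object of class `nucleodyn_heatmap`: matrices `mean` and
#'   `count` (rows = y bins, cols = x bins), bin sizes in px and um.
#' @export
sf_heatmap <- function(tracks, bin_size_px = 17, field_shape,
                       pixel_size_um = 0.3) {
  if (bin_size_px < 1) abort("bin_size_px must be >= 1")
  if (length(field_shape) != 2L) abort("field_shape must be (y, x)")
  xb_max <- ceiling(field_shape[2] / bin_size_px) - 1L
  yb_max <- ceiling(field_shape[1] / bin_size_px) - 1L

  xp <- tracks$x_um / pixel_size_um
  yp <- tracks$y_um / pixel_size_um
  out <- xp < 0 | yp < 0 | xp >= field_shape[2] | yp >= field_shape[1]
  if (any(out)) {
    warn(sprintf("%d centroids outside field clipped to edge bins", sum(out)))
  }
  xb <- pmin(pmax(floor(xp / bin_size_px), 0L), xb_max)
  yb <- pmin(pmax(floor(yp / bin_size_px), 0L), yb_max)

  mean_m <- matrix(NA_real_, yb_max + 1L, xb_max + 1L)
  count_m <- matrix(0L, yb_max + 1L, xb_max + 1L)
  df <- tibble(xb = xb, yb = yb, sf = tracks$sf) |>
    dplyr::group_by(.data$xb, .data$yb) |>
    dplyr::summarise(m = mean(.data$sf), n = dplyr::n(), .groups = "drop")
  idx <- cbind(df$yb + 1L, df$xb + 1L)
  mean_m[idx] <- df$m
  count_m[idx] <- df$n

  structure(
    list(
      mean = mean_m, count = count_m, bin_size_px = bin_size_px,
      bin_size_um = bin_size_px * pixel_size_um,
      pixel_size_um = pixel_size_um
    ),
    class = "nucleodyn_heatmap"
  )
}

#' @export
print.nucleodyn_heatmap <- function(x, ...) {
  cat(sprintf(
    "SF heatmap: %d x %d bins of %d px (%.2f um); %d populated\n",
    nrow(x$mean), ncol(x$mean), x$bin_size_px, x$bin_size_um,
    sum(x$count > 0)
  ))
  invisible(x)
}
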