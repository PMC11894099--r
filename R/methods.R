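#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn correlation_matrix long tibble of pairwise correlations
#'   (`attribute1`, `attribute2`, `r`, `p`, `n`), upper triangle only.
#' @param x a `nucleodyn_cor` object.
#' @param ... unused.
#' @export
tidy.nucleodyn_cor <- function(x, ...) {
  k <- length(x$attributes)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    attribute1 = x$attributes[pairs[, 1]],
    attribute2 = x$attributes[pairs[, 2]],
    r = x$r[pairs],
    p = x$p[pairs],
    n = x$n[pairs],
    method = x$method
  )
}

#' @describeIn correlation_matrix one-row overview (method, attribute
#'   and pair counts, smallest p-value).
#' @export
glance.nucleodyn_cor <- function(x, ...) {
  td <- tidy(x)
  tibble(
    method = x$method,
    n_attributes = length(x$attributes),
    n_pairs = nrow(td),
    min_p = suppressWarnings(min(td$p, na.rm = TRUE))
  )
}

#' @describeIn correlation_matrix correlation-matrix tile plot.
#' @param object a `nucleodyn_cor` object.
#' @export
autoplot.nucleodyn_cor <- function(object, ...) {
  df <- expand.grid(attribute1 = object$attributes,
                    attribute2 = object$attributes,
                    stringsAsFactors = FALSE)
  df$r <- as.vector(object$r)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$attribute1, y = .data$attribute2, fill = .data$r
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn sf_heatmap long tibble of bins (`bin_x`, `bin_y`,
#'   `x_um`, `y_um`, `mean_sf`, `n`).
#' @param x a `nucleodyn_heatmap` object.
#' @param ... unused.
#' @export
tidy.nucleodyn_heatmap <- function(x, ...) {
  nb <- dim(x$mean)
  df <- expand.grid(bin_y = seq_len(nb[1]) - 1L, bin_x = seq_len(nb[2]) - 1L)
  tibble(
    bin_x = df$bin_x, bin_y = df$bin_y,
    x_um = (df$bin_x + 0.5) * x$bin_size_um,
    y_um = (df$bin_y + 0.5) * x$bin_size_um,
    mean_sf = as.vector(x$mean),
    n = as.vector(x$count)
  )
}

#' @describeIn sf_heatmap one-row overview (bin counts, coverage,
#'   count-weighted mean SF).
#' @export
glance.nucleodyn_heatmap <- function(x, ...) {
  tibble(
    n_bins = length(x$mean),
    n_populated = sum(x$count > 0),
    bin_size_um = x$bin_size_um,
    weighted_mean_sf = sum(x$mean * x$count, na.rm = TRUE) /
      max(sum(x$count), 1)
  )
}

#' @describeIn sf_heatmap heatmap tile plot (grey = no data).
#' @param object a `nucleodyn_heatmap` object.
#' @export
autoplot.nucleodyn_heatmap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x_um, y = .data$y_um, fill = .data$mean_sf
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey92", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "mean SF") +
    ggplot2::theme_minimal()
}

#' @describeIn render_movie ground-truth SF traces over time, one line
#'   per nucleus, with the squeezing threshold marked.
#' @param object a `synth_movie` object.
#' @param ... unused.
#' @export
autoplot.synth_movie <- function(object, ...) {
  gt <- object$ground_truth
  gt$time_min <- gt$frame * object$frame_interval_s / 60
  ggplot2::ggplot(gt, ggplot2::aes(
    x = .data$time_min, y = .data$sf_true,
    colour = factor(.data$nucleus_id)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.4, linetype = "dashed") +
    ggplot2::labs(x = "time (min)", y = "shape factor",
                  colour = "nucleus") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Shape-factor traces of measured tracks
#'
#' @param tracks tracks tibble with `track_id`, `frame`, `sf`.
#' @param frame_interval_s frame interval for the time axis.
#' @param sf_threshold squeezing threshold drawn as a dashed line.
#' @return a ggplot object.
#' @export
plot_sf_tracks <- function(tracks, frame_interval_s = 30,
                           sf_threshold = 0.4) {
  tracks$time_min <- tracks$frame * frame_interval_s / 60
  ggplot2::ggplot(tracks, ggplot2::aes(
    x = .data$time_min, y = .data$sf, colour = factor(.data$track_id)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = sf_threshold, linetype = "dashed") +
    ggplot2::labs(x = "time (min)", y = "shape factor", colour = "track") +
    ggplot2::theme_minimal()
}
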