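#' Background-corrected rim intensity of one nucleus
#'
#' Reproduces the manual lamina-rim protocol deterministically: the raw
#' value is the mean of per-line mean intensities over the chosen
#' z-slices, the background is the mean of the background-line means at
#' the same slices, and the corrected value is their difference.
#' Negative corrected values are retained and flagged, not clamped.
#'
#' @param stack `(z, y, x)` image array.
#' @param rim_lines tibble of line endpoints `x0, y0, x1, y1` in 0-based
#'   pixel coordinates (>= 1 line).
#' @param background_lines tibble of background line endpoints (>= 1).
#' @param z_slices 1-based z indices to average over; defaults to the 3
#'   central slices.
#' @return one-row tibble: `raw`, `background`, `corrected`,
#'   `negative_flag`.
#' @export
rim_intensity <- function(stack, rim_lines, background_lines,
                          z_slices = NULL) {
  if (length(dim(stack)) == 2L) stack <- array(stack, dim = c(1L, dim(stack)))
  nz <- dim(stack)[1]
  if (is.null(z_slices)) {
    mid <- ceiling(nz / 2)
    z_slices <- intersect((mid - 1):(mid + 1), seq_len(nz))
  }
  if (!nrow(rim_lines) || !nrow(background_lines)) {
    abort("at least one rim line and one background line are required")
  }
  raw <- mean(vapply(seq_len(nrow(rim_lines)), function(i) {
    line_mean(stack, rim_lines[i, ], z_slices)
  }, numeric(1)))
  bg <- mean(vapply(seq_len(nrow(background_lines)), function(i) {
    line_mean(stack, background_lines[i, ], z_slices)
  }, numeric(1)))
  corrected <- raw - bg
  tibble(raw = raw, background = bg, corrected = corrected,
         negative_flag = corrected < 0)
}

# mean intensity along a line, averaged over the given z slices;
# samples at ~1 px steps with nearest-pixel lookup
line_mean <- function(stack, line, z_slices) {
  ny <- dim(stack)[2]; nx <- dim(stack)[3]
  len <- sqrt((line$x1 - line$x0)^2 + (line$y1 - line$y0)^2)
  # epsilon guards against float noise in the length flipping the
  # sample count between nuclei with identical geometry
  n <- max(2L, as.integer(ceiling(len - 1e-9)) + 1L)
  xs <- seq(line$x0, line$x1, length.out = n)
  ys <- seq(line$y0, line$y1, length.out = n)
  # half-up rounding with a small epsilon so samples landing within
  # floating-point error of a pixel boundary resolve identically for
  # every nucleus regardless of its absolute position
  rows <- as.integer(floor(ys + 0.5 + 1e-9)) + 1L
  cols <- as.integer(floor(xs + 0.5 + 1e-9)) + 1L
  if (any(rows < 1 | rows > ny | cols < 1 | cols > nx)) {
    abort("sampling line extends outside the image")
  }
  mean(vapply(z_slices, function(z) {
    mean(stack[z, , ][cbind(rows, cols)])
  }, numeric(1)))
}

#' Measure all nuclei of a lamina fixture
#'
#' Runs [rim_intensity()] for every nucleus of a
#' [make_lamina_fixture()] output using automatically placed rim and
#' background lines.
#'
#' @param fixture output of [make_lamina_fixture()].
#' @param n_lines rim lines per nucleus.
#' @return tibble of intensity records: `nucleus_id`, `cell_class`,
#'   `age_group`, `raw`, `background`, `corrected`, `negative_flag`.
#' @export
measure_lamina_fixture <- function(fixture, n_lines = 3) {
  ln <- lamina_rim_lines(fixture, n_lines = n_lines)
  purrr::map_dfr(seq_len(nrow(fixture$nuclei)), function(i) {
    nid <- fixture$nuclei$nucleus_id[i]
    rec <- rim_intensity(
      fixture$stack,
      ln$rim_lines[ln$rim_lines$nucleus_id == nid, ],
      ln$background_lines
    )
    dplyr::bind_cols(
      fixture$nuclei[i, c("nucleus_id", "cell_class", "age_group")], rec
    )
  })
}

#' Normalise intensity records to a reference cell class
#'
#' Divides each record's background-corrected intensity by the mean
#' corrected intensity of the reference class within the same age
#' group. Age groups lacking reference records are skipped with a
#' warning (normalised value NA).
#'
#' @param records tibble with `cell_class`, `age_group`, `corrected`.
#' @param reference_class class used as the denominator.
#' @return records with a `normalized` column.
#' @export
normalize_to_reference <- function(records, reference_class = "epithelial") {
  need <- c("cell_class", "age_group", "corrected")
  if (!all(need %in% names(records))) {
    abort(paste("records must have columns:", paste(need, collapse = ", ")))
  }
  out <- records |>
    dplyr::group_by(.data$age_group) |>
    dplyr::mutate(
      .ref = mean(.data$corrected[.data$cell_class == reference_class])
    ) |>
    dplyr::ungroup()
  missing <- unique(out$age_group[is.nan(out$.ref) | is.na(out$.ref)])
  if (length(missing)) {
    warn(paste("no reference-class records for age group(s):",
               paste(missing, collapse = ", ")))
  }
  out |>
    dplyr::mutate(normalized = .data$corrected / .data$.ref) |>
    dplyr::select(-".ref")
}

#' Lamin stoichiometry ratio table
#'
#' Computes per-age medians of corrected channel intensities, normalises
#' each channel's median to its value at the reference age, and reports
#' the ratio of the two normalised medians (A-type over B-type by
#' default). The ratio at the reference age is 1 by construction.
#'
#' @param records tibble with `age_group`, `channel`, `corrected`.
#' @param channel_num,channel_den channel labels forming the ratio
#'   numerator and denominator.
#' @param reference_age age group used for normalisation.
#' @return tibble with one row per age group: per-channel `median_*`,
#'   `norm_*` and `ratio`.
#' @export
lamin_stoichiometry <- function(records, channel_num = "dLamC",
                                channel_den = "dLamB",
                                reference_age = "18h") {
  need <- c("age_group", "channel", "corrected")
  if (!all(need %in% names(records))) {
    abort(paste("records must have columns:", paste(need, collapse = ", ")))
  }
  chans <- c(channel_num, channel_den)
  if (!all(chans %in% records$channel)) {
    abort("both channels must be present in the records")
  }
  med <- records |>
    dplyr::filter(.data$channel %in% chans) |>
    dplyr::group_by(.data$age_group, .data$channel) |>
    dplyr::summarise(median = median(.data$corrected), .groups = "drop")
  ref <- med |>
    dplyr::filter(.data$age_group == reference_age)
  if (nrow(ref) < 2L) {
    abort("both channels must be present at the reference age")
  }
  ref_vals <- setNames(ref$median, ref$channel)
  if (any(ref_vals == 0)) {
    warn("zero reference-age median; normalised values undefined")
  }
  med |>
    dplyr::mutate(norm = .data$median / unname(ref_vals[.data$channel])) |>
    tidyr::pivot_wider(names_from = "channel",
                       values_from = c("median", "norm")) |>
    dplyr::mutate(
      ratio = .data[[paste0("norm_", channel_num)]] /
        .data[[paste0("norm_", channel_den)]]
    )
}

#' Mean 3D nuclear intensity with negative-control correction
#'
#' Per labelled nucleus, the mean voxel intensity inside the 3D label
#' minus the negative-control mean of the same batch. Negative
#' corrected values are retained and flagged.
#'
#' @param labels integer `(z, y, x)` label array.
#' @param volume intensity array of the same shape.
#' @param negative_control_mean background level measured on the
#'   negative control.
#' @return tibble: `nucleus_id`, `mean_intensity`, `control`,
#'   `corrected`, `negative_flag`.
#' @export
nuclear_mean_3d <- function(labels, volume, negative_control_mean) {
  if (!identical(dim(labels), dim(volume))) {
    abort("labels and volume must have identical dimensions")
  }
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) {
    return(tibble(nucleus_id = integer(0), mean_intensity = numeric(0),
                  control = numeric(0), corrected = numeric(0),
                  negative_flag = logical(0)))
  }
  means <- vapply(ids, function(id) mean(volume[labels == id]), numeric(1))
  tibble(
    nucleus_id = as.integer(ids), mean_intensity = means,
    control = negative_control_mean,
    corrected = means - negative_control_mean,
    negative_flag = means - negative_control_mean < 0
  )
}

#' Phagosome count and total area within a cell
#'
#' @param cell_mask logical `(y, x)` cell mask.
#' @param phagosome_labels integer `(y, x)` phagosome label image.
#' @param pixel_size_um pixel size.
#' @return one-row tibble: `count`, `total_area_um2`. Only label pixels
#'   inside the cell mask are counted.
#' @export
quantify_phagosomes <- function(cell_mask, phagosome_labels,
                                pixel_size_um = 0.3) {
  if (!identical(dim(cell_mask), dim(phagosome_labels))) {
    abort("cell_mask and phagosome_labels must have identical dimensions")
  }
  inside <- phagosome_labels
  inside[!(cell_mask != 0)] <- 0L
  ids <- unique(inside[inside > 0L])
  tibble(
    count = length(ids),
    total_area_um2 = sum(inside > 0L) * pixel_size_um^2
  )
}

#' Nuclear instability event rate
#'
#' Events (atypical nuclear shapes, ruptures or micronuclei) observed
#' over an imaging period, normalised to the total number of hemocytes
#' and expressed as a percentage.
#'
#' @param event_count number of instability events.
#' @param hemocyte_total total hemocytes observed (> 0).
#' @return percentage (numeric scalar).
#' @export
instability_rate <- function(event_count, hemocyte_total) {
  if (any(hemocyte_total <= 0)) abort("hemocyte_total must be positive")
  if (any(event_count < 0)) abort("event_count must be non-negative")
  100 * event_count / hemocyte_total
}
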