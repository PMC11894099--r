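#' Vessel diameter from an intensity profile
#'
#' Samples the wall-channel intensity along a measurement line crossing
#' the vessel, finds the two outermost local maxima exceeding half the
#' profile's dynamic range, refines each peak position with a 3-point
#' parabolic fit, and returns the peak-to-peak distance. The estimate
#' can be averaged over parallel lines, mirroring the practice of
#' averaging several diameter measurements per vessel. It is invariant
#' to rescaling the image intensities by any positive factor.
#'
#' @param img `(y, x)` wall-channel image.
#' @param line numeric `c(x0, y0, x1, y1)` in 0-based pixel coordinates;
#'   the line must cross both walls.
#' @param n_parallel number of parallel lines averaged (spaced
#'   `spacing_px` apart, centred on `line`).
#' @param spacing_px perpendicular spacing between parallel lines.
#' @param pixel_size_um pixel size.
#' @return diameter in micrometres.
#' @export
diameter_from_profile <- function(img, line, n_parallel = 1,
                                  spacing_px = 1, pixel_size_um = 0.3) {
  if (length(line) != 4) abort("line must be c(x0, y0, x1, y1)")
  if (n_parallel < 1) abort("n_parallel must be >= 1")
  dx <- line[3] - line[1]; dy <- line[4] - line[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) abort("line has zero length")
  # perpendicular unit vector for the parallel offsets
  px <- -dy / len; py <- dx / len
  offsets <- (seq_len(n_parallel) - (n_parallel + 1) / 2) * spacing_px
  ds <- vapply(offsets, function(o) {
    profile_diameter(
      img,
      c(line[1] + o * px, line[2] + o * py,
        line[3] + o * px, line[4] + o * py),
      pixel_size_um
    )
  }, numeric(1))
  mean(ds)
}

profile_diameter <- function(img, line, pixel_size_um) {
  n <- max(3L, ceiling(sqrt((line[3] - line[1])^2 +
                            (line[4] - line[2])^2)) + 1L)
  xs <- seq(line[1], line[3], length.out = n)
  ys <- seq(line[2], line[4], length.out = n)
  step <- sqrt((xs[2] - xs[1])^2 + (ys[2] - ys[1])^2)
  prof <- bilinear_sample(img, xs, ys)
  thr <- min(prof) + 0.5 * (max(prof) - min(prof))
  # interior local maxima above half the dynamic range
  mid <- 2:(n - 1)
  peaks <- mid[prof[mid] >= prof[mid - 1] & prof[mid] >= prof[mid + 1] &
                 prof[mid] >= thr]
  # collapse plateaus: keep the first index of each run of adjacent peaks
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  if (length(peaks) < 2) {
    abort("fewer than two wall peaks found; diameter unmeasurable",
          class = "nucleodyn_unmeasurable")
  }
  p1 <- head(peaks, 1); p2 <- tail(peaks, 1)
  refine <- function(i) {
    y0 <- prof[i - 1]; y1 <- prof[i]; y2 <- prof[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom == 0) return(i)
    i + 0.5 * (y0 - y2) / denom
  }
  (refine(p2) - refine(p1)) * step * pixel_size_um
}

bilinear_sample <- function(img, xs, ys) {
  ny <- nrow(img); nx <- ncol(img)
  # 0-based coordinates; clamp to the valid interpolation domain
  xs <- pmin(pmax(xs, 0), nx - 1)
  ys <- pmin(pmax(ys, 0), ny - 1)
  x0 <- pmin(floor(xs), nx - 2); y0 <- pmin(floor(ys), ny - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

#' Derived transit metrics
#'
#' Combines the vessel diameters before, during and after nuclear
#' occupation with the nuclear diameter: `relative_change =
#' d_during / d_pre` and `residual_um = d_during - d_nucleus` (the
#' residual space left around the nucleus during transit).
#'
#' @param d_pre,d_during,d_post,d_nucleus diameters in micrometres
#'   (vectors of equal length, all positive).
#' @param transit_id optional identifiers.
#' @return tibble with the inputs plus `relative_change` and
#'   `residual_um`.
#' @export
transit_metrics <- function(d_pre, d_during, d_post, d_nucleus,
                            transit_id = NULL) {
  if (any(c(d_pre, d_during, d_post, d_nucleus) <= 0)) {
    abort("all diameters must be positive")
  }
  n <- length(d_pre)
  tibble(
    transit_id = transit_id %||% seq_len(n),
    d_pre_um = d_pre, d_during_um = d_during, d_post_um = d_post,
    d_nucleus_um = d_nucleus,
    relative_change = d_during / d_pre,
    residual_um = d_during - d_nucleus
  )
}

#' Measure one transit movie end to end
#'
#' Detects the transit interval from the nuclear channel (frames where
#' the intensity between the walls at the measurement line exceeds the
#' background mean + 3 sd), measures the vessel diameter per phase from
#' the wall channel, and the nuclear diameter as the min-Feret of the
#' thresholded nucleus in the central transit frame.
#'
#' @param tm a [make_vessel_transit_movie()] object.
#' @param n_parallel parallel diameter lines averaged per frame.
#' @return one-row tibble from [transit_metrics()] plus the detected
#'   phase frames as attributes `frames_during`.
#' @export
measure_transit <- function(tm, n_parallel = 4) {
  if (!inherits(tm, "transit_movie")) abort("tm must be a transit_movie")
  nt <- dim(tm$walls)[1]; ny <- dim(tm$walls)[2]; nx <- dim(tm$walls)[3]
  xl <- tm$truth$x_line_px
  yc <- tm$truth$y_center_px

  # background statistics of the nuclear channel from a corner patch
  patch <- tm$nuclei[, 1:8, 1:8]
  thr <- mean(patch) + 3 * max(sd(patch), 1e-6)

  # nuclear signal between the walls at the measurement line
  halfw <- tm$truth$d_pre_um / tm$pixel_size_um / 2
  rows <- which(abs((0:(ny - 1)) - yc) <= halfw)
  sig <- vapply(seq_len(nt), function(t) {
    mean(tm$nuclei[t, rows, round(xl) + 1])
  }, numeric(1))
  during <- which(sig > thr)
  if (!length(during)) {
    abort("no transit detected in the nuclear channel",
          class = "nucleodyn_unmeasurable")
  }
  pre <- seq_len(min(during) - 1)
  post <- if (max(during) < nt) (max(during) + 1):nt else integer(0)
  if (!length(pre) || !length(post)) {
    abort("transit must be preceded and followed by free frames",
          class = "nucleodyn_unmeasurable")
  }

  vline <- c(xl, 0, xl, ny - 1)
  mean_d <- function(frames) {
    mean(vapply(frames, function(t) {
      diameter_from_profile(tm$walls[t, , ], vline, n_parallel = n_parallel,
                            spacing_px = 2,
                            pixel_size_um = tm$pixel_size_um)
    }, numeric(1)))
  }
  d_pre <- mean_d(pre)
  d_during <- mean_d(during)
  d_post <- mean_d(post)

  mid <- during[ceiling(length(during) / 2)]
  nuc_mask <- tm$nuclei[mid, , ] > thr
  d_nuc <- min_diameter(nuc_mask, tm$pixel_size_um)

  out <- transit_metrics(d_pre, d_during, d_post, d_nuc)
  attr(out, "frames_during") <- during - 1L
  out
}

#' Correlations of transit measurements
#'
#' The two relationships examined for vessel dilation during nuclear
#' transit: resting diameter against relative dilation (negative when
#' smaller vessels dilate proportionally more) and vessel against
#' nuclear diameter during transit. Pearson r with two-sided t-based p,
#' plus the simple linear regression slope, intercept and R-squared.
#'
#' @param measurements tibble from [transit_metrics()] (>= 3 rows).
#' @return tibble with one row per relationship: `relation`, `r`, `p`,
#'   `slope`, `intercept`, `r_squared`, `n`.
#' @export
transit_correlations <- function(measurements) {
  if (nrow(measurements) < 3) abort("need at least 3 measurements")
  rel <- function(x, y, label) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (sd(x) == 0 || sd(y) == 0) {
      warn(sprintf("zero variance in %s; correlation undefined", label))
      return(tibble(relation = label, r = NA_real_, p = NA_real_,
                    slope = NA_real_, intercept = NA_real_,
                    r_squared = NA_real_, n = n))
    }
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tt), df = n - 2)
    }
    fit <- stats::lm(y ~ x)
    # suppress the "essentially perfect fit" note on exact relationships
    r2 <- suppressWarnings(summary(fit)$r.squared)
    tibble(relation = label, r = r, p = p,
           slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
           r_squared = r2, n = n)
  }
  dplyr::bind_rows(
    rel(measurements$d_pre_um, measurements$relative_change,
        "d_pre_vs_relative_change"),
    rel(measurements$d_during_um, measurements$d_nucleus_um,
        "d_during_vs_d_nucleus")
  )
}
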