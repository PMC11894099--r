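#' Lamina-rim immunostaining fixture
#'
#' Builds an image stack with two classes of nuclei drawn as annular
#' lamina rims: epithelial nuclei at rim intensity `epithelial_level`
#' above background and hemocyte nuclei at `ratio` times that level.
#' All nuclei share identical rim geometry, so the ratio of
#' background-corrected rim intensities recovers `ratio` exactly in the
#' noise-free case.
#'
#' @param ratio hemocyte / epithelial rim intensity ratio (> 0).
#' @param n_hemocyte,n_epithelial nuclei per class.
#' @param background_level constant background intensity.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed (noise only; geometry is deterministic).
#' @param epithelial_level epithelial rim intensity above background.
#' @param rim_radius_px inner rim radius; rims are
#'   `rim_thickness_px` thick.
#' @param rim_thickness_px rim thickness in pixels.
#' @param z_slices stack depth; rims are drawn on every slice.
#' @param age_group age label attached to every nucleus.
#' @return list with `stack` (`(z, y, x)` array) and `nuclei` (tibble:
#'   `nucleus_id`, `cell_class`, `age_group`, `cx_px`, `cy_px`,
#'   `rim_radius_px`, `rim_thickness_px`).
#' @examples
#' fx <- make_lamina_fixture(ratio = 0.25, n_hemocyte = 4,
#'                           n_epithelial = 4, noise_sd = 0, seed = 1)
#' @export
make_lamina_fixture <- function(ratio, n_hemocyte = 10, n_epithelial = 10,
                                background_level = 10, noise_sd = 0,
                                seed = 1, epithelial_level = 100,
                                rim_radius_px = 8, rim_thickness_px = 2,
                                z_slices = 5, age_group = "18h") {
  if (ratio <= 0) abort("ratio must be positive")
  n_total <- n_hemocyte + n_epithelial
  if (n_total < 1) abort("at least one nucleus is required")

  cell <- 4 * (rim_radius_px + rim_thickness_px)
  ncol_grid <- ceiling(sqrt(n_total))
  nrow_grid <- ceiling(n_total / ncol_grid)
  # one empty grid row at the bottom reserved for background lines
  ny <- (nrow_grid + 1) * cell
  nx <- ncol_grid * cell

  classes <- c(rep("hemocyte", n_hemocyte), rep("epithelial", n_epithelial))
  idx <- seq_len(n_total) - 1L
  nuclei <- tibble(
    nucleus_id = seq_len(n_total),
    cell_class = classes,
    age_group = age_group,
    cx_px = (idx %% ncol_grid) * cell + cell / 2,
    cy_px = (idx %/% ncol_grid) * cell + cell / 2,
    rim_radius_px = rim_radius_px,
    rim_thickness_px = rim_thickness_px
  )

  plane <- matrix(background_level, ny, nx)
  xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
  for (i in seq_len(n_total)) {
    d <- sqrt((xg - nuclei$cx_px[i])^2 + (yg - nuclei$cy_px[i])^2)
    rim <- d >= rim_radius_px & d < rim_radius_px + rim_thickness_px
    lvl <- if (classes[i] == "hemocyte") ratio * epithelial_level
           else epithelial_level
    plane[rim] <- background_level + lvl
  }

  stack <- array(rep(plane, z_slices), dim = c(ny, nx, z_slices))
  stack <- aperm(stack, c(3, 1, 2)) # (z, y, x)
  if (noise_sd > 0) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(seed)
    stack <- stack + array(rnorm(length(stack), 0, noise_sd), dim = dim(stack))
    restore_rng(old)
  }

  list(stack = stack, nuclei = nuclei)
}

#' Rim and background sampling lines for a lamina fixture
#'
#' Generates, per nucleus, `n_lines` evenly rotated diameters through
#' the rim annulus (the automated analogue of manual line placement
#' across the lamina), and `n_background` horizontal lines in the empty
#' margin at the bottom of the field.
#'
#' @param fixture output of [make_lamina_fixture()].
#' @param n_lines chords per nucleus.
#' @param n_background background lines.
#' @return list with `rim_lines` (tibble: `nucleus_id`, `x0`, `y0`,
#'   `x1`, `y1`) and `background_lines` (same columns, no id).
#' @export
lamina_rim_lines <- function(fixture, n_lines = 3, n_background = 3) {
  nuc <- fixture$nuclei
  len <- nuc$rim_radius_px + nuc$rim_thickness_px
  lines <- purrr::map_dfr(seq_len(nrow(nuc)), function(i) {
    ang <- pi * (seq_len(n_lines) - 1) / n_lines
    tibble(
      nucleus_id = nuc$nucleus_id[i],
      x0 = nuc$cx_px[i] - len[i] * cos(ang),
      y0 = nuc$cy_px[i] - len[i] * sin(ang),
      x1 = nuc$cx_px[i] + len[i] * cos(ang),
      y1 = nuc$cy_px[i] + len[i] * sin(ang)
    )
  })
  dims <- dim(fixture$stack)
  ny <- dims[2]; nx <- dims[3]
  yb <- ny - 2 - (seq_len(n_background) - 1) * 3
  bg <- tibble(x0 = 2, y0 = yb, x1 = min(nx - 3, 2 + 20), y1 = yb)
  list(rim_lines = lines, background_lines = bg)
}

#' Two-channel vessel transit movie
#'
#' Renders a vessel as two parallel bright wall lines (Gaussian
#' cross-section, 1 px sd) separated by `pre_diameter_um` that widen to
#' `dilation_factor * pre_diameter_um` while the nucleus centroid lies
#' within the measurement region, then relax. The nuclear channel
#' carries a bright disk travelling along the vessel.
#'
#' @param pre_diameter_um wall separation before/after transit.
#' @param dilation_factor multiplicative dilation during transit (>= 1).
#' @param nucleus_diameter_um diameter of the transiting nucleus; must
#'   fit inside the dilated vessel.
#' @param seed RNG seed for the noise channel.
#' @param pixel_size_um pixel size.
#' @param n_frames number of frames.
#' @param noise_sd additive Gaussian noise SD on both channels.
#' @param wall_intensity,nucleus_intensity,bg_intensity intensity levels.
#' @return object of class `transit_movie`: `walls` and `nuclei`
#'   `(t, y, x)` arrays plus a `truth` list with the measurement column
#'   `x_line_px`, per-phase frame indices (0-based) and the generating
#'   diameters.
#' @export
make_vessel_transit_movie <- function(pre_diameter_um = 5,
                                      dilation_factor = 1.2,
                                      nucleus_diameter_um = 4,
                                      seed = 1, pixel_size_um = 0.3,
                                      n_frames = 24, noise_sd = 0,
                                      wall_intensity = 200,
                                      nucleus_intensity = 180,
                                      bg_intensity = 10) {
  if (dilation_factor < 1) abort("dilation_factor must be >= 1")
  if (pre_diameter_um <= 0 || nucleus_diameter_um <= 0) {
    abort("diameters must be positive")
  }
  d_during_um <- dilation_factor * pre_diameter_um
  if (nucleus_diameter_um > d_during_um) {
    abort("nucleus is wider than the dilated vessel")
  }
  ps <- pixel_size_um
  d_pre_px <- pre_diameter_um / ps
  d_dur_px <- d_during_um / ps
  r_px <- nucleus_diameter_um / 2 / ps

  ny <- ceiling(d_dur_px) + 60
  nx <- 160
  yc <- (ny - 1) / 2
  x_line <- (nx - 1) / 2

  # nucleus travels left to right at constant speed
  xs <- seq(10 + r_px, nx - 11 - r_px, length.out = n_frames)
  during <- abs(xs - x_line) <= r_px
  first_d <- which(during)[1]
  last_d <- tail(which(during), 1)

  ygrid <- 0:(ny - 1)
  walls <- array(bg_intensity, dim = c(n_frames, ny, nx))
  nuclei <- array(bg_intensity, dim = c(n_frames, ny, nx))
  for (t in seq_len(n_frames)) {
    d_px <- if (during[t]) d_dur_px else d_pre_px
    prof <- wall_intensity * (exp(-(ygrid - (yc - d_px / 2))^2 / 2) +
                              exp(-(ygrid - (yc + d_px / 2))^2 / 2))
    walls[t, , ] <- walls[t, , ] + matrix(prof, ny, nx)
    disk <- draw_ellipse_mask(ny, nx, xs[t], yc, r_px, r_px)
    plane <- nuclei[t, , ]
    plane[disk] <- nucleus_intensity
    nuclei[t, , ] <- plane
  }
  if (noise_sd > 0) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(seed)
    walls <- walls + array(rnorm(length(walls), 0, noise_sd), dim = dim(walls))
    nuclei <- nuclei + array(rnorm(length(nuclei), 0, noise_sd),
                             dim = dim(nuclei))
    restore_rng(old)
  }

  truth <- list(
    x_line_px = x_line, y_center_px = yc,
    frames_pre = seq_len(first_d - 1) - 1L,
    frames_during = (first_d:last_d) - 1L,
    frames_post = if (last_d < n_frames) ((last_d + 1):n_frames) - 1L
                  else integer(0),
    d_pre_um = pre_diameter_um, d_during_um = d_during_um,
    d_post_um = pre_diameter_um, d_nucleus_um = nucleus_diameter_um,
    relative_change = dilation_factor,
    residual_um = d_during_um - nucleus_diameter_um
  )
  structure(
    list(walls = walls, nuclei = nuclei, truth = truth,
         pixel_size_um = ps),
    class = "transit_movie"
  )
}

#' Simulate a cohort of vessel transit measurements
#'
#' Generates transit records in which vessels dilate to just accommodate
#' the incoming nucleus: `D_during = max(D_pre, D_nucleus + clearance)`.
#' Smaller vessels therefore dilate proportionally more, reproducing an
#' inverse relationship between resting diameter and relative dilation,
#' and a tight positive relationship between vessel and nuclear
#' diameters during transit.
#'
#' @param n number of transit events.
#' @param seed RNG seed.
#' @param d_pre_range resting vessel diameter range (um).
#' @param d_nucleus_range nuclear diameter range (um).
#' @param clearance_um mean residual clearance added to the nuclear
#'   diameter when the vessel must dilate.
#' @param noise_um measurement noise SD on the during-transit diameter.
#' @return tibble of transit measurements (see [transit_metrics()]).
#' @export
simulate_transit_cohort <- function(n = 13, seed = 1,
                                    d_pre_range = c(3.5, 7),
                                    d_nucleus_range = c(3.5, 5.5),
                                    clearance_um = 0.4, noise_um = 0.1) {
  if (n < 3) abort("n must be >= 3")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  d_pre <- runif(n, d_pre_range[1], d_pre_range[2])
  d_nuc <- runif(n, d_nucleus_range[1], d_nucleus_range[2])
  d_dur <- pmax(d_pre, d_nuc + clearance_um + abs(rnorm(n, 0, noise_um)))
  transit_metrics(d_pre = d_pre, d_during = d_dur, d_post = d_pre,
                  d_nucleus = d_nuc)
}
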