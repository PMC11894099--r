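#' Rasterize an ellipse as a binary mask
#'
#' Fills the ellipse \eqn{(u/a)^2 + (v/b)^2 \le 1}, where \eqn{(u, v)}
#' are coordinates rotated by `angle` about the centre, evaluated at
#' pixel centres (0-based coordinates).
#'
#' @param ny,nx mask dimensions (rows = y, cols = x).
#' @param cx,cy centre in 0-based pixel coordinates.
#' @param a,b semi-axes in pixels (`a` along the rotated x axis).
#' @param angle rotation in radians.
#' @return logical matrix.
#' @export
draw_ellipse_mask <- function(ny, nx, cx, cy, a, b, angle = 0) {
  if (a <= 0 || b <= 0) abort("semi-axes must be positive")
  x <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  y <- matrix(rep(0:(ny - 1), nx), ny, nx)
  ca <- cos(angle); sa <- sin(angle)
  u <- ((x - cx) * ca + (y - cy) * sa) / a
  v <- (-(x - cx) * sa + (y - cy) * ca) / b
  u * u + v * v <= 1
}

# fill an ellipsoid into a (z, y, x) volume; centre/axes in voxel units
fill_ellipsoid <- function(vol, cx, cy, cz, a, b, c, angle, value) {
  nz <- dim(vol)[1]; ny <- dim(vol)[2]; nx <- dim(vol)[3]
  xr <- max(1L, floor(cx - a) + 1L - 1L):min(nx, ceiling(cx + a) + 1L + 1L)
  yr <- max(1L, floor(cy - a) + 1L - 1L):min(ny, ceiling(cy + a) + 1L + 1L)
  zr <- max(1L, floor(cz - c) + 1L - 1L):min(nz, ceiling(cz + c) + 1L + 1L)
  ca <- cos(angle); sa <- sin(angle)
  # 0-based coordinates of the candidate voxels
  gx <- xr - 1L; gy <- yr - 1L; gz <- zr - 1L
  for (zi in seq_along(zr)) {
    w <- (gz[zi] - cz) / c
    w2 <- w * w
    if (w2 > 1) next
    xm <- matrix(rep(gx, each = length(gy)), length(gy), length(gx))
    ym <- matrix(rep(gy, length(gx)), length(gy), length(gx))
    u <- ((xm - cx) * ca + (ym - cy) * sa) / a
    v <- (-(xm - cx) * sa + (ym - cy) * ca) / b
    inside <- u * u + v * v + w2 <= 1
    if (any(inside)) {
      slab <- vol[zr[zi], yr, xr]
      slab[inside] <- value
      vol[zr[zi], yr, xr] <- slab
    }
  }
  vol
}

#' Render a synthetic nuclear movie with ground truth
#'
#' Draws migrating nuclei as uniform-intensity ellipsoids in a
#' `(t, z, y, x)` stack. Each nucleus's in-plane semi-axes `(a, b)`
#' realise the frame's true shape factor under the
#' \eqn{(a-b)/(a+b)} formula while conserving projected area
#' (`a * b` constant), the major axis is aligned with the instantaneous
#' velocity, and motion is confined to the vessel channels when the
#' regime defines them. Poisson shot noise and Gaussian read noise are
#' applied last. Nuclei are laid out with pairwise centroid spacing of
#' at least twice the nuclear diameter at all times.
#'
#' @param config a [synth_movie_config()].
#' @return object of class `synth_movie`: list with `data` (numeric
#'   `(t, z, y, x)` array), `ground_truth` (tibble: `frame`,
#'   `nucleus_id`, `x_px`, `y_px`, `z_px`, `semi_major_px`,
#'   `semi_minor_px`, `sf_true`, `squeezing`), `vessel_mask` (integer
#'   `(y, x)` label matrix or `NULL`), plus the physical metadata and
#'   the config.
#' @examples
#' cfg <- synth_movie_config(synth_regime("vessel"), n_nuclei = 2,
#'                           n_frames = 6, field_px = c(96, 128),
#'                           z_slices = 3, seed = 3)
#' mv <- render_movie(cfg)
#' dim(mv$data)
#' @export
render_movie <- function(config) {
  if (!inherits(config, "synth_movie_config")) {
    abort("config must be a synth_movie_config")
  }
  reg <- config$regime
  ps <- config$pixel_size_um
  ny <- config$field_px[1]; nx <- config$field_px[2]
  nz <- config$z_slices; nt <- config$n_frames
  r_px <- reg$nucleus_diameter_um / 2 / ps
  diam_px <- 2 * r_px

  sf_max <- min(reg$sf_squeeze + 4 * reg$sf_jitter_sd, 1 - 1e-4)
  a_max <- r_px * sqrt((1 + sf_max) / (1 - sf_max))

  in_channel <- !is.null(reg$channel_width_um)
  if (in_channel) {
    cw_px <- reg$channel_width_um / ps
    if (diam_px > cw_px) {
      abort("nucleus does not fit inside the vessel channel")
    }
  }

  # vertical layout: one lane (channel) per nucleus so that pairwise
  # centroid spacing >= 2 * diameter holds at every frame
  lane_gap <- max(2 * diam_px + 2, if (in_channel) cw_px + 4 else 0)
  y0 <- lane_gap / 2 + 2
  lane_y <- y0 + (seq_len(config$n_nuclei) - 1) * lane_gap
  x_margin <- a_max + 3
  if (max(lane_y) + lane_gap / 2 > ny || 2 * x_margin + 4 > nx) {
    abort("field too small for the requested nuclei at the required spacing")
  }
  y_wander <- if (in_channel) {
    max(0, min((cw_px - diam_px) / 2 - 0.5, 2))
  } else {
    min(0.25 * diam_px, 3)
  }

  step_px <- reg$speed_um_per_min * config$frame_interval_s / 60 / ps
  cz <- (nz - 1) / 2
  c_vox <- max(1, min(r_px * ps / config$z_step_um, nz / 2))

  truth_list <- vector("list", config$n_nuclei)
  for (i in seq_len(config$n_nuclei)) {
    sseed <- nucleus_seed(config$seed, i)
    series <- simulate_sf_series(reg, nt, seed = sseed)

    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(nucleus_seed(config$seed, i) + 1L)
    dir <- sample(c(-1, 1), 1)
    x <- numeric(nt); y <- numeric(nt)
    x[1] <- runif(1, x_margin, nx - 1 - x_margin)
    y[1] <- lane_y[i]
    if (nt > 1) {
      for (t in 2:nt) {
        dx <- dir * step_px * runif(1, 0.7, 1.3)
        if (x[t - 1] + dx < x_margin || x[t - 1] + dx > nx - 1 - x_margin) {
          dir <- -dir
          dx <- -dx
        }
        x[t] <- x[t - 1] + dx
        y[t] <- min(max(y[t - 1] + rnorm(1, 0, 0.3), lane_y[i] - y_wander),
                    lane_y[i] + y_wander)
      }
    }
    restore_rng(old)

    vx <- c(diff(x), tail(diff(x), 1) %||% 0)
    vy <- c(diff(y), tail(diff(y), 1) %||% 0)
    if (nt == 1) { vx <- 1; vy <- 0 }
    angle <- atan2(vy, vx)
    a <- r_px * sqrt((1 + series$sf) / (1 - series$sf))
    b <- r_px^2 / a

    truth_list[[i]] <- tibble(
      frame = series$frame, nucleus_id = i, x_px = x, y_px = y,
      z_px = cz, semi_major_px = a, semi_minor_px = b,
      sf_true = series$sf, squeezing = series$squeezing,
      orientation_rad = angle
    )
  }
  truth <- dplyr::bind_rows(truth_list) |> dplyr::arrange(.data$frame, .data$nucleus_id)

  data <- array(config$bg_intensity, dim = c(nt, nz, ny, nx))
  for (t in seq_len(nt)) {
    vol <- array(config$bg_intensity, dim = c(nz, ny, nx))
    ft <- truth[truth$frame == t - 1L, ]
    for (k in seq_len(nrow(ft))) {
      vol <- fill_ellipsoid(
        vol, ft$x_px[k], ft$y_px[k], cz,
        ft$semi_major_px[k], ft$semi_minor_px[k], c_vox,
        ft$orientation_rad[k], config$fg_intensity
      )
    }
    data[t, , , ] <- vol
  }

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(config$seed)
  if (config$noise_poisson) {
    data[] <- rpois(length(data), lambda = data)
  }
  if (config$noise_gaussian_sd > 0) {
    data[] <- data + rnorm(length(data), 0, config$noise_gaussian_sd)
  }
  data[data < 0] <- 0
  restore_rng(old)

  vessel_mask <- NULL
  if (in_channel) {
    vessel_mask <- matrix(0L, ny, nx)
    for (i in seq_len(config$n_nuclei)) {
      rows <- which(abs((0:(ny - 1)) - lane_y[i]) <= cw_px / 2)
      vessel_mask[rows, ] <- i
    }
  }

  structure(
    list(
      data = data, ground_truth = truth, vessel_mask = vessel_mask,
      pixel_size_um = ps, z_step_um = config$z_step_um,
      frame_interval_s = config$frame_interval_s, config = config
    ),
    class = "synth_movie"
  )
}

#' @export
print.synth_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "synth_movie: %d frames, %d z, %d x %d px (%.2f um/px, %.0f s/frame), %d nuclei\n",
    d[1], d[2], d[3], d[4], x$pixel_size_um, x$frame_interval_s,
    max(x$ground_truth$nucleus_id)
  ))
  invisible(x)
}
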