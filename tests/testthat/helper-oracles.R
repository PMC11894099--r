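# Independent oracles used across the suite. These deliberately avoid
# the package's vectorised code paths: explicit double loops and
# exhaustive enumeration only.

# central second moments of a mask by explicit double summation,
# including the unit-square (uniform pixel) term, then eigen-axes
oracle_moment_axes <- function(mask) {
  n <- 0
  sx <- 0; sy <- 0
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        n <- n + 1
        sx <- sx + (c - 1)
        sy <- sy + (r - 1)
      }
    }
  }
  cx <- sx / n; cy <- sy / n
  sxx <- 0; syy <- 0; sxy <- 0
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        dx <- (c - 1) - cx
        dy <- (r - 1) - cy
        sxx <- sxx + dx * dx
        syy <- syy + dy * dy
        sxy <- sxy + dx * dy
      }
    }
  }
  sxx <- sxx / n + 1 / 12
  syy <- syy / n + 1 / 12
  sxy <- sxy / n
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)$values
  list(a = 2 * sqrt(ev[1]), b = 2 * sqrt(max(ev[2], 0)))
}

# run-length-encoding event oracle: walk the series frame by frame
oracle_events <- function(sf, threshold, frames = seq_along(sf) - 1L) {
  events <- list()
  cur <- NULL
  for (i in seq_along(sf)) {
    broken <- i > 1 && frames[i] - frames[i - 1] != 1L
    if (sf[i] >= threshold) {
      if (is.null(cur) || broken) {
        if (!is.null(cur)) events[[length(events) + 1L]] <- cur
        cur <- c(start = frames[i], end = frames[i], len = 1L)
      } else {
        cur["end"] <- frames[i]
        cur["len"] <- cur["len"] + 1L
      }
    } else {
      if (!is.null(cur)) events[[length(events) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) events[[length(events) + 1L]] <- cur
  list(
    starts = vapply(events, `[[`, numeric(1), "start"),
    ends = vapply(events, `[[`, numeric(1), "end"),
    lens = vapply(events, `[[`, numeric(1), "len"),
    proportion = sum(sf >= threshold) / length(sf)
  )
}

# exhaustive max Feret: largest distance over all hull vertex pairs
oracle_max_feret <- function(mask) {
  hull <- nucleodyn:::mask_hull(mask)
  best <- 0
  for (i in seq_len(nrow(hull))) {
    for (j in seq_len(nrow(hull))) {
      best <- max(best, sum((hull[i, ] - hull[j, ])^2))
    }
  }
  sqrt(best)
}

# min width by scanning projections over a fine grid of directions
oracle_min_feret <- function(mask, n_dir = 3600) {
  hull <- nucleodyn:::mask_hull(mask)
  widths <- vapply(seq_len(n_dir), function(k) {
    th <- pi * (k - 1) / n_dir
    proj <- hull[, 1] * cos(th) + hull[, 2] * sin(th)
    max(proj) - min(proj)
  }, numeric(1))
  min(widths)
}

# random connected blob: union of a few overlapping random ellipses
random_blob <- function(seed, size = 48) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  n_ell <- sample(1:3, 1)
  cx0 <- runif(1, size * 0.35, size * 0.65)
  cy0 <- runif(1, size * 0.35, size * 0.65)
  for (i in seq_len(n_ell)) {
    a <- runif(1, 3, size / 4)
    b <- runif(1, 2, a)
    ang <- runif(1, 0, pi)
    cx <- cx0 + runif(1, -3, 3)
    cy <- cy0 + runif(1, -3, 3)
    m <- m | draw_ellipse_mask(size, size, cx, cy, a, b, ang)
  }
  m
}

# small noise-free vessel movie shared by several tests (built lazily)
.test_cache <- new.env()

test_movie <- function() {
  if (is.null(.test_cache$movie)) {
    cfg <- synth_movie_config(
      synth_regime("vessel"), n_nuclei = 2, n_frames = 12,
      field_px = c(96, 160), z_slices = 3,
      noise_gaussian_sd = 0, noise_poisson = FALSE, seed = 42
    )
    .test_cache$movie <- render_movie(cfg)
  }
  .test_cache$movie
}

test_classifier <- function() {
  if (is.null(.test_cache$classifier)) {
    mv <- test_movie()
    vol <- mv$data[1, , , ]
    scr <- auto_scribbles(vol)
    .test_cache$classifier <- train_pixel_classifier(vol, scr$fg, scr$bg)
  }
  .test_cache$classifier
}
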