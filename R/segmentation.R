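#' Feature bank specification for pixel classification
#'
#' A small deterministic filter bank applied per z-slice: the raw
#' intensity, Gaussian smoothings, the gradient magnitude of a smoothed
#' image, and Laplacian-of-Gaussian responses.
#'
#' @param gauss_sigmas Gaussian smoothing scales (px).
#' @param grad_sigma scale at which the gradient magnitude is computed.
#' @param log_sigmas Laplacian-of-Gaussian scales (px).
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(gauss_sigmas = c(1, 2, 4), grad_sigma = 2,
                         log_sigmas = c(2, 4)) {
  if (any(c(gauss_sigmas, grad_sigma, log_sigmas) <= 0)) {
    abort("feature scales must be positive")
  }
  structure(
    list(gauss_sigmas = gauss_sigmas, grad_sigma = grad_sigma,
         log_sigmas = log_sigmas),
    class = "feature_spec"
  )
}

feature_names <- function(spec) {
  c("raw",
    paste0("gauss_s", spec$gauss_sigmas),
    paste0("gradmag_s", spec$grad_sigma),
    paste0("log_s", spec$log_sigmas))
}

# --- separable convolution with replicate boundaries -----------------------
# Implemented as banded-matrix products (BLAS) with matrices cached per
# (size, kernel); orders of magnitude faster than per-call FFT filtering
# for the many small slices the feature bank processes.

.conv_cache <- new.env(parent = emptyenv())

conv_band_matrix <- function(n, k) {
  key <- paste0(n, ":", paste(signif(k, 12), collapse = ","))
  hit <- get0(key, .conv_cache)
  if (!is.null(hit)) return(hit)
  r <- (length(k) - 1L) / 2L
  B <- matrix(0, n, n + 2L * r)
  for (i in seq_len(n)) B[i, i:(i + 2L * r)] <- k
  assign(key, B, .conv_cache)
  B
}

pad_replicate <- function(img, ry, rx) {
  ny <- nrow(img); nx <- ncol(img)
  img[c(rep(1L, ry), seq_len(ny), rep(ny, ry)),
      c(rep(1L, rx), seq_len(nx), rep(nx, rx)), drop = FALSE]
}

# 2D convolution with the separable kernel ky (rows) x kx (cols)
conv2_sep <- function(img, ky, kx) {
  ry <- (length(ky) - 1L) / 2L
  rx <- (length(kx) - 1L) / 2L
  p <- pad_replicate(img, ry, rx)
  By <- conv_band_matrix(nrow(img), rev(ky))
  Bx <- conv_band_matrix(ncol(img), rev(kx))
  By %*% p %*% t(Bx)
}

gauss_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

smooth2d <- function(img, sigma) {
  k <- gauss_kernel(sigma)
  conv2_sep(img, k, k)
}

# per-slice features; img is a (y, x) matrix, returns n_px x n_feat matrix
slice_features <- function(img, spec) {
  feats <- list(raw = as.numeric(img))
  for (s in spec$gauss_sigmas) {
    feats[[paste0("gauss_s", s)]] <- as.numeric(smooth2d(img, s))
  }
  sm <- smooth2d(img, spec$grad_sigma)
  d1 <- c(-0.5, 0, 0.5)
  gx <- conv2_sep(sm, 1, d1)
  gy <- conv2_sep(sm, d1, 1)
  feats[[paste0("gradmag_s", spec$grad_sigma)]] <-
    as.numeric(sqrt(gx^2 + gy^2))
  d2 <- c(1, -2, 1)
  for (s in spec$log_sigmas) {
    smo <- smooth2d(img, s)
    feats[[paste0("log_s", s)]] <-
      as.numeric(conv2_sep(smo, d2, 1) + conv2_sep(smo, 1, d2))
  }
  do.call(cbind, feats)
}

# features of a (z, y, x) volume, voxel order matching as.numeric(volume)
volume_features <- function(vol, spec) {
  if (length(dim(vol)) == 2L) vol <- array(vol, dim = c(1L, dim(vol)))
  nz <- dim(vol)[1]
  per_slice <- lapply(seq_len(nz), function(z) {
    slice_features(vol[z, , , drop = TRUE], spec)
  })
  n_feat <- ncol(per_slice[[1]])
  n_px <- prod(dim(vol)[2:3])
  out <- matrix(NA_real_, nz * n_px, n_feat)
  # voxel linear order of (z, y, x) arrays is z-fastest
  for (z in seq_len(nz)) {
    out[seq(z, by = nz, length.out = n_px), ] <- per_slice[[z]]
  }
  colnames(out) <- colnames(per_slice[[1]])
  out
}

#' Train a pixel classifier from scribble annotations
#'
#' Fits a ridge-regularised logistic model mapping filter-bank features
#' to foreground probability, the trainable-segmentation step that
#' produces the nuclear probability map.
#'
#' @param volumes a `(z, y, x)` array or list of such arrays.
#' @param fg_masks,bg_masks logical arrays (or lists) of the same shape
#'   marking foreground and background scribble voxels; each class needs
#'   at least 50 annotated voxels.
#' @param spec a [feature_spec()].
#' @param lambda ridge penalty.
#' @return object of class `pixel_classifier` (feature spec, weights,
#'   bias); serialisable with [write_classifier()].
#' @export
train_pixel_classifier <- function(volumes, fg_masks, bg_masks,
                                   spec = feature_spec(), lambda = 1e-2) {
  if (!is.list(volumes)) {
    volumes <- list(volumes); fg_masks <- list(fg_masks)
    bg_masks <- list(bg_masks)
  }
  xs <- list(); ys <- list()
  for (i in seq_along(volumes)) {
    fg <- fg_masks[[i]] != 0
    bg <- bg_masks[[i]] != 0
    if (!any(fg) && !any(bg)) next
    feats <- volume_features(volumes[[i]], spec)
    # fixed annotation order: foreground voxels first, then background
    xs[[length(xs) + 1L]] <- rbind(feats[fg, , drop = FALSE],
                                   feats[bg, , drop = FALSE])
    ys[[length(ys) + 1L]] <- c(rep(1L, sum(fg)), rep(0L, sum(bg)))
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  if (sum(y == 1) < 50 || sum(y == 0) < 50) {
    abort("need at least 50 annotated voxels in each class")
  }

  col_sds <- apply(x, 2, sd)
  if (all(col_sds < 1e-12)) {
    # no feature varies across the annotations: fall back to the class
    # prior (zero weights, intercept at the prior log-odds)
    co <- c(stats::qlogis(mean(y)), rep(0, ncol(x)))
  } else {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = TRUE)
    co <- as.numeric(coef(fit))
  }
  clf <- structure(
    list(spec = spec, bias = co[1],
         weights = setNames(co[-1], colnames(x)), lambda = lambda),
    class = "pixel_classifier"
  )

  p_train <- as.numeric(stats::plogis(x %*% clf$weights + clf$bias))
  auc <- rank_auc(p_train, y)
  if (is.na(auc) || auc < 0.55) {
    warn("annotated classes are not separable by the feature bank; predicted probabilities will stay near the class prior")
  }
  clf
}

# Mann-Whitney AUC of scores vs binary labels
rank_auc <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("pixel_classifier:", length(x$weights), "features, lambda =",
      x$lambda, "\n")
  invisible(x)
}

#' Predict a foreground probability map
#'
#' @param x a `synth_movie`, a `(t, z, y, x)` array (give `frame`), or a
#'   single `(z, y, x)` volume.
#' @param classifier a trained [train_pixel_classifier()] model.
#' @param frame 1-based frame index when `x` is a movie.
#' @return numeric `(z, y, x)` array of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(x, classifier, frame = NULL) {
  if (!inherits(classifier, "pixel_classifier")) {
    abort("classifier must be a pixel_classifier")
  }
  vol <- extract_volume(x, frame)
  feats <- volume_features(vol, classifier$spec)
  if (ncol(feats) != length(classifier$weights) ||
      !identical(colnames(feats), names(classifier$weights))) {
    abort("feature bank of the input does not match the training spec")
  }
  p <- as.numeric(stats::plogis(feats %*% classifier$weights +
                                  classifier$bias))
  array(p, dim = dim(vol))
}

extract_volume <- function(x, frame) {
  if (inherits(x, "synth_movie")) x <- x$data
  nd <- length(dim(x))
  if (nd == 4L) {
    if (is.null(frame)) abort("frame must be given for a 4D movie")
    if (frame < 1 || frame > dim(x)[1]) abort("frame out of range")
    array(x[frame, , , ], dim = dim(x)[2:4])
  } else if (nd == 3L) {
    x
  } else if (nd == 2L) {
    array(x, dim = c(1L, dim(x)))
  } else {
    abort("x must be a 2D, 3D or 4D array")
  }
}

#' Segment nuclei from a probability map
#'
#' Thresholds the probability map (inclusive at the threshold), labels
#' 26-connected 3D components, removes components smaller than
#' `min_volume_vox`, and renumbers the survivors 1..K by decreasing
#' volume.
#'
#' @param prob `(z, y, x)` probability array.
#' @param prob_threshold threshold in (0, 1).
#' @param min_volume_vox minimum component volume in voxels.
#' @return integer label array of the same shape with attribute
#'   `volumes` (voxel count per label).
#' @export
segment_nuclei <- function(prob, prob_threshold = 0.5, min_volume_vox = 30) {
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    abort("prob_threshold must be in (0, 1)")
  }
  if (length(dim(prob)) == 2L) prob <- array(prob, dim = c(1L, dim(prob)))
  mask <- prob >= prob_threshold
  storage.mode(mask) <- "logical"
  labels <- .label_components_3d(mask)
  vols <- tabulate(labels[labels > 0L])
  keep <- which(vols >= min_volume_vox)
  # renumber 1..K by descending volume; ties broken by old label id
  keep <- keep[order(-vols[keep], keep)]
  remap <- integer(length(vols) + 1L)
  remap[keep + 1L] <- seq_along(keep)
  out <- array(remap[labels + 1L], dim = dim(labels))
  attr(out, "volumes") <- vols[keep]
  out
}

#' Maximum z-projection of one label's mask
#'
#' @param labels integer `(z, y, x)` label array.
#' @param id label to project.
#' @return logical `(y, x)` matrix.
#' @export
project_mask_2d <- function(labels, id) {
  if (length(dim(labels)) == 2L) {
    labels <- array(labels, dim = c(1L, dim(labels)))
  }
  sel <- labels == id
  if (!any(sel)) {
    abort(sprintf("label %s not present", id), class = "nucleodyn_not_found")
  }
  apply(sel, c(2, 3), any)
}

#' Segment every frame of a movie
#'
#' @param movie a `synth_movie` or `(t, z, y, x)` array.
#' @param classifier a [train_pixel_classifier()] model.
#' @inheritParams segment_nuclei
#' @return list of per-frame label arrays.
#' @export
segment_movie <- function(movie, classifier, prob_threshold = 0.5,
                          min_volume_vox = 30) {
  data <- if (inherits(movie, "synth_movie")) movie$data else movie
  nt <- dim(data)[1]
  lapply(seq_len(nt), function(t) {
    prob <- predict_probability(data, classifier, frame = t)
    segment_nuclei(prob, prob_threshold, min_volume_vox)
  })
}

#' Quantile-scribble training annotations from one frame
#'
#' Deterministic bootstrap annotations for synthetic movies: the
#' brightest voxels of a frame are marked foreground and the dimmest
#' half background (subsampled at a fixed stride), so a classifier can
#' be trained without manual scribbles.
#'
#' @param vol `(z, y, x)` volume.
#' @param fg_quantile intensity quantile above which voxels are marked
#'   foreground.
#' @param n_per_class approximate annotation count per class.
#' @return list of logical arrays `fg` and `bg`.
#' @export
auto_scribbles <- function(vol, fg_quantile = 0.995, n_per_class = 1000) {
  v <- as.numeric(vol)
  qf <- stats::quantile(v, fg_quantile, names = FALSE)
  qb <- stats::quantile(v, 0.5, names = FALSE)
  fg_idx <- which(v >= qf)
  bg_idx <- which(v <= qb)
  stride_f <- max(1L, floor(length(fg_idx) / n_per_class))
  stride_b <- max(1L, floor(length(bg_idx) / n_per_class))
  fg <- logical(length(v)); bg <- logical(length(v))
  fg[fg_idx[seq(1, length(fg_idx), by = stride_f)]] <- TRUE
  bg[bg_idx[seq(1, length(bg_idx), by = stride_b)]] <- TRUE
  list(fg = array(fg, dim = dim(vol)), bg = array(bg, dim = dim(vol)))
}
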