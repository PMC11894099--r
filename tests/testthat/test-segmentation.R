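test_that("classifier separates bright nuclei from background accurately", {
  mv <- test_movie()
  clf <- test_classifier()
  # held-out frame: compare thresholded probability to the render mask
  vol <- mv$data[5, , , ]
  truth <- vol > 100
  prob <- predict_probability(vol, clf)
  expect_true(all(prob >= 0 & prob <= 1))
  pred <- prob >= 0.5
  acc <- mean(pred == truth)
  expect_gte(acc, 0.95)
  jac <- sum(pred & truth) / sum(pred | truth)
  expect_gte(jac, 0.8)
})

test_that("training requires both classes and enough annotations", {
  vol <- array(rnorm(4 * 20 * 20, 100, 5), dim = c(4, 20, 20))
  fg <- array(FALSE, dim(vol)); bg <- array(FALSE, dim(vol))
  fg[1, 1:5, 1:5] <- TRUE # 100 fg, 0 bg
  expect_error(train_pixel_classifier(vol, fg, bg), "50 annotated")
})

test_that("uninformative annotations give prior-level probabilities and a warning", {
  # identical intensity everywhere: features carry no class signal
  vol <- array(50, dim = c(3, 24, 24))
  fg <- array(FALSE, dim(vol)); bg <- array(FALSE, dim(vol))
  fg[1, 1:10, 1:10] <- TRUE
  bg[3, 14:23, 14:23] <- TRUE
  expect_warning(clf <- train_pixel_classifier(vol, fg, bg),
                 "not separable")
  prob <- predict_probability(vol, clf)
  # prior is 0.5 (equal annotation counts)
  expect_true(all(abs(prob - 0.5) < 0.05))
})

test_that("serialised classifiers reproduce probabilities bit-identically", {
  clf <- test_classifier()
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  clf2 <- read_classifier(path)
  expect_identical(clf$weights, clf2$weights)
  expect_identical(clf$bias, clf2$bias)
  vol <- test_movie()$data[3, , , ]
  expect_identical(predict_probability(vol, clf),
                   predict_probability(vol, clf2))
})

test_that("a blank frame scores below 0.5 everywhere", {
  clf <- test_classifier()
  blank <- array(0, dim = dim(test_movie()$data)[2:4])
  prob <- predict_probability(blank, clf)
  expect_lt(max(prob), 0.5)
})

test_that("segmentation finds the right components and respects min volume", {
  mv <- test_movie()
  clf <- test_classifier()
  prob <- predict_probability(mv, clf, frame = 1)
  labels <- segment_nuclei(prob, 0.5, 30)
  expect_equal(max(labels), 2) # two well-separated nuclei
  # labels ordered by descending volume
  vols <- attr(labels, "volumes")
  expect_true(all(diff(vols) <= 0))
  expect_true(all(vols >= 30))

  # empty probability map
  expect_equal(max(segment_nuclei(array(0.1, c(2, 8, 8)), 0.5, 1)), 0)

  # min-volume boundary: component of exactly min_volume kept, below removed
  prob2 <- array(0, c(1, 10, 30))
  prob2[1, 2:4, 2:4] <- 1    # 9 voxels
  prob2[1, 2:4, 20:23] <- 1  # 12 voxels
  lab2 <- segment_nuclei(prob2, 0.5, min_volume_vox = 10)
  expect_equal(max(lab2), 1)
  lab3 <- segment_nuclei(prob2, 0.5, min_volume_vox = 9)
  expect_equal(max(lab3), 2)
})

test_that("3D labelling uses 26-connectivity and partitions the foreground", {
  # two voxels touching only diagonally across z are one 26-connected piece
  m <- array(0, c(2, 4, 4))
  m[1, 1, 1] <- 1
  m[2, 2, 2] <- 1
  lab <- segment_nuclei(m, 0.5, 1)
  expect_equal(max(lab), 1)
  # foreground partition: every thresholded voxel labelled exactly once
  set.seed(3)
  p <- array(runif(5 * 20 * 20), c(5, 20, 20))
  lab2 <- segment_nuclei(p, 0.5, 1)
  expect_identical(lab2 > 0, p >= 0.5)
})

test_that("raising the threshold never grows any component", {
  mv <- test_movie()
  clf <- test_classifier()
  prob <- predict_probability(mv, clf, frame = 2)
  lo <- segment_nuclei(prob, 0.4, 1)
  hi <- segment_nuclei(prob, 0.7, 1)
  expect_true(all(lo[hi > 0] > 0)) # hi foreground subset of lo foreground
  expect_lte(sum(hi > 0), sum(lo > 0))
})

test_that("2D projection is the max over z of the selected label", {
  # single-slice volume: projection equals the slice mask
  v <- array(0L, c(1, 6, 6)); v[1, 2:4, 3:5] <- 1L
  expect_equal(project_mask_2d(v, 1), v[1, , ] == 1)
  # disjoint footprints across z: projection is their union
  v2 <- array(0L, c(2, 6, 6))
  v2[1, 1:2, 1:2] <- 1L
  v2[2, 5:6, 5:6] <- 1L
  pr <- project_mask_2d(v2, 1)
  expect_equal(sum(pr), 8)
  expect_error(project_mask_2d(v2, 9), class = "nucleodyn_not_found")
  # sphere: projected area close to the analytic disk
  r <- 6
  sph <- array(0, c(15, 31, 31))
  for (z in 1:15) {
    dz <- z - 8
    if (abs(dz) <= r) {
      rz <- sqrt(r^2 - dz^2)
      if (rz >= 0.5) {
        sph[z, , ] <- draw_ellipse_mask(31, 31, 15, 15, rz, rz) * 1
      }
    }
  }
  lab <- segment_nuclei(sph, 0.5, 1)
  area <- sum(project_mask_2d(lab, 1))
  expect_lt(abs(area - pi * r^2) / (pi * r^2), 0.05)
})

test_that("noise-free movies are detected at exactly the ground-truth count", {
  for (seed in c(101, 202, 303)) {
    cfg <- synth_movie_config(
      synth_regime("vessel"), n_nuclei = 2, n_frames = 6,
      field_px = c(96, 160), z_slices = 3,
      noise_gaussian_sd = 0, noise_poisson = FALSE, seed = seed
    )
    mv <- render_movie(cfg)
    vol <- mv$data[1, , , ]
    scr <- auto_scribbles(vol)
    clf <- train_pixel_classifier(vol, scr$fg, scr$bg)
    labs <- segment_movie(mv, clf)
    expect_true(all(vapply(labs, max, numeric(1)) == 2))
  }
})
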