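test_that("squeezing events are maximal threshold runs with inclusive boundary", {
  res <- detect_squeezing(c(0.2, 0.5, 0.6, 0.3, 0.45), threshold = 0.4,
                          frame_interval_s = 30)
  expect_equal(nrow(res$events), 2)
  expect_equal(res$events$n_frames, c(2, 1))
  expect_equal(res$events$duration_min, c(1, 0.5))
  expect_equal(res$proportion, 3 / 5)

  # exactly at the threshold counts as squeezing
  at <- detect_squeezing(c(0.39, 0.40, 0.39), 0.4, 30)
  expect_equal(nrow(at$events), 1)
  expect_equal(at$proportion, 1 / 3)

  none <- detect_squeezing(c(0.1, 0.2, 0.39), 0.4, 30)
  expect_equal(nrow(none$events), 0)
  expect_equal(none$proportion, 0)
})

test_that("missing frames break squeeze runs instead of interpolating", {
  # same SF values, but a one-frame gap inside the run
  res <- detect_squeezing(c(0.5, 0.6, 0.7), 0.4, 30, frames = c(0L, 1L, 3L))
  expect_equal(nrow(res$events), 2)
  expect_equal(res$events$n_frames, c(2, 1))
})

test_that("event detection matches the run-length-encoding oracle", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    sf <- runif(n)
    frames <- cumsum(sample(1:2, n, replace = TRUE, prob = c(0.9, 0.1)))
    res <- detect_squeezing(sf, 0.4, 30, frames = frames)
    or <- oracle_events(sf, 0.4, frames)
    expect_equal(nrow(res$events), length(or$lens))
    expect_equal(res$events$n_frames, as.integer(or$lens))
    expect_equal(res$events$start_frame, as.integer(or$starts))
    expect_equal(res$proportion, or$proportion)
  }
})

test_that("track summaries: polyline arithmetic and persistence limits", {
  mk <- function(x, y, sf = 0.2) {
    tibble::tibble(frame = seq_along(x) - 1L, x_um = x, y_um = y, sf = sf)
  }
  # hand-summed polyline: (0,0) -> (1,0) -> (1,1)
  s <- summarize_track(mk(c(0, 1, 1), c(0, 0, 1)), frame_interval_s = 30)
  expect_equal(s$path_length_15 / s$euclidean_15, 2 / sqrt(2))
  expect_equal(s$persistence, sqrt(2) / 2, tolerance = 1e-12)
  expect_true(s$rescaled) # 1 min track rescaled to the 15-min window
  expect_equal(s$path_length_15, 2 * 15 / 1)

  # straight line at constant speed: persistence exactly 1
  s2 <- summarize_track(mk(seq(0, 30, by = 1), rep(0, 31)),
                        frame_interval_s = 30)
  expect_equal(s2$persistence, 1)
  expect_false(s2$rescaled)
  expect_equal(s2$mean_speed_um_min, 2)
  expect_equal(s2$path_length_15, 30) # truncated at 15 min = 30 steps

  # stationary track: zero speed, persistence undefined (NA, not 0)
  s3 <- summarize_track(mk(rep(1, 6), rep(2, 6)), frame_interval_s = 30)
  expect_equal(s3$mean_speed_um_min, 0)
  expect_true(is.na(s3$persistence))
})

test_that("Euclidean distance never exceeds path length (triangle inequality)", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    tr <- tibble::tibble(
      frame = seq_len(n) - 1L,
      x_um = cumsum(rnorm(n)), y_um = cumsum(rnorm(n)),
      sf = runif(n)
    )
    s <- summarize_track(tr, frame_interval_s = 30)
    expect_lte(s$euclidean_15, s$path_length_15 + 1e-12)
    expect_gte(s$squeeze_prop, 0)
    expect_lte(s$squeeze_prop, 1)
  }
})

test_that("correlation matrix: hand-computed values, symmetry, warnings", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  for (m in c("spearman", "pearson")) {
    cm <- correlation_matrix(d, c("x", "y"), method = m)
    expect_equal(cm$r["x", "y"], 1)
  }
  # hand-ranked Spearman: 1 - 6*sum(d^2)/(n(n^2-1)) = 0.6
  d2 <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  cm2 <- correlation_matrix(d2, c("x", "y"), method = "spearman")
  expect_equal(cm2$r["x", "y"], 0.6)

  d3 <- tibble::tibble(x = rnorm(10)) |> dplyr::mutate(y = -x)
  cm3 <- correlation_matrix(d3, c("x", "y"), method = "pearson")
  expect_equal(cm3$r["x", "y"], -1)
  expect_true(isSymmetric(cm3$r))
  expect_equal(unname(diag(cm3$r)), c(1, 1))

  d4 <- tibble::tibble(x = rnorm(10), y = rep(1, 10))
  expect_warning(cm4 <- correlation_matrix(d4, c("x", "y")), "zero variance")
  expect_true(is.na(cm4$r["x", "y"]))

  # t-approximate p agrees with the closed form
  set.seed(1)
  d5 <- tibble::tibble(x = rnorm(20)) |> dplyr::mutate(y = x + rnorm(20))
  cm5 <- correlation_matrix(d5, c("x", "y"), method = "pearson")
  r <- cm5$r["x", "y"]; n <- 20
  expect_equal(cm5$p["x", "y"],
               2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2))
})

test_that("tidy/glance/autoplot methods work on correlation objects", {
  set.seed(2)
  d <- tibble::tibble(a = rnorm(15)) |>
    dplyr::mutate(b = a + rnorm(15), c = rnorm(15))
  cm <- correlation_matrix(d)
  td <- generics::tidy(cm)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3) # 3 attribute pairs
  expect_true(all(abs(td$r) <= 1))
  gl <- generics::glance(cm)
  expect_equal(gl$n_attributes, 3)
  expect_s3_class(ggplot2::autoplot(cm), "ggplot")
})

test_that("heatmap bins conserve the global mean and follow half-open bins", {
  set.seed(5)
  tr <- tibble::tibble(
    x_um = runif(200, 0, 60), y_um = runif(200, 0, 45), sf = runif(200)
  )
  hm <- sf_heatmap(tr, bin_size_px = 17, field_shape = c(160, 200),
                   pixel_size_um = 0.3)
  wmean <- sum(hm$mean * hm$count, na.rm = TRUE) / sum(hm$count)
  expect_equal(wmean, mean(tr$sf), tolerance = 1e-9)
  expect_equal(sum(hm$count), 200)
  expect_true(all(is.na(hm$mean[hm$count == 0])))

  # single populated bin carries the global mean
  tr1 <- tibble::tibble(x_um = runif(20, 0.3, 1), y_um = runif(20, 0.3, 1),
                        sf = runif(20))
  hm1 <- sf_heatmap(tr1, 17, c(160, 200), 0.3)
  expect_equal(sum(hm1$count > 0), 1)
  expect_equal(hm1$mean[1, 1], mean(tr1$sf))

  # boundary centroid goes to the higher-index bin (half-open intervals)
  trb <- tibble::tibble(x_um = 17 * 0.3, y_um = 0, sf = 0.5)
  hmb <- sf_heatmap(trb, 17, c(34, 51), 0.3)
  expect_equal(hmb$count[1, 2], 1L)
  expect_equal(hmb$count[1, 1], 0L)

  # out-of-field centroids are clipped to the edge bin with a warning
  tro <- tibble::tibble(x_um = c(-1, 100), y_um = c(5, 5), sf = c(0.3, 0.6))
  expect_warning(hmo <- sf_heatmap(tro, 17, c(34, 51), 0.3), "clipped")
  expect_equal(sum(hmo$count), 2)
})

test_that("heatmap tidy/autoplot expose bins with physical coordinates", {
  tr <- tibble::tibble(x_um = c(1, 10), y_um = c(1, 10), sf = c(0.2, 0.6))
  hm <- sf_heatmap(tr, 17, c(68, 68), 0.3)
  td <- generics::tidy(hm)
  expect_equal(nrow(td), length(hm$mean))
  expect_equal(sum(td$n), 2)
  expect_s3_class(ggplot2::autoplot(hm), "ggplot")
})
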