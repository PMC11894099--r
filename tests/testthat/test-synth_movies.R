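test_that("regime and config invariants are enforced", {
  expect_error(synth_regime("vessel", p_enter_squeeze = 1.5), "probability")
  expect_error(synth_regime("open", sf_baseline = 0.5), "0.4")
  expect_error(synth_regime("open", sf_squeeze = 0.3), "0.4")
  expect_error(synth_regime("vessel", nucleus_diameter_um = -1), "positive")
  expect_error(synth_movie_config(n_frames = 1), "n_frames")
  expect_error(synth_movie_config(pixel_size_um = 0), "pixel_size_um")
  # vessel defaults squeeze more, and exit squeezing more slowly, than open
  v <- synth_regime("vessel"); o <- synth_regime("open")
  expect_gt(v$p_enter_squeeze, o$p_enter_squeeze)
  expect_lt(v$p_exit_squeeze, o$p_exit_squeeze)
})

test_that("absorbing round state yields no squeezing at all", {
  reg <- synth_regime("open", p_enter_squeeze = 0)
  s <- simulate_sf_series(reg, 500, seed = 3)
  expect_true(all(!s$squeezing))
  expect_true(all(s$sf < 0.4))
  expect_equal(nrow(detect_squeezing(s$sf, 0.4, 30)$events), 0)
})

test_that("squeeze-run lengths follow the geometric mean 1/p_exit", {
  reg <- synth_regime("vessel", p_exit_squeeze = 0.5)
  s <- simulate_sf_series(reg, 1e5, seed = 11)
  runs <- rle(s$squeezing)
  mean_run <- mean(runs$lengths[runs$values])
  expect_lt(abs(mean_run - 2) / 2, 0.05)
  # stationary occupancy p_enter/(p_enter+p_exit) at long horizon
  occ <- reg$p_enter_squeeze / (reg$p_enter_squeeze + reg$p_exit_squeeze)
  expect_lt(abs(mean(s$squeezing) - occ) / occ, 0.02)
})

test_that("vessel regime out-squeezes open regime in every seeded replicate", {
  v <- synth_regime("vessel"); o <- synth_regime("open")
  wins <- vapply(1:60, function(rep) {
    pv <- mean(vapply(1:20, function(i) {
      mean(simulate_sf_series(v, 40, seed = rep * 1000 + i)$squeezing)
    }, numeric(1)))
    po <- mean(vapply(1:20, function(i) {
      mean(simulate_sf_series(o, 40, seed = rep * 1000 + 500 + i)$squeezing)
    }, numeric(1)))
    pv > po
  }, logical(1))
  expect_true(all(wins))
})

test_that("series and movies are bit-identical under identical seed and config", {
  reg <- synth_regime("vessel")
  expect_identical(simulate_sf_series(reg, 100, seed = 5),
                   simulate_sf_series(reg, 100, seed = 5))
  cfg <- synth_movie_config(reg, n_nuclei = 2, n_frames = 5,
                            field_px = c(96, 128), z_slices = 3, seed = 8)
  m1 <- render_movie(cfg); m2 <- render_movie(cfg)
  expect_identical(m1$data, m2$data)
  expect_identical(m1$ground_truth, m2$ground_truth)
})

test_that("adding a nucleus does not perturb existing trajectories", {
  reg <- synth_regime("open")
  c2 <- synth_movie_config(reg, n_nuclei = 2, n_frames = 8,
                           field_px = c(128, 128), z_slices = 3,
                           noise_gaussian_sd = 0, noise_poisson = FALSE,
                           seed = 21)
  c3 <- synth_movie_config(reg, n_nuclei = 3, n_frames = 8,
                           field_px = c(192, 128), z_slices = 3,
                           noise_gaussian_sd = 0, noise_poisson = FALSE,
                           seed = 21)
  g2 <- render_movie(c2)$ground_truth
  g3 <- render_movie(c3)$ground_truth
  g2sub <- g2[g2$nucleus_id <= 2, c("frame", "nucleus_id", "x_px", "sf_true")]
  g3sub <- g3[g3$nucleus_id <= 2, c("frame", "nucleus_id", "x_px", "sf_true")]
  expect_equal(g2sub, g3sub)
})

test_that("rendered static disk has the analytic area and nucleus count", {
  reg <- synth_regime("open", speed_um_per_min = 0, p_enter_squeeze = 0,
                      sf_jitter_sd = 0, sf_baseline = 0,
                      nucleus_diameter_um = 6)
  cfg <- synth_movie_config(reg, n_nuclei = 1, n_frames = 2,
                            pixel_size_um = 0.3, field_px = c(96, 96),
                            z_slices = 3, noise_gaussian_sd = 0,
                            noise_poisson = FALSE, seed = 2)
  mv <- render_movie(cfg)
  expect_equal(nrow(mv$ground_truth), 2 * 1)
  expect_true(all(table(mv$ground_truth$frame) == cfg$n_nuclei))
  mask <- mv$data[1, 2, , ] > 100
  r_px <- 3 / 0.3 # radius 10 px
  expect_lt(abs(sum(mask) - pi * r_px^2) / (pi * r_px^2), 0.02)
})

test_that("rendered ellipse reproduces the 2:1 moment axis ratio", {
  reg <- synth_regime("vessel", p_enter_squeeze = 0,
                      sf_baseline = 1 / 3, sf_jitter_sd = 0,
                      speed_um_per_min = 0)
  # SF = 1/3 corresponds to a/b = 2
  cfg <- synth_movie_config(reg, n_nuclei = 1, n_frames = 2,
                            field_px = c(96, 128), z_slices = 3,
                            noise_gaussian_sd = 0, noise_poisson = FALSE,
                            seed = 9)
  mv <- render_movie(cfg)
  mask <- mv$data[1, 2, , ] > 100
  sh <- measure_shape(mask)
  ratio <- sh$long_axis_um / sh$short_axis_um
  expect_lt(abs(ratio - 2) / 2, 0.05)
})

test_that("rendered-mask SF tracks true SF within 0.05 for 12+ px nuclei", {
  mv <- test_movie() # noise-free vessel movie, 5 um (~17 px) nuclei
  gt <- mv$ground_truth
  for (i in seq_len(nrow(gt))) {
    mask <- mv$data[gt$frame[i] + 1, 2, , ] > 100
    # isolate this nucleus: window around its centroid
    lab <- segment_nuclei(array(mask * 1, dim = c(1, dim(mask))),
                          0.5, 10)
    ids <- unique(lab[lab > 0])
    best <- NULL; bestd <- Inf
    for (id in ids) {
      m2 <- project_mask_2d(lab, id)
      co <- which(m2, arr.ind = TRUE)
      d <- (mean(co[, 2]) - 1 - gt$x_px[i])^2 + (mean(co[, 1]) - 1 - gt$y_px[i])^2
      if (d < bestd) { bestd <- d; best <- m2 }
    }
    expect_lt(abs(measure_shape(best)$sf - gt$sf_true[i]), 0.05)
  }
})

test_that("oversized nuclei are rejected", {
  reg <- synth_regime("vessel", nucleus_diameter_um = 8, channel_width_um = 6)
  cfg <- synth_movie_config(reg, n_nuclei = 1, n_frames = 2, seed = 1)
  expect_error(render_movie(cfg), "channel")
  reg2 <- synth_regime("open", nucleus_diameter_um = 40)
  cfg2 <- synth_movie_config(reg2, n_nuclei = 2, n_frames = 2,
                             field_px = c(64, 64), seed = 1)
  expect_error(render_movie(cfg2), "field")
})

test_that("lamina fixture: exact ratio recovery and intensity-scale invariance", {
  fx1 <- make_lamina_fixture(ratio = 1, n_hemocyte = 3, n_epithelial = 3,
                             noise_sd = 0, seed = 1)
  rec1 <- measure_lamina_fixture(fx1)
  hm <- mean(rec1$corrected[rec1$cell_class == "hemocyte"])
  em <- mean(rec1$corrected[rec1$cell_class == "epithelial"])
  expect_equal(hm, em, tolerance = 1e-12)

  fx <- make_lamina_fixture(ratio = 0.25, n_hemocyte = 4, n_epithelial = 4,
                            noise_sd = 0, seed = 1)
  rec <- normalize_to_reference(measure_lamina_fixture(fx), "epithelial")
  expect_equal(mean(rec$normalized[rec$cell_class == "hemocyte"]), 0.25,
               tolerance = 1e-12)

  # doubling every pixel (background included) leaves the ratio unchanged
  fxn <- make_lamina_fixture(ratio = 0.4, n_hemocyte = 6, n_epithelial = 6,
                             noise_sd = 5, seed = 7)
  ratio_of <- function(stack) {
    fx2 <- list(stack = stack, nuclei = fxn$nuclei)
    r <- normalize_to_reference(measure_lamina_fixture(fx2), "epithelial")
    mean(r$normalized[r$cell_class == "hemocyte"])
  }
  r1 <- ratio_of(fxn$stack)
  r2 <- ratio_of(fxn$stack * 2)
  expect_lt(abs(r2 - r1) / r1, 0.01)
})

test_that("transit movie fixture encodes the requested geometry", {
  # no dilation: relative change 1 within 2%
  tm0 <- make_vessel_transit_movie(5, 1, 4, seed = 1)
  m0 <- measure_transit(tm0)
  expect_lt(abs(m0$relative_change - 1), 0.02)

  tm <- make_vessel_transit_movie(5, 1.2, 4, seed = 2, pixel_size_um = 0.3)
  m <- measure_transit(tm)
  expect_lt(abs(m$d_during_um - 6), 0.3) # within 1 px
  expect_equal(tm$truth$residual_um,
               tm$truth$d_during_um - tm$truth$d_nucleus_um)
  expect_error(make_vessel_transit_movie(5, 1.1, 7, seed = 1), "wider")
  expect_error(make_vessel_transit_movie(5, 0.9, 4, seed = 1), ">= 1")
})
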