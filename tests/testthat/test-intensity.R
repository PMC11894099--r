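test_that("rim intensity follows the stated background-subtraction arithmetic", {
  # three background rows at 10, 12, 14; rim row at 100
  img <- matrix(0, 20, 30)
  img[5, ] <- 100
  img[10, ] <- 10; img[12, ] <- 12; img[14, ] <- 14
  stack <- array(rep(img, 3), c(20, 30, 3)) |> aperm(c(3, 1, 2))
  rim <- tibble::tibble(x0 = 2, y0 = 4, x1 = 27, y1 = 4)
  bg <- tibble::tibble(x0 = 2, y0 = c(9, 11, 13), x1 = 27, y1 = c(9, 11, 13))
  rec <- rim_intensity(stack, rim, bg)
  expect_equal(rec$raw, 100)
  expect_equal(rec$background, 12)
  expect_equal(rec$corrected, 88)
  expect_false(rec$negative_flag)

  # uniform image: corrected 0
  uni <- array(37, c(3, 20, 30))
  rec2 <- rim_intensity(uni, rim, bg[1, ])
  expect_equal(rec2$corrected, 0)

  # lines outside the image are rejected
  bad <- tibble::tibble(x0 = -5, y0 = 2, x1 = 40, y1 = 2)
  expect_error(rim_intensity(stack, bad, bg), "outside")
  expect_error(rim_intensity(stack, rim[0, ], bg), "at least one")
})

test_that("corrected rim ratio of lamina fixtures is exact without noise", {
  fx <- make_lamina_fixture(ratio = 0.25, n_hemocyte = 5, n_epithelial = 5,
                            noise_sd = 0, seed = 3)
  rec <- measure_lamina_fixture(fx)
  h <- mean(rec$corrected[rec$cell_class == "hemocyte"])
  e <- mean(rec$corrected[rec$cell_class == "epithelial"])
  expect_equal(h / e, 0.25, tolerance = 1e-12)
})

test_that("normalisation to the reference class divides by its age-group mean", {
  rec <- tibble::tibble(
    cell_class = c("hemocyte", "hemocyte", "epithelial", "epithelial"),
    age_group = "40h",
    corrected = c(20, 30, 90, 110)
  )
  out <- normalize_to_reference(rec, "epithelial")
  expect_equal(out$normalized[1:2], c(0.2, 0.3))
  # reference records normalise to mean 1 within the age group
  expect_equal(mean(out$normalized[out$cell_class == "epithelial"]), 1)
  # global rescaling leaves normalised values unchanged
  out2 <- normalize_to_reference(
    dplyr::mutate(rec, corrected = corrected * 7.3), "epithelial")
  expect_equal(out$normalized, out2$normalized)
  # missing reference group warns and yields NA
  rec2 <- dplyr::filter(rec, cell_class == "hemocyte")
  expect_warning(out3 <- normalize_to_reference(rec2, "epithelial"),
                 "no reference")
  expect_true(all(is.na(out3$normalized)))
})

test_that("corrected intensities are invariant to uniform offsets", {
  fx <- make_lamina_fixture(ratio = 0.5, n_hemocyte = 3, n_epithelial = 3,
                            noise_sd = 0, seed = 2)
  rec <- measure_lamina_fixture(fx)
  fx_off <- list(stack = fx$stack + 55.5, nuclei = fx$nuclei)
  rec_off <- measure_lamina_fixture(fx_off)
  expect_equal(rec$corrected, rec_off$corrected, tolerance = 1e-9)
})

test_that("lamin stoichiometry table reproduces hand-computed ratios", {
  rec <- tibble::tibble(
    age_group = rep(c("18h", "75h"), each = 6),
    channel = rep(rep(c("dLamC", "dLamB"), each = 3), 2),
    corrected = c(9, 10, 11, 9, 10, 11,   # 18h: both medians 10
                  9, 10, 11, 19, 20, 21)  # 75h: C 10, B 20
  )
  tab <- lamin_stoichiometry(rec, "dLamC", "dLamB", reference_age = "18h")
  expect_equal(tab$ratio[tab$age_group == "18h"], 1)
  expect_equal(tab$ratio[tab$age_group == "75h"], 0.5)
  # identical channels: ratio identically 1
  rec2 <- dplyr::mutate(rec, corrected = rep(c(9, 10, 11), 4))
  tab2 <- lamin_stoichiometry(rec2)
  expect_true(all(tab2$ratio == 1))
  # swapping which channel is numerator inverts the ratio
  tab3 <- lamin_stoichiometry(rec, "dLamB", "dLamC", reference_age = "18h")
  expect_equal(tab3$ratio, 1 / tab$ratio)
  # uniform-across-age scaling of one channel cancels out
  rec4 <- dplyr::mutate(rec, corrected = ifelse(channel == "dLamC",
                                                corrected * 3, corrected))
  tab4 <- lamin_stoichiometry(rec4)
  expect_equal(tab4$ratio, tab$ratio)
  expect_error(lamin_stoichiometry(dplyr::filter(rec, channel == "dLamC")),
               "both channels")
})

test_that("3D nuclear means subtract the negative control", {
  labs <- array(0L, c(3, 10, 10))
  labs[1:2, 2:4, 2:4] <- 1L
  labs[2:3, 7:9, 7:9] <- 2L
  vol <- array(10, c(3, 10, 10))
  vol[labs == 1L] <- 50
  vol[labs == 2L] <- 80
  rec <- nuclear_mean_3d(labs, vol, negative_control_mean = 10)
  expect_equal(rec$corrected, c(40, 70))
  expect_false(any(rec$negative_flag))
  # uniform field: corrected v - c, flagged when negative
  rec2 <- nuclear_mean_3d(labs, array(5, c(3, 10, 10)), 10)
  expect_equal(rec2$corrected, c(-5, -5))
  expect_true(all(rec2$negative_flag))
  # control equal to the background mean of an empty volume: ~0
  empty <- array(0L, c(2, 5, 5))
  expect_equal(nrow(nuclear_mean_3d(empty, array(10, c(2, 5, 5)), 10)), 0)
})

test_that("phagosome counts and areas respect the cell mask", {
  cell <- matrix(TRUE, 12, 12)
  ph <- matrix(0L, 12, 12)
  ph[2, 2:3] <- 1L          # 2 px
  ph[5, 4:6] <- 2L          # 3 px
  ph[9:10, 8:9] <- 3L       # 4 px (one outside below)
  ph[9, 10] <- 3L           # 5th px of blob 3
  res <- quantify_phagosomes(cell, ph, pixel_size_um = 1)
  expect_equal(res$count, 3)
  expect_equal(res$total_area_um2, 10)
  # blob partially outside the cell mask: only in-mask pixels counted
  cell2 <- cell; cell2[, 8:12] <- FALSE
  res2 <- quantify_phagosomes(cell2, ph, pixel_size_um = 1)
  expect_equal(res2$count, 2)
  expect_equal(res2$total_area_um2, 5)
  # empty label image
  res3 <- quantify_phagosomes(cell, matrix(0L, 12, 12), 1)
  expect_equal(res3$count, 0)
  expect_equal(res3$total_area_um2, 0)
})

test_that("instability rate is a percentage of the hemocyte total", {
  expect_equal(instability_rate(2, 50), 4)
  expect_equal(instability_rate(0, 50), 0)
  expect_equal(instability_rate(50, 50), 100)
  expect_error(instability_rate(1, 0), "positive")
  expect_error(instability_rate(-1, 10), "non-negative")
})
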