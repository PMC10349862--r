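test_that("sampling a constant image gives constant samples", {
  m <- adc_map(matrix(725, 20, 20))
  l <- loi(c(5, 3), c(5, 13), "s1", "l1")   # length 10 px along a row
  prof <- sample_loi(m, l)
  expect_length(prof$values, 11L)
  expect_true(all(prof$values == 725))
  expect_equal(prof$positions_px, 0:10)
  expect_equal(prof$positions_mm, (0:10) * 0.8)
})

test_that("bilinear interpolation is exact for linear fields", {
  # midpoint between two pixels
  m <- adc_map(cbind(rep(400, 4), rep(600, 4), rep(800, 4)))
  l <- loi(c(1.5, 0), c(1.5, 1), "s1", "l1")
  prof <- sample_loi(m, l, step_px = 0.5)
  expect_equal(prof$values[2], 500)
  # the plane value = 10*row + col is reproduced along a diagonal
  vals <- outer(0:19, 0:19, function(r, c) 10 * r + c + 100)
  mp <- adc_map(vals)
  ld <- loi(c(2, 3), c(15, 17), "s1", "l2")
  p <- sample_loi(mp, ld, step_px = 0.7)
  u <- (ld$point_F - ld$point_A) / sqrt(sum((ld$point_F - ld$point_A)^2))
  expected <- 10 * (2 + p$positions_px * u[1]) +
    (3 + p$positions_px * u[2]) + 100
  expect_lt(max(abs(p$values - expected)), 1e-9)
})

test_that("sampling is translation invariant and reverses with the LOI", {
  set.seed(1)
  base <- matrix(runif(900, 500, 1500), 30, 30)
  big <- matrix(0, 40, 40)
  big[1:30, 1:30] <- base
  shifted <- matrix(0, 40, 40)
  shifted[6:35, 9:38] <- base
  l1 <- loi(c(3, 4), c(20, 25))
  l2 <- loi(c(8, 12), c(25, 33))  # same LOI shifted by (5, 8)
  p1 <- sample_loi(adc_map(big), l1)
  p2 <- sample_loi(adc_map(shifted), l2)
  expect_lt(max(abs(p1$values - p2$values)), 1e-10)

  fwd <- sample_loi(adc_map(big), loi(c(2, 2), c(2, 12)))
  rev <- sample_loi(adc_map(big), loi(c(2, 12), c(2, 2)))
  expect_lt(max(abs(fwd$values - rev(rev$values))), 1e-9)
})

test_that("out-of-bounds sampling is an error, not clamping", {
  m <- adc_map(matrix(725, 8, 8))
  expect_error(sample_loi(m, loi(c(1, 1), c(9, 9))), "bounds")
})

test_that("exclusion-mask crossings are reported with their positions", {
  vals <- matrix(725, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[8:12, 8:12] <- TRUE  # ventricle-like block
  m <- adc_map(vals, exclusion_mask = mask)
  l <- loi(c(10, 1), c(10, 18))
  expect_warning(sample_loi(m, l), "exclusion mask")
  rep <- validate_loi(m, l)
  expect_equal(rep$issue, "mask_crossing")
  expect_match(rep$detail, "\\[")
  clean <- validate_loi(adc_map(vals), loi(c(2, 2), c(2, 10)))
  expect_equal(nrow(clean), 0L)
})

test_that("near-contralateral LOI pairs are flagged", {
  m <- adc_map(matrix(725, 40, 40))
  l1 <- loi(c(20, 2), c(20, 20), "s1", "l1")           # direction +col
  ang <- 175 * pi / 180                                # 175 deg from +col
  l2 <- loi(c(20, 20) - 15 * c(sin(ang), cos(ang)), c(20, 20), "s1", "l2")
  rep <- validate_loi(m, list(l1, l2))
  expect_true("contralateral" %in% rep$issue)
  l3 <- loi(c(2, 20), c(20, 20), "s1", "l3")           # 90 deg apart
  expect_equal(nrow(validate_loi(m, list(l1, l3))), 0L)
})

test_that("axis-aligned phantom sampling matches the analytic profile", {
  gm <- generate_map(default_gbm_spec(noise_sd = 0), "GBM",
                     angles_deg = c(0, 90))
  for (k in 1:2) {
    prof <- sample_loi(gm$map, gm$lois[[k]])
    expect_lt(max(abs(prof$values - gm$truths[[k]]$clean_values)), 1)
  }
})

test_that("band averaging reduces to the single ray on smooth fields", {
  m <- adc_map(outer(0:19, 0:19, function(r, c) 10 * r + c + 100))
  l <- loi(c(5, 5), c(5, 14))
  single <- sample_loi(m, l)
  band <- sample_loi(m, l, band_px = 3L)
  expect_lt(max(abs(single$values - band$values)), 1e-9)
  expect_error(sample_loi(m, l, band_px = 2L), "odd")
})
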