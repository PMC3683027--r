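test_that("air fraction is the clamped linear densitometry estimate", {
  cal <- hu_calibration(-781, -122)
  v <- image_volume(array(rep(c(-781, -122, -451.5, -1000, 200, -500), 2),
                          c(3, 2, 2)))
  b <- air_fraction(v, cal)
  expect_equal(b[1, 1, 1], 1)            # I = hu_air
  expect_equal(b[2, 1, 1], 0)            # I = hu_tissue
  expect_equal(b[3, 1, 1], 0.5)          # midpoint
  expect_equal(b[1, 2, 1], 1)            # below hu_air: clamped
  expect_equal(b[2, 2, 1], 0)            # above hu_tissue: clamped
  expect_true(all(b >= 0 & b <= 1))
  # monotone non-increasing in intensity
  xs <- seq(-900, 100, by = 50)
  bx <- air_fraction(image_volume(array(rep(xs, 4), c(length(xs), 2, 2))), cal)
  expect_true(all(diff(bx[, 1, 1]) <= 0))
  proc <- image_volume(array(0, c(4, 4, 4)), intensity_kind = "processed")
  expect_error(air_fraction(proc, cal), "raw HU")
  expect_error(hu_calibration(-100, -500), "hu_air")
  expect_error(hu_calibration(-1200, -122), "range")
})

test_that("HU calibration recovers known two-mode mixtures", {
  set.seed(42)
  errs_air <- errs_tis <- numeric(20)
  for (r in 1:20) {
    mu_l <- runif(1, -700, -600); sd_l <- runif(1, 40, 80)
    mu_t <- runif(1, -140, -100); sd_t <- runif(1, 20, 40)
    n <- c(24, 24, 24)
    msk <- array(FALSE, n); msk[seq_len(6000)] <- TRUE
    arr <- array(0, n)
    arr[msk] <- rnorm(6000, mu_l, sd_l)
    arr[!msk] <- rnorm(prod(n) - 6000, mu_t, sd_t)
    cal <- calibrate_hu(image_volume(arr), lung_mask(msk))
    expect_identical(cal$provenance, "fitted")
    errs_air[r] <- cal$hu_air - (mu_l - 2 * sd_l)
    errs_tis[r] <- cal$hu_tissue - mu_t
  }
  expect_lt(stats::median(abs(errs_air)), 10)
  expect_lt(stats::median(abs(errs_tis)), 5)
})

test_that("calibration rejects unimodal histograms", {
  set.seed(1)
  arr <- array(rnorm(8000, -400, 50), c(20, 20, 20))
  msk <- array(TRUE, c(20, 20, 20))
  expect_error(calibrate_hu(image_volume(arr), lung_mask(msk)),
               "two detectable modes")
})

test_that("joint ventilation vanishes for identical images under identity", {
  spec <- quiet_spec()
  ph <- make_phantom(spec)
  g <- lungvent:::grid_of(ph$volume)
  zero <- displacement_field(array(0, c(g$dims, 3)), g$spacing, g$origin)
  jv <- jacobian_to_voxels(deformation_gradient(zero))
  cal <- hu_calibration(spec$hu_air, spec$hu_tissue)
  jm <- joint_ventilation_map(jv, ph$volume, ph$volume, zero, cal, ph$mask)
  expect_true(all(abs(jm$values) < 1e-12))
})

test_that("joint and kinematic estimates agree on tissue-conserving pairs", {
  spec <- phantom_spec(dims = c(48, 48, 48), noise_sd = 0)
  ph <- make_phantom(spec)
  g <- lungvent:::grid_of(ph$volume)
  f <- compose_fields(
    scale_field(1.6^(1 / 3), g),
    analytic_field("sinusoidal", amplitude = rep(0.05, 3),
                   wavenumber = rep(2 * pi / (0.15 * 47), 3)))
  fld <- evaluate_field(f, g)
  src <- deform_phantom(ph, f, "tissue_conserving", noise_sd = 0)
  jv <- jacobian_to_voxels(deformation_gradient(fld))
  cal <- hu_calibration(spec$hu_air, spec$hu_tissue)
  km <- kinematic_volume_map(jv, ph$mask)
  jm <- joint_ventilation_map(jv, ph$volume, src, fld, cal, ph$mask)
  sel <- ph$mask$data
  rel <- sqrt(mean((jm$values - km$values)[sel]^2)) /
    sqrt(mean(km$values[sel]^2))
  expect_lt(rel, 0.02)
  expect_lt(abs(total_ventilation(jm) - total_ventilation(km)) /
              total_ventilation(km), 0.02)
})

test_that("a collapsed region shows reduced joint ventilation but full kinematic", {
  spec <- quiet_spec(dims = c(32, 32, 32), vessel_count = 0, airway = FALSE)
  ph <- make_phantom(spec)
  g <- lungvent:::grid_of(ph$volume)
  f <- scale_field(1.2^(1 / 3), g)
  coll <- list(center = spec$lung_center, semi_axes = spec$semi_axes * 0.35)
  src <- deform_phantom(ph, f, "tissue_conserving", collapsed_region = coll,
                        noise_sd = 0)
  fld <- evaluate_field(f, g)
  jv <- jacobian_to_voxels(deformation_gradient(fld))
  cal <- hu_calibration(spec$hu_air, spec$hu_tissue)
  km <- kinematic_volume_map(jv, ph$mask)
  jm <- joint_ventilation_map(jv, ph$volume, src, fld, cal, ph$mask)
  ctr <- round(spec$lung_center / spec$spacing) + 1
  v0 <- spec$spacing^3 / 1000
  # kinematic sees the deformation: (J - 1) V0
  expect_equal(km$values[ctr[1], ctr[2], ctr[3]], 0.2 * v0, tolerance = 0.01)
  # joint sees only the air actually admitted: (J - 1) beta V0
  expect_equal(jm$values[ctr[1], ctr[2], ctr[3]], 0.2 * 0.5 * v0,
               tolerance = 0.05)
  expect_lt(jm$values[ctr[1], ctr[2], ctr[3]],
            km$values[ctr[1], ctr[2], ctr[3]])
})

test_that("coefficient of variation follows its closed forms", {
  msk <- lung_mask(array(TRUE, c(4, 4, 4)))
  vals <- array(3, c(4, 4, 4))
  m <- structure(list(values = vals, mask = msk, method = "kinematic",
                      flagged = array(FALSE, c(4, 4, 4))),
                 class = "ventilation_map")
  expect_equal(coefficient_of_variation(m), 0)
  vals2 <- array(rep(c(1, 3), each = 32), c(4, 4, 4))
  m2 <- m; m2$values <- vals2
  expect_equal(coefficient_of_variation(m2), 0.5)
  m3 <- m2; m3$values <- 7 * vals2
  expect_equal(coefficient_of_variation(m3), 0.5)
  m4 <- m2; m4$values <- vals2 - 2
  expect_error(coefficient_of_variation(m4), "zero mean")
  # flagged voxels are excluded
  m5 <- m2
  m5$flagged <- array(rep(c(TRUE, FALSE), each = 32), c(4, 4, 4))
  expect_equal(coefficient_of_variation(m5), 0)
})
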