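test_that("misregistration bounds equal the grid nearest-neighbor distances", {
  b <- misregistration_bounds()
  expect_equal(unname(b["in_plane"]), sqrt(2), tolerance = 1e-12)
  expect_equal(unname(b["three_d"]), sqrt(3), tolerance = 1e-12)
})

test_that("the misregistration rule matches its z-slice and in-plane clauses", {
  expect_false(classify_misregistered(c(0, 0, 0)))
  expect_true(classify_misregistered(c(0, 0, 2)))      # two slices in z
  expect_false(classify_misregistered(c(0, 0, 1)))     # one slice: allowed
  expect_false(classify_misregistered(c(1, 1, 0)))     # equals sqrt(2): allowed
  expect_true(classify_misregistered(c(1.001, 1.001, 0)))
  expect_true(classify_misregistered(c(1.5, 0, 0)))
  # consistency with the 3D bound: any displacement beyond sqrt(3) is flagged
  set.seed(8)
  for (r in 1:200) {
    d <- runif(3, -2.5, 2.5)
    if (sqrt(sum(d^2)) > sqrt(3) + 1e-9)
      expect_true(classify_misregistered(d))
  }
})

test_that("TRE summaries follow hand-computed values", {
  lt <- landmark_set(1:3, rbind(c(5, 5, 5), c(10, 10, 10), c(2, 2, 2)))
  expect_identical(compute_tre(lt, lt)$mean, 0)
  lw <- landmark_set(1:3, rbind(c(6, 6, 6), c(10, 10, 11), c(2, 4, 2)))
  rep <- compute_tre(lt, lw)
  expect_equal(rep$table$tre_voxels, c(sqrt(3), 1, 2), tolerance = 1e-12)
  expect_equal(rep$mean, mean(c(sqrt(3), 1, 2)), tolerance = 1e-12)
  # population SD on a two-landmark case: TRE 1 and 2 -> mean 1.5, SD 0.5
  r2 <- compute_tre(landmark_set(1:2, rbind(c(0, 0, 0), c(5, 5, 5))),
                    landmark_set(1:2, rbind(c(1, 0, 0), c(5, 7, 5))))
  expect_equal(r2$mean, 1.5)
  expect_equal(r2$sd, 0.5)
  # id matching is by id, not order
  lw_shuffled <- lw[c(3, 1, 2), ]
  expect_equal(compute_tre(lt, lw_shuffled)$mean, rep$mean)
  expect_error(compute_tre(lt, landmark_set(4:6, as.matrix(lt[, 2:4]))),
               "id mismatch")
})

test_that("PV assembly orders phases and takes pressure from the trace", {
  tr <- simulate_ventilator_trace(0.325, 8, hysteresis_width = 0.2)
  totals <- data.frame(time_ms = tr$time_ms, volume_mL = tr$volume_mL)
  pv <- assemble_pv(totals, tr)
  expect_s3_class(pv, "pv_curve")
  expect_identical(nrow(pv), 11L)
  expect_true(attr(pv, "closed"))
  expect_identical(pv$volume_mL[1], 0)
  # monotone inhale limb under linear inflation
  expect_true(all(diff(pv$volume_mL[pv$phase == "inhale"]) > 0))
  expect_error(assemble_pv(totals[c(2, 1, 3:11), ], tr), "increasing")
  expect_error(assemble_pv(totals[1:2, ], tr), ">= 3")
  bad <- totals; bad$time_ms[5] <- 450
  expect_error(assemble_pv(bad, tr), "not found")
})

test_that("compliance is the OLS slope over the selected limb", {
  p <- seq(0, 8, length.out = 9)
  pv <- structure(data.frame(pressure_cmH2O = c(p, rev(p)[-1]),
                             volume_mL = c(0.325 * p, 0.325 * rev(p)[-1]),
                             phase = rep(c("inhale", "exhale"), c(9, 8))),
                  class = c("pv_curve", "data.frame"))
  expect_equal(compliance(pv, "inhale"), 0.325, tolerance = 1e-12)
  expect_equal(compliance(pv, "both"), 0.325, tolerance = 1e-12)
  # constant volume -> slope 0; offsets leave the slope unchanged
  pv0 <- pv; pv0$volume_mL <- 1
  expect_equal(compliance(pv0, "inhale"), 0, tolerance = 1e-12)
  pv1 <- pv; pv1$volume_mL <- pv$volume_mL + 5
  expect_equal(compliance(pv1, "inhale"), 0.325, tolerance = 1e-12)
  pvc <- pv; pvc$pressure_cmH2O <- 3
  expect_error(compliance(pvc, "inhale"), "constant pressure")
})

test_that("hysteresis area follows the shoelace formula and orientation", {
  # rectangle loop: deltaP = 8, limbs offset by 0.5 mL -> area 4
  rect <- structure(data.frame(
    pressure_cmH2O = c(0, 8, 8, 0),
    volume_mL = c(0, 0, 0.5, 0.5),
    phase = c("inhale", "inhale", "exhale", "exhale")),
    class = c("pv_curve", "data.frame"))
  expect_equal(hysteresis_area(rect), 4, tolerance = 1e-12)
  rev_rect <- rect[c(4, 3, 2, 1), ]
  rev_rect$phase <- rev(rect$phase)
  expect_equal(hysteresis_area(rev_rect), -4, tolerance = 1e-12)
  # identical limbs: zero area
  tr0 <- simulate_ventilator_trace(0.325, 8, hysteresis_width = 0)
  pv0 <- assemble_pv(data.frame(time_ms = tr0$time_ms,
                                volume_mL = tr0$volume_mL), tr0)
  expect_equal(hysteresis_area(pv0), 0, tolerance = 1e-12)
  # simulated loop area is positive (exhale above inhale)
  tr <- simulate_ventilator_trace(0.325, 8, hysteresis_width = 0.3)
  pv <- assemble_pv(data.frame(time_ms = tr$time_ms,
                               volume_mL = tr$volume_mL), tr)
  expect_gt(hysteresis_area(pv), 0)
  # crossing limbs warn
  cross <- structure(data.frame(
    pressure_cmH2O = c(0, 2, 6, 8, 8, 6, 2, 0),
    volume_mL = c(0, 0.5, 0.8, 1, 1, 0.9, 0.2, 0),
    phase = rep(c("inhale", "exhale"), each = 4)),
    class = c("pv_curve", "data.frame"))
  expect_warning(hysteresis_area(cross), "cross")
})

test_that("field-based TRE measures landmark endpoint error", {
  spec <- quiet_spec(dims = c(32, 32, 32), vessel_count = 3)
  ph <- make_phantom(spec)
  g <- lungvent:::grid_of(ph$volume)
  f <- scale_field(1.1, g)
  truth <- evaluate_field(f, g)
  rep0 <- landmark_tre_fields(ph$landmarks, f, truth)
  expect_lt(rep0$mean, 1e-9)
  # a field off by one voxel everywhere scores TRE 1
  off <- truth
  off$vectors[, , , 1] <- off$vectors[, , , 1] + spec$spacing
  rep1 <- landmark_tre_fields(ph$landmarks, f, off)
  expect_equal(rep1$mean, 1, tolerance = 1e-6)
})

test_that("click-error simulation returns a small-displacement report", {
  spec <- phantom_spec(dims = c(32, 32, 32), seed = 5)
  ph <- make_phantom(spec)
  rep <- click_error_report(ph$volume, ph$landmarks, sigma = 1)
  expect_s3_class(rep, "tre_report")
  expect_true(all(is.finite(rep$table$tre_voxels)))
  expect_lt(rep$mean, 2)
})
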