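test_that("parenchyma follows the air-fraction mixture and is uniform when quiet", {
  spec <- quiet_spec(vessel_count = 0, airway = FALSE)
  ph <- make_phantom(spec)
  # voxels well inside the lung, away from the smoothed boundary
  core <- lungvent:::morph_op(ph$mask$data, 3, "erode")
  vals <- ph$volume$data[core]
  expect_equal(unique(round(vals, 9)), -451.5)   # -122 - 0.5 * (-122 + 781)
  # far field is pure tissue; the partial-volume skirt stays within the
  # parenchyma-tissue range
  expect_identical(ph$volume$data[1, 1, 1], -122)
  expect_true(all(ph$volume$data >= -451.5 - 1e-9 &
                  ph$volume$data <= -122 + 1e-9))
})

test_that("mask volume matches the analytic ellipsoid volume at fine grids", {
  spec <- quiet_spec(dims = c(64, 64, 64))
  ph <- make_phantom(spec)
  v_analytic <- 4 / 3 * pi * prod(spec$semi_axes)
  v_mask <- sum(ph$mask$data) * spec$spacing^3
  expect_lt(abs(v_mask - v_analytic) / v_analytic, 0.02)
})

test_that("phantom generation is bit-reproducible and fails on overflowing shapes", {
  s <- phantom_spec(dims = c(24, 24, 24), seed = 7)
  a <- make_phantom(s); b <- make_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$landmarks, b$landmarks)
  expect_error(make_phantom(phantom_spec(dims = c(24, 24, 24),
                                         semi_axes = c(3, 3, 3))),
               "not contained")
})

test_that("evaluate_field matches closed forms", {
  g <- test_grid(12)
  expect_true(all(evaluate_field(analytic_field("identity"), g)$vectors == 0))
  ctr <- c(1, 1, 1)
  A <- diag(3) * 1.1
  u <- evaluate_field(analytic_field("affine", matrix = A, center = ctr), g)
  X <- lungvent:::voxel_centers(g)
  expect_equal(matrix(u$vectors, ncol = 3), 0.1 * sweep(X, 2, ctr),
               tolerance = 1e-12)
  fs <- analytic_field("sinusoidal", amplitude = c(0.3, 0, 0),
                       wavenumber = c(2.1, 0, 0))
  us <- evaluate_field(fs, g)
  expect_equal(us$vectors[, , , 1],
               array(0.3 * sin(2.1 * X[, 1]), g$dims), tolerance = 1e-12)
  expect_true(all(us$vectors[, , , 2:3] == 0))
  expect_error(lungvent:::field_u_points(structure(list(kind = "bogus",
    params = list()), class = "analytic_field"), X), "unknown")
})

test_that("analytic Jacobians agree with symbolic forms and finite differences", {
  g <- test_grid(16)
  expect_equal(analytic_jacobian(analytic_field("identity"), g),
               array(1, g$dims))
  A <- diag(c(1.1, 1.1, 1.1))
  expect_equal(analytic_jacobian(analytic_field("affine", matrix = A,
                                                center = c(0, 0, 0)), g),
               array(1.331, g$dims), tolerance = 1e-12)
  fs <- analytic_field("sinusoidal", amplitude = c(0.25, 0, 0),
                       wavenumber = c(1.8, 0, 0))
  X <- lungvent:::voxel_centers(g)
  expect_equal(analytic_jacobian(fs, g),
               array(1 + 0.25 * 1.8 * cos(1.8 * X[, 1]), g$dims),
               tolerance = 1e-12)
  # radial inflation: central-difference determinant of the evaluated map
  fr <- analytic_field("radial_inflation", amplitude = 0.08,
                       center = c(1.1, 1.1, 1.1), scale = 0.8)
  h <- 1e-5
  p0 <- matrix(c(0.8, 0.9, 1.0), 1, 3)
  Jnum <- det(vapply(1:3, function(d) {
    e <- rep(0, 3); e[d] <- h
    xp <- p0 + rep(e, each = 1); xm <- p0 - rep(e, each = 1)
    (as.numeric(xp + lungvent:::field_u_points(fr, xp)) -
     as.numeric(xm + lungvent:::field_u_points(fr, xm))) / (2 * h)
  }, numeric(3)))
  expect_equal(as.numeric(lungvent:::field_jacobian_points(fr, p0)), Jnum,
               tolerance = 1e-6)
})

test_that("finite-difference J of evaluated fields converges at second order", {
  err_at <- function(n) {
    g <- test_grid(n, spacing = 0.15 * 16 / n)
    fs <- analytic_field("sinusoidal", amplitude = rep(0.06, 3),
                         wavenumber = rep(2 * pi / (0.15 * 15), 3))
    jv <- jacobian_to_voxels(deformation_gradient(evaluate_field(fs, g)))
    ja <- analytic_jacobian(fs, g)
    interior <- array(FALSE, g$dims)
    interior[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- TRUE
    max(abs(jv$J - ja)[interior])
  }
  e1 <- err_at(16); e2 <- err_at(32)
  expect_gt(e1 / e2, 3.5)
})

test_that("tissue-conserving deformation satisfies the conservation identity", {
  spec <- quiet_spec(vessel_count = 0, airway = FALSE)
  ph <- make_phantom(spec)
  g <- lungvent:::grid_of(ph$volume)
  f <- scale_field(1.2^(1 / 3), g)
  src <- deform_phantom(ph, f, "tissue_conserving", noise_sd = 0)
  beta_f <- attr(src, "beta_clean")
  # uniform J: (1 - beta_f) * J = 1 - beta_r at corresponding points; with
  # an affine map the preimage of every voxel has the analytic beta
  X <- lungvent:::field_preimage(f, lungvent:::voxel_centers(g))
  beta_r <- lungvent:::phantom_beta(spec, ph$geometry, X)
  expect_equal((1 - as.numeric(beta_f)) * 1.2, 1 - beta_r, tolerance = 1e-12)
  # derived values: beta_r = 0.5, J = 1.2 -> beta_f = 0.58333, I_f = -506.4
  core <- lungvent:::morph_op(ph$mask$data, 4, "erode")
  expect_equal(mean(beta_f[core]), 1 - 0.5 / 1.2, tolerance = 1e-6)
  expect_equal(mean(src$data[core]), -122 - (1 - 0.5 / 1.2) * 659,
               tolerance = 1e-3)
})

test_that("identity and J = 1 deformations leave the phantom unchanged", {
  spec <- quiet_spec(vessel_count = 2)
  ph <- make_phantom(spec)
  for (mode in c("passive", "tissue_conserving")) {
    out <- deform_phantom(ph, analytic_field("identity"), mode, noise_sd = 0)
    expect_equal(out$data, ph$volume$data, tolerance = 1e-9)
  }
  # rotation: J = 1 everywhere, intensities transported unchanged
  th <- 0.2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  fr <- analytic_field("affine", matrix = R,
                       center = spec$lung_center)
  out <- deform_phantom(ph, fr, "tissue_conserving", noise_sd = 0)
  bf <- attr(out, "beta_clean")
  X <- lungvent:::field_preimage(fr, lungvent:::voxel_centers(
    lungvent:::grid_of(ph$volume)))
  expect_equal(as.numeric(bf),
               lungvent:::phantom_beta(spec, ph$geometry, X),
               tolerance = 1e-9)
  expect_error(deform_phantom(ph, analytic_field("sinusoidal",
    amplitude = c(0.4, 0, 0), wavenumber = c(2 * pi / (0.15 * 8), 0, 0)),
    "tissue_conserving"), "J <= 0")
})

test_that("collapsed regions deform without admitting air", {
  spec <- quiet_spec(dims = c(32, 32, 32), vessel_count = 0, airway = FALSE)
  ph <- make_phantom(spec)
  g <- lungvent:::grid_of(ph$volume)
  f <- scale_field(1.2^(1 / 3), g)
  coll <- list(center = spec$lung_center, semi_axes = spec$semi_axes * 0.3)
  src <- deform_phantom(ph, f, "tissue_conserving", collapsed_region = coll,
                        noise_sd = 0)
  bf <- attr(src, "beta_clean")
  ctr_idx <- round(spec$lung_center / spec$spacing) + 1
  expect_equal(bf[ctr_idx[1], ctr_idx[2], ctr_idx[3]], 0.5, tolerance = 1e-6)
  # outside the collapsed region the conserving update applies
  edge_idx <- ctr_idx + c(round(0.7 * spec$semi_axes[1] / spec$spacing), 0, 0)
  expect_equal(bf[edge_idx[1], ctr_idx[2], ctr_idx[3]], 1 - 0.5 / 1.2,
               tolerance = 1e-3)
})

test_that("simulated ventilator traces form closed physiological loops", {
  tr0 <- simulate_ventilator_trace(0.325, 8, hysteresis_width = 0)
  inh <- tr0[tr0$phase == "inhale", ]
  exh <- tr0[tr0$phase == "exhale", ]
  expect_equal(stats::approx(inh$pressure_cmH2O, inh$volume_mL, xout = 4)$y,
               stats::approx(exh$pressure_cmH2O, exh$volume_mL, xout = 4)$y,
               tolerance = 1e-12)
  # C * deltaP arithmetic: span 0.325 * 8 = 2.6 mL
  expect_equal(diff(range(tr0$volume_mL)), 2.6, tolerance = 1e-12)
  tr <- simulate_ventilator_trace(0.325, 8, hysteresis_width = 0.3)
  expect_equal(tr$volume_mL[1], tr$volume_mL[nrow(tr)], tolerance = 1e-12)
  expect_equal(tr$pressure_cmH2O[1], tr$pressure_cmH2O[nrow(tr)],
               tolerance = 1e-12)
  # exhale limb above inhale at mid-pressure
  expect_gt(stats::approx(tr$pressure_cmH2O[tr$phase == "exhale"],
                          tr$volume_mL[tr$phase == "exhale"], xout = 4)$y,
            stats::approx(tr$pressure_cmH2O[tr$phase == "inhale"],
                          tr$volume_mL[tr$phase == "inhale"], xout = 4)$y)
})

test_that("phantom studies reproduce their own trace through ground truth", {
  spec <- quiet_spec(dims = c(32, 32, 32))
  st <- phantom_study(spec, n_phases = 5)
  expect_length(st$sources, 5)
  g <- lungvent:::grid_of(st$target)
  v0 <- spec$spacing^3 / 1000
  msk <- st$phantom$mask$data
  pts <- lungvent:::voxel_centers(g)[as.numeric(msk) > 0, ]
  for (p in c(2, 4)) {
    J <- lungvent:::field_jacobian_points(st$fields[[p]], pts)
    expect_equal(sum(J - 1) * v0, st$trace$volume_mL[p], tolerance = 1e-8)
  }
})
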