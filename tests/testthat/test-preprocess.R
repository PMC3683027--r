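test_that("gaussian filter has unit DC gain and contracts noise variance", {
  const <- image_volume(array(7, c(12, 12, 12)))
  expect_equal(gaussian_filter(const, 1)$data, const$data, tolerance = 1e-12)
  # unit impulse: kernel mass 1
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  sm <- gaussian_filter(image_volume(imp), 1)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  set.seed(3)
  noise <- image_volume(array(rnorm(12^3), c(12, 12, 12)))
  expect_lt(stats::var(as.numeric(gaussian_filter(noise, 1)$data)),
            stats::var(as.numeric(noise$data)))
})

test_that("region growing recovers the phantom lung and respects connectivity", {
  spec <- quiet_spec(dims = c(32, 32, 32))
  ph <- make_phantom(spec)
  seed <- round(spec$lung_center / spec$spacing) - c(3, 0, 0)
  m <- grow_lung_mask(ph$volume, seed, upper_threshold = -280)
  m <- refine_mask(m, 2, 2)
  dice <- 2 * sum(m$data & ph$mask$data) / (sum(m$data) + sum(ph$mask$data))
  expect_gte(dice, 0.99)
  # seed in background
  expect_error(grow_lung_mask(ph$volume, c(1, 1, 1), -280), "background")
  # two disjoint low regions: grow from one only
  a <- array(0, c(16, 16, 16))
  a[3:5, 3:5, 3:5] <- -500
  a[12:14, 12:14, 12:14] <- -500
  v <- image_volume(a)
  m2 <- grow_lung_mask(v, c(3, 3, 3), -100)
  expect_identical(sum(m2$data), 27L)
  expect_false(any(m2$data[12:14, 12:14, 12:14]))
})

test_that("morphological closing fills holes and is gentle on convex masks", {
  m <- array(FALSE, c(16, 16, 16))
  m[5:12, 5:12, 5:12] <- TRUE
  m[8, 8, 8] <- FALSE                      # interior hole
  r <- refine_mask(lung_mask(m), 1, 1)
  expect_true(r$data[8, 8, 8])
  # sphere: closing changes at most a thin boundary layer
  g <- test_grid(24)
  X <- lungvent:::voxel_centers(g)
  sph <- array(sqrt(rowSums(sweep(X, 2, rep(1.725, 3))^2)) <= 0.9, g$dims)
  rs <- refine_mask(lung_mask(sph), 1, 1)
  expect_lt(sum(xor(rs$data, sph)) / sum(sph), 0.15)
  # empty mask stays empty
  e <- refine_mask(lung_mask(array(FALSE, c(8, 8, 8))), 1, 1)
  expect_false(any(e$data))
})

test_that("background saturation is mask-local and idempotent", {
  spec <- quiet_spec()
  ph <- make_phantom(spec)
  allm <- lung_mask(array(TRUE, spec$dims), spec$spacing)
  expect_equal(saturate_background(ph$volume, allm)$data, ph$volume$data)
  none <- lung_mask(array(FALSE, spec$dims), spec$spacing)
  sat0 <- saturate_background(ph$volume, none)
  expect_identical(unique(as.numeric(sat0$data)), max(ph$volume$data))
  s1 <- saturate_background(ph$volume, ph$mask)
  expect_identical(s1$data[ph$mask$data], ph$volume$data[ph$mask$data])
  s2 <- saturate_background(s1, ph$mask)
  expect_identical(s2$data, s1$data)
})

test_that("bone removal replaces every supra-threshold voxel with tissue-like noise", {
  spec <- phantom_spec(dims = c(32, 32, 32), noise_sd = 0,
                       parenchyma_texture_sd = 0, bone = TRUE)
  ph <- make_phantom(spec)
  expect_true(any(ph$volume$data >= 300))
  out <- remove_bone(ph$volume, 300, fill_mean = -120, fill_sd = 25, seed = 2)
  expect_true(all(out$data < 300))
  sel <- ph$volume$data >= 300
  expect_lt(abs(mean(out$data[sel]) + 120), 3 * 25 / sqrt(sum(sel)) + 1.5)
  # no bone -> identity
  quiet <- make_phantom(quiet_spec())
  expect_identical(remove_bone(quiet$volume, 300)$data, quiet$volume$data)
  # deterministic under seed
  out2 <- remove_bone(ph$volume, 300, fill_mean = -120, fill_sd = 25, seed = 2)
  expect_identical(out$data, out2$data)
})

test_that("histogram equalization is monotone and near-uniform inside the mask", {
  set.seed(5)
  a <- array(sample(c(10, 50), 4096, replace = TRUE, prob = c(0.3, 0.7)),
             c(16, 16, 16))
  a <- a + rnorm(length(a), 0, 0.01)
  v <- image_volume(a)
  m <- lung_mask(array(TRUE, dim(a)))
  eq <- equalize_histogram(v, m)
  # two-value image 30%/70%: the low cluster lands at the 30% point of the
  # output range and the high cluster at the top (CDF within one bin of
  # uniform)
  expect_lt(abs(mean(eq$data <= 500) - 0.3), 1 / 256 + 0.01)
  expect_equal(max(eq$data), 1000, tolerance = 1e-9)
  # monotone: ranks preserved
  ord <- order(a)
  expect_true(all(diff(eq$data[ord]) >= -1e-9))
  # constant inside mask: warning, unchanged
  cv <- image_volume(array(1, c(8, 8, 8)))
  expect_warning(out <- equalize_histogram(cv, lung_mask(array(TRUE, c(8, 8, 8)))),
                 "constant")
  expect_identical(out$data, cv$data)
})

test_that("prepare composes its stages and leaves grid metadata intact", {
  spec <- phantom_spec(dims = c(32, 32, 32), seed = 3)
  ph <- make_phantom(spec)
  expect_identical(prepare(ph$volume, "A"), ph$volume)
  params <- list(threshold = -280,
                 seed_index = round(spec$lung_center / spec$spacing))
  pd <- prepare(ph$volume, "D", params)
  # level D = saturate(grow+refine(gaussian(vol)))
  sm <- gaussian_filter(ph$volume, 1)
  mk <- refine_mask(grow_lung_mask(sm, params$seed_index, -280), 2, 2)
  expect_equal(pd$data, saturate_background(sm, mk)$data, tolerance = 1e-12)
  pe <- prepare(ph$volume, "E", params)
  expect_identical(dim(pe$data), spec$dims)
  expect_identical(pe$spacing, spec$spacing)
  # level E in-mask histogram near-uniform: quartiles of the output spread
  x <- pe$data[pe$mask$data]
  qs <- as.numeric(stats::quantile(x, c(0.25, 0.5, 0.75))) / 1000
  expect_true(all(abs(qs - c(0.25, 0.5, 0.75)) < 0.05))
  # masking is idempotent: level C twice equals once
  pc <- prepare(ph$volume, "C", params)
  pc2 <- prepare(pc, "C", utils::modifyList(params, list(mask = pc$mask)))
  expect_equal(pc2$data, pc$data, tolerance = 1e-12)
})
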