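#' Phantom specification
#'
#' Describes a synthetic lung-CT test object: an ellipsoidal low-HU lung
#' compartment with embedded tissue-HU vessels and an air-HU airway, a
#' tissue-HU background, optional bone arcs, and additive Gaussian HU noise.
#' Parenchymal intensity follows the linear air-fraction mixture
#' \eqn{I = HU_{tiss} - \beta (HU_{tiss} - HU_{air})}. All structure edges are
#' smoothed over 2 voxels, the effective reconstruction point-spread width at
#' this resolution: a reconstructed CT image is band-limited, so sharper
#' edges would be aliased on the sampling grid and no interpolant could
#' resolve them.
#'
#' @param dims Grid size (>= 16 per axis).
#' @param spacing Voxel edge (mm).
#' @param lung_center Ellipsoid center in mm (default: grid center).
#' @param semi_axes Ellipsoid semi-axes in mm (default: 0.40/0.30/0.30 of the
#'   grid extent).
#' @param parenchyma_air_fraction Air fraction \eqn{\beta_r} of the parenchyma
#'   in the reference (FRC) state; default 0.5, typical of rodent lung at end
#'   expiration.
#' @param hu_air,hu_tissue Calibration HU values; defaults -781 / -122, the
#'   in-lung air and soft-tissue values of healthy ventilated rats on
#'   micro-CT (air in the living lung reads well above -1000 HU because of
#'   shading, aliasing and beam-hardening artifacts).
#' @param vessel_count Number of vessel branches grown inside the lung.
#' @param vessel_radius Vessel tube radius (mm).
#' @param airway Logical: include a central air-filled airway tube.
#' @param bone Logical: include high-HU rib-like arcs outside the lung.
#' @param hu_bone HU of bone structures.
#' @param parenchyma_texture_sd SD (in air-fraction units) of a band-limited
#'   random texture superposed on the parenchymal air fraction (default 0.06,
#'   about 40 HU of structured contrast): unresolved vasculature and acinar
#'   structure give real parenchyma a fine texture that registration relies
#'   on, and a featureless parenchyma would make histogram equalization
#'   amplify pure noise instead. The texture is a fixed sum of random-phase
#'   cosines (wavelengths 4-12 voxels), so it is evaluable at arbitrary
#'   points and deforms consistently.
#' @param noise_sd SD of additive Gaussian HU noise (default 20, typical
#'   parenchymal noise at this resolution).
#' @param seed RNG seed; phantom generation is bit-reproducible given the seed.
#' @return A list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(dims = c(64, 64, 64), spacing = 0.15,
                         lung_center = NULL, semi_axes = NULL,
                         parenchyma_air_fraction = 0.5,
                         hu_air = -781, hu_tissue = -122,
                         vessel_count = 5, vessel_radius = 2.2 * spacing,
                         airway = TRUE, bone = TRUE, hu_bone = 1200,
                         parenchyma_texture_sd = 0.06,
                         noise_sd = 20, seed = 1) {
  dims <- as.integer(dims)
  if (any(dims < 16L)) stop("phantom_spec: dims must be >= 16 per axis")
  if (parenchyma_air_fraction <= 0 || parenchyma_air_fraction >= 1)
    stop("phantom_spec: parenchyma_air_fraction must be in (0, 1)")
  if (hu_air >= hu_tissue) stop("phantom_spec: hu_air must be < hu_tissue")
  extent <- (dims - 1) * spacing
  structure(list(
    dims = dims, spacing = spacing,
    lung_center = lung_center %||% (extent / 2),
    semi_axes = semi_axes %||% (extent * c(0.40, 0.30, 0.30)),
    parenchyma_air_fraction = parenchyma_air_fraction,
    hu_air = hu_air, hu_tissue = hu_tissue,
    vessel_count = vessel_count, vessel_radius = vessel_radius,
    airway = airway, bone = bone, hu_bone = hu_bone,
    parenchyma_texture_sd = parenchyma_texture_sd,
    noise_sd = noise_sd, seed = seed), class = "phantom_spec")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Interface transition width (mm): the effective reconstruction PSF. Two
# voxels, the narrowest edge a band-limited reconstruction can carry.
psf_edge <- function(spec) 2 * spec$spacing

# Quintic smoothstep of a signed distance (mm): 0 outside, 1 inside,
# transition over `edge` mm centered on the interface.
soft_in <- function(signed_dist, edge) {
  t <- pmin(pmax(signed_dist / edge + 0.5, 0), 1)
  t * t * (3 - 2 * t)
}

# Distance (mm) from points (n x 3) to a segment p0-p1.
dist_to_segment <- function(pts, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  w1 <- pts[, 1] - p0[1]; w2 <- pts[, 2] - p0[2]; w3 <- pts[, 3] - p0[3]
  t <- pmin(pmax((w1 * v[1] + w2 * v[2] + w3 * v[3]) / L2, 0), 1)
  sqrt((w1 - t * v[1])^2 + (w2 - t * v[2])^2 + (w3 - t * v[3])^2)
}

# Grow a deterministic vessel tree inside the ellipsoid. Returns segments
# (list of p0, p1, radius) and branch points (junctions), all in mm.
grow_vessel_tree <- function(spec) {
  c0 <- spec$lung_center; ax <- spec$semi_axes
  hilum <- c0 + c(0.85 * ax[1], 0, 0)
  segs <- list()
  branch_pts <- list()
  if (spec$vessel_count > 0) {
    segs <- list(list(p0 = hilum, p1 = c0, radius = spec$vessel_radius * 1.3))
    for (b in seq_len(spec$vessel_count)) {
      parent <- segs[[1 + (b - 1L) %% length(segs)]]
      t <- 0.35 + 0.5 * stats::runif(1)
      bp <- parent$p0 + t * (parent$p1 - parent$p0)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      len <- (0.35 + 0.25 * stats::runif(1)) * min(ax)
      endp <- bp + len * dir
      # keep the branch inside the ellipsoid (retract if necessary)
      e <- function(p) sum(((p - c0) / ax)^2)
      while (e(endp) > 0.55 && len > 0.05 * min(ax)) {
        len <- 0.8 * len
        endp <- bp + len * dir
      }
      segs[[length(segs) + 1L]] <- list(p0 = bp, p1 = endp,
                                        radius = spec$vessel_radius)
      branch_pts[[length(branch_pts) + 1L]] <- bp
    }
  }
  list(segments = segs,
       branch_points = if (length(branch_pts)) do.call(rbind, branch_pts)
                       else matrix(numeric(0), 0, 3))
}

# Band-limited parenchymal texture: a fixed sum of random-phase cosines with
# wavelengths of 4-12 voxels (within the PSF band limit), zero mean, total SD
# spec$parenchyma_texture_sd in air-fraction units. Deterministic given the
# phantom seed; evaluable at arbitrary points so deformed phantoms carry the
# same (advected) texture.
make_parenchyma_texture <- function(spec, n_modes = 60) {
  if (spec$parenchyma_texture_sd <= 0) return(NULL)
  dirs <- matrix(stats::rnorm(3 * n_modes), n_modes, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  wl <- stats::runif(n_modes, 4, 12) * spec$spacing
  K <- dirs * (2 * pi / wl)
  phi <- stats::runif(n_modes, 0, 2 * pi)
  amp <- abs(stats::rnorm(n_modes))
  # sd of sum of independent-phase cosines: sqrt(sum(amp^2) / 2)
  amp <- amp * spec$parenchyma_texture_sd / sqrt(sum(amp^2) / 2)
  list(K = K, phi = phi, amp = amp)
}

texture_at <- function(tex, pts) {
  if (is.null(tex)) return(0)
  as.numeric(cos(sweep(pts %*% t(tex$K), 2, tex$phi, "+")) %*% tex$amp)
}

# Structure weights (all in [0,1]) of the phantom model at arbitrary mm
# points. Shared by image generation and by analytic deformation.
phantom_weights <- function(spec, geo, pts) {
  edge <- psf_edge(spec)
  c0 <- spec$lung_center; ax <- spec$semi_axes
  e <- sqrt(((pts[, 1] - c0[1]) / ax[1])^2 + ((pts[, 2] - c0[2]) / ax[2])^2 +
            ((pts[, 3] - c0[3]) / ax[3])^2)
  r_eff <- 1 / sqrt(mean(1 / ax^2))
  w_lung <- soft_in((1 - e) * r_eff, edge)
  w_vessel <- rep(0, nrow(pts))
  for (s in geo$segments) {
    d <- dist_to_segment(pts, s$p0, s$p1)
    w_vessel <- pmax(w_vessel, soft_in(s$radius - d, edge))
  }
  w_air <- rep(0, nrow(pts))
  if (isTRUE(spec$airway)) {
    aw0 <- c0 + c(0.95 * ax[1], 0, 0)
    aw1 <- c0 + c(0.15 * ax[1], 0, 0)
    d <- dist_to_segment(pts, aw0, aw1)
    w_air <- soft_in(1.4 * spec$vessel_radius - d, edge)
  }
  w_bone <- rep(0, nrow(pts))
  if (isTRUE(spec$bone)) {
    ext <- (spec$dims - 1) * spec$spacing
    gc <- ext / 2
    rib_R <- min(1.18 * max(ax), min(gc[1], gc[2]) - 2.5 * spec$spacing)
    zs <- gc[3] + c(-0.55, 0, 0.55) * ax[3]
    rho <- sqrt((pts[, 1] - gc[1])^2 + (pts[, 2] - gc[2])^2)
    ang <- atan2(pts[, 2] - gc[2], pts[, 1] - gc[1])
    in_arc <- abs(ang) < 2.1
    for (z0 in zs) {
      d <- sqrt((rho - rib_R)^2 + (pts[, 3] - z0)^2)
      w_bone <- pmax(w_bone, soft_in(1.5 * spec$spacing - d, edge) * in_arc)
    }
  }
  list(lung = w_lung, vessel = w_vessel, air = w_air, bone = w_bone)
}

# Air fraction of the noiseless phantom at arbitrary mm points, optionally
# with the parenchymal reference value replaced (used by deform_phantom).
phantom_beta <- function(spec, geo, pts, parenchyma_beta = NULL) {
  w <- phantom_weights(spec, geo, pts)
  bpar <- parenchyma_beta %||% (spec$parenchyma_air_fraction +
                                  texture_at(geo$texture, pts))
  bpar <- pmin(pmax(bpar, 0.05), 0.95)
  beta <- bpar * w$lung * (1 - w$vessel)
  beta <- beta * (1 - w$air) + 1 * w$air * w$lung
  beta
}

# Noiseless intensity of the phantom at arbitrary mm points given an air
# fraction field.
phantom_intensity <- function(spec, geo, pts, beta) {
  w <- phantom_weights(spec, geo, pts)
  I <- spec$hu_tissue - beta * (spec$hu_tissue - spec$hu_air)
  I * (1 - w$bone) + spec$hu_bone * w$bone
}

#' Generate a synthetic lung-CT phantom
#'
#' Builds the reference (lowest-inflation) image: an ellipsoidal lung whose
#' parenchyma sits at the air-fraction mixture HU, vessels at tissue HU, an
#' optional central air-HU airway and optional bone arcs, plus seeded Gaussian
#' noise. The returned object carries the analytic model (geometry and clean
#' air-fraction field), the ground-truth lung mask, and landmarks at vessel
#' branch points.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class \code{phantom} with elements \code{volume}
#'   ([image_volume()]), \code{mask} ([lung_mask()]), \code{beta} (clean
#'   per-voxel air fraction), \code{landmarks} ([landmark_set()] at vessel
#'   branch points, 0-based voxel indices), \code{geometry}, and \code{spec}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ext_lo <- spec$lung_center - spec$semi_axes - 2 * spec$spacing
  ext_hi <- spec$lung_center + spec$semi_axes + 2 * spec$spacing
  if (any(ext_lo < 0) || any(ext_hi > (spec$dims - 1) * spec$spacing))
    stop("make_phantom: lung shape not contained in grid")
  grid <- list(dims = spec$dims, spacing = spec$spacing, origin = c(0, 0, 0))
  with_seed(spec$seed, {
    geo <- grow_vessel_tree(spec)
    geo$texture <- make_parenchyma_texture(spec)
    pts <- voxel_centers(grid)
    beta <- phantom_beta(spec, geo, pts)
    I <- phantom_intensity(spec, geo, pts, beta)
    if (spec$noise_sd > 0) I <- I + stats::rnorm(length(I), 0, spec$noise_sd)
    w <- phantom_weights(spec, geo, pts)
    vol <- image_volume(array(I, spec$dims), spacing = spec$spacing,
                        intensity_kind = "raw_hu")
    msk <- lung_mask(array(w$lung >= 0.5, spec$dims), spacing = spec$spacing)
    lm_ijk <- if (nrow(geo$branch_points) > 0)
      sweep(geo$branch_points, 2, c(0, 0, 0)) / spec$spacing
    else matrix(numeric(0), 0, 3)
    lms <- landmark_set(seq_len(nrow(lm_ijk)), lm_ijk, dims = spec$dims)
    structure(list(volume = vol, mask = msk,
                   beta = array(beta, spec$dims), landmarks = lms,
                   geometry = geo, spec = spec),
              class = "phantom")
  })
}

# --- Analytic deformation fields --------------------------------------------

#' Construct an analytic deformation field
#'
#' Closed-form displacement fields with exact Jacobians, used as ground truth
#' for the finite-element kinematics and for building deformed phantom images.
#' All fields use the pull-back convention x(X) = X + u(X) in mm.
#'
#' Kinds:
#' \describe{
#'   \item{identity}{u = 0, J = 1.}
#'   \item{affine}{u = (A - I)(X - center) + offset; J = det(A).}
#'   \item{radial_inflation}{x - center = lambda(r) (X - center) with
#'     lambda(r) = 1 + amplitude * exp(-r^2 / (2 scale^2));
#'     J = lambda^2 (lambda + r lambda').}
#'   \item{sinusoidal}{u_d = amplitude_d * sin(wavenumber_d * X_d + phase_d),
#'     each axis independent;
#'     J = prod_d (1 + a_d k_d cos(k_d X_d + phase_d)).}
#' }
#'
#' @param kind One of \code{"identity"}, \code{"affine"},
#'   \code{"radial_inflation"}, \code{"sinusoidal"}.
#' @param ... Parameters of the chosen kind: \code{matrix}, \code{offset},
#'   \code{center} (affine); \code{amplitude}, \code{center}, \code{scale}
#'   (radial); \code{amplitude}, \code{wavenumber}, \code{phase} length-3
#'   vectors (sinusoidal).
#' @return An object of class \code{analytic_field}.
#' @export
analytic_field <- function(kind = c("identity", "affine", "radial_inflation",
                                    "sinusoidal"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  if (kind == "affine") {
    p$matrix <- p$matrix %||% diag(3)
    p$offset <- p$offset %||% c(0, 0, 0)
    if (abs(det(p$matrix)) < 1e-12) stop("analytic_field: singular affine matrix")
    stopifnot(!is.null(p$center))
  } else if (kind == "radial_inflation") {
    stopifnot(!is.null(p$amplitude), !is.null(p$center), !is.null(p$scale))
  } else if (kind == "sinusoidal") {
    p$amplitude <- rep(p$amplitude %||% 0, length.out = 3)
    p$wavenumber <- rep(p$wavenumber %||% 0, length.out = 3)
    p$phase <- rep(p$phase %||% 0, length.out = 3)
  }
  structure(list(kind = kind, params = p), class = "analytic_field")
}

#' Compose analytic fields
#'
#' Applies fields in order: with two fields, x = X + u1(X) followed by
#' x' = x + u2(x). The composed Jacobian is the product of the factors'
#' Jacobians evaluated along the chain.
#'
#' @param ... \code{analytic_field} objects, applied left to right.
#' @return An \code{analytic_field} of kind \code{"composed"}.
#' @export
compose_fields <- function(...) {
  fields <- list(...)
  stopifnot(all(vapply(fields, inherits, TRUE, "analytic_field")))
  structure(list(kind = "composed", params = list(fields = fields)),
            class = "analytic_field")
}

# Displacement u (n x 3, mm) of an analytic field at arbitrary mm points.
field_u_points <- function(field, pts) {
  p <- field$params
  switch(field$kind,
    identity = matrix(0, nrow(pts), 3),
    affine = {
      d <- sweep(pts, 2, p$center)
      d %*% t(p$matrix - diag(3)) +
        matrix(p$offset, nrow(pts), 3, byrow = TRUE)
    },
    radial_inflation = {
      d <- sweep(pts, 2, p$center)
      r2 <- rowSums(d^2)
      lam <- 1 + p$amplitude * exp(-r2 / (2 * p$scale^2))
      d * (lam - 1)
    },
    sinusoidal = {
      cbind(p$amplitude[1] * sin(p$wavenumber[1] * pts[, 1] + p$phase[1]),
            p$amplitude[2] * sin(p$wavenumber[2] * pts[, 2] + p$phase[2]),
            p$amplitude[3] * sin(p$wavenumber[3] * pts[, 3] + p$phase[3]))
    },
    composed = {
      x <- pts
      for (f in p$fields) x <- x + field_u_points(f, x)
      x - pts
    },
    stop("unknown field kind: ", field$kind))
}

# Exact Jacobian determinant of an analytic field at arbitrary mm points.
field_jacobian_points <- function(field, pts) {
  p <- field$params
  switch(field$kind,
    identity = rep(1, nrow(pts)),
    affine = rep(det(p$matrix), nrow(pts)),
    radial_inflation = {
      d <- sweep(pts, 2, p$center)
      r <- sqrt(rowSums(d^2))
      g <- exp(-r^2 / (2 * p$scale^2))
      lam <- 1 + p$amplitude * g
      dlam <- -p$amplitude * r / p$scale^2 * g
      lam^2 * (lam + r * dlam)
    },
    sinusoidal = {
      (1 + p$amplitude[1] * p$wavenumber[1] *
         cos(p$wavenumber[1] * pts[, 1] + p$phase[1])) *
      (1 + p$amplitude[2] * p$wavenumber[2] *
         cos(p$wavenumber[2] * pts[, 2] + p$phase[2])) *
      (1 + p$amplitude[3] * p$wavenumber[3] *
         cos(p$wavenumber[3] * pts[, 3] + p$phase[3]))
    },
    composed = {
      J <- rep(1, nrow(pts))
      x <- pts
      for (f in p$fields) {
        J <- J * field_jacobian_points(f, x)
        x <- x + field_u_points(f, x)
      }
      J
    },
    stop("unknown field kind: ", field$kind))
}

#' Evaluate an analytic field on a grid
#'
#' @param field An [analytic_field()].
#' @param grid An [image_volume()], [lung_mask()] or a list with \code{dims},
#'   \code{spacing}, \code{origin}.
#' @return A [displacement_field()] sampled at voxel centers (mm).
#' @export
evaluate_field <- function(field, grid) {
  if (!is.list(grid) || is.null(grid$dims)) grid <- grid_of(grid)
  u <- field_u_points(field, voxel_centers(grid))
  displacement_field(array(u, c(grid$dims, 3)), spacing = grid$spacing,
                     origin = grid$origin)
}

#' Exact per-voxel Jacobian of an analytic field
#'
#' @inheritParams evaluate_field
#' @return 3D array of J at voxel centers.
#' @export
analytic_jacobian <- function(field, grid) {
  if (!is.list(grid) || is.null(grid$dims)) grid <- grid_of(grid)
  array(field_jacobian_points(field, voxel_centers(grid)), grid$dims)
}

# Preimage X of source voxel centers x under x = X + u(X), by fixed-point
# iteration (converges for the sub-voxel-gradient fields used here).
field_preimage <- function(field, pts, tol = 1e-10, maxit = 60) {
  X <- pts
  for (it in seq_len(maxit)) {
    Xn <- pts - field_u_points(field, X)
    if (max(abs(Xn - X)) < tol) return(Xn)
    X <- Xn
  }
  X
}

#' Deform a phantom image under a known field
#'
#' Builds the "source" (inflated) image corresponding to a reference phantom
#' and an analytic deformation field, so that warping the source back by the
#' field reproduces the reference. Two intensity models:
#' \describe{
#'   \item{passive}{a pure warp: intensities are transported unchanged.}
#'   \item{tissue_conserving}{local tissue volume is conserved, so the air
#'     fraction updates as \eqn{\beta_f = 1 - (1 - \beta_r)/J} and the
#'     intensity follows the linear HU mixture. This is the physics that makes
#'     intensity change consistent with local volume change.}
#' }
#'
#' @param target A \code{phantom} (preferred: intensities are evaluated from
#'   the analytic model, not interpolated).
#' @param field An [analytic_field()].
#' @param mode \code{"passive"} or \code{"tissue_conserving"}.
#' @param collapsed_region Optional list(center, semi_axes) in mm: inside this
#'   region the air fraction is held at its reference value even though the
#'   geometry deforms — emulating a collapsed airway whose territory moves but
#'   does not ventilate. Kinematic and intensity-joint ventilation maps
#'   disagree there by construction.
#' @param noise_sd Additive Gaussian HU noise on the output (default: the
#'   phantom spec's noise_sd).
#' @param seed Seed for the output noise.
#' @return An [image_volume()] on the same grid, with attribute
#'   \code{"beta_clean"} carrying the noiseless deformed air-fraction array.
#' @export
deform_phantom <- function(target, field, mode = c("tissue_conserving", "passive"),
                           collapsed_region = NULL, noise_sd = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "phantom"), inherits(field, "analytic_field"))
  spec <- target$spec
  grid <- grid_of(target$volume)
  pts <- voxel_centers(grid)
  X <- field_preimage(field, pts)
  beta_r <- phantom_beta(spec, target$geometry, X)
  if (mode == "tissue_conserving") {
    J <- field_jacobian_points(field, X)
    w <- phantom_weights(spec, target$geometry, X)
    if (any(J <= 0 & w$lung > 0.5))
      stop("deform_phantom: J <= 0 inside the lung (tissue_conserving)")
    beta_f <- 1 - (1 - beta_r) / J
    if (!is.null(collapsed_region)) {
      d <- sweep(X, 2, collapsed_region$center)
      e <- sqrt(rowSums(sweep(d, 2, collapsed_region$semi_axes, "/")^2))
      wc <- soft_in((1 - e) * min(collapsed_region$semi_axes),
                    psf_edge(spec))
      beta_f <- wc * beta_r + (1 - wc) * beta_f
    }
    beta_f <- pmin(pmax(beta_f, 0), 1)
  } else {
    beta_f <- beta_r
  }
  I <- phantom_intensity(spec, target$geometry, X, beta_f)
  nsd <- noise_sd %||% spec$noise_sd
  if (nsd > 0) {
    sd_seed <- seed %||% (spec$seed + 1L)
    I <- with_seed(sd_seed, I + stats::rnorm(length(I), 0, nsd))
  }
  out <- image_volume(array(I, grid$dims), spacing = grid$spacing,
                      origin = grid$origin, intensity_kind = "raw_hu")
  attr(out, "beta_clean") <- array(beta_f, grid$dims)
  out
}

#' Simulate a ventilator pressure-volume trace
#'
#' One breathing cycle sampled at \code{n_points} times: pressure ramps from 0
#' to \code{peak_pressure} over the inhale (400 ms) and back over the exhale
#' (600 ms). The inhale limb is \eqn{V = C P - (w/2)\sin(\pi P/P_{peak})},
#' the exhale limb the mirror image, giving a closed loop whose limbs are
#' separated by \code{hysteresis_width} mL at mid-pressure (exhale above
#' inhale, as in the lung).
#'
#' @param compliance Compliance C in mL/cmH2O.
#' @param peak_pressure Peak tracheal pressure (cmH2O); default 8, a typical
#'   ventilated-rat tidal excursion from ~0 cmH2O.
#' @param hysteresis_width Limb separation at mid-pressure (mL).
#' @param n_points Samples per cycle (>= 4); default 11.
#' @param inhale_ms,exhale_ms Phase durations (default 400/600 ms).
#' @return A [ventilator_trace()].
#' @export
simulate_ventilator_trace <- function(compliance, peak_pressure = 8,
                                      hysteresis_width = 0,
                                      n_points = 11,
                                      inhale_ms = 400, exhale_ms = 600) {
  stopifnot(compliance > 0, n_points >= 4)
  cycle <- inhale_ms + exhale_ms
  t <- seq(0, cycle, length.out = n_points)
  inhale <- t <= inhale_ms
  P <- ifelse(inhale, peak_pressure * t / inhale_ms,
              peak_pressure * (1 - (t - inhale_ms) / exhale_ms))
  bump <- sin(pi * P / peak_pressure)
  V <- compliance * P + ifelse(inhale, -1, 1) * hysteresis_width / 2 * bump
  ventilator_trace(t, P, V, ifelse(inhale, "inhale", "exhale"))
}

#' Generate a full multi-phase phantom study
#'
#' Emulates one 4D CT acquisition: a reference phantom at end expiration
#' (phase 1, the registration target), plus \code{n_phases - 1} source images
#' at the later time points of a simulated ventilator cycle. Each phase is a
#' tissue-conserving deformation of the reference by a uniform inflation about
#' the lung center (scaled so the lung's volume change tracks the ventilator
#' trace) composed with a small sinusoidal perturbation that gives the
#' B-spline registration stage something genuinely non-affine to recover.
#'
#' @param spec A [phantom_spec()].
#' @param n_phases Number of time points (default 11).
#' @param peak_jacobian Parenchymal volume ratio at peak inflation (default
#'   1.6: a rat tidal breath of ~2.6 mL on an FRC of ~4 mL).
#' @param peak_pressure Peak pressure, cmH2O.
#' @param hysteresis_frac Hysteresis width as a fraction of tidal volume.
#' @param perturb_amplitude Sinusoidal perturbation amplitude at peak, in
#'   voxels (default 0.3).
#' @return A list of class \code{phantom_study}: phantom, target, sources,
#'   fields (analytic), trace, and per-phase pressures/times.
#' @export
phantom_study <- function(spec, n_phases = 11, peak_jacobian = 1.6,
                          peak_pressure = 8, hysteresis_frac = 0.15,
                          perturb_amplitude = 0.3) {
  ph <- make_phantom(spec)
  v0_mL <- spec$spacing^3 / 1000
  V_lung <- sum(ph$mask$data) * v0_mL
  C_sim <- V_lung * (peak_jacobian - 1) / peak_pressure
  # short studies (< 4 phases) subsample a denser simulated cycle
  n_pts <- if (n_phases >= 4) n_phases else 2L * n_phases - 1L
  trace <- simulate_ventilator_trace(C_sim, peak_pressure,
                                     hysteresis_width = hysteresis_frac *
                                       C_sim * peak_pressure,
                                     n_points = n_pts)
  if (n_phases < 4) trace <- trace[seq(1L, n_pts, by = 2L), ]
  Vmax <- max(trace$volume_mL)
  # one wavelength across the lung per axis, phased so that J integrates to
  # ~1 over the lung: the perturbation redistributes volume without adding it
  k <- pi / spec$semi_axes
  phs <- -k * spec$lung_center
  fields <- vector("list", n_phases)
  sources <- vector("list", n_phases)
  grid <- list(dims = spec$dims, spacing = spec$spacing, origin = c(0, 0, 0))
  mask_pts <- voxel_centers(grid)[as.numeric(ph$mask$data) > 0, , drop = FALSE]
  n_mask <- nrow(mask_pts)
  for (p in seq_len(n_phases)) {
    V <- trace$volume_mL[p]
    amp <- perturb_amplitude * spec$spacing * (V / max(Vmax, .Machine$double.eps))
    sin_f <- analytic_field("sinusoidal", amplitude = rep(amp, 3),
                            wavenumber = k, phase = phs)
    # uniform inflation factor solved so that the composed field's Jacobian
    # summed over the mask reproduces the trace volume exactly:
    # s^3 * sum(J_sin) = n_mask + V / v0
    s <- ((n_mask + V / v0_mL) /
            sum(field_jacobian_points(sin_f, mask_pts)))^(1 / 3)
    aff <- analytic_field("affine", matrix = diag(3) * s,
                          center = spec$lung_center)
    fields[[p]] <- compose_fields(sin_f, aff)
    sources[[p]] <- if (p == 1L) ph$volume
      else deform_phantom(ph, fields[[p]], "tissue_conserving",
                          seed = spec$seed + p)
  }
  structure(list(phantom = ph, target = ph$volume, sources = sources,
                 fields = fields, trace = trace,
                 pressures = trace$pressure_cmH2O, times = trace$time_ms,
                 landmarks = ph$landmarks, spec = spec),
            class = "phantom_study")
}

#' Write a phantom study to a directory
#'
#' Emits phase volumes (NIfTI), ground-truth displacement fields (MetaImage),
#' the lung mask, the landmark CSV and the ventilator trace CSV.
#'
#' @param study A [phantom_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(study$sources)) {
    write_volume(study$sources[[p]],
                 file.path(dir, sprintf("phase_%02d.nii.gz", p)))
    fld <- evaluate_field(study$fields[[p]], grid_of(study$target))
    export_field(fld, file.path(dir, sprintf("field_%02d.mha", p)))
  }
  write_volume(study$phantom$mask, file.path(dir, "lung_mask.nii.gz"))
  write_landmarks(study$landmarks, file.path(dir, "landmarks.csv"))
  write_ventilator_trace(study$trace, file.path(dir, "ventilator.csv"))
  invisible(dir)
}
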