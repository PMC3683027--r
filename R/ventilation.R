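#' HU calibration
#'
#' Representative Hounsfield values for in-lung air and soft tissue.
#' Air inside a living rodent lung reads well above the nominal -1000 HU
#' because of shading, view aliasing and beam hardening, so calibration
#' against the image histogram (or a configured per-group pair) is required
#' before air fractions are computed.
#'
#' @param hu_air,hu_tissue Calibration values (HU), \code{hu_air < hu_tissue},
#'   both within [-1100, 200]. Defaults -781 / -122 (healthy control group).
#' @param provenance \code{"configured"} or \code{"fitted"}.
#' @return A list of class \code{hu_calibration}.
#' @export
hu_calibration <- function(hu_air = -781, hu_tissue = -122,
                           provenance = c("configured", "fitted")) {
  provenance <- match.arg(provenance)
  if (!(hu_air < hu_tissue)) stop("hu_calibration: hu_air must be < hu_tissue")
  if (hu_air < -1100 || hu_tissue > 200)
    stop("hu_calibration: values outside the plausible range [-1100, 200]")
  structure(list(hu_air = hu_air, hu_tissue = hu_tissue,
                 provenance = provenance), class = "hu_calibration")
}

# Smoothed histogram (1-HU bins, 10-HU moving-average smoothing) of a sample.
smoothed_hist <- function(x, smooth_hu = 10) {
  br <- seq(floor(min(x)) - 0.5, ceiling(max(x)) + 0.5, by = 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), length(br) - 1)
  k <- rep(1 / smooth_hu, smooth_hu)
  hs <- stats::filter(h, k, sides = 2)
  hs[is.na(hs)] <- 0
  list(mids = (br[-1] + br[-length(br)]) / 2, counts = as.numeric(hs),
       raw = h)
}

# Gaussian fit to a histogram peak: quadratic fit to log counts over the
# half-maximum region around the mode (a least-squares Gaussian fit).
fit_gaussian_peak <- function(mids, counts, mode_idx) {
  peak <- counts[mode_idx]
  half <- peak / 2
  lo <- mode_idx; while (lo > 1 && counts[lo - 1] > half) lo <- lo - 1
  hi <- mode_idx; while (hi < length(counts) && counts[hi + 1] > half) hi <- hi + 1
  sel <- lo:hi
  sel <- sel[counts[sel] > 0]
  if (length(sel) < 5)
    stop("calibrate_hu: Gaussian fit non-convergent (peak too narrow)")
  xm <- mids[sel]; yl <- log(counts[sel])
  co <- stats::coef(stats::lm(yl ~ xm + I(xm^2)))
  if (!is.finite(co[3]) || co[3] >= 0)
    stop("calibrate_hu: Gaussian fit non-convergent (non-concave peak)")
  sigma <- sqrt(-1 / (2 * co[3]))
  mu <- -co[2] / (2 * co[3])
  list(mu = mu, sigma = sigma)
}

#' Calibrate HU values from peak-inflation images
#'
#' Pools the highest-inflation volumes of a dose group, then: the tissue value
#' is the location of the tissue mode of the pooled (smoothed, 1-HU-binned)
#' histogram; the air value is \eqn{\mu - 2\sigma} of a Gaussian fitted to the
#' isolated lung (air-dominated) peak — the lowest HU value typically
#' expected in the group.
#'
#' @param volumes A single [image_volume()] or list of them (raw HU, highest
#'   inflation level).
#' @param masks Matching [lung_mask()] or list of them (isolates the lung
#'   peak).
#' @param min_separation Minimum HU distance between the lung and tissue modes
#'   for them to count as two detectable modes (default 150).
#' @return An [hu_calibration()] with \code{provenance = "fitted"} and
#'   attributes \code{lung_mu}, \code{lung_sigma}.
#' @export
calibrate_hu <- function(volumes, masks, min_separation = 150) {
  if (inherits(volumes, "image_volume")) volumes <- list(volumes)
  if (inherits(masks, "lung_mask")) masks <- list(masks)
  stopifnot(length(volumes) == length(masks), length(volumes) >= 1)
  lung_vals <- unlist(lapply(seq_along(volumes), function(i) {
    volumes[[i]]$data[masks[[i]]$data]
  }))
  all_vals <- unlist(lapply(volumes, function(v) as.numeric(v$data)))
  if (length(lung_vals) < 100)
    stop("calibrate_hu: too few in-mask voxels")
  hl <- smoothed_hist(lung_vals)
  lung_mode_idx <- which.max(hl$counts)
  lung_mode <- hl$mids[lung_mode_idx]
  ha <- smoothed_hist(all_vals)
  tiss_sel <- ha$mids > lung_mode + min_separation
  if (!any(tiss_sel) || max(ha$counts[tiss_sel]) < 0.05 * max(ha$counts))
    stop("calibrate_hu: fewer than two detectable modes in the pooled histogram")
  hu_tissue <- ha$mids[tiss_sel][which.max(ha$counts[tiss_sel])]
  fit <- fit_gaussian_peak(hl$mids, hl$counts, lung_mode_idx)
  hu_air <- fit$mu - 2 * fit$sigma
  out <- hu_calibration(hu_air, hu_tissue, provenance = "fitted")
  attr(out, "lung_mu") <- fit$mu
  attr(out, "lung_sigma") <- fit$sigma
  out
}

#' Per-voxel air fraction
#'
#' Linear CT-densitometry estimate
#' \eqn{\beta = (HU_{tiss} - I) / (HU_{tiss} - HU_{air})}, clamped to [0, 1]
#' (noisy voxels can fall outside the calibration range).
#'
#' @param vol An [image_volume()] with \code{intensity_kind = "raw_hu"}.
#' @param cal An [hu_calibration()].
#' @return 3D array of air fractions in [0, 1].
#' @export
air_fraction <- function(vol, cal) {
  stopifnot(inherits(cal, "hu_calibration"))
  if (!identical(vol$intensity_kind, "raw_hu"))
    stop("air_fraction: volume must carry raw HU intensities")
  b <- (cal$hu_tissue - vol$data) / (cal$hu_tissue - cal$hu_air)
  array(pmin(pmax(b, 0), 1), dim(vol$data))
}

#' Intensity-joint regional ventilation map
#'
#' Joint estimate combining the kinematic volume ratio with the change in
#' local air fraction read from the unprocessed images:
#' \deqn{rV_{joint} = V_0 (J \beta_f(T(\phi)) - \beta_r(\phi))}
#' where \eqn{\beta_f} is the floating image's air fraction sampled at the
#' warped location \eqn{T(\phi) = X + u(X)}. Unlike the purely kinematic
#' estimate, a region that deforms but does not admit air (e.g. distal to a
#' collapsed airway) correctly shows reduced ventilation.
#'
#' @param J_voxels Per-voxel Jacobian (array or [jacobian_to_voxels()] list).
#' @param vol_ref_raw,vol_float_raw Unprocessed (raw HU) reference and
#'   floating volumes.
#' @param field The [displacement_field()] (reference -> floating).
#' @param cal An [hu_calibration()].
#' @param mask A [lung_mask()] on the reference grid.
#' @param spacing Voxel spacing (mm).
#' @return A \code{ventilation_map} with \code{method = "joint"}.
#' @export
joint_ventilation_map <- function(J_voxels, vol_ref_raw, vol_float_raw, field,
                                  cal, mask, spacing = mask$spacing) {
  flagged <- NULL
  if (is.list(J_voxels)) { flagged <- J_voxels$flagged; J_voxels <- J_voxels$J }
  stopifnot_same_grid(vol_ref_raw, mask, "reference volume and mask")
  grid <- grid_of(vol_ref_raw)
  beta_r <- air_fraction(vol_ref_raw, cal)
  X <- voxel_centers(grid)
  u <- matrix(field$vectors, ncol = 3)
  idxf <- sweep(X + u, 2, grid$origin) / grid$spacing
  # tricubic sampling: the sampled intensity enters the estimate
  # quantitatively, and trilinear interpolation error at vessel and lung-edge
  # interfaces would dominate the joint-kinematic residual
  If <- sample_volume_cubic(vol_float_raw$data, idxf, cal$hu_tissue)
  beta_f <- pmin(pmax((cal$hu_tissue - If) / (cal$hu_tissue - cal$hu_air), 0), 1)
  v0_mL <- spacing^3 / 1000
  vals <- v0_mL * (J_voxels * array(beta_f, grid$dims) - beta_r)
  vals[!mask$data] <- 0
  structure(list(values = vals, mask = mask, method = "joint",
                 flagged = flagged %||% array(FALSE, grid$dims),
                 v0_mL = v0_mL),
            class = "ventilation_map")
}

#' Coefficient of variation of a ventilation map
#'
#' SD/mean over in-mask voxels (population SD; voxels flagged for folded
#' elements are excluded) — a global heterogeneity index that rises with
#' emphysematous destruction.
#'
#' @param map A \code{ventilation_map}.
#' @param mask Optional [lung_mask()] override.
#' @return Scalar CoV.
#' @export
coefficient_of_variation <- function(map, mask = NULL) {
  msk <- (mask %||% map$mask)$data & !map$flagged
  if (!any(msk)) stop("coefficient_of_variation: empty mask")
  x <- map$values[msk]
  m <- mean(x)
  if (abs(m) < .Machine$double.eps * 100 * max(1, max(abs(x))))
    stop("coefficient_of_variation: zero mean ventilation")
  sqrt(mean((x - m)^2)) / m
}
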