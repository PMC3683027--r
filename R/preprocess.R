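#' Gaussian smoothing
#'
#' Separable Gaussian filter with unit DC gain. "Radius 1" in the imaging-GUI
#' sense is interpreted as sigma = 1 voxel with a kernel truncated at 3 sigma;
#' edges are handled by renormalizing the kernel over in-image samples, which
#' preserves constants everywhere.
#'
#' @param vol An [image_volume()].
#' @param radius Gaussian sigma in voxels (> 0).
#' @return Smoothed [image_volume()] (same grid).
#' @export
gaussian_filter <- function(vol, radius = 1) {
  stopifnot(inherits(vol, "image_volume"), radius > 0)
  h <- max(1L, ceiling(3 * radius))
  off <- seq(-h, h)
  w <- exp(-off^2 / (2 * radius^2))
  w <- w / sum(w)
  a <- vol$data
  ones <- array(1, dim(a))
  for (axis in 1:3) {
    acc <- array(0, dim(a)); norm <- array(0, dim(a))
    for (m in seq_along(off)) {
      acc <- acc + w[m] * shift_axis(a, axis, off[m], pad = "value", value = 0)
      norm <- norm + w[m] * shift_axis(ones, axis, off[m], pad = "value", value = 0)
    }
    a <- acc / norm
  }
  out <- vol
  out$data <- a
  out
}

#' Grow a lung mask from a seed point
#'
#' 26-connected region growing: the connected component of voxels strictly
#' below \code{upper_threshold} that contains the seed.
#'
#' @param vol An [image_volume()].
#' @param seed_index 0-based integer voxel index (i, j, k) inside the lung.
#' @param upper_threshold HU threshold; defaults to the Otsu threshold of the
#'   volume (separating the low-HU lung from tissue).
#' @return A [lung_mask()].
#' @export
grow_lung_mask <- function(vol, seed_index, upper_threshold = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  upper_threshold <- upper_threshold %||% lung_threshold(vol$data)
  s <- as.integer(round(seed_index)) + 1L
  d <- dim(vol$data)
  if (any(s < 1L) || any(s > d))
    stop("grow_lung_mask: seed outside grid")
  if (vol$data[s[1], s[2], s[3]] >= upper_threshold)
    stop("grow_lung_mask: seed voxel is not below the threshold ",
         "(seed in background?)")
  cand <- vol$data < upper_threshold
  comp <- array(FALSE, d)
  comp[s[1], s[2], s[3]] <- TRUE
  frontier <- comp
  repeat {
    grown <- dilate26(frontier) & cand & !comp
    if (!any(grown)) break
    comp <- comp | grown
    frontier <- grown
  }
  if (sum(comp) < 2L) stop("grow_lung_mask: empty region grown from seed")
  lung_mask(comp, spacing = vol$spacing, origin = vol$origin)
}

# One 26-neighborhood dilation step (zero padding).
dilate26 <- function(m) {
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    s <- shift_axis(m, 1, dx, pad = "value", value = FALSE)
    s <- shift_axis(s, 2, dy, pad = "value", value = FALSE)
    s <- shift_axis(s, 3, dz, pad = "value", value = FALSE)
    out <- out | s
  }
  out
}

# Default lung threshold: the histogram valley between the two lowest
# substantial intensity modes (lung parenchyma vs soft tissue). Modes are
# local maxima of the smoothed 256-bin histogram with counts >= 5% of the
# dominant mode, so small populations (airway lumen, bone) do not register.
# Falls back to Otsu when fewer than two modes are detectable.
lung_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  hs <- as.numeric(stats::filter(h, rep(1 / 5, 5), sides = 2))
  hs[is.na(hs)] <- 0
  mids <- (br[-1] + br[-length(br)]) / 2
  n <- length(hs)
  is_peak <- hs >= c(-Inf, hs[-n]) & hs >= c(hs[-1], -Inf) & hs > 0
  peaks <- which(is_peak)
  # a substantial mode holds >= 2% of all voxels within +-25 HU of its
  # location — mass, not bin height, so a spread-out parenchymal mode is not
  # drowned out by a near-delta background spike
  if (length(peaks) > 0) {
    halfw <- max(1L, round(25 / diff(mids[1:2])))
    mass <- vapply(peaks, function(p)
      sum(h[max(1, p - halfw):min(n, p + halfw)]), numeric(1))
    peaks <- peaks[mass >= 0.02 * sum(h)]
  }
  # merge plateaus/adjacent detections closer than 10 bins
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) > 10)
    peaks <- peaks[keep]
  }
  if (length(peaks) < 2) return(otsu_threshold(x, nbins))
  lo <- peaks[1]; hi <- peaks[2]
  valley <- lo + which.min(hs[lo:hi]) - 1
  mids[valley]
}

# Otsu's threshold on a 256-bin histogram.
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

ball_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

morph_op <- function(m, r, op = c("dilate", "erode")) {
  op <- match.arg(op)
  offs <- ball_offsets(r)
  pad_val <- op == "erode"   # erosion pads with TRUE so borders are not eaten
  out <- if (op == "dilate") array(FALSE, dim(m)) else array(TRUE, dim(m))
  for (q in seq_len(nrow(offs))) {
    s <- shift_axis(m, 1, offs$dx[q], pad = "value", value = pad_val)
    s <- shift_axis(s, 2, offs$dy[q], pad = "value", value = pad_val)
    s <- shift_axis(s, 3, offs$dz[q], pad = "value", value = pad_val)
    out <- if (op == "dilate") out | s else out & s
  }
  out
}

#' Morphological mask refinement (closing)
#'
#' Dilation followed by erosion with ball structuring elements — fills missed
#' interior voxels and smooths the mask boundary.
#'
#' @param mask A [lung_mask()].
#' @param dilate_r,erode_r Ball radii in voxels (>= 1; default 2/2).
#' @return A refined [lung_mask()].
#' @export
refine_mask <- function(mask, dilate_r = 2, erode_r = 2) {
  stopifnot(inherits(mask, "lung_mask"), dilate_r >= 1, erode_r >= 1)
  m <- morph_op(mask$data, dilate_r, "dilate")
  m <- morph_op(m, erode_r, "erode")
  lung_mask(m, spacing = mask$spacing, origin = mask$origin)
}

#' Saturate everything outside the lung
#'
#' Sets voxels outside the mask to the maximum intensity found inside it —
#' the ceiling of the lung's own intensity range, as when a binary mask is
#' added to a display-windowed image. This removes the ribcage/heart
#' gradients that would otherwise anchor a non-rigid warp at the parenchymal
#' boundary, while keeping the saturation step commensurate with the in-lung
#' contrast (a bone-level saturation value would make the metric hostage to
#' one-voxel differences in the two images' segmented boundaries).
#'
#' @param vol An [image_volume()].
#' @param mask A [lung_mask()] on the same grid.
#' @return An [image_volume()] with \code{intensity_kind = "processed"}.
#' @export
saturate_background <- function(vol, mask) {
  stopifnot_same_grid(vol, mask, "volume and mask")
  out <- vol
  sat <- if (any(mask$data)) max(vol$data[mask$data]) else max(vol$data)
  out$data[!mask$data] <- sat
  out$intensity_kind <- "processed"
  out
}

#' Replace bone signal with tissue-like noise
#'
#' Voxels at or above \code{bone_threshold} are replaced with draws from
#' \code{Normal(fill_mean, fill_sd)} — typical surrounding soft-tissue signal
#' including its noise.
#'
#' @param vol An [image_volume()].
#' @param bone_threshold HU threshold above soft tissue (default 300).
#' @param fill_mean,fill_sd Fill statistics (default: mean/sd of sub-threshold
#'   voxels in the tissue range).
#' @param seed RNG seed making the replacement deterministic.
#' @return An [image_volume()].
#' @export
remove_bone <- function(vol, bone_threshold = 300, fill_mean = NULL,
                        fill_sd = NULL, seed = 1) {
  stopifnot(inherits(vol, "image_volume"))
  sel <- vol$data >= bone_threshold
  if (!any(sel)) return(vol)
  tissue <- vol$data[vol$data < bone_threshold & vol$data > -300]
  if (length(tissue) < 10) tissue <- vol$data[!sel]
  fill_mean <- fill_mean %||% mean(tissue)
  fill_sd <- fill_sd %||% stats::sd(tissue)
  out <- vol
  out$data[sel] <- with_seed(seed,
    stats::rnorm(sum(sel), fill_mean, fill_sd))
  # draws above the threshold would defeat the purpose; fold them back
  out$data[out$data >= bone_threshold] <- fill_mean
  out
}

#' Histogram equalization inside a mask
#'
#' Classic CDF-based equalization over the masked voxels only (256 bins, no
#' saturation): a rank-preserving remap making the in-mask histogram
#' approximately uniform over a fixed output range. Voxels outside the mask
#' are set to the ceiling of that range — the display-saturation behavior of
#' equalizing a masked 8-bit image. A fixed range (rather than each image's
#' own min/max) keeps the background level and the in-lung intensity scale
#' identical across the phases of a series, which is what lets mean-squared
#' error compare images whose raw HU distributions shift with inflation.
#'
#' @param vol An [image_volume()].
#' @param mask A [lung_mask()] on the same grid.
#' @param nbins Number of histogram bins (default 256).
#' @param out_range Output intensity range (default c(0, 1000)).
#' @return An [image_volume()] with \code{intensity_kind = "processed"}.
#' @export
equalize_histogram <- function(vol, mask, nbins = 256,
                               out_range = c(0, 1000)) {
  stopifnot_same_grid(vol, mask, "volume and mask")
  if (!any(mask$data)) stop("equalize_histogram: empty mask")
  x <- vol$data[mask$data]
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("equalize_histogram: constant image inside mask; returning input")
    return(vol)
  }
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  bin <- findInterval(x, br, rightmost.closed = TRUE)
  h <- tabulate(bin, nbins)
  cdf <- cumsum(h) / sum(h)
  out <- vol
  out$data[mask$data] <- out_range[1] + cdf[bin] * diff(out_range)
  out$data[!mask$data] <- out_range[2]
  out$intensity_kind <- "processed"
  out
}

#' Image preparation levels
#'
#' The graded preparation pipeline that conditions images for registration:
#' \describe{
#'   \item{A}{original image, no processing.}
#'   \item{B}{bone signal replaced with tissue-like noise.}
#'   \item{C}{lung mask grown and refined; all non-lung background saturated.}
#'   \item{D}{as C, preceded by Gaussian filtering (radius 1).}
#'   \item{E}{as D, followed by histogram equalization inside the mask.}
#' }
#' Level E is the recommended input to registration.
#'
#' @param vol An [image_volume()].
#' @param level One of \code{"A".."E"}.
#' @param params List of stage parameters: \code{seed_index} (0-based, for
#'   mask growing; default: the volume's minimum-intensity voxel),
#'   \code{threshold} (mask threshold; default Otsu), \code{sigma} (filter
#'   sigma, default 1), \code{dilate_r}/\code{erode_r} (default 2/2),
#'   \code{bone_threshold}, \code{fill_mean}, \code{fill_sd}, \code{seed},
#'   \code{mask} (a precomputed [lung_mask()], skips segmentation).
#' @return An [image_volume()]; for levels C-E the lung mask used is attached
#'   as element \code{mask}.
#' @export
prepare <- function(vol, level = c("E", "A", "B", "C", "D"), params = list()) {
  level <- match.arg(level)
  p <- utils::modifyList(list(sigma = 1, dilate_r = 2, erode_r = 2,
                              bone_threshold = 300, seed = 1), params)
  if (level == "A") return(vol)
  if (level == "B")
    return(remove_bone(vol, p$bone_threshold, p$fill_mean, p$fill_sd, p$seed))
  work <- if (level %in% c("D", "E")) gaussian_filter(vol, p$sigma) else vol
  mask <- p$mask
  if (is.null(mask)) {
    seed_index <- p$seed_index %||% (which_min_index(work$data) - 1L)
    mask <- grow_lung_mask(work, seed_index, p$threshold)
    mask <- refine_mask(mask, p$dilate_r, p$erode_r)
  }
  out <- saturate_background(work, mask)
  if (level == "E") out <- equalize_histogram(out, mask)
  out$mask <- mask
  out
}

which_min_index <- function(a) {
  arrayInd(which.min(a), dim(a))[1, ]
}
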