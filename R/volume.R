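#' Construct an image volume
#'
#' The basic container for 3D CT data: a numeric array on a regular grid with
#' isotropic spacing. Voxel indices are 0-based throughout the package; the
#' world position of voxel (i, j, k) is \code{origin + c(i, j, k) * spacing}
#' (mm, position of the voxel center).
#'
#' @param data 3D numeric array (all values finite, every dim >= 2).
#' @param spacing Voxel edge length in mm (isotropic). Defaults to 0.15 mm,
#'   the reconstruction resolution of rodent micro-CT this package targets.
#' @param origin World position (mm) of the center of voxel (0, 0, 0).
#' @param intensity_kind \code{"raw_hu"} for calibrated Hounsfield data,
#'   \code{"processed"} after any preparation step that destroys HU semantics.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = 0.15, origin = c(0, 0, 0),
                         intensity_kind = c("raw_hu", "processed")) {
  intensity_kind <- match.arg(intensity_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image_volume: `data` must be a 3D array (non-3D data)")
  if (any(dim(data) < 2L))
    stop("image_volume: all three dims must be >= 2")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("image_volume: `spacing` must be a single positive number (mm)")
  if (!all(is.finite(data)))
    stop("image_volume: all values must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), intensity_kind = intensity_kind),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %g mm, %s, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"), x$spacing, x$intensity_kind,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a lung mask
#'
#' @param data 3D logical array on the same grid as its parent volume.
#' @param spacing,origin Grid metadata, as for [image_volume()].
#' @return An object of class \code{lung_mask}.
#' @export
lung_mask <- function(data, spacing = 0.15, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("lung_mask: `data` must be a 3D array")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("lung_mask: data must be logical or 0/1")
    data <- array(as.logical(data), dim(data))
  }
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %s voxels, %d in mask (%.1f%%)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

#' Construct a displacement field
#'
#' Displacements are stored in mm on the reference grid under the pull-back
#' convention: for each reference voxel center X, \code{X + u(X)} is the
#' corresponding location in the source image, so the field can be used
#' directly to resample the source onto the reference grid.
#'
#' @param vectors 4D numeric array with dims \code{c(nx, ny, nz, 3)} (mm).
#' @param spacing,origin Grid metadata of the reference grid.
#' @return An object of class \code{displacement_field}.
#' @export
displacement_field <- function(vectors, spacing = 0.15, origin = c(0, 0, 0)) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement_field: `vectors` must have dims (nx, ny, nz, 3)")
  if (!all(is.finite(vectors)))
    stop("displacement_field: all components must be finite")
  structure(list(vectors = vectors, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- sqrt(rowSums(matrix(x$vectors, ncol = 3)^2))
  cat(sprintf("<displacement_field> %s voxels, |u| mean %.3g mm, max %.3g mm\n",
              paste(dim(x$vectors)[1:3], collapse = "x"), mean(m), max(m)))
  invisible(x)
}

grid_of <- function(x) {
  d <- if (inherits(x, "displacement_field")) dim(x$vectors)[1:3] else dim(x$data)
  list(dims = d, spacing = x$spacing, origin = x$origin)
}

stopifnot_same_grid <- function(a, b, what = "objects") {
  ga <- grid_of(a); gb <- grid_of(b)
  if (!identical(ga$dims, gb$dims))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(ga$dims, collapse = "x"), paste(gb$dims, collapse = "x")))
  invisible(TRUE)
}

#' World coordinates of all voxel centers
#'
#' @param grid A list with \code{dims}, \code{spacing}, \code{origin} (as
#'   returned internally), or any package grid object.
#' @return n x 3 matrix of mm coordinates in array (column-major) order.
#' @keywords internal
voxel_centers <- function(grid) {
  if (!is.list(grid) || is.null(grid$dims)) grid <- grid_of(grid)
  d <- grid$dims
  i <- (seq_len(d[1]) - 1) * grid$spacing + grid$origin[1]
  j <- (seq_len(d[2]) - 1) * grid$spacing + grid$origin[2]
  k <- (seq_len(d[3]) - 1) * grid$spacing + grid$origin[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

# Shift an array along one axis by d voxels. pad = "replicate" repeats the
# edge plane, "value" fills with `value`.
shift_axis <- function(a, axis, d, pad = c("replicate", "value"), value = 0) {
  pad <- match.arg(pad)
  if (d == 0L) return(a)
  n <- dim(a)[axis]
  src <- seq_len(n) - d
  if (pad == "replicate") {
    src <- pmin(pmax(src, 1L), n)
    idx <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
    idx[[axis]] <- src
    return(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  out <- array(value, dim(a))
  keep <- src >= 1L & src <= n
  if (!any(keep)) return(out)
  dst <- which(keep)
  idx_o <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
  idx_i <- idx_o
  idx_o[[axis]] <- dst
  idx_i[[axis]] <- src[keep]
  out[idx_o[[1]], idx_o[[2]], idx_o[[3]]] <-
    a[idx_i[[1]], idx_i[[2]], idx_i[[3]], drop = FALSE]
  out
}

# Sample a 3D array at fractional 0-based voxel indices (n x 3 matrix).
sample_volume <- function(data, idx, fill) {
  interp3_cpp(as.numeric(data), as.integer(dim(data)),
              idx[, 1], idx[, 2], idx[, 3], fill)
}

# Tricubic (Catmull-Rom) sampling: used where sampled intensities feed
# quantitative estimates (air fractions), not for plain warping.
sample_volume_cubic <- function(data, idx, fill) {
  interp3_cubic_cpp(as.numeric(data), as.integer(dim(data)),
                    idx[, 1], idx[, 2], idx[, 3], fill)
}

# Sample value + spatial gradient (gradient per voxel index unit).
sample_volume_grad <- function(data, idx, fill) {
  interp3_grad_cpp(as.numeric(data), as.integer(dim(data)),
                   idx[, 1], idx[, 2], idx[, 3], fill)
}
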