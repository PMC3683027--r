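#' Hexahedral grid over voxel centroids
#'
#' The finite-element discretization: trilinear isoparametric 8-noded
#' hexahedral elements whose nodes are the voxel centroids, so a grid of
#' \code{nx x ny x nz} voxels carries \code{(nx-1)(ny-1)(nz-1)} elements of
#' edge length equal to the voxel spacing. Local node numbering follows the
#' natural-coordinate sign pattern of [shape_gradients()].
#'
#' @param mask_or_dims A [lung_mask()], [image_volume()] or length-3 dims.
#' @param spacing Voxel spacing (mm); taken from the object when given one.
#' @return A list of class \code{hex_grid} with \code{dims}, \code{spacing},
#'   \code{origin}, \code{n_elements}, and \code{element_dims}.
#' @export
build_hex_grid <- function(mask_or_dims, spacing = 0.15) {
  if (inherits(mask_or_dims, c("lung_mask", "image_volume", "displacement_field"))) {
    g <- grid_of(mask_or_dims)
    dims <- g$dims; spacing <- g$spacing; origin <- g$origin
  } else {
    dims <- as.integer(mask_or_dims); origin <- c(0, 0, 0)
  }
  if (any(dims < 2L))
    stop("build_hex_grid: all dims must be >= 2 (got ",
         paste(dims, collapse = "x"), ")")
  ed <- dims - 1L
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 element_dims = ed, n_elements = as.integer(prod(ed))),
            class = "hex_grid")
}

# Local node sign pattern (natural coordinates of the 8 nodes).
hex_node_signs <- function() {
  as.matrix(expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1)))
}

#' Isoparametric shape-function gradients at the element center
#'
#' For trilinear shape functions
#' \eqn{N_a = \prod_d (1 + \varsigma_d \varsigma_{a,d})/8} the gradient at the
#' element center \eqn{\varsigma = 0} is \eqn{\varsigma_{a,d}/8}.
#'
#' @return 8 x 3 matrix of \eqn{\partial N_a / \partial \varsigma_d}, entries
#'   all +-1/8; node order matches \code{hex_node_signs()}.
#' @export
shape_gradients <- function() {
  hex_node_signs() / 8
}

#' Deformation gradient on the hexahedral mesh
#'
#' Per element, \eqn{F = \sum_a x_a \otimes \partial N_a/\partial X} evaluated
#' at the element centroid, with current nodal positions
#' \eqn{x_a = X_a + u(X_a)} and the shape-function gradients mapped from the
#' reference element through the (diagonal, regular-grid) isoparametric
#' Jacobian. One centroid evaluation point per element: exact for affine
#' motions (trilinear completeness) and second-order accurate otherwise.
#' Elements with \eqn{J \le 0} (non-physical folding) are flagged and counted.
#'
#' @param field A [displacement_field()] on the grid's voxel lattice.
#' @param grid A [build_hex_grid()] (default: built from the field).
#' @return A list of class \code{deformation_field}: \code{F} (array
#'   \code{element_dims x 3 x 3}), \code{J} (array \code{element_dims}),
#'   \code{flagged} (logical array, J <= 0), \code{n_nonpositive},
#'   \code{grid}.
#' @export
deformation_gradient <- function(field, grid = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  grid <- grid %||% build_hex_grid(field)
  d <- grid$dims
  if (!identical(as.integer(dim(field$vectors)[1:3]), as.integer(d)))
    stop("deformation_gradient: field dims do not match grid")
  h <- grid$spacing
  ed <- grid$element_dims
  # dN_a/dX at the centroid = sign_a / (4 h); the reference-position part of
  # sum_a X_a (x) dN_a/dX is exactly the identity on a regular grid, so F is
  # accumulated from the displacement alone and I is added.
  Fm <- array(0, c(ed, 3, 3))
  signs <- hex_node_signs()
  corner <- function(a, di, dj, dk)
    a[seq_len(ed[1]) + di, seq_len(ed[2]) + dj, seq_len(ed[3]) + dk]
  for (a in 1:8) {
    s <- signs[a, ]
    di <- (s[1] + 1) / 2; dj <- (s[2] + 1) / 2; dk <- (s[3] + 1) / 2
    for (d1 in 1:3) {
      uc <- corner(field$vectors[, , , d1], di, dj, dk)
      for (d2 in 1:3)
        if (s[d2] != 0) Fm[, , , d1, d2] <- Fm[, , , d1, d2] +
            uc * (s[d2] / (4 * h))
    }
  }
  for (d1 in 1:3) Fm[, , , d1, d1] <- Fm[, , , d1, d1] + 1
  J <- Fm[, , , 1, 1] * (Fm[, , , 2, 2] * Fm[, , , 3, 3] -
                         Fm[, , , 2, 3] * Fm[, , , 3, 2]) -
       Fm[, , , 1, 2] * (Fm[, , , 2, 1] * Fm[, , , 3, 3] -
                         Fm[, , , 2, 3] * Fm[, , , 3, 1]) +
       Fm[, , , 1, 3] * (Fm[, , , 2, 1] * Fm[, , , 3, 2] -
                         Fm[, , , 2, 2] * Fm[, , , 3, 1])
  flagged <- J <= 0
  structure(list(F = Fm, J = array(J, ed), flagged = flagged,
                 n_nonpositive = sum(flagged), grid = grid),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %s elements, J in [%.4g, %.4g], %d flagged (J<=0)\n",
              paste(x$grid$element_dims, collapse = "x"), min(x$J), max(x$J),
              x$n_nonpositive))
  invisible(x)
}

#' Isochoric (shape-change) part of the deformation gradient
#'
#' \eqn{\bar F = J^{-1/3} F}: the volume-preserving factor, separating change
#' of shape from change of volume. Elements flagged with \eqn{J \le 0} yield
#' NA.
#'
#' @param def A [deformation_gradient()] result.
#' @return Array with the dims of \code{def$F}.
#' @export
isochoric_part <- function(def) {
  s <- ifelse(def$J > 0, def$J^(-1 / 3), NA_real_)
  out <- def$F
  for (d1 in 1:3) for (d2 in 1:3)
    out[, , , d1, d2] <- out[, , , d1, d2] * s
  out
}

#' Per-voxel Jacobian from per-element values
#'
#' Each voxel takes the mean of J over its incident elements (up to 8;
#' boundary voxels average the available ones).
#'
#' @param def A [deformation_gradient()] result.
#' @return List: \code{J} (per-voxel array), \code{flagged} (per-voxel
#'   logical: any incident element folded).
#' @export
jacobian_to_voxels <- function(def) {
  ed <- def$grid$element_dims
  d <- def$grid$dims
  acc <- array(0, d); cnt <- array(0, d); flg <- array(FALSE, d)
  el <- function(a) array(a, ed)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- seq_len(ed[1]) + di; jj <- seq_len(ed[2]) + dj
    kk <- seq_len(ed[3]) + dk
    acc[ii, jj, kk] <- acc[ii, jj, kk] + def$J
    cnt[ii, jj, kk] <- cnt[ii, jj, kk] + 1
    flg[ii, jj, kk] <- flg[ii, jj, kk] | def$flagged
  }
  list(J = acc / cnt, flagged = flg)
}

#' Kinematic regional ventilation map
#'
#' The volume of air gained per voxel, from the kinematics alone:
#' \eqn{rV = (J - 1) V_0} inside the mask (zero outside), with
#' \eqn{V_0 = spacing^3} the reference voxel volume converted to mL.
#'
#' @param J_voxels Per-voxel Jacobian array (or the list from
#'   [jacobian_to_voxels()]).
#' @param mask A [lung_mask()].
#' @param spacing Voxel spacing in mm.
#' @return A \code{ventilation_map}: \code{values} (mL), \code{mask},
#'   \code{method = "kinematic"}, \code{flagged}.
#' @export
kinematic_volume_map <- function(J_voxels, mask, spacing = mask$spacing) {
  flagged <- NULL
  if (is.list(J_voxels)) { flagged <- J_voxels$flagged; J_voxels <- J_voxels$J }
  stopifnot(identical(dim(J_voxels), dim(mask$data)))
  v0_mL <- spacing^3 / 1000     # mm^3 -> mL
  vals <- (J_voxels - 1) * v0_mL
  vals[!mask$data] <- 0
  structure(list(values = vals, mask = mask, method = "kinematic",
                 flagged = flagged %||% array(FALSE, dim(J_voxels)),
                 v0_mL = v0_mL),
            class = "ventilation_map")
}

#' @export
print.ventilation_map <- function(x, ...) {
  inm <- x$values[x$mask$data]
  cat(sprintf("<ventilation_map> (%s) total %.4g mL over %d voxels, %d flagged\n",
              x$method, sum(inm), length(inm), sum(x$flagged & x$mask$data)))
  invisible(x)
}

#' Total ventilation over the mask
#'
#' Sum of per-voxel volume change (mL) over in-mask, unflagged voxels.
#'
#' @param map A \code{ventilation_map}.
#' @return Scalar mL.
#' @export
total_ventilation <- function(map) {
  sel <- map$mask$data & !map$flagged
  sum(map$values[sel])
}
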