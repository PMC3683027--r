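#' Registration configuration
#'
#' Defaults mirror a two-stage strategy that works well for rodent lung 4D CT:
#' an affine stage on a 4x4x4-subsampled grid with 30 iterations, then a
#' single-resolution cubic B-spline free-form deformation with a 10-voxel
#' control-grid spacing, 30 iterations and a smoothness penalty weight of
#' 0.001. The metric is mean squared intensity error in both stages; the
#' optimizer is Levenberg-Marquardt for the 12 affine parameters and
#' gradient descent with a backtracking line search for the control points.
#' The penalty is normalized by the metric-region intensity variance and the
#' control spacing (see [bspline_register()]), making the weight
#' dimensionless.
#'
#' @param affine_subsample Per-axis integer subsampling for the affine stage.
#' @param affine_iters Affine iterations.
#' @param bspline_grid_spacing Control-point spacing in voxels (per axis).
#' @param bspline_iters B-spline iterations.
#' @param regularization Weight of the control-point second-difference
#'   (bending-energy surrogate) penalty.
#' @param fill Out-of-domain fill intensity (default: the source maximum,
#'   i.e. the saturation value of prepared images).
#' @return A list of class \code{registration_config}.
#' @export
registration_config <- function(affine_subsample = c(4, 4, 4),
                                affine_iters = 30,
                                bspline_grid_spacing = c(10, 10, 10),
                                bspline_iters = 30,
                                regularization = 0.001,
                                fill = NULL) {
  stopifnot(all(affine_subsample >= 1), affine_iters >= 1,
            all(bspline_grid_spacing >= 1), bspline_iters >= 0,
            regularization >= 0)
  structure(list(affine_subsample = rep(as.integer(affine_subsample),
                                        length.out = 3),
                 affine_iters = as.integer(affine_iters),
                 bspline_grid_spacing = rep(as.integer(bspline_grid_spacing),
                                            length.out = 3),
                 bspline_iters = as.integer(bspline_iters),
                 regularization = regularization, fill = fill),
            class = "registration_config")
}

#' Construct an affine transform
#'
#' World-coordinate map about the volume center c:
#' \code{x = c + matrix \%*\% (X - c) + offset} (mm).
#'
#' @param matrix Invertible 3x3 matrix.
#' @param offset Length-3 translation (mm).
#' @param center Length-3 center (mm).
#' @return An object of class \code{affine_transform}.
#' @export
affine_transform <- function(matrix = diag(3), offset = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  if (abs(det(matrix)) < 1e-12) stop("affine_transform: singular matrix")
  structure(list(matrix = matrix, offset = as.numeric(offset),
                 center = as.numeric(center)), class = "affine_transform")
}

apply_affine <- function(tf, pts) {
  sweep(sweep(pts, 2, tf$center) %*% t(tf$matrix), 2, tf$center + tf$offset, "+")
}

volume_center <- function(grid) {
  grid$origin + (grid$dims - 1) / 2 * grid$spacing
}

#' Affine registration
#'
#' Minimizes the mean squared intensity error between the target and the
#' affinely warped source, over a subsampled voxel grid, by gradient descent
#' with a backtracking line search. Both images should be prepared
#' (level E recommended) and on the same grid.
#'
#' @param target,source [image_volume()]s on the same grid.
#' @param cfg A [registration_config()].
#' @param roi Optional [lung_mask()]: the metric is evaluated over this
#'   region (dilated by 3 voxels to keep the boundary gradient). Defaults to
#'   the mask attached by [prepare()] when present; prepared images are
#'   mostly uniform saturated background, over which the MSE is degenerate.
#' @return An [affine_transform()] (about the volume center), with attributes
#'   \code{metric} (per-accepted-iteration MSE trace) and \code{converged}.
#' @export
affine_register <- function(target, source, cfg = registration_config(),
                            roi = NULL) {
  stopifnot_same_grid(target, source, "target and source")
  grid <- grid_of(target)
  sub <- cfg$affine_subsample
  idx <- lapply(1:3, function(a) seq(1L, grid$dims[a], by = sub[a]))
  sel <- as.matrix(expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]]))
  keep <- metric_roi(target, roi)
  if (!is.null(keep)) sel <- sel[keep[sel], , drop = FALSE]
  X <- sweep((sel - 1) * grid$spacing, 2, grid$origin, "+")
  Tv <- target$data[sel]
  ctr <- volume_center(grid)
  fill <- cfg$fill %||% max(source$data)
  Xc <- sweep(X, 2, ctr)
  s2 <- mean(rowSums(Xc^2)) / 3    # preconditioner for the matrix block
  sdat <- source$data

  eval_metric <- function(par) {
    M <- matrix(par[1:9], 3, 3)
    tvec <- par[10:12]
    x <- Xc %*% t(diag(3) + M)
    x <- sweep(x, 2, ctr + tvec, "+")
    idxf <- sweep(x, 2, grid$origin) / grid$spacing
    Sv <- sample_volume(sdat, idxf, fill)
    mean((Sv - Tv)^2)
  }

  par <- rep(0, 12)
  E <- eval_metric(par)
  if (!is.finite(E)) stop("affine_register: non-finite metric at identity")
  trace <- E
  lambda <- 1e-3
  converged <- TRUE
  n <- length(Tv)
  for (it in seq_len(cfg$affine_iters)) {
    # Levenberg-Marquardt on the 12 parameters: residual Jacobian columns are
    # dS/dx_d * d x_d/dp, assembled into 12x12 normal equations.
    M <- matrix(par[1:9], 3, 3)
    x <- Xc %*% t(diag(3) + M)
    x <- sweep(x, 2, ctr + par[10:12], "+")
    idxf <- sweep(x, 2, grid$origin) / grid$spacing
    vg <- sample_volume_grad(sdat, idxf, fill)
    r <- vg[, 1] - Tv
    g_mm <- vg[, 2:4] / grid$spacing          # dS/dx in HU per mm
    Jr <- cbind(g_mm[, 1] * Xc[, 1], g_mm[, 1] * Xc[, 2], g_mm[, 1] * Xc[, 3],
                g_mm[, 2] * Xc[, 1], g_mm[, 2] * Xc[, 2], g_mm[, 2] * Xc[, 3],
                g_mm[, 3] * Xc[, 1], g_mm[, 3] * Xc[, 2], g_mm[, 3] * Xc[, 3],
                g_mm)
    # column order above is M_11, M_12, M_13, M_21, ..., then t; par stores M
    # column-major, so reorder to match
    ord <- c(1, 4, 7, 2, 5, 8, 3, 6, 9, 10, 11, 12)
    Jr <- Jr[, ord]
    JtJ <- crossprod(Jr) / n
    g <- crossprod(Jr, r) / n
    if (!all(is.finite(JtJ)) || !all(is.finite(g))) break
    dscale <- diag(JtJ)
    dscale[dscale <= 0] <- max(dscale, 1)
    accepted <- FALSE
    for (ls in 1:20) {
      delta <- tryCatch(
        solve(JtJ + lambda * diag(dscale, 12), -g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        par_new <- par + as.numeric(delta)
        E_new <- eval_metric(par_new)
        if (is.finite(E_new) && E_new < E) {
          par <- par_new; E <- E_new; accepted <- TRUE
          lambda <- max(lambda / 4, 1e-10)
          break
        }
      }
      lambda <- lambda * 8
    }
    trace <- c(trace, E)
    if (!accepted) { converged <- it > 1; break }
    if (length(trace) > 2 &&
        abs(trace[length(trace) - 1] - E) < 1e-10 * (E + 1e-12)) break
  }
  out <- affine_transform(diag(3) + matrix(par[1:9], 3, 3), par[10:12], ctr)
  attr(out, "metric") <- trace
  attr(out, "converged") <- converged
  out
}

# Metric region of interest: the target's lung mask dilated by 3 voxels
# (keeps the boundary intensity step), or NULL for the full grid.
metric_roi <- function(target, roi = NULL) {
  roi <- roi %||% target$mask
  if (is.null(roi)) return(NULL)
  morph_op(roi$data, 3, "dilate")
}

# --- Cubic B-spline free-form deformation -----------------------------------

# Cubic B-spline basis values for fractional offsets t in [0,1):
# weights for control points at i0-1, i0, i0+1, i0+2.
bspline_w <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# Sparse basis matrix mapping control-point values to per-voxel values.
# Control lattice: spacing delta (voxels per axis), index range covers the
# image with one extra knot span on each side (cubic support).
bspline_basis <- function(dims, delta) {
  if (any(delta >= dims))
    stop("bspline_register: control grid larger than image")
  nk <- ceiling((dims - 1) / delta) + 1L     # knot spans cover [0, dims-1]
  nctrl <- nk + 3L                            # control points per axis
  ax <- vector("list", 3)
  for (a in 1:3) {
    s <- (seq_len(dims[a]) - 1) / delta[a]
    i0 <- pmin(floor(s), nk[a] - 1L)
    ax[[a]] <- list(i0 = i0, w = bspline_w(s - i0))
  }
  N <- prod(dims)
  vi <- rep(seq_len(dims[1]), times = dims[2] * dims[3])
  vj <- rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3])
  vk <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  rows <- vector("list", 64); cols <- rows; vals <- rows
  q <- 0L
  for (dz in 0:3) for (dy in 0:3) for (dx in 0:3) {
    q <- q + 1L
    ci <- ax[[1]]$i0[vi] + dx          # 0-based control index in 0..nctrl-1
    cj <- ax[[2]]$i0[vj] + dy
    ck <- ax[[3]]$i0[vk] + dz
    col <- 1L + ci + nctrl[1] * (cj + nctrl[2] * ck)
    wq <- ax[[1]]$w[vi, dx + 1L] * ax[[2]]$w[vj, dy + 1L] *
          ax[[3]]$w[vk, dz + 1L]
    rows[[q]] <- seq_len(N); cols[[q]] <- col; vals[[q]] <- wq
  }
  W <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals),
                            dims = c(N, prod(nctrl)))
  list(W = W, nctrl = nctrl)
}

# Second-difference operator over the control lattice (all three axes
# stacked): a bending-energy surrogate.
ctrl_second_diff <- function(nctrl) {
  M <- prod(nctrl)
  idx <- array(seq_len(M), nctrl)
  Ds <- list()
  for (a in 1:3) {
    n <- nctrl[a]
    if (n < 3) next
    take <- function(shift) {
      sl <- lapply(nctrl, seq_len)
      sl[[a]] <- seq_len(n - 2) + shift
      as.numeric(idx[sl[[1]], sl[[2]], sl[[3]]])
    }
    m <- length(take(0))
    Ds[[length(Ds) + 1]] <- Matrix::sparseMatrix(
      i = rep(seq_len(m), 3),
      j = c(take(0), take(1), take(2)),
      x = rep(c(1, -2, 1), each = m), dims = c(m, M))
  }
  do.call(rbind, Ds)
}

#' B-spline non-rigid registration
#'
#' Cubic B-spline free-form deformation refined on top of an affine
#' initialization: the map is \code{x(X) = A(X) + u_b(X)} with \code{u_b}
#' parameterized on a coarse control lattice. The objective is mean squared
#' intensity error plus \code{regularization} times the squared Frobenius
#' norm of control-point second differences. Gradient descent with a
#' backtracking line search guarantees a non-increasing objective over
#' accepted iterations.
#'
#' @param target,source [image_volume()]s on the same grid.
#' @param init An [affine_transform()] initialization (identity by default).
#' @param cfg A [registration_config()].
#' @param roi Optional metric region of interest, as in [affine_register()].
#' @return A [displacement_field()] (total displacement, mm, pull-back
#'   convention), with attributes \code{objective} (accepted-iteration trace)
#'   and \code{converged}.
#' @export
bspline_register <- function(target, source, init = NULL,
                             cfg = registration_config(), roi = NULL) {
  stopifnot_same_grid(target, source, "target and source")
  grid <- grid_of(target)
  init <- init %||% affine_transform(center = volume_center(grid))
  bb <- bspline_basis(grid$dims, cfg$bspline_grid_spacing)
  W <- bb$W
  D <- ctrl_second_diff(bb$nctrl)
  DtD <- Matrix::crossprod(D)
  lam <- cfg$regularization
  X <- voxel_centers(grid)
  keep <- metric_roi(target, roi)
  kidx <- if (is.null(keep)) seq_len(nrow(X)) else which(as.numeric(keep) > 0)
  Wk <- W[kidx, , drop = FALSE]
  Xk <- X[kidx, , drop = FALSE]
  Axk <- apply_affine(init, Xk)
  Tv <- as.numeric(target$data)[kidx]
  fill <- cfg$fill %||% max(source$data)
  sdat <- source$data
  N <- length(kidx)
  M <- ncol(W)
  cpts <- matrix(0, M, 3)

  # Penalty normalization: intensity variance over the ROI divided by the
  # squared control spacing (mm), so `regularization` is dimensionless — it
  # weighs squared intensity error against fractional control-lattice
  # curvature, and one default works across intensity scales and grids.
  pscale <- stats::var(Tv) / mean((cfg$bspline_grid_spacing * grid$spacing)^2)
  obj <- function(u, cp) {
    x <- Axk + u
    idxf <- sweep(x, 2, grid$origin) / grid$spacing
    Sv <- sample_volume(sdat, idxf, fill)
    mse <- mean((Sv - Tv)^2)
    reg <- if (lam > 0) lam * pscale * sum((D %*% cp)^2) else 0
    mse + reg
  }

  u <- matrix(0, N, 3)
  E <- obj(u, cpts)
  trace <- E
  step <- NULL
  converged <- TRUE
  for (it in seq_len(cfg$bspline_iters)) {
    x <- Axk + u
    idxf <- sweep(x, 2, grid$origin) / grid$spacing
    vg <- sample_volume_grad(sdat, idxf, fill)
    r <- vg[, 1] - Tv
    g_mm <- vg[, 2:4] / grid$spacing
    G <- as.matrix(2 / N * Matrix::crossprod(Wk, r * g_mm))
    if (lam > 0) G <- G + as.matrix(2 * lam * pscale * (DtD %*% cpts))
    dir <- -G
    Wd <- as.matrix(Wk %*% dir)
    gd <- sum(G * G)
    if (gd <= 0 || !is.finite(gd)) break
    if (is.null(step)) {
      # first step sized so the largest voxel displacement is half a voxel
      step <- 0.5 * grid$spacing / max(abs(Wd))
    }
    accepted <- FALSE
    for (ls in 1:30) {
      cpts_trial <- cpts + step * dir
      u_trial <- u + step * Wd
      E_new <- obj(u_trial, cpts_trial)
      if (is.finite(E_new) && E_new < E - 1e-6 * step * gd) {
        cpts <- cpts_trial; u <- u_trial; E <- E_new
        accepted <- TRUE
        step <- step * 1.8
        break
      }
      step <- step / 2
    }
    trace <- c(trace, E)
    if (!accepted) { converged <- it > 1; break }
  }
  total_u <- as.matrix(W %*% cpts)
  Ax_all <- apply_affine(init, X)
  total <- (Ax_all + total_u) - X   # total displacement incl. the affine part
  out <- displacement_field(array(total, c(grid$dims, 3)),
                            spacing = grid$spacing, origin = grid$origin)
  attr(out, "objective") <- trace
  attr(out, "converged") <- converged
  out
}

#' Register a source phase to the target
#'
#' The full two-stage pipeline: affine then B-spline.
#'
#' @inheritParams bspline_register
#' @return A [displacement_field()] (see [bspline_register()]).
#' @export
register_pair <- function(target, source, cfg = registration_config(),
                          roi = NULL) {
  aff <- affine_register(target, source, cfg, roi = roi)
  bspline_register(target, source, init = aff, cfg = cfg, roi = roi)
}

#' Warp an image by a displacement field
#'
#' Resamples the source onto the reference grid: output(X) = source(X + u(X))
#' by trilinear interpolation; out-of-domain samples take \code{fill}.
#'
#' @param source An [image_volume()].
#' @param field A [displacement_field()] on the reference grid.
#' @param fill Out-of-domain fill value (default: the source maximum).
#' @return An [image_volume()] on the reference grid.
#' @export
warp_image <- function(source, field, fill = NULL) {
  grid <- grid_of(field)
  X <- voxel_centers(grid)
  u <- matrix(field$vectors, ncol = 3)
  idxf <- sweep(X + u, 2, grid$origin) / grid$spacing
  fill <- fill %||% max(source$data)
  out <- sample_volume(source$data, idxf, fill)
  image_volume(array(out, grid$dims), spacing = grid$spacing,
               origin = grid$origin, intensity_kind = source$intensity_kind)
}

#' Import an externally computed displacement field
#'
#' Reads a 3-component vector volume (MetaImage or NIfTI) into the package's
#' pull-back mm convention, so fields produced by external registration tools
#' drive the downstream kinematics directly.
#'
#' @param path Vector-volume path (4D with 3 components).
#' @param grid Reference grid (an [image_volume()] or grid list) the field
#'   must match.
#' @param units \code{"mm"} (stored values are mm) or \code{"voxel"} (values
#'   are voxel offsets; converted using the grid spacing).
#' @return A [displacement_field()].
#' @export
import_field <- function(path, grid, units = c("mm", "voxel")) {
  units <- match.arg(units)
  if (!is.list(grid) || is.null(grid$dims)) grid <- grid_of(grid)
  lp <- tolower(path)
  if (grepl("\\.(mhd|mha)$", lp)) {
    res <- read_metaimage_raw(path)
  } else if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    res <- list(data = array(as.numeric(img), dim(img)))
  } else stop("import_field: unknown field format: ", path)
  d <- dim(res$data)
  if (length(d) != 4L || d[4] != 3L)
    stop("import_field: expected a 3-component vector volume, got dims ",
         paste(d, collapse = "x"))
  if (!identical(as.integer(d[1:3]), as.integer(grid$dims)))
    stop("import_field: field dims ", paste(d[1:3], collapse = "x"),
         " do not match grid ", paste(grid$dims, collapse = "x"))
  v <- res$data
  if (units == "voxel") v <- v * grid$spacing
  displacement_field(v, spacing = grid$spacing, origin = grid$origin)
}

#' Export a displacement field
#'
#' @param field A [displacement_field()].
#' @param path Output path (\code{.mha}/\code{.mhd} or \code{.nii}/\code{.nii.gz}).
#' @return `path`, invisibly.
#' @export
export_field <- function(field, path) {
  lp <- tolower(path)
  if (grepl("\\.(mhd|mha)$", lp)) {
    write_metaimage_raw(field$vectors, path, field$spacing, field$origin,
                        type = "MET_DOUBLE")
  } else if (grepl("\\.nii(\\.gz)?$", lp)) {
    v <- field$vectors
    attr(v, "pixdim") <- c(rep(field$spacing, 3), 1)
    RNifti::writeNifti(v, path, datatype = "double", version = 2)
  } else stop("export_field: unknown field format: ", path)
  invisible(path)
}
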