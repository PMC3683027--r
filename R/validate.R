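#' Grid-geometry misregistration bounds
#'
#' Computed from the voxel-grid model: the greatest in-plane nearest-neighbor
#' distance (over the 8 in-plane neighbors of a voxel) and the greatest 3D
#' nearest-neighbor distance (over the 26 neighbors), in voxel lengths.
#' These are the sqrt(2) ~ 1.41 and sqrt(3) ~ 1.73 pixel-length bounds used
#' to classify a landmark as misregistered.
#'
#' @return Named vector \code{c(in_plane = sqrt(2), three_d = sqrt(3))},
#'   computed by enumeration of the neighbor offsets.
#' @export
misregistration_bounds <- function() {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  in_plane <- offs[offs[, "dk"] == 0, , drop = FALSE]
  c(in_plane = max(sqrt(rowSums(in_plane^2))),
    three_d = max(sqrt(rowSums(offs^2))))
}

#' Classify landmarks as misregistered
#'
#' A landmark is misregistered when it is off by more than one slice in the
#' z-dimension and/or farther in-plane than the greatest in-plane
#' nearest-neighbor distance (sqrt(2) voxel lengths; strict inequality with a
#' 1e-9 tolerance, so an exactly diagonal in-plane offset is not flagged).
#' Any landmark within the rule is then within the greatest 3D
#' nearest-neighbor distance (sqrt(3) voxel lengths).
#'
#' @param delta n x 3 matrix of per-landmark displacements (voxel units).
#' @return Logical vector of flags.
#' @export
classify_misregistered <- function(delta) {
  delta <- matrix(as.numeric(delta), ncol = 3)
  eps <- 1e-9
  in_plane <- sqrt(delta[, 1]^2 + delta[, 2]^2)
  abs(delta[, 3]) > 1 + eps | in_plane > sqrt(2) + eps
}

#' Landmark target registration error
#'
#' Per-landmark displacement between target and warped-image locations, the
#' Euclidean TRE in voxel lengths, and the misregistration flag; with a
#' mean +- SD summary (population SD).
#'
#' @param landmarks_target,landmarks_warped [landmark_set()]s with matching
#'   ids (0-based voxel coordinates).
#' @return A list of class \code{tre_report}: \code{table} (id, di, dj, dk,
#'   tre_voxels, misregistered), \code{mean}, \code{sd},
#'   \code{pct_misregistered}.
#' @export
compute_tre <- function(landmarks_target, landmarks_warped) {
  lt <- as.data.frame(landmarks_target)
  lw <- as.data.frame(landmarks_warped)
  if (!setequal(lt$id, lw$id))
    stop("compute_tre: landmark id mismatch")
  lw <- lw[match(lt$id, lw$id), ]
  d <- as.matrix(lw[, c("i", "j", "k")]) - as.matrix(lt[, c("i", "j", "k")])
  tre <- sqrt(rowSums(d^2))
  mis <- classify_misregistered(d)
  tab <- data.frame(id = lt$id, di = d[, 1], dj = d[, 2], dk = d[, 3],
                    tre_voxels = tre, misregistered = mis)
  structure(list(table = tab, mean = mean(tre),
                 sd = sqrt(mean((tre - mean(tre))^2)),
                 pct_misregistered = 100 * mean(mis)),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report> %d landmarks, TRE %.2f +- %.2f voxels, %.1f%% misregistered\n",
              nrow(x$table), x$mean, x$sd, x$pct_misregistered))
  invisible(x)
}

#' TRE of an estimated field against a ground-truth field
#'
#' Landmark endpoint error: each landmark's true warped position (through the
#' ground-truth field) is compared with its position through the estimated
#' field, in voxel lengths.
#'
#' @param landmarks A [landmark_set()] on the reference grid.
#' @param field_true,field_est Ground-truth and estimated
#'   [displacement_field()]s (or an [analytic_field()] for the truth).
#' @return A \code{tre_report}.
#' @export
landmark_tre_fields <- function(landmarks, field_true, field_est) {
  grid <- grid_of(field_est)
  lm <- as.data.frame(landmarks)
  pts <- sweep(as.matrix(lm[, c("i", "j", "k")]) * grid$spacing, 2,
               grid$origin, "+")
  u_true <- if (inherits(field_true, "analytic_field"))
    field_u_points(field_true, pts)
  else sample_field_points(field_true, pts)
  u_est <- sample_field_points(field_est, pts)
  mk <- function(u) landmark_set(lm$id,
    sweep(pts + u, 2, grid$origin) / grid$spacing)
  compute_tre(mk(u_true), mk(u_est))
}

# Sample a displacement field (mm) at arbitrary mm points.
sample_field_points <- function(field, pts) {
  grid <- grid_of(field)
  idxf <- sweep(pts, 2, grid$origin) / grid$spacing
  vapply(1:3, function(d)
    sample_volume(field$vectors[, , , d], idxf, 0), numeric(nrow(pts)))
}

#' Assemble a pressure-volume curve from per-phase map totals
#'
#' Orders the per-phase total ventilation volumes by acquisition time and
#' pairs them with the ventilator's tracheal pressures and phase labels,
#' giving the map-derived PV loop. The first (lowest-inflation) phase is the
#' registration target, so its volume is zero by construction.
#'
#' @param map_totals data.frame with columns \code{time_ms} and
#'   \code{volume_mL} (one row per phase: total ventilation over the mask),
#'   and optionally \code{pressure_cmH2O} and \code{phase}.
#' @param trace Optional [ventilator_trace()] supplying pressure and phase by
#'   matching \code{time_ms}.
#' @return A \code{pv_curve}: data.frame (pressure_cmH2O, volume_mL, phase)
#'   ordered by time, with attribute \code{closed}.
#' @export
assemble_pv <- function(map_totals, trace = NULL) {
  mt <- as.data.frame(map_totals)
  if (anyDuplicated(mt$time_ms) || is.unsorted(mt$time_ms, strictly = TRUE))
    stop("assemble_pv: time points must be strictly increasing and unique")
  if (!is.null(trace)) {
    m <- match(mt$time_ms, trace$time_ms)
    if (anyNA(m)) stop("assemble_pv: map time points not found in trace")
    mt$pressure_cmH2O <- trace$pressure_cmH2O[m]
    mt$phase <- trace$phase[m]
  }
  if (is.null(mt$pressure_cmH2O) || is.null(mt$phase))
    stop("assemble_pv: pressure and phase required (supply a trace)")
  if (nrow(mt) < 3) stop("assemble_pv: need >= 3 time points")
  if (length(unique(mt$phase)) < 2)
    stop("assemble_pv: phases must span inhale and exhale")
  out <- mt[, c("pressure_cmH2O", "volume_mL", "phase")]
  closed <- abs(out$volume_mL[1] - out$volume_mL[nrow(out)]) <
    0.05 * max(abs(out$volume_mL)) + 1e-12
  structure(out, class = c("pv_curve", "data.frame"), closed = closed)
}

#' Compliance from a PV curve
#'
#' Ordinary least-squares slope of volume against pressure over the selected
#' limb (mL/cmH2O). Default limb is the inhale.
#'
#' @param pv A \code{pv_curve} (or data.frame with pressure_cmH2O, volume_mL,
#'   phase).
#' @param limb \code{"inhale"}, \code{"exhale"} or \code{"both"}.
#' @return Scalar compliance (mL/cmH2O).
#' @export
compliance <- function(pv, limb = c("inhale", "exhale", "both")) {
  limb <- match.arg(limb)
  d <- as.data.frame(pv)
  if (limb != "both") d <- d[d$phase == limb, ]
  if (nrow(d) < 2) stop("compliance: need >= 2 samples in the selected limb")
  if (stats::sd(d$pressure_cmH2O) == 0)
    stop("compliance: constant pressure in the selected limb")
  unname(stats::coef(stats::lm(volume_mL ~ pressure_cmH2O, data = d))[2])
}

#' Hysteresis area of a PV loop
#'
#' Shoelace (polygon) area of the closed (pressure, volume) loop, in
#' mL*cmH2O; positive when the inhale limb lies below the exhale limb in
#' volume at equal pressure (the physiological orientation). If the limbs
#' cross, a warning is issued and the signed area is returned.
#'
#' @param pv A \code{pv_curve}.
#' @return Signed area (mL*cmH2O).
#' @export
hysteresis_area <- function(pv) {
  d <- as.data.frame(pv)
  p <- d$pressure_cmH2O; v <- d$volume_mL
  n <- length(p)
  nxt <- c(2:n, 1)
  area <- sum(p * v[nxt] - p[nxt] * v) / 2
  inh <- d$phase == "inhale"; exh <- !inh
  if (sum(inh) >= 2 && sum(exh) >= 2) {
    pr <- sort(unique(p))
    pr <- pr[pr > min(p) & pr < max(p)]
    if (length(pr) >= 2) {
      vi <- stats::approx(p[inh], v[inh], xout = pr, ties = mean)$y
      ve <- stats::approx(p[exh], v[exh], xout = pr, ties = mean)$y
      gap <- ve - vi
      gap <- gap[is.finite(gap)]
      if (length(gap) >= 2 && min(gap) < -1e-9 && max(gap) > 1e-9)
        warning("hysteresis_area: PV loop limbs cross (self-intersecting loop); ",
                "returning signed area")
    }
  }
  area
}

#' Observer click-error report
#'
#' Simulates the landmark re-identification an observer performs on a
#' blurred copy of the target (blurring emulates the softening a warp
#' introduces): each landmark's neighborhood patch from the original image is
#' re-located in the Gaussian-filtered copy by local normalized
#' cross-correlation, and the displacement is reported in the same form as a
#' TRE report. This characterizes typical "mouse click" error; it is a
#' report, not a pass/fail gate.
#'
#' @param vol Target [image_volume()].
#' @param landmarks A [landmark_set()].
#' @param sigma Blur sigma in voxels (default 1).
#' @param search Search radius in voxels (default 2).
#' @param patch Patch half-width in voxels (default 2).
#' @return A \code{tre_report} of the click displacements.
#' @export
click_error_report <- function(vol, landmarks, sigma = 1, search = 2,
                               patch = 2) {
  blurred <- gaussian_filter(vol, sigma)
  lm <- as.data.frame(landmarks)
  d <- dim(vol$data)
  best <- matrix(0, nrow(lm), 3)
  for (r in seq_len(nrow(lm))) {
    p <- round(as.numeric(lm[r, c("i", "j", "k")])) + 1L
    p <- pmin(pmax(p, 1 + patch + search), d - patch - search)
    ref <- vol$data[(p[1] - patch):(p[1] + patch),
                    (p[2] - patch):(p[2] + patch),
                    (p[3] - patch):(p[3] + patch)]
    ref <- ref - mean(ref)
    sc_best <- -Inf
    for (dx in -search:search) for (dy in -search:search)
      for (dz in -search:search) {
        q <- p + c(dx, dy, dz)
        cand <- blurred$data[(q[1] - patch):(q[1] + patch),
                             (q[2] - patch):(q[2] + patch),
                             (q[3] - patch):(q[3] + patch)]
        cand <- cand - mean(cand)
        denom <- sqrt(sum(ref^2) * sum(cand^2))
        sc <- if (denom > 0) sum(ref * cand) / denom else -Inf
        if (sc > sc_best) { sc_best <- sc; best[r, ] <- c(dx, dy, dz) }
      }
  }
  lt <- landmark_set(lm$id, as.matrix(lm[, c("i", "j", "k")]))
  lw <- landmark_set(lm$id, as.matrix(lm[, c("i", "j", "k")]) + best)
  compute_tre(lt, lw)
}
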