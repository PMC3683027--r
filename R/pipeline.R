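#' Study configuration
#'
#' Describes a full multi-phase run. Phases are ordered by acquisition time;
#' the first (lowest-inflation) phase is always the registration target — a
#' deliberate invariant, overridable only with an explicit flag.
#'
#' @param phases List of [image_volume()]s or file paths, in acquisition
#'   order, first = lowest inflation (the target).
#' @param times Acquisition times (ms), one per phase; defaults to the trace
#'   times when a trace is given.
#' @param trace Optional [ventilator_trace()] (or CSV path).
#' @param fields Optional list of precomputed [displacement_field()]s or
#'   field-file paths (one per phase; entry 1 may be NULL/identity). When
#'   given, registration is skipped.
#' @param prep_level Preparation level for registration inputs (default "E").
#' @param prep_params Parameters passed to [prepare()].
#' @param reg A [registration_config()].
#' @param cal An [hu_calibration()], or \code{"fit"} to calibrate from the
#'   highest-inflation phase.
#' @param mask Optional [lung_mask()]; default: segmented from the target.
#' @param landmarks Optional [landmark_set()] (or CSV path) on the target
#'   grid.
#' @param true_fields Optional list of ground-truth [analytic_field()]s or
#'   [displacement_field()]s (phantom studies), enabling TRE reporting.
#' @param outdir Optional output directory; when given, fields, maps, the PV
#'   CSV and the run report are written there.
#' @param seed Seed recorded in the report and used for any stochastic stage.
#' @param allow_target_override Permit a target other than phase 1.
#' @param target_index Index of the registration target (must be 1 unless
#'   \code{allow_target_override}).
#' @return A list of class \code{study_config}.
#' @export
study_config <- function(phases, times = NULL, trace = NULL, fields = NULL,
                         prep_level = "E", prep_params = list(),
                         reg = registration_config(), cal = hu_calibration(),
                         mask = NULL, landmarks = NULL, true_fields = NULL,
                         outdir = NULL, seed = 1,
                         allow_target_override = FALSE, target_index = 1L) {
  if (length(phases) < 2) stop("study_config: need >= 2 phases")
  if (target_index != 1L && !allow_target_override)
    stop("study_config: the lowest-inflation phase (index 1) must be the ",
         "target; set allow_target_override to change this")
  structure(list(phases = phases, times = times, trace = trace,
                 fields = fields, prep_level = prep_level,
                 prep_params = prep_params, reg = reg, cal = cal,
                 mask = mask, landmarks = landmarks,
                 true_fields = true_fields, outdir = outdir, seed = seed,
                 target_index = as.integer(target_index)),
            class = "study_config")
}

load_phase <- function(x, what = "phase") {
  if (inherits(x, "image_volume")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("run_study: missing ", what, " file: ", x)
    return(read_volume(x))
  }
  stop("run_study: ", what, " must be an image_volume or a path")
}

#' Run a full ventilation-mapping study
#'
#' Orchestrates the pipeline on an ordered phase series: preparation of every
#' phase, displacement-field estimation (two-stage registration) or import,
#' finite-element kinematics (F, J), kinematic and intensity-joint
#' ventilation maps per phase, PV-curve assembly against the ventilator
#' trace, compliance, heterogeneity (CoV), and landmark TRE when ground truth
#' is available. Deterministic given the config seed.
#'
#' @param config A [study_config()], or a [phantom_study()] (run directly,
#'   optionally overriding settings via \code{...}).
#' @param ... When \code{config} is a \code{phantom_study}: overrides passed
#'   to [study_config()] (e.g. \code{fields} to use the ground-truth fields,
#'   \code{reg}, \code{outdir}).
#' @return A run report: list with \code{per_phase} (data.frame of totals and
#'   diagnostics), \code{pv} (\code{pv_curve}), \code{compliance},
#'   \code{cov}, \code{hysteresis_area}, \code{tre} (or NULL),
#'   \code{calibration}, \code{seed}, \code{config_hash}, \code{timing}.
#' @export
run_study <- function(config, ...) {
  if (inherits(config, "phantom_study")) {
    st <- config
    config <- study_config(phases = st$sources, times = st$times,
                           trace = st$trace, landmarks = st$landmarks,
                           true_fields = st$fields,
                           mask = st$phantom$mask, ...)
  }
  stopifnot(inherits(config, "study_config"))
  t0 <- proc.time()["elapsed"]
  n <- length(config$phases)
  vols <- lapply(seq_len(n), function(i)
    load_phase(config$phases[[i]], sprintf("phase %d", i)))
  grid <- grid_of(vols[[1]])
  trace <- config$trace
  if (is.character(trace)) trace <- read_ventilator_trace(trace)
  times <- config$times %||% (if (!is.null(trace)) trace$time_ms[seq_len(n)]
                              else seq_len(n) - 1)
  landmarks <- config$landmarks
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)

  # --- preparation ----------------------------------------------------------
  # each phase is segmented and saturated with its own mask (the lung grows
  # with inflation, so reusing the target mask would clip the sources); the
  # analysis mask is the target's. When fields are imported and a mask is
  # supplied, the prepared images are never consumed, so preparation is
  # skipped.
  need_prep <- is.null(config$fields) || is.null(config$mask)
  prep <- vector("list", n)
  if (need_prep)
    for (i in seq_len(n))
      prep[[i]] <- prepare(vols[[i]], config$prep_level, config$prep_params)
  mask <- config$mask %||% prep[[1]]$mask
  if (is.null(mask)) stop("run_study: no mask available (use level C-E or ",
                          "provide one)")
  t_prep <- proc.time()["elapsed"] - t0

  # --- calibration ----------------------------------------------------------
  cal <- config$cal
  if (identical(cal, "fit")) {
    peak <- if (!is.null(trace)) which.max(trace$volume_mL[seq_len(n)]) else n
    cal <- calibrate_hu(vols[[peak]], mask)
  }

  # --- displacement fields --------------------------------------------------
  t1 <- proc.time()["elapsed"]
  fields <- vector("list", n)
  zero_field <- displacement_field(array(0, c(grid$dims, 3)),
                                   spacing = grid$spacing, origin = grid$origin)
  fields[[1]] <- zero_field
  registered <- is.null(config$fields)
  for (i in 2:n) {
    fields[[i]] <- if (!registered) {
      f <- config$fields[[i]]
      if (is.null(f)) zero_field
      else if (inherits(f, "displacement_field")) f
      else if (inherits(f, "analytic_field")) evaluate_field(f, grid)
      else import_field(f, grid)
    } else {
      register_pair(prep[[1]], prep[[i]], config$reg)
    }
  }
  t_reg <- proc.time()["elapsed"] - t1

  # --- kinematics + ventilation maps ---------------------------------------
  t2 <- proc.time()["elapsed"]
  per_phase <- data.frame(phase = seq_len(n), time_ms = times,
                          total_kinematic_mL = 0, total_joint_mL = 0,
                          n_flagged = 0L)
  jmaps <- vector("list", n)
  kmaps <- vector("list", n)
  vmaps <- vector("list", n)
  for (i in seq_len(n)) {
    def <- deformation_gradient(fields[[i]])
    jv <- jacobian_to_voxels(def)
    kmaps[[i]] <- kinematic_volume_map(jv, mask)
    vmaps[[i]] <- joint_ventilation_map(jv, vols[[1]], vols[[i]], fields[[i]],
                                        cal, mask)
    jmaps[[i]] <- jv
    per_phase$total_kinematic_mL[i] <- total_ventilation(kmaps[[i]])
    per_phase$total_joint_mL[i] <- total_ventilation(vmaps[[i]])
    per_phase$n_flagged[i] <- sum(jv$flagged & mask$data)
  }
  t_maps <- proc.time()["elapsed"] - t2

  # --- validation -----------------------------------------------------------
  pv <- NULL; comp <- NA_real_; hyst <- NA_real_
  if (!is.null(trace)) {
    pv <- assemble_pv(data.frame(time_ms = times,
                                 volume_mL = per_phase$total_joint_mL),
                      trace)
    # default inhale limb; short studies without two inhale samples fall
    # back to the full loop
    comp <- tryCatch(compliance(pv, "inhale"),
                     error = function(e) compliance(pv, "both"))
    hyst <- hysteresis_area(pv)
  }
  peak_i <- if (!is.null(trace)) which.max(trace$volume_mL[seq_len(n)]) else n
  cov <- coefficient_of_variation(vmaps[[peak_i]])
  tre <- NULL
  if (!is.null(landmarks) && !is.null(config$true_fields)) {
    tre <- landmark_tre_fields(landmarks, config$true_fields[[peak_i]],
                               fields[[peak_i]])
  }

  report <- list(per_phase = per_phase, pv = pv, compliance = comp,
                 cov = cov, hysteresis_area = hyst, tre = tre,
                 calibration = cal, peak_phase = peak_i,
                 maps = list(kinematic = kmaps, joint = vmaps),
                 fields = fields, mask = mask,
                 seed = config$seed, config_hash = config_hash(config),
                 registered = registered,
                 timing = c(prepare = unname(t_prep),
                            register = unname(t_reg),
                            maps = unname(t_maps)))
  if (!is.null(config$outdir)) write_report(report, config$outdir, grid)
  class(report) <- "study_report"
  report
}

config_hash <- function(config) {
  slim <- config[setdiff(names(config), c("phases", "fields", "true_fields",
                                          "mask", "trace", "landmarks"))]
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(slim, f)
  unname(tools::md5sum(f))
}

write_report <- function(report, outdir, grid) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(report$per_phase)
  for (i in 2:n) {
    export_field(report$fields[[i]],
                 file.path(outdir, sprintf("field_%02d.mha", i)))
    jvol <- image_volume(report$maps$kinematic[[i]]$values /
                           report$maps$kinematic[[i]]$v0_mL + 1,
                         spacing = grid$spacing, origin = grid$origin,
                         intensity_kind = "processed")
    write_volume(jvol, file.path(outdir, sprintf("jacobian_%02d.nii.gz", i)))
    for (m in c("kinematic", "joint")) {
      mv <- image_volume(report$maps[[m]][[i]]$values, spacing = grid$spacing,
                         origin = grid$origin, intensity_kind = "processed")
      write_volume(mv, file.path(outdir, sprintf("rv_%s_%02d.nii.gz", m, i)))
    }
  }
  if (!is.null(report$pv))
    utils::write.csv(as.data.frame(report$pv),
                     file.path(outdir, "pv_curve.csv"), row.names = FALSE)
  utils::write.csv(report$per_phase, file.path(outdir, "per_phase.csv"),
                   row.names = FALSE)
  summary_lines <- c(
    sprintf("seed: %s", report$seed),
    sprintf("config_hash: %s", report$config_hash),
    sprintf("compliance_mL_per_cmH2O: %.6g", report$compliance),
    sprintf("cov: %.6g", report$cov),
    sprintf("hysteresis_area_mL_cmH2O: %.6g", report$hysteresis_area),
    if (!is.null(report$tre))
      sprintf("tre_mean_voxels: %.6g", report$tre$mean))
  writeLines(summary_lines, file.path(outdir, "summary.txt"))
  if (!is.null(report$tre))
    utils::write.csv(report$tre$table, file.path(outdir, "tre_report.csv"),
                     row.names = FALSE)
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d phases%s\n", nrow(x$per_phase),
              if (x$registered) " (registered)" else " (imported fields)"))
  cat(sprintf("  compliance %.4g mL/cmH2O, CoV %.3f, hysteresis %.4g mL*cmH2O\n",
              x$compliance, x$cov, x$hysteresis_area))
  if (!is.null(x$tre))
    cat(sprintf("  TRE %.2f +- %.2f voxels\n", x$tre$mean, x$tre$sd))
  invisible(x)
}

#' Image-preparation ablation
#'
#' Re-runs registration under each preparation level A-E on one
#' target/source pair with known ground truth, reporting per-level mean
#' landmark TRE and the percentage of misregistered landmarks — the
#' experiment design that identifies which preparation level yields the most
#' accurate warps.
#'
#' @param target,source [image_volume()]s (raw).
#' @param true_field Ground-truth [analytic_field()] or
#'   [displacement_field()] for the pair.
#' @param landmarks [landmark_set()] on the target grid.
#' @param reg A [registration_config()].
#' @param prep_params Parameters for [prepare()].
#' @return data.frame with one row per level: level, mean_tre_voxels,
#'   sd_tre_voxels, pct_misregistered.
#' @export
run_prep_ablation <- function(target, source, true_field, landmarks,
                              reg = registration_config(),
                              prep_params = list()) {
  levels <- c("A", "B", "C", "D", "E")
  out <- data.frame(level = levels, mean_tre_voxels = NA_real_,
                    sd_tre_voxels = NA_real_, pct_misregistered = NA_real_)
  for (li in seq_along(levels)) {
    lv <- levels[li]
    pt <- prepare(target, lv, prep_params)
    ps <- prepare(source, lv, prep_params)
    fld <- register_pair(pt, ps, reg)
    tre <- landmark_tre_fields(landmarks, true_field, fld)
    out$mean_tre_voxels[li] <- tre$mean
    out$sd_tre_voxels[li] <- tre$sd
    out$pct_misregistered[li] <- tre$pct_misregistered
  }
  out
}
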