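#' Read a 3D image volume
#'
#' Supported formats: NIfTI (\code{.nii}, \code{.nii.gz}), MetaImage
#' (\code{.mhd}, \code{.mha}) and multi-page TIFF stacks. Spacing is taken
#' from the header where the format carries one; anisotropic headers are
#' rejected unless an explicit \code{spacing} override is given, because all
#' downstream kinematics assume an isotropic grid.
#'
#' @param path File path.
#' @param format One of \code{"nifti"}, \code{"metaimage"}, \code{"tiff_stack"};
#'   inferred from the extension when \code{NULL}.
#' @param spacing Optional isotropic spacing override in mm (required for TIFF
#'   stacks, which carry no calibrated spacing; default 0.15 there).
#' @param intensity_kind Passed to [image_volume()].
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = NULL, spacing = NULL,
                        intensity_kind = "raw_hu") {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  format <- format %||% infer_format(path)
  res <- switch(format,
    nifti = read_nifti_raw(path),
    metaimage = read_metaimage_raw(path),
    tiff_stack = read_tiff_raw(path),
    stop("read_volume: unknown format: ", format))
  if (length(dim(res$data)) != 3L)
    stop("read_volume: non-3D data in ", path,
         " (dims: ", paste(dim(res$data), collapse = "x"), ")")
  sp <- res$spacing
  if (is.null(spacing)) {
    if (is.null(sp)) sp <- rep(0.15, 3)
    if (diff(range(sp)) > 1e-6 * max(sp))
      stop("read_volume: anisotropic spacing (", paste(signif(sp, 6),
           collapse = ", "), ") without an explicit `spacing` override")
    spacing <- sp[1]
  }
  image_volume(res$data, spacing = spacing,
               origin = res$origin %||% c(0, 0, 0),
               intensity_kind = intensity_kind)
}

#' Write a 3D image volume
#'
#' Round-trips with [read_volume()] are lossless for the native float type of
#' each format and exact for spacing metadata.
#'
#' @param vol An [image_volume()] or [lung_mask()].
#' @param path Output path.
#' @param format As in [read_volume()]; inferred from the extension if `NULL`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  format <- format %||% infer_format(path)
  is_mask <- inherits(vol, "lung_mask")
  data <- if (is_mask) array(as.numeric(vol$data), dim(vol$data)) else vol$data
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  switch(format,
    nifti = {
      attr(data, "pixdim") <- rep(vol$spacing, 3)
      # NIfTI-2: 64-bit header fields keep the spacing metadata exact
      RNifti::writeNifti(data, path, version = 2,
                         datatype = if (is_mask) "uint8" else "double")
    },
    metaimage = write_metaimage_raw(data, path, vol$spacing, vol$origin,
                                    type = if (is_mask) "MET_UCHAR" else "MET_DOUBLE"),
    tiff_stack = {
      slices <- lapply(seq_len(dim(data)[3]), function(k) data[, , k])
      tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
    },
    stop("write_volume: unknown format: ", format))
  invisible(path)
}

infer_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(mhd|mha)$", lp)) return("metaimage")
  if (grepl("\\.(tif|tiff)$", lp)) return("tiff_stack")
  stop("cannot infer volume format from extension: ", path)
}

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1]; d <- dim(img) }
  list(data = array(as.numeric(img), d),
       spacing = abs(hdr$pixdim[2:4]), origin = NULL)
}

read_tiff_raw <- function(path) {
  sl <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(sl)) sl <- list(sl)
  sl <- lapply(sl, function(s) if (length(dim(s)) == 3L) s[, , 1] else s)
  d2 <- dim(sl[[1]])
  if (length(sl) < 2L)
    stop("read_volume: non-3D data (single-slice TIFF)")
  data <- array(0, c(d2[1], d2[2], length(sl)))
  for (k in seq_along(sl)) data[, , k] <- sl[[k]]
  list(data = data, spacing = NULL, origin = NULL)
}

# --- MetaImage (.mhd/.mha): plain text header + raw little-endian data ------

metaimage_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_FLOAT = "double",
                     MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                     MET_USHORT = 2L, MET_INT = 4L, MET_FLOAT = 4L,
                     MET_DOUBLE = 8L)

read_metaimage_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("read_volume: truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("read_volume: malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  nchan <- as.integer(hdr$ElementNumberOfChannels %||% "1")
  type <- hdr$ElementType %||% "MET_DOUBLE"
  if (!type %in% names(metaimage_types))
    stop("read_volume: unsupported MetaImage ElementType: ", type)
  msb <- toupper(hdr$ElementByteOrderMSB %||% hdr$BinaryDataByteOrderMSB %||% "FALSE")
  endian <- if (msb %in% c("TRUE", "1")) "big" else "little"
  n <- prod(dims) * nchan
  if (identical(data_file, "LOCAL")) {
    raw_vals <- readBin(con, what = metaimage_types[[type]], n = n,
                        size = metaimage_sizes[[type]], endian = endian,
                        signed = !type %in% c("MET_UCHAR", "MET_USHORT"))
  } else {
    rawpath <- file.path(dirname(path), data_file)
    raw_vals <- readBin(rawpath, what = metaimage_types[[type]], n = n,
                        size = metaimage_sizes[[type]], endian = endian,
                        signed = !type %in% c("MET_UCHAR", "MET_USHORT"))
  }
  if (length(raw_vals) != n) stop("read_volume: MetaImage data shorter than DimSize")
  full_dims <- if (nchan > 1L) c(dims, nchan) else dims
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])[seq_len(min(3L, ndims))]
  else NULL
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])[seq_len(min(3L, ndims))]
  else NULL
  list(data = array(as.numeric(raw_vals), full_dims), spacing = sp, origin = org)
}

write_metaimage_raw <- function(data, path, spacing, origin,
                                type = "MET_DOUBLE") {
  d <- dim(data)
  nchan <- if (length(d) == 4L) d[4] else 1L
  dims <- d[1:3]
  mha <- grepl("\\.mha$", tolower(path))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %s", paste(dims, collapse = " ")),
           sprintf("ElementSpacing = %s",
                   paste(format(rep(spacing, 3), digits = 17), collapse = " ")),
           sprintf("Offset = %s",
                   paste(format(origin, digits = 17), collapse = " ")),
           if (nchan > 1L) sprintf("ElementNumberOfChannels = %d", nchan),
           sprintf("ElementType = %s", type),
           sprintf("ElementDataFile = %s",
                   if (mha) "LOCAL" else paste0(basename(tools::file_path_sans_ext(path)), ".raw")))
  size <- metaimage_sizes[[type]]
  vals <- if (metaimage_types[[type]] == "integer") as.integer(data)
          else as.numeric(data)
  if (mha) {
    con <- file(path, "wb")
    writeLines(hdr, con)
    writeBin(vals, con, size = size, endian = "little")
    close(con)
  } else {
    writeLines(hdr, path)
    rawpath <- file.path(dirname(path),
                         paste0(basename(tools::file_path_sans_ext(path)), ".raw"))
    con <- file(rawpath, "wb")
    writeBin(vals, con, size = size, endian = "little")
    close(con)
  }
  invisible(path)
}

# --- Landmarks ---------------------------------------------------------------

#' Read a landmark table
#'
#' CSV with header \code{id,i,j,k}: 0-based voxel-index coordinates, possibly
#' fractional (sub-voxel identification is allowed).
#'
#' @param path CSV path.
#' @param dims Optional grid dims; coordinates are checked against
#'   \code{[0, dims - 1]} when given.
#' @return A \code{landmark_set}: data.frame with columns id, i, j, k.
#' @export
read_landmarks <- function(path, dims = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "i", "j", "k")
  if (!all(req %in% names(df)))
    stop("read_landmarks: CSV must have header id,i,j,k")
  landmark_set(df$id, as.matrix(df[, c("i", "j", "k")]), dims = dims)
}

#' Construct a landmark set
#'
#' @param id Unique landmark identifiers.
#' @param ijk n x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @param dims Optional grid dims for a bounds check.
#' @return A \code{landmark_set} data.frame.
#' @export
landmark_set <- function(id, ijk, dims = NULL) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  if (anyDuplicated(id)) stop("landmark_set: duplicate ids")
  if (length(id) != nrow(ijk)) stop("landmark_set: id/coordinate length mismatch")
  if (!is.null(dims)) {
    for (a in 1:3)
      if (any(ijk[, a] < 0 | ijk[, a] > dims[a] - 1))
        stop("landmark_set: coordinates out of grid bounds on axis ", a)
  }
  structure(data.frame(id = id, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3]),
            class = c("landmark_set", "data.frame"))
}

#' Write a landmark table
#' @param lms A \code{landmark_set}.
#' @param path CSV path.
#' @export
write_landmarks <- function(lms, path) {
  utils::write.csv(as.data.frame(lms)[, c("id", "i", "j", "k")], path,
                   row.names = FALSE)
  invisible(path)
}

# --- Ventilator traces -------------------------------------------------------

#' Read a ventilator pressure-volume trace
#'
#' CSV with header \code{time_ms,pressure_cmH2O,volume_mL,phase}. Time must be
#' strictly increasing and the phase labels must form one contiguous inhale
#' run followed by one exhale run (one breathing cycle).
#'
#' @param path CSV path.
#' @return A \code{ventilator_trace} data.frame.
#' @export
read_ventilator_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_ms", "pressure_cmH2O", "volume_mL", "phase")
  if (!all(req %in% names(df)))
    stop("read_ventilator_trace: CSV must have header ",
         paste(req, collapse = ","))
  ventilator_trace(df$time_ms, df$pressure_cmH2O, df$volume_mL, df$phase)
}

#' Construct a ventilator trace
#'
#' @param time_ms Sample times (strictly increasing).
#' @param pressure_cmH2O Tracheal pressure.
#' @param volume_mL Cumulative inhaled volume.
#' @param phase \code{"inhale"}/\code{"exhale"} labels, one inhale run then
#'   one exhale run.
#' @return A \code{ventilator_trace} data.frame.
#' @export
ventilator_trace <- function(time_ms, pressure_cmH2O, volume_mL, phase) {
  if (any(diff(time_ms) <= 0))
    stop("ventilator_trace: time must be strictly increasing")
  if (!all(phase %in% c("inhale", "exhale")))
    stop("ventilator_trace: unknown phase label: ",
         paste(setdiff(unique(phase), c("inhale", "exhale")), collapse = ", "))
  r <- rle(phase)
  if (!identical(r$values, c("inhale", "exhale")) &&
      !identical(r$values, "inhale") && !identical(r$values, "exhale"))
    stop("ventilator_trace: phase must be one inhale run then one exhale run")
  structure(data.frame(time_ms = time_ms, pressure_cmH2O = pressure_cmH2O,
                       volume_mL = volume_mL, phase = phase),
            class = c("ventilator_trace", "data.frame"))
}

#' Write a ventilator trace
#' @param trace A \code{ventilator_trace}.
#' @param path CSV path.
#' @export
write_ventilator_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
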