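#' SUV volume container
#'
#' Constructs a 3D standardized-uptake-value (SUV) volume on a regular,
#' axis-aligned grid. All segmentation and metric computations in the package
#' operate on this container. Voxel values are SUV (g/mL) and must be
#' non-negative and finite; grid spacing is in mm.
#'
#' The grid convention is: voxel indices are 1-based in R, and the physical
#' position of the center of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`. Only axis-aligned volumes are
#' supported; no orientation matrix handling is performed.
#'
#' @param values 3D numeric array of SUV.
#' @param spacing Numeric length-3, voxel spacing `(sx, sy, sz)` in mm; all
#'   components must be positive.
#' @param origin Numeric length-3, physical position (mm) of the center of
#'   voxel `(1, 1, 1)`.
#' @param patient_id,scan_id Identifiers carried through the pipeline;
#'   `scan_id` should be `"scan1"` or `"scan2"` for test-retest pairs.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(values, spacing, origin = c(0, 0, 0),
                       patient_id = NA_character_, scan_id = NA_character_) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  if (any(!is.finite(values)))
    stop("SUV values must be finite")
  if (any(values < 0))
    stop(sprintf("SUV values must be non-negative (minimum found: %g)",
                 min(values)))
  structure(list(values = values,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 patient_id = as.character(patient_id),
                 scan_id = as.character(scan_id)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<suv_volume> %s / %s: %d x %d x %d voxels @ %g x %g x %g mm, SUV range [%.3g, %.3g]\n",
              x$patient_id, x$scan_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume in mL
#'
#' @param x An `suv_volume` or `voi_mask`.
#' @return Volume of one voxel in mL (`sx * sy * sz / 1000`).
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Label mask (VOI) container
#'
#' An integer label image on the same grid as its companion [suv_volume()]:
#' 0 is background, positive integers label regions (e.g. the liver reference
#' VOI, or one lesion per label). Masks must share the exact grid of the
#' volume they annotate; no resampling is performed.
#'
#' @param labels 3D array of non-negative integers.
#' @param spacing,origin Grid geometry, as in [suv_volume()].
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voi_mask")
}

.check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$labels)))
    stop("mask grid does not match volume grid")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6)
    stop("mask spacing does not match volume spacing")
  invisible(TRUE)
}

#' VOI summary statistics
#'
#' Mean, standard deviation and maximum SUV over the voxels carrying a given
#' label, as used for the liver reference region that drives the
#' candidate-detection threshold (see [liver_threshold()]).
#'
#' @param volume An [suv_volume()].
#' @param mask A [voi_mask()] on the same grid.
#' @param label Integer label to summarize (default 1).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A list of class `voi_stats`: `mean`, `sd`, `max`, `n_voxels`.
#' @export
voi_stats <- function(volume, mask, label = 1L, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  .check_aligned(volume, mask)
  idx <- which(mask$labels == label)
  if (length(idx) == 0L)
    stop(sprintf("empty VOI: label %d not present in mask", label))
  v <- volume$values[idx]
  n <- length(v)
  s <- if (n == 1L) 0 else stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  structure(list(mean = mean(v), sd = s, max = max(v), n_voxels = n),
            class = "voi_stats")
}

.sidecar_path <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path))
    sub("\\.nii(\\.gz)?$", ".json", path)
  else paste0(path, ".json")
}

#' Read an SUV volume from NIfTI
#'
#' Reads a 3D single-channel NIfTI file as an [suv_volume()]. Spacing and
#' origin are taken from the header (sform translation); `patient_id` and
#' `scan_id` are restored from a sidecar JSON file (written by
#' [write_suv_volume()]) when one is present next to the image.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [suv_volume()].
#' @export
read_suv_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got %d dimensions", length(d)))
  vals <- array(as.numeric(img), dim = d)
  if (any(vals < 0))
    stop(sprintf("negative SUV values present (minimum: %g)", min(vals)))
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- as.numeric(xf[1:3, 4])
  pid <- NA_character_; sid <- NA_character_
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    pid <- meta$patient_id %||% NA_character_
    sid <- meta$scan_id %||% NA_character_
  }
  suv_volume(vals, spacing = spacing, origin = origin,
             patient_id = pid, scan_id = sid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_nifti <- function(arr, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  m <- diag(4)
  diag(m)[1:3] <- spacing
  m[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write an SUV volume to NIfTI
#'
#' Writes the volume as float32 NIfTI with spacing/origin encoded in the
#' header, plus a sidecar JSON carrying `patient_id` and `scan_id`.
#' [read_suv_volume()] inverts it (values at float32 precision).
#'
#' @param volume An [suv_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_suv_volume <- function(volume, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  .write_nifti(volume$values, volume$spacing, volume$origin, path, "float")
  jsonlite::write_json(list(patient_id = volume$patient_id,
                            scan_id = volume$scan_id),
                       .sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label mask from NIfTI
#'
#' @param path Path to a NIfTI label image (integer labels).
#' @return A [voi_mask()].
#' @export
read_voi_mask <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got %d dimensions", length(d)))
  xf <- RNifti::xform(img)
  voi_mask(array(as.integer(round(img)), dim = d),
           spacing = RNifti::pixdim(img)[1:3],
           origin = as.numeric(xf[1:3, 4]))
}

#' Write a label mask to NIfTI (uint16)
#'
#' @param mask A [voi_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voi_mask <- function(mask, path) {
  if (max(mask$labels) > 65535L)
    stop("labels exceed uint16 range")
  .write_nifti(mask$labels, mask$spacing, mask$origin, path, "uint16")
}
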