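# CT volume I/O and the three-step slice preprocessing:
# (1) clip voxel values to a Hounsfield-unit window,
# (2) resize each axial slice to a square target raster,
# (3) linearly rescale each slice into [0, 1].

#' Construct a CT volume object
#'
#' A `ct_volume` is an ordered stack of axial slices of Hounsfield-unit (HU)
#' values.  Voxels are indexed `(slice, row, col)`; slice index 1..n_slices
#' follows axial acquisition order (user-facing slice indices elsewhere in the
#' package are 0-based, matching the (x, y, slice) location convention).
#'
#' @param voxels 3D numeric array indexed `(slice, row, col)`, values in HU.
#' @param scan_id Scan identifier string.
#' @param patient_id Patient identifier string (defaults to `scan_id`).
#' @return An object of class `ct_volume` with fields `voxels`, `scan_id`,
#'   `patient_id`, `n_slices`, `in_plane_shape` (rows, cols).
#' @export
ct_volume <- function(voxels, scan_id, patient_id = scan_id) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort_invalid("voxels must be a 3D array indexed (slice, row, col)")
  }
  d <- dim(voxels)
  if (d[1] < 1L) abort_invalid("a CT volume needs at least one slice")
  structure(
    list(
      voxels = voxels,
      scan_id = as.character(scan_id),
      patient_id = as.character(patient_id),
      n_slices = d[1],
      in_plane_shape = d[2:3]
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume> scan '%s' (patient '%s'): %d axial slices of %d x %d px\n",
    x$scan_id, x$patient_id, x$n_slices,
    x$in_plane_shape[1], x$in_plane_shape[2]
  ))
  invisible(x)
}

#' Extract one axial slice as a matrix
#'
#' @param volume A [ct_volume()].
#' @param slice_index 0-based axial slice index.
#' @return Numeric matrix (rows x cols) of HU values.
#' @export
get_slice <- function(volume, slice_index) {
  stopifnot(inherits(volume, "ct_volume"))
  if (slice_index < 0L || slice_index >= volume$n_slices) {
    abort_invalid(sprintf(
      "slice_index %d out of range [0, %d]", slice_index, volume$n_slices - 1L
    ))
  }
  matrix(volume$voxels[slice_index + 1L, , ],
         nrow = volume$in_plane_shape[1], ncol = volume$in_plane_shape[2])
}

#' Preprocessing configuration
#'
#' Defaults reproduce the clinical protocol: voxel values limited to the
#' window \[-200, 600\] HU (a heuristic window keeping bone plus the
#' surrounding soft tissue informative for detection), axial slices resized to
#' 512 x 512 pixels, then each slice linearly scaled into \[0, 1\].
#'
#' @param hu_min,hu_max HU window bounds (`hu_min < hu_max`).
#' @param target_size Side length in pixels of the square output raster
#'   (>= 8).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_min = -200, hu_max = 600, target_size = 512L) {
  if (!(hu_min < hu_max)) abort_invalid("hu_min must be < hu_max")
  if (target_size < 8L) abort_invalid("target_size must be >= 8")
  structure(
    list(hu_min = hu_min, hu_max = hu_max, target_size = as.integer(target_size)),
    class = "preprocess_config"
  )
}

#' Read a CT volume from a NIfTI file
#'
#' Reads a volumetric NIfTI image (`.nii` or `.nii.gz`) whose voxel values are
#' already in Hounsfield units.  The NIfTI k-axis is taken as the axial slice
#' axis; i maps to image columns (x) and j to rows (y).
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param scan_id Scan identifier; defaults to the file name without
#'   extension.
#' @param patient_id Patient identifier; defaults to `scan_id`.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, scan_id = NULL, patient_id = NULL) {
  if (!file.exists(path)) {
    abort_not_found(sprintf("volume file not found: %s", path))
  }
  if (dir.exists(path)) {
    abort_format(sprintf(
      "%s is a directory; only single-file NIfTI volumes are supported", path
    ))
  }
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    abort_format(sprintf("not a NIfTI volume (expected .nii/.nii.gz): %s", path))
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) abort_format(sprintf("failed to read %s: %s", path, conditionMessage(e)))
  )
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) {
    abort_format(sprintf(
      "%s is not a 3D volume (found %d dimensions)", path, length(dim(arr))
    ))
  }
  if (is.null(scan_id)) scan_id <- sub("\\.nii(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  if (is.null(patient_id)) patient_id <- scan_id
  # NIfTI arrays are (i = x/col, j = y/row, k = slice); reorder to (slice, row, col)
  ct_volume(aperm(arr, c(3L, 2L, 1L)), scan_id = scan_id, patient_id = patient_id)
}

#' Write a CT volume to a NIfTI file
#'
#' Inverse of [load_volume()]: `load_volume(write_volume(v, p))` reproduces
#' the voxel array exactly.
#'
#' @param volume A [ct_volume()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(sprintf("output directory does not exist: %s", dir))
  RNifti::writeNifti(aperm(volume$voxels, c(3L, 2L, 1L)), path)
  invisible(path)
}

#' Clip values to the Hounsfield-unit window
#'
#' Values below `hu_min` become `hu_min`, values above `hu_max` become
#' `hu_max`; in-window values are unchanged.  Idempotent; shape-preserving.
#'
#' @param x Numeric array, matrix or vector of HU values.
#' @param config A [preprocess_config()].
#' @return Clipped object of the same shape.
#' @export
clip_hu <- function(x, config = preprocess_config()) {
  x[] <- pmin(pmax(x, config$hu_min), config$hu_max)
  x
}

#' Resize a slice to the square target raster
#'
#' Bilinear interpolation onto a `target_size` x `target_size` raster.
#' Non-square inputs are stretched (no letterboxing); the returned scale
#' factors let annotations be rescaled analytically with [rescale_box()]
#' rather than redrawn.
#'
#' @param slice Numeric matrix (>= 2 rows and columns).
#' @param config A [preprocess_config()].
#' @return List with `image` (target raster), `scale_x` (= target / input
#'   cols) and `scale_y` (= target / input rows).
#' @export
resize_to_target <- function(slice, config = preprocess_config()) {
  if (!is.matrix(slice) || nrow(slice) < 2L || ncol(slice) < 2L) {
    abort_invalid("slice must be a matrix with at least 2 rows and 2 columns")
  }
  ts <- config$target_size
  scale_y <- ts / nrow(slice)
  scale_x <- ts / ncol(slice)
  if (nrow(slice) == ts && ncol(slice) == ts) {
    out <- slice
  } else {
    # EBImage matrices are (x, y); transpose so rows/cols map to h/w correctly
    out <- t(EBImage::resize(t(slice), w = ts, h = ts, filter = "bilinear"))
  }
  list(image = out, scale_x = scale_x, scale_y = scale_y)
}

#' Linearly rescale a slice into \[0, 1\]
#'
#' Maps the slice's minimum to 0 and maximum to 1.  A constant slice maps to
#' all zeros (the conservative "no signal" convention for the degenerate
#' min == max case).
#'
#' @param slice Numeric matrix.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
normalize_unit <- function(slice) {
  lo <- min(slice)
  hi <- max(slice)
  if (hi == lo) {
    slice[] <- 0
    return(slice)
  }
  (slice - lo) / (hi - lo)
}

#' Apply the full preprocessing pipeline to one slice
#'
#' Order matters and is fixed: HU clipping, then resizing, then per-slice
#' \[0, 1\] normalization.  Clipping first means each slice's unit interval
#' spans at most the HU window.
#'
#' @param slice Numeric matrix of HU values.
#' @param config A [preprocess_config()].
#' @return List with `image` (normalized target raster), `scale_x`,
#'   `scale_y`.
#' @export
preprocess_slice <- function(slice, config = preprocess_config()) {
  r <- resize_to_target(clip_hu(slice, config), config)
  r$image <- normalize_unit(r$image)
  r
}

#' Preprocess every slice of a volume
#'
#' @param volume A [ct_volume()].
#' @param config A [preprocess_config()].
#' @return List with `images` (list of normalized matrices, one per slice, in
#'   axial order), `scale_x`, `scale_y`, `scan_id`.
#' @export
preprocess_volume <- function(volume, config = preprocess_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  sx <- config$target_size / volume$in_plane_shape[2]
  sy <- config$target_size / volume$in_plane_shape[1]
  images <- lapply(seq_len(volume$n_slices) - 1L, function(s) {
    preprocess_slice(get_slice(volume, s), config)$image
  })
  list(images = images, scale_x = sx, scale_y = sy, scan_id = volume$scan_id)
}
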