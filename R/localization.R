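# 2D-slice detections -> unique 3D location estimate.
#
# The aggregation rule is a pure argmax: run the detector on every axial
# slice, collect all positive detections, pick the one with the highest
# classification score, and take its box center together with its slice
# index as the (x, y, slice) location estimate for the scan.

#' Run the detector over every axial slice of a volume
#'
#' Each slice is preprocessed (HU clip, resize to the detector raster,
#' unit normalization) and passed to [detect_slice()]; the returned
#' detections carry their 0-based `slice_index` and the scan id, and are
#' concatenated across slices.  Box coordinates are on the preprocessed
#' raster.
#'
#' @param detector A detector implementing [predict_boxes()].
#' @param volume A [ct_volume()].
#' @param preprocess A [preprocess_config()]; its `target_size` must equal
#'   the detector raster `det_config$input_size`.
#' @param det_config A [detector_config()].
#' @return Data frame of detections (possibly zero rows) with columns
#'   `scan_id, slice_index, x, y, w, h, score, class_label`.
#' @export
detect_volume <- function(detector, volume, preprocess, det_config) {
  stopifnot(inherits(volume, "ct_volume"))
  if (preprocess$target_size != det_config$input_size) {
    abort_invalid("preprocess target_size must equal the detector input_size")
  }
  prep <- preprocess_volume(volume, preprocess)
  out <- vector("list", volume$n_slices)
  for (s in seq_len(volume$n_slices)) {
    det <- detect_slice(detector, prep$images[[s]], det_config)
    if (nrow(det)) {
      det$scan_id <- volume$scan_id
      det$slice_index <- s - 1L
    }
    out[[s]] <- det
  }
  do.call(rbind, out)
}

#' Reduce positive detections to the unique location estimate
#'
#' Selects the detection with the maximum classification score; its box
#' center (continuous pixel coordinates, no rounding) and slice index form
#' the scan's location estimate.  Exactly tied scores are broken by lowest
#' slice index, then lowest box `x`, then lowest box `y`, making the result
#' independent of input order.
#'
#' @param detections Data frame of positive detections for one scan, as
#'   returned by [detect_volume()].
#' @return `NULL` if `detections` is empty; otherwise an object of class
#'   `location_estimate` with fields `scan_id, x, y, slice, score, source`
#'   (the winning detection row).
#' @export
estimate_location <- function(detections) {
  if (is.null(detections) || nrow(detections) == 0L) return(NULL)
  i <- order(-detections$score, detections$slice_index,
             detections$x, detections$y)[1]
  win <- detections[i, , drop = FALSE]
  structure(
    list(scan_id = win$scan_id,
         x = win$x + win$w / 2,
         y = win$y + win$h / 2,
         slice = win$slice_index,
         score = win$score,
         source = win),
    class = "location_estimate"
  )
}

#' @export
print.location_estimate <- function(x, ...) {
  cat(sprintf("<location_estimate> scan '%s': (x = %.2f, y = %.2f, slice = %d), score %.3f\n",
              x$scan_id, x$x, x$y, x$slice, x$score))
  invisible(x)
}

#' Localize the target structure in a volume
#'
#' Convenience wrapper: [detect_volume()] followed by
#' [estimate_location()].
#'
#' @inheritParams detect_volume
#' @return A `location_estimate`, or `NULL` when no slice yields a positive
#'   detection.
#' @export
localize_volume <- function(detector, volume, preprocess, det_config) {
  estimate_location(detect_volume(detector, volume, preprocess, det_config))
}
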