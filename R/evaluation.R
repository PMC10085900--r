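# Evaluation stack: IoU, per-slice outcome classification, VOC-style
# interpolated average precision, per-scan localization evaluation, and the
# summary report.

# scalar IoU on (x, y, w, h) values; also used by NMS
iou_xywh <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  iw <- pmax(0, pmin(ax + aw, bx + bw) - pmax(ax, bx))
  ih <- pmax(0, pmin(ay + ah, by + bh) - pmax(ay, by))
  inter <- iw * ih
  inter / (aw * ah + bw * bh - inter)
}

#' Intersection over union of two boxes
#'
#' `|A intersect B| / |A union B|` using continuous box areas; 0 for
#' disjoint boxes, 1 only for identical boxes.
#'
#' @param a,b [bounding_box()] objects (positive area by construction).
#' @return IoU value in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (a$w <= 0 || a$h <= 0 || b$w <= 0 || b$h <= 0) {
    abort_invalid("boxes must have positive area")
  }
  iou_xywh(a$x, a$y, a$w, a$h, b$x, b$y, b$w, b$h)
}

#' Classify the detection outcome for one slice
#'
#' Applies the per-detection rules: a detection is positive when its score
#' is at or above `score_threshold`; a positive detection matches when its
#' IoU with the slice's ground-truth box exceeds `iou_threshold` and the
#' class agrees.  The slice is TP if annotated with a matching positive
#' detection; FP if there is a positive detection but no match (whether or
#' not the slice is annotated); FN if annotated with no positive detection;
#' TN if unannotated with no positive detection.
#'
#' @param detections Data frame of detections for this slice (any scores;
#'   filtering to positives happens here).
#' @param annotation A [slice_annotation()] with its box on the detection
#'   raster, or `NULL` for an unannotated slice.
#' @param score_threshold Positive-detection threshold (default 0.05).
#' @param iou_threshold Match threshold (default 0.5, strict `>`).
#' @return List with `category` (`"TP"/"FP"/"TN"/"FN"`), `annotated`,
#'   `best_iou` (max IoU of positive detections vs ground truth, `NA` if
#'   undefined) and `best_score` (max detection score on the slice, `NA` if
#'   no detections).
#' @export
classify_slice <- function(detections, annotation = NULL,
                           score_threshold = 0.05, iou_threshold = 0.5) {
  annotated <- !is.null(annotation)
  best_score <- if (!is.null(detections) && nrow(detections)) max(detections$score) else NA_real_
  pos <- if (is.null(detections) || nrow(detections) == 0L) {
    empty_detections()
  } else {
    detections[detections$score >= score_threshold, , drop = FALSE]
  }
  best_iou <- NA_real_
  if (annotated && nrow(pos)) {
    gt <- annotation$box
    ious <- iou_xywh(pos$x, pos$y, pos$w, pos$h, gt$x, gt$y, gt$w, gt$h)
    right_class <- pos$class_label == annotation$class_label
    best_iou <- max(ious)
    matched <- any(ious > iou_threshold & right_class)
  } else {
    matched <- FALSE
  }
  category <- if (annotated) {
    if (matched) "TP" else if (nrow(pos)) "FP" else "FN"
  } else {
    if (nrow(pos)) "FP" else "TN"
  }
  list(category = category, annotated = annotated,
       best_iou = best_iou, best_score = best_score)
}

#' Classify every slice of a test set
#'
#' @param detections Data frame of positive detections across scans
#'   (`scan_id, slice_index, x, y, w, h, score, class_label`).
#' @param annotations An [annotation_set()] with boxes on the detection
#'   raster.
#' @param scan_slices Named integer vector: slices per scan
#'   (`scan_id -> n_slices`); every slice of every scan is evaluated.
#' @param score_threshold,iou_threshold As in [classify_slice()].
#' @return Data frame with one row per slice: `scan_id, slice_index,
#'   annotated, category, best_iou, best_score`.
#' @export
classify_slices <- function(detections, annotations, scan_slices,
                            score_threshold = 0.05, iou_threshold = 0.5) {
  ann_df <- as.data.frame(annotations)
  rows <- vector("list", sum(scan_slices))
  k <- 0L
  for (sid in names(scan_slices)) {
    det_scan <- detections[detections$scan_id == sid, , drop = FALSE]
    ann_scan <- ann_df[ann_df$scan_id == sid, , drop = FALSE]
    for (s in seq_len(scan_slices[[sid]]) - 1L) {
      det <- det_scan[det_scan$slice_index == s, , drop = FALSE]
      arow <- ann_scan[ann_scan$slice_index == s, , drop = FALSE]
      ann <- if (nrow(arow)) {
        slice_annotation(sid, s, bounding_box(arow$x, arow$y, arow$w, arow$h),
                         arow$class_label)
      } else NULL
      res <- classify_slice(det, ann, score_threshold, iou_threshold)
      k <- k + 1L
      rows[[k]] <- data.frame(scan_id = sid, slice_index = s,
                              annotated = res$annotated,
                              category = res$category,
                              best_iou = res$best_iou,
                              best_score = res$best_score)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Interpolated average precision
#'
#' Detections are ranked by descending classification score across the whole
#' test set and greedily matched: a detection is a true positive if its IoU
#' with a not-yet-matched ground-truth box on its slice exceeds
#' `iou_threshold` (each ground truth is matched at most once; duplicates
#' count as false positives).  Precision and recall are accumulated down the
#' ranked list and the all-point interpolated precision
#' `p_interp(r) = max p(r')` over `r' >= r` gives
#' `AP = sum (r_{n+1} - r_n) p_interp(r_{n+1})`.
#'
#' @param detections Data frame of positive detections
#'   (`scan_id, slice_index, x, y, w, h, score`).
#' @param annotations An [annotation_set()] on the same raster; must contain
#'   at least one annotation.
#' @param iou_threshold Match threshold (strict `>`, default 0.5).
#' @return Object of class `ap_result`: `ap` in `[0, 1]`, `curve` (data
#'   frame `recall, precision, score` down the ranked list),
#'   `n_ground_truth`.
#' @export
average_precision <- function(detections, annotations, iou_threshold = 0.5) {
  n_gt <- length(annotations$annotations)
  if (n_gt == 0L) abort_invalid("average precision needs at least one ground truth")
  if (is.null(detections) || nrow(detections) == 0L) {
    return(structure(list(ap = 0,
                          curve = data.frame(recall = numeric(0),
                                             precision = numeric(0),
                                             score = numeric(0)),
                          n_ground_truth = n_gt),
                     class = "ap_result"))
  }
  ann_df <- as.data.frame(annotations)
  ann_key <- paste(ann_df$scan_id, ann_df$slice_index, sep = "\r")
  matched <- rep(FALSE, nrow(ann_df))
  ord <- order(-detections$score)
  tp <- logical(length(ord))
  for (r in seq_along(ord)) {
    d <- detections[ord[r], ]
    j <- match(paste(d$scan_id, d$slice_index, sep = "\r"), ann_key)
    if (!is.na(j) && !matched[j]) {
      v <- iou_xywh(d$x, d$y, d$w, d$h,
                    ann_df$x[j], ann_df$y[j], ann_df$w[j], ann_df$h[j])
      if (v > iou_threshold) {
        tp[r] <- TRUE
        matched[j] <- TRUE
      }
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  p_interp <- rev(cummax(rev(precision)))
  ap <- sum((recall - c(0, head(recall, -1))) * p_interp)
  structure(
    list(ap = ap,
         curve = data.frame(recall = recall, precision = precision,
                            score = detections$score[ord]),
         n_ground_truth = n_gt),
    class = "ap_result"
  )
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> AP = %.4f over %d ground truths (%d detections)\n",
              x$ap, x$n_ground_truth, nrow(x$curve)))
  invisible(x)
}

#' Evaluate the location estimate for one scan
#'
#' Per-scan categories: FN when no estimate exists (every scan contains the
#' target, so a missing estimate is always a miss); TP when the winning
#' detection's slice is annotated and its box matches that slice's ground
#' truth at IoU above `iou_threshold`; FP otherwise.  There is no TN
#' category.  For TP and FP, `axial_distance` is the Euclidean in-plane
#' distance from the estimate to the ground-truth box center on the nearest
#' annotated slice (nearest by absolute slice difference, ties to the lower
#' slice index) and `slice_offset` the signed slice difference (estimate
#' minus nearest annotated slice; 0 for in-slice estimates).
#'
#' @param estimate A `location_estimate` or `NULL`.
#' @param scan_annotations List of [slice_annotation()] for the scan, boxes
#'   on the detection raster; must be non-empty.
#' @param iou_threshold Match threshold (strict `>`, default 0.5).
#' @return List with `scan_id, category ("TP"/"FP"/"FN"), axial_distance,
#'   slice_offset` (distances `NA` iff FN).
#' @export
evaluate_scan_localization <- function(estimate, scan_annotations,
                                       iou_threshold = 0.5) {
  if (length(scan_annotations) == 0L) {
    abort_invalid("scan has no annotations; every evaluated scan must contain the target")
  }
  if (is.null(estimate)) {
    return(list(scan_id = scan_annotations[[1]]$scan_id, category = "FN",
                axial_distance = NA_real_, slice_offset = NA_integer_))
  }
  slices <- vapply(scan_annotations, `[[`, integer(1), "slice_index")
  # nearest annotated slice: smallest |difference|, ties to the lower index
  d <- abs(slices - estimate$slice)
  nearest <- scan_annotations[[order(d, slices)[1]]]
  center <- box_center(nearest$box)
  axial <- sqrt((estimate$x - center[["x"]])^2 + (estimate$y - center[["y"]])^2)
  offset <- estimate$slice - nearest$slice_index
  in_slice <- which(slices == estimate$slice)
  category <- "FP"
  if (length(in_slice)) {
    gt <- scan_annotations[[in_slice[1]]]$box
    src <- estimate$source
    if (iou_xywh(src$x, src$y, src$w, src$h, gt$x, gt$y, gt$w, gt$h) > iou_threshold) {
      category <- "TP"
    }
  }
  list(scan_id = estimate$scan_id, category = category,
       axial_distance = axial, slice_offset = as.integer(offset))
}

summ3 <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, lq = NA_real_, uq = NA_real_))
  q <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], lq = q[2], uq = q[3])
}

mean_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
}

#' Summarize an evaluation run
#'
#' Builds the full report: the presence/absence slice table (annotated
#' slices split into detected-and-matched vs not, unannotated slices into
#' positively-detected vs not — so the row totals are the numbers of
#' annotated and unannotated slices), raw outcome-category counts, AP,
#' median/quartile score and IoU summaries (linear-interpolation quantiles),
#' and per-scan localization categories with mean/SD axial distances.
#' Slices with no detection contribute a classification score of 0 to the
#' score summaries.
#'
#' @param slice_outcomes Data frame from [classify_slices()].
#' @param ap_result An `ap_result` from [average_precision()].
#' @param scan_results List of per-scan results from
#'   [evaluate_scan_localization()].
#' @return Object of class `evaluation_report`.
#' @export
summarize_evaluation <- function(slice_outcomes, ap_result, scan_results) {
  so <- slice_outcomes
  ann <- so[so$annotated, , drop = FALSE]
  una <- so[!so$annotated, , drop = FALSE]
  tbl <- data.frame(
    row = c("soi_in_slice", "soi_not_in_slice"),
    detected = c(sum(ann$category == "TP"), sum(una$category == "FP")),
    not_detected = c(sum(ann$category != "TP"), sum(una$category == "TN")),
    total = c(nrow(ann), nrow(una))
  )
  tbl$detected_pct <- ifelse(tbl$total > 0, 100 * tbl$detected / tbl$total, NA)
  tbl$not_detected_pct <- ifelse(tbl$total > 0, 100 * tbl$not_detected / tbl$total, NA)

  outcome_counts <- c(
    TP = sum(so$category == "TP"), FP = sum(so$category == "FP"),
    TN = sum(so$category == "TN"), FN = sum(so$category == "FN")
  )

  score0 <- function(v) ifelse(is.na(v), 0, v)
  score_summary <- rbind(
    annotated_slices = summ3(score0(ann$best_score)),
    false_positive_slices = summ3(score0(so$best_score[so$category == "FP"])),
    true_negative_slices = summ3(score0(so$best_score[so$category == "TN"]))
  )
  iou_summary <- rbind(annotated_slices = summ3(ann$best_iou))

  cats <- vapply(scan_results, `[[`, character(1), "category")
  dist <- vapply(scan_results, function(r) as.numeric(r$axial_distance), numeric(1))
  offs <- vapply(scan_results, function(r) as.numeric(r$slice_offset), numeric(1))
  n_scans <- length(scan_results)
  scan_summary <- data.frame(
    category = c("TP", "FP", "FN"),
    count = c(sum(cats == "TP"), sum(cats == "FP"), sum(cats == "FN")),
    fraction = if (n_scans > 0) {
      c(mean(cats == "TP"), mean(cats == "FP"), mean(cats == "FN"))
    } else rep(NA_real_, 3)
  )
  scan_distance <- rbind(
    TP = mean_sd(dist[cats == "TP"]),
    FP = mean_sd(dist[cats == "FP"])
  )
  mean_fp_offset <- if (any(cats == "FP")) mean(abs(offs[cats == "FP"])) else NA_real_

  structure(
    list(slice_table = tbl, outcome_counts = outcome_counts,
         ap = ap_result, score_summary = score_summary,
         iou_summary = iou_summary, scan_summary = scan_summary,
         scan_distance = scan_distance, mean_fp_slice_offset = mean_fp_offset,
         n_slices = nrow(so), n_scans = n_scans),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d slices, %d scans\n", x$n_slices, x$n_scans))
  cat(sprintf("  AP: %.4f\n", x$ap$ap))
  t <- x$slice_table
  cat(sprintf("  target in slice:     %d / %d detected (%.1f%%)\n",
              t$detected[1], t$total[1], t$detected_pct[1]))
  cat(sprintf("  target not in slice: %d / %d false positives (%.1f%%)\n",
              t$detected[2], t$total[2], t$detected_pct[2]))
  s <- x$scan_summary
  cat(sprintf("  scans: %d TP (%.0f%%), %d FP (%.0f%%), %d FN (%.0f%%)\n",
              s$count[1], 100 * s$fraction[1], s$count[2], 100 * s$fraction[2],
              s$count[3], 100 * s$fraction[3]))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    ap = report$ap$ap,
    n_ground_truth = report$ap$n_ground_truth,
    slice_table = report$slice_table,
    outcome_counts = as.list(report$outcome_counts),
    score_summary = as.data.frame(report$score_summary),
    iou_summary = as.data.frame(report$iou_summary),
    scan_summary = report$scan_summary,
    scan_distance = as.data.frame(report$scan_distance),
    mean_fp_slice_offset = report$mean_fp_slice_offset,
    n_slices = report$n_slices,
    n_scans = report$n_scans
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
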