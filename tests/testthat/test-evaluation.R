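test_that("IoU matches closed forms and its invariances", {
  a <- bounding_box(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bounding_box(20, 20, 5, 5)), 0)
  expect_equal(iou(a, bounding_box(5, 0, 10, 10)), 1 / 3)

  set.seed(13)
  for (i in 1:25) {
    b1 <- bounding_box(runif(1, 0, 50), runif(1, 0, 50), runif(1, 1, 30), runif(1, 1, 30))
    b2 <- bounding_box(runif(1, 0, 50), runif(1, 0, 50), runif(1, 1, 30), runif(1, 1, 30))
    v <- iou(b1, b2)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(iou(b2, b1), v)                      # symmetry
    shift <- function(b, dx, dy) bounding_box(b$x + dx, b$y + dy, b$w, b$h)
    expect_equal(iou(shift(b1, 7, 3), shift(b2, 7, 3)), v)   # translation
    expect_equal(iou(rescale_box(b1, 2.5, 2.5), rescale_box(b2, 2.5, 2.5)),
                 v, tolerance = 1e-12)                # uniform scaling
  }
})

test_that("slice outcomes follow the positive/match rules", {
  ann <- slice_annotation("s", 3L, bounding_box(10, 10, 20, 10))
  # matching positive detection on an annotated slice
  tp <- classify_slice(make_det("s", 3L, x = 11, y = 10, w = 20, h = 10, score = 0.96),
                       ann)
  expect_equal(tp$category, "TP")
  expect_gt(tp$best_iou, 0.5)
  # no detections at all on an unannotated slice
  tn <- classify_slice(make_det()[0, ], NULL)
  expect_equal(tn$category, "TN")
  expect_true(is.na(tn$best_score))
  # positive but poorly-overlapping detection on an annotated slice
  fp <- classify_slice(make_det("s", 3L, x = 28, y = 18, w = 20, h = 10, score = 0.9),
                       ann)
  expect_lt(fp$best_iou, 0.5)
  expect_equal(fp$category, "FP")
  # annotated slice with only sub-threshold detections is a miss
  fn <- classify_slice(make_det("s", 3L, x = 11, y = 10, w = 20, h = 10, score = 0.01),
                       ann)
  expect_equal(fn$category, "FN")
})

test_that("average precision matches hand-derived and degenerate cases", {
  anns <- annotation_set(list(
    slice_annotation("s", 0L, bounding_box(10, 10, 8, 6)),
    slice_annotation("s", 1L, bounding_box(30, 10, 8, 6))
  ))
  # ranked outcomes: match, non-match, match
  dets <- rbind(
    make_det("s", 0L, x = 10, y = 10, w = 8, h = 6, score = 0.9),
    make_det("s", 5L, x = 90, y = 90, w = 8, h = 6, score = 0.8),
    make_det("s", 1L, x = 30, y = 10, w = 8, h = 6, score = 0.7)
  )
  res <- average_precision(dets, anns)
  expect_equal(res$ap, 5 / 6, tolerance = 1e-12)
  expect_equal(res$curve$recall, c(0.5, 0.5, 1))
  expect_equal(res$curve$precision, c(1, 0.5, 2 / 3))

  # perfect detector
  perfect <- dets[c(1, 3), ]
  expect_equal(average_precision(perfect, anns)$ap, 1)

  # one ground truth, one non-matching detection
  one <- annotation_set(list(slice_annotation("s", 0L, bounding_box(10, 10, 8, 6))))
  expect_equal(average_precision(make_det("s", 4L, x = 80, y = 80), one)$ap, 0)

  expect_error(average_precision(dets, annotation_set()),
               class = "clavloc_invalid_input")
})

test_that("AP depends on score ranks only and dominates the trapezoidal area", {
  set.seed(17)
  for (trial in 1:30) {
    inst <- ap_oracle_instance(seed = 1000 + trial)
    res <- average_precision(inst$detections, inst$annotations)
    # strictly monotone transform of the scores leaves AP unchanged
    warped <- inst$detections
    warped$score <- plogis(3 * warped$score - 1)
    expect_equal(average_precision(warped, inst$annotations)$ap, res$ap,
                 tolerance = 1e-12)
    # interpolated AP >= trapezoid under the raw precision-recall curve
    r <- res$curve$recall; p <- res$curve$precision
    trap <- sum(diff(c(0, r)) * (p + c(1, head(p, -1))) / 2)
    expect_gte(res$ap, trap - 1e-12)
    # recalls are non-decreasing down the ranked list
    expect_true(all(diff(r) >= 0))
  }
})

test_that("scan localization categories and distances follow the per-scan rules", {
  anns <- lapply(c(13L, 14L, 15L), function(s) {
    slice_annotation("s", s, bounding_box(20, 30, 20, 10))
  })
  # no estimate: automatic miss (every scan contains the target)
  fn <- evaluate_scan_localization(NULL, anns)
  expect_equal(fn$category, "FN")
  expect_true(is.na(fn$axial_distance) && is.na(fn$slice_offset))

  # estimate exactly at a ground-truth center on an annotated slice
  hit <- estimate_location(make_det("s", 14L, x = 20, y = 30, w = 20, h = 10,
                                    score = 0.9))
  tp <- evaluate_scan_localization(hit, anns)
  expect_equal(tp$category, "TP")
  expect_equal(tp$axial_distance, 0)
  expect_equal(tp$slice_offset, 0L)

  # estimate one slice below the annotated span
  near <- estimate_location(make_det("s", 12L, x = 21, y = 31, w = 20, h = 10,
                                     score = 0.9))
  fp <- evaluate_scan_localization(near, anns)
  expect_equal(fp$category, "FP")
  expect_equal(fp$slice_offset, -1L)
  expect_equal(fp$axial_distance, sqrt(2))

  # positive but non-matching box on an annotated slice is also FP, offset 0
  off <- estimate_location(make_det("s", 14L, x = 60, y = 70, w = 20, h = 10,
                                    score = 0.9))
  fp2 <- evaluate_scan_localization(off, anns)
  expect_equal(fp2$category, "FP")
  expect_equal(fp2$slice_offset, 0L)

  expect_error(evaluate_scan_localization(hit, list()),
               class = "clavloc_invalid_input")
})

test_that("nearest-annotated-slice ties resolve to the lower index", {
  anns <- lapply(c(10L, 14L), function(s) {
    slice_annotation("s", s, bounding_box(s, 30, 20, 10))  # distinct centers
  })
  est <- estimate_location(make_det("s", 12L, x = 10, y = 30, w = 20, h = 10,
                                    score = 0.9))
  res <- evaluate_scan_localization(est, anns)
  expect_equal(res$slice_offset, 2L)  # measured against slice 10, not 14
})

test_that("the report reproduces the presence/absence table fractions", {
  synth_outcomes <- rbind(
    data.frame(scan_id = "s", slice_index = 1:338, annotated = TRUE,
               category = "TP", best_iou = 0.8, best_score = 0.99),
    data.frame(scan_id = "s", slice_index = 1:41, annotated = TRUE,
               category = "FN", best_iou = NA, best_score = NA),
    data.frame(scan_id = "s", slice_index = 1:51, annotated = FALSE,
               category = "FP", best_iou = NA, best_score = 0.88),
    data.frame(scan_id = "s", slice_index = 1:30416, annotated = FALSE,
               category = "TN", best_iou = NA, best_score = NA)
  )
  ap <- structure(list(ap = 0.82, curve = data.frame(), n_ground_truth = 379L),
                  class = "ap_result")
  rep <- summarize_evaluation(synth_outcomes, ap, list())
  tbl <- rep$slice_table
  expect_equal(tbl$total, c(379L, 30467L))
  expect_equal(round(tbl$detected_pct, 1), c(89.2, 0.2))
  expect_equal(round(tbl$not_detected_pct, 1), c(10.8, 99.8))
  expect_equal(sum(rep$outcome_counts), nrow(synth_outcomes))

  all_tp <- data.frame(scan_id = "s", slice_index = 1:10, annotated = TRUE,
                       category = "TP", best_iou = 0.9, best_score = 1)
  rep2 <- summarize_evaluation(all_tp, ap, list())
  expect_equal(rep2$slice_table$detected_pct[1], 100)
  expect_equal(rep2$slice_table$not_detected_pct[1], 0)
})

test_that("score summaries use linear-interpolation quantiles", {
  outcomes <- data.frame(scan_id = "s", slice_index = 0:2, annotated = TRUE,
                         category = "TP", best_iou = 0.8,
                         best_score = c(0.1, 0.2, 0.3))
  ap <- structure(list(ap = 1, curve = data.frame(), n_ground_truth = 3L),
                  class = "ap_result")
  rep <- summarize_evaluation(outcomes, ap, list())
  expect_equal(unname(rep$score_summary["annotated_slices", ]),
               c(0.2, 0.15, 0.25))
})

test_that("reports serialize to JSON with the confusion and scan structure intact", {
  runs <- small_training_runs()
  rep <- runs[[1]]$eval$report
  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.json")
  write_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$ap, rep$ap$ap)
  expect_equal(back$n_scans, rep$n_scans)
  expect_equal(length(back$scan_summary), 3)
})
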