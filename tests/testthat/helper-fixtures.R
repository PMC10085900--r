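# Shared fixtures.  Training runs are cached in an environment so the
# seeded end-to-end fits are computed once per test session and shared
# between the contract tests and the acceptance suite.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# detection data-frame builder matching the package's detection schema
make_det <- function(scan_id = "s1", slice_index = 0L, x = 10, y = 10,
                     w = 20, h = 10, score = 0.9, class_label = "sternum") {
  data.frame(scan_id = scan_id, slice_index = as.integer(slice_index),
             x = x, y = y, w = w, h = h, score = score,
             class_label = class_label)
}

# rescale an annotation list onto the detector raster
scale_annotations <- function(anns, size) {
  lapply(anns, function(a) {
    a$box <- rescale_box(a$box, size / a$orig_cols, size / a$orig_rows)
    a$orig_rows <- as.integer(size)
    a$orig_cols <- as.integer(size)
    a
  })
}

# small phantom dataset + train/val/test split used by several tests
small_phantom_split <- function() {
  cached("small_split", {
    ds <- generate_dataset(10, phantom_spec(), seed = 301)
    s1 <- split_holdout(ds, 0.8, seed = 302)  # 8 trainval / 2 test
    s2 <- split_holdout(s1$train, 0.75, seed = 303)  # 6 train / 2 val
    list(train = s2$train, val = s2$rest, test = s1$rest)
  })
}

small_config <- function(seed = 401) {
  mini_detector_config(seed = seed, epochs = 3L)
}

build_sds <- function(part, size = 64L) {
  slice_dataset(lapply(part, `[[`, "volume"), dataset_annotations(part), size)
}

# evaluate a trained detector on held-out volumes; returns detections,
# per-scan results, outcomes and the report
evaluate_on_split <- function(detector, test_part, cfg) {
  size <- cfg$input_size
  pp <- preprocess_config(target_size = size)
  dets <- list()
  scan_results <- list()
  for (d in test_part) {
    dd <- detect_volume(detector, d$volume, pp, cfg)
    est <- estimate_location(dd)
    anns <- scale_annotations(d$annotations$annotations, size)
    scan_results[[d$volume$scan_id]] <- evaluate_scan_localization(est, anns)
    dets[[d$volume$scan_id]] <- dd
  }
  detections <- do.call(rbind, dets)
  test_anns <- annotation_set(scale_annotations(
    dataset_annotations(test_part)$annotations, size))
  scan_slices <- setNames(
    vapply(test_part, function(d) d$volume$n_slices, integer(1)),
    vapply(test_part, function(d) d$volume$scan_id, character(1))
  )
  outcomes <- classify_slices(detections, test_anns, scan_slices,
                              cfg$score_threshold)
  ap <- average_precision(detections, test_anns)
  list(detections = detections, scan_results = scan_results,
       outcomes = outcomes, ap = ap,
       report = summarize_evaluation(outcomes, ap, scan_results))
}

# two identical seeded small training runs (determinism checks + smoke
# properties); each element has $fit and $eval
small_training_runs <- function() {
  cached("small_runs", {
    sp <- small_phantom_split()
    cfg <- small_config()
    tr <- build_sds(sp$train)
    va <- build_sds(sp$val)
    run_once <- function() {
      fit <- train_detector(tr, va, cfg)
      list(fit = fit, eval = evaluate_on_split(fit$detector, sp$test, cfg))
    }
    list(run_once(), run_once())
  })
}

# the headline seeded end-to-end fit: 40 training phantoms at default
# phantom conditions, 5 validation, 12 held-out test volumes
headline_run <- function() {
  cached("headline_run", {
    ds <- generate_dataset(57, phantom_spec(), seed = 501)
    s1 <- split_holdout(ds, 0.8, seed = 502)   # 45 trainval / 12 test
    s2 <- split_holdout(s1$train, 0.9, seed = 503)  # 40 train / 5 val
    cfg <- mini_detector_config(seed = 504)
    fit <- train_detector(build_sds(s2$train), build_sds(s2$rest), cfg)
    list(fit = fit, test = s1$rest, cfg = cfg,
         eval = evaluate_on_split(fit$detector, s1$rest, cfg))
  })
}

# independent average-precision oracle: detections either coincide exactly
# with a ground-truth box or are placed disjoint from everything, so
# matching reduces to "highest score per ground truth wins"; AP is then
# computed by direct enumeration of max-right interpolated precision
ap_oracle_instance <- function(seed) {
  set.seed(seed)
  n_gt <- sample(1:5, 1)
  n_det <- sample(1:10, 1)
  gt <- data.frame(scan_id = "s", slice_index = seq_len(n_gt) - 1L,
                   x = 10 * seq_len(n_gt), y = 5, w = 8, h = 6)
  anns <- annotation_set(lapply(seq_len(n_gt), function(i) {
    slice_annotation("s", gt$slice_index[i],
                     bounding_box(gt$x[i], gt$y[i], gt$w[i], gt$h[i]),
                     orig_rows = 128L, orig_cols = 128L)
  }))
  scores <- round(runif(n_det), 6)
  hits <- sample(c(NA, seq_len(n_gt)), n_det, replace = TRUE)
  det <- do.call(rbind, lapply(seq_len(n_det), function(i) {
    if (is.na(hits[i])) {
      # disjoint decoy far from every ground truth, on an unannotated slice
      make_det("s", 100L + i, x = 200 + 20 * i, y = 100, w = 5, h = 5,
               score = scores[i])
    } else {
      j <- hits[i]
      make_det("s", gt$slice_index[j], x = gt$x[j], y = gt$y[j],
               w = gt$w[j], h = gt$h[j], score = scores[i])
    }
  }))
  # oracle TP flags: per ground truth, the highest-scoring coinciding
  # detection is the match (ties broken by rank order, as greedy matching does)
  ord <- order(-det$score)
  used <- rep(FALSE, n_gt)
  tp <- logical(n_det)
  for (r in ord) {
    j <- hits[r]
    if (!is.na(j) && !used[j]) {
      tp[r] <- TRUE
      used[j] <- TRUE
    }
  }
  tp_ranked <- tp[ord]
  list(detections = det, annotations = anns, tp_ranked = tp_ranked, n_gt = n_gt)
}

ap_oracle_from_flags <- function(tp_ranked, n_gt) {
  cum_tp <- cumsum(tp_ranked)
  rec <- cum_tp / n_gt
  prec <- cum_tp / seq_along(tp_ranked)
  ap <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    if (rec[i] > prev_r) {
      ap <- ap + (rec[i] - prev_r) * max(prec[rec >= rec[i]])
      prev_r <- rec[i]
    }
  }
  ap
}
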