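# End-to-end orchestration: simulate -> split -> train -> localize ->
# evaluate, driven by a single run configuration (YAML-serializable).

#' Build a run configuration
#'
#' Bundles the nested preprocessing, detector and phantom configurations
#' with dataset sizing, paths and the mandatory master seed.  All stage
#' seeds are derived from `seed`, so a run is a pure function of its
#' configuration.
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Master integer seed (mandatory; no silent nondeterminism).
#' @param n_volumes Number of phantoms to simulate (ignored when
#'   `input_dir` is given).
#' @param test_fraction Fraction of scans held out for testing.
#' @param train_fraction Train share of the remaining scans (the rest
#'   becomes the validation set).
#' @param preprocess A [preprocess_config()]; its `target_size` must equal
#'   the detector `input_size`.
#' @param detector A [detector_config()].
#' @param phantom A [phantom_spec()].
#' @param input_dir Optional directory of NIfTI volumes plus
#'   `annotations.csv`; when given, simulation is skipped.
#' @param log_level Package log level for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed, n_volumes = 50L, test_fraction = 0.2,
                       train_fraction = 0.9,
                       preprocess = preprocess_config(target_size = 64L),
                       detector = mini_detector_config(),
                       phantom = phantom_spec(),
                       input_dir = NULL, log_level = "info") {
  if (missing(seed) || is.null(seed)) abort_invalid("a run seed is mandatory")
  if (preprocess$target_size != detector$input_size) {
    abort_invalid("preprocess target_size must equal detector input_size")
  }
  if (is.null(input_dir) && n_volumes < 5L) {
    abort_invalid("need at least 5 volumes to form train/val/test splits")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_volumes = as.integer(n_volumes), test_fraction = test_fraction,
         train_fraction = train_fraction, preprocess = preprocess,
         detector = detector, phantom = phantom, input_dir = input_dir,
         log_level = log_level),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Top-level keys `out_dir, seed, n_volumes, test_fraction, train_fraction,
#' input_dir, log_level` plus nested blocks `preprocess` (`hu_min, hu_max,
#' target_size`), `detector` (fields of [detector_config()]) and `phantom`
#' (fields of [phantom_spec()]).  Missing fields take the package defaults.
#'
#' @param path YAML file path.
#' @param overrides Named list of top-level overrides (e.g. from CLI
#'   flags).
#' @return A [run_config()].
#' @export
load_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort_not_found(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, overrides)
  pp <- do.call(preprocess_config, as.list(y$preprocess))
  det <- do.call(detector_config, as.list(y$detector))
  ph <- do.call(phantom_spec, as.list(y$phantom))
  args <- y[setdiff(names(y), c("preprocess", "detector", "phantom"))]
  do.call(run_config, c(args, list(preprocess = pp, detector = det, phantom = ph)))
}

load_input_dataset <- function(input_dir) {
  ann_path <- file.path(input_dir, "annotations.csv")
  if (!file.exists(ann_path)) {
    abort_invalid(sprintf("no annotations.csv in %s and simulation disabled", input_dir))
  }
  files <- sort(list.files(input_dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) abort_invalid(sprintf("no NIfTI volumes found in %s", input_dir))
  anns <- read_annotations(ann_path)
  lapply(files, function(f) {
    vol <- load_volume(f)
    list(volume = vol,
         annotations = annotation_set(annotations_for_scan(anns, vol$scan_id)))
  })
}

#' Run the full localization pipeline
#'
#' Executes the workflow end to end: simulate phantoms (or ingest volumes
#' and annotations from `input_dir`), split by scan into train/validation/
#' test, train the detector, localize every test volume, and evaluate
#' (per-slice outcomes, AP, per-scan localization).  All artifacts —
#' detector weights, training history CSV, predictions CSV, report JSON and
#' a manifest — are written under `config$out_dir`; a `.incomplete` marker
#' is present while the run is in progress and removed on success.
#'
#' @param config A [run_config()].
#' @return The `evaluation_report`, invisibly also written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  old_level <- set_log_level(config$log_level)
  on.exit(set_log_level(old_level), add = TRUE)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  marker <- file.path(out, ".incomplete")
  file.create(marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_clavloc(sprintf("pipeline stage '%s' failed: %s",
                            name, conditionMessage(e)), "clavloc_stage_error")
    })
  }

  clog(sprintf("run seed %d; HU window [%g, %g]; score threshold %g; IoU threshold 0.5",
               config$seed, config$preprocess$hu_min, config$preprocess$hu_max,
               config$detector$score_threshold))

  dataset <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      load_input_dataset(config$input_dir)
    } else {
      generate_dataset(config$n_volumes, config$phantom, seed = config$seed)
    }
  })

  splits <- stage("split", {
    s1 <- split_holdout(dataset, 1 - config$test_fraction, seed = config$seed + 1L)
    s2 <- split_holdout(s1$train, config$train_fraction, seed = config$seed + 2L)
    list(train = s2$train, val = s2$rest, test = s1$rest)
  })
  clog(sprintf("split: %d train / %d val / %d test scans",
               length(splits$train), length(splits$val), length(splits$test)))

  det_cfg <- config$detector
  det_cfg$seed <- config$seed + 3L
  size <- det_cfg$input_size
  as_sds <- function(part) {
    slice_dataset(lapply(part, `[[`, "volume"), dataset_annotations(part),
                  size, config$preprocess$hu_min, config$preprocess$hu_max)
  }
  trained <- stage("train", {
    train_detector(as_sds(splits$train), as_sds(splits$val), det_cfg)
  })
  write.csv(trained$history, file.path(out, "history.csv"), row.names = FALSE)
  save_detector(trained$detector, file.path(out, "weights.rds"))

  test_eval <- stage("localize", {
    detections <- list()
    scan_results <- list()
    for (d in splits$test) {
      dets <- detect_volume(trained$detector, d$volume, config$preprocess, det_cfg)
      est <- estimate_location(dets)
      ann_scaled <- lapply(d$annotations$annotations, function(a) {
        a$box <- rescale_box(a$box, size / a$orig_cols, size / a$orig_rows)
        a
      })
      scan_results[[d$volume$scan_id]] <- evaluate_scan_localization(est, ann_scaled)
      detections[[d$volume$scan_id]] <- dets
    }
    list(detections = do.call(rbind, c(list(empty_detections()), detections)),
         scan_results = scan_results)
  })
  write.csv(test_eval$detections, file.path(out, "predictions.csv"),
            row.names = FALSE)

  report <- stage("evaluate", {
    test_anns_scaled <- annotation_set(lapply(
      dataset_annotations(splits$test)$annotations, function(a) {
        a$box <- rescale_box(a$box, size / a$orig_cols, size / a$orig_rows)
        a$orig_rows <- size
        a$orig_cols <- size
        a
      }))
    scan_slices <- setNames(
      vapply(splits$test, function(d) d$volume$n_slices, integer(1)),
      vapply(splits$test, function(d) d$volume$scan_id, character(1))
    )
    outcomes <- classify_slices(test_eval$detections, test_anns_scaled,
                                scan_slices, det_cfg$score_threshold)
    ap <- average_precision(test_eval$detections, test_anns_scaled)
    summarize_evaluation(outcomes, ap, test_eval$scan_results)
  })
  write_report(report, file.path(out, "report.json"))

  manifest <- list(
    seed = config$seed,
    n_volumes = length(dataset),
    splits = lapply(splits, function(p) vapply(p, function(d) d$volume$scan_id,
                                               character(1))),
    score_threshold = det_cfg$score_threshold,
    iou_threshold = 0.5,
    hu_window = c(config$preprocess$hu_min, config$preprocess$hu_max),
    input_size = size,
    artifacts = c("weights.rds", "history.csv", "predictions.csv", "report.json")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  file.remove(marker)
  clog(sprintf("pipeline complete: AP %.3f, %d/%d scans localized in an annotated slice",
               report$ap$ap, report$scan_summary$count[1], report$n_scans))
  report
}
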