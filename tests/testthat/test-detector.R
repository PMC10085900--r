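test_that("focal loss matches its closed form and limiting cases", {
  # near-perfect prediction contributes (essentially) nothing
  expect_lt(focal_loss(1 - 1e-6, 1), 1e-9)
  # gamma = 0, alpha = 1 reduces to plain cross-entropy
  expect_equal(focal_loss(0.5, 1, alpha = 1, gamma = 0), log(2))
  # hand-evaluated closed form: 0.25 * (1 - 0.9)^2 * (-log 0.9)
  expect_equal(focal_loss(0.9, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.01 * (-log(0.9)), tolerance = 1e-12)
})

test_that("focal loss is non-negative, decreasing in p_t, and down-weights easy examples", {
  p <- seq(0.01, 0.99, by = 0.01)
  for (y in c(0, 1)) {
    l <- focal_loss(p, y)
    expect_true(all(l >= 0))
    lt <- if (y == 1) l else rev(l)  # loss as a function of increasing p_t
    expect_true(all(diff(lt) < 0))
    # modulating factor strictly below the alpha-weighted cross-entropy
    expect_true(all(focal_loss(p, y, gamma = 2) < focal_loss(p, y, gamma = 0)))
  }
})

test_that("the plateau scheduler decays by factor^2 after three constant-loss epochs", {
  st <- lr_plateau_init(1e-3, patience = 1L, factor = 10)
  for (i in 1:3) st <- lr_plateau_update(st, 0.5)  # loss never improves after epoch 1
  expect_equal(st$lr, 1e-3 / 100)
  # improvement resets the counter
  st2 <- lr_plateau_init(1e-3, patience = 2L, factor = 10)
  st2 <- lr_plateau_update(st2, 0.5)
  st2 <- lr_plateau_update(st2, 0.4)
  st2 <- lr_plateau_update(st2, 0.41)
  expect_equal(st2$lr, 1e-3)
})

test_that("NMS keeps the higher-scoring of two heavily overlapping boxes", {
  boxes <- data.frame(x = c(0, 1), y = c(0, 0), w = c(20, 20), h = c(10, 10))
  keep <- nms(boxes, c(0.9, 0.8), iou_threshold = 0.5)
  expect_equal(keep, 1L)
  # disjoint boxes both survive, ordered by score
  boxes2 <- data.frame(x = c(0, 50), y = c(0, 50), w = c(10, 10), h = c(10, 10))
  expect_equal(nms(boxes2, c(0.3, 0.7)), c(2L, 1L))
})

test_that("an untrained detector yields no positive detections on an empty image", {
  cfg <- mini_detector_config(seed = 17)
  det <- init_detector(cfg)
  out <- detect_slice(det, matrix(0, 64, 64), cfg)
  expect_equal(nrow(out), 0L)
  expect_error(detect_slice(det, matrix(0, 32, 32), cfg),
               class = "clavloc_invalid_input")
})

test_that("training rejects empty or annotation-free datasets", {
  cfg <- small_config()
  empty <- structure(list(images = list(), boxes = list(),
                          scan_id = character(0), slice_index = integer(0),
                          input_size = 64L), class = "slice_dataset")
  expect_error(train_detector(empty, empty, cfg), class = "clavloc_invalid_input")
  no_ann <- structure(list(images = list(matrix(0, 64, 64)),
                           boxes = list(NULL), scan_id = "s",
                           slice_index = 0L, input_size = 64L),
                      class = "slice_dataset")
  expect_error(train_detector(no_ann, empty, cfg), class = "clavloc_invalid_input")
})

test_that("seeded training produces a full, improving, reproducible history", {
  runs <- small_training_runs()
  h <- runs[[1]]$fit$history
  expect_equal(nrow(h), small_config()$epochs)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(diff(h$lr) <= 0))
  # identical seed and data give a bit-identical history
  expect_identical(h, runs[[2]]$fit$history)
})

test_that("the trained detector finds the phantom target with valid detection contracts", {
  run <- headline_run()
  cfg <- run$cfg
  d <- run$test[[1]]
  ann <- d$annotations$annotations[[1]]
  img <- preprocess_slice(get_slice(d$volume, ann$slice_index),
                          preprocess_config(target_size = 64))$image
  dets <- detect_slice(run$fit$detector, img, cfg)
  expect_gt(nrow(dets), 0L)
  expect_true(all(dets$score >= cfg$score_threshold))
  expect_true(all(diff(dets$score) <= 0))  # sorted descending
  gt <- rescale_box(ann$box, 0.5, 0.5)
  best <- iou(bounding_box(dets$x[1], dets$y[1], dets$w[1], dets$h[1]), gt)
  expect_gt(best, 0.5)
  # surviving detections respect the NMS overlap bound
  if (nrow(dets) > 1) {
    for (i in 1:(nrow(dets) - 1)) for (j in (i + 1):nrow(dets)) {
      expect_lte(iou(bounding_box(dets$x[i], dets$y[i], dets$w[i], dets$h[i]),
                     bounding_box(dets$x[j], dets$y[j], dets$w[j], dets$h[j])),
                 cfg$nms_iou)
    }
  }
})

test_that("flip augmentation approximates training on the mirror-doubled dataset", {
  sp <- small_phantom_split()
  cfg_aug <- mini_detector_config(seed = 421, epochs = 6L)
  tr <- build_sds(sp$train)
  va <- build_sds(sp$val)
  fit_aug <- train_detector(tr, va, cfg_aug)

  # mirror-double the training set along the horizontal axis
  flipped_images <- lapply(tr$images, function(m) m[, rev(seq_len(ncol(m)))])
  flipped_boxes <- lapply(tr$boxes, function(b) {
    if (is.null(b)) NULL else bounding_box(64 - b$x - b$w, b$y, b$w, b$h)
  })
  doubled <- structure(list(
    images = c(tr$images, flipped_images),
    boxes = c(tr$boxes, flipped_boxes),
    scan_id = c(tr$scan_id, paste0(tr$scan_id, "_flip")),
    slice_index = c(tr$slice_index, tr$slice_index),
    input_size = 64L
  ), class = "slice_dataset")
  cfg_plain <- mini_detector_config(seed = 421, epochs = 6L)
  cfg_plain$augment_flip <- FALSE
  fit_plain <- train_detector(doubled, va, cfg_plain)

  va_aug <- tail(fit_aug$history$val_loss, 1)
  va_plain <- tail(fit_plain$history$val_loss, 1)
  expect_lte(abs(va_aug - va_plain), 0.2 * max(va_aug, va_plain))
})

test_that("detectors survive a save/load round trip with identical predictions", {
  runs <- small_training_runs()
  det <- runs[[1]]$fit$detector
  dir <- withr::local_tempdir()
  path <- file.path(dir, "weights.rds")
  save_detector(det, path)
  det2 <- load_detector(path)
  img <- matrix(runif(64 * 64), 64)
  expect_identical(predict_boxes(det, img), predict_boxes(det2, img))
  expect_error(load_detector(file.path(dir, "missing.rds")),
               class = "clavloc_not_found")
})
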