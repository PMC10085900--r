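# Compact one-stage anchor-based detector with focal loss.
#
# The architecture follows the RetinaNet family — dense anchors on a coarse
# feature grid, a sigmoid classification head trained with focal loss and a
# smooth-L1 box-regression head — but with a small three-stage convolutional
# backbone and a single stride-8 feature level, sized so that training on
# synthetic phantoms completes on one CPU.  An adapter seam (the
# `predict_boxes()` generic) lets a full-scale external detector be dropped
# into the localization and evaluation stack unchanged.

#' Focal loss
#'
#' Cross-entropy scaled by `(1 - p_t)^gamma` so that well-classified examples
#' contribute little, which is what lets a one-stage detector train against
#' the overwhelming majority of easy background anchors.  With
#' `p_t = p` for `y = 1` and `1 - p` for `y = 0`, and `alpha_t = alpha` or
#' `1 - alpha` respectively:
#' `loss = -alpha_t * (1 - p_t)^gamma * log(p_t)`.
#' At `gamma = 0` this reduces to alpha-weighted cross-entropy.
#'
#' @param p Predicted probability (vectorized); clamped to
#'   `[1e-7, 1 - 1e-7]` for log stability.
#' @param y Binary label, 0 or 1 (vectorized).
#' @param alpha Weight on the positive class (default 0.25).
#' @param gamma Focusing exponent (default 2).
#' @return Non-negative loss value(s), same length as `p`.
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2) {
  n <- max(length(p), length(y))
  p <- rep_len(pmin(pmax(p, 1e-7), 1 - 1e-7), n)
  y <- rep_len(y, n)
  p_t <- ifelse(y == 1, p, 1 - p)
  alpha_t <- ifelse(y == 1, alpha, 1 - alpha)
  -alpha_t * (1 - p_t)^gamma * log(p_t)
}

# focal loss and its gradient w.r.t. the logit, from logits
focal_from_logits <- function(z, y, alpha, gamma) {
  p <- 1 / (1 + exp(-z))
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  p_t <- ifelse(y == 1, pc, 1 - pc)
  alpha_t <- ifelse(y == 1, alpha, 1 - alpha)
  loss <- -alpha_t * (1 - p_t)^gamma * log(p_t)
  # dL/dp_t, then chain through p_t = p or 1 - p and dp/dz = p(1 - p)
  dL_dpt <- alpha_t * (gamma * (1 - p_t)^pmax(gamma - 1, 0) * log(p_t) -
                         (1 - p_t)^gamma / p_t)
  sign_pt <- ifelse(y == 1, 1, -1)
  dz <- dL_dpt * sign_pt * pc * (1 - pc)
  list(loss = loss, dz = dz)
}

smooth_l1 <- function(d, beta = 0.1) {
  a <- abs(d)
  loss <- ifelse(a < beta, 0.5 * d^2 / beta, a - 0.5 * beta)
  grad <- ifelse(a < beta, d / beta, sign(d))
  list(loss = loss, grad = grad)
}

#' Detector configuration
#'
#' Defaults mirror the clinical training protocol: 20 epochs of Adam at base
#' learning rate 1e-5 (appropriate for fine-tuning a pretrained full-scale
#' backbone), learning rate divided by 10 whenever the monitored loss fails
#' to improve for 3 consecutive epochs, random flip augmentation, and a
#' positive-detection score threshold of 0.05.  For CPU-scale training of
#' the compact detector from random initialization use
#' [mini_detector_config()].
#'
#' @param epochs Number of training epochs (>= 1).
#' @param base_lr Base learning rate for Adam (> 0).
#' @param plateau_patience Epochs without improvement before the learning
#'   rate is decayed (>= 1).
#' @param lr_decay_factor Factor the learning rate is divided by at each
#'   plateau.
#' @param score_threshold Classification score at or above which a detection
#'   is positive (in `[0, 1]`).
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param focal_alpha,focal_gamma Focal-loss parameters.
#' @param anchor_sizes Anchor side lengths (pixels, geometric mean of width
#'   and height).
#' @param aspect_ratios Anchor width/height ratios.
#' @param input_size Square input raster side length (pixels, multiple
#'   of 8).
#' @param augment_flip Apply random flip augmentation during training.
#' @param seed Integer seed making a training run reproducible.
#' @param batch_size Mini-batch size.
#' @param monitor Which loss drives the plateau scheduler, `"train"` or
#'   `"val"`.
#' @param channels Backbone channel widths for the three stages.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(epochs = 20L, base_lr = 1e-5,
                            plateau_patience = 3L, lr_decay_factor = 10,
                            score_threshold = 0.05, nms_iou = 0.5,
                            focal_alpha = 0.25, focal_gamma = 2,
                            anchor_sizes = c(32, 64, 128),
                            aspect_ratios = c(0.5, 1, 2),
                            input_size = 512L, augment_flip = TRUE,
                            seed = 1L, batch_size = 16L,
                            monitor = c("train", "val"),
                            channels = c(16L, 32L, 48L)) {
  monitor <- match.arg(monitor)
  if (epochs < 1L) abort_invalid("epochs must be >= 1")
  if (base_lr <= 0) abort_invalid("base_lr must be > 0")
  if (plateau_patience < 1L) abort_invalid("plateau_patience must be >= 1")
  if (score_threshold < 0 || score_threshold > 1) {
    abort_invalid("score_threshold must be in [0, 1]")
  }
  if (input_size %% 8L != 0L) abort_invalid("input_size must be a multiple of 8")
  structure(
    list(epochs = as.integer(epochs), base_lr = base_lr,
         plateau_patience = as.integer(plateau_patience),
         lr_decay_factor = lr_decay_factor,
         score_threshold = score_threshold, nms_iou = nms_iou,
         focal_alpha = focal_alpha, focal_gamma = focal_gamma,
         anchor_sizes = anchor_sizes, aspect_ratios = aspect_ratios,
         input_size = as.integer(input_size), augment_flip = augment_flip,
         seed = as.integer(seed), batch_size = as.integer(batch_size),
         monitor = monitor, channels = as.integer(channels)),
    class = "detector_config"
  )
}

#' Phantom-scale detector configuration
#'
#' A configuration sized for training the compact detector from random
#' initialization on 64 x 64 phantom rasters on one CPU: 10 epochs at a
#' learning rate of 2e-3 (a from-scratch compact net needs a much larger
#' step size than a pretrained backbone), anchors matched to the wide, flat
#' joint-region target.
#'
#' @param seed Integer seed for the training run.
#' @param ... Overrides passed on to [detector_config()].
#' @return An object of class `detector_config`.
#' @export
mini_detector_config <- function(seed = 1L, ...) {
  defaults <- list(epochs = 10L, base_lr = 2e-3, input_size = 64L,
                   anchor_sizes = c(12, 16), aspect_ratios = c(2, 3),
                   batch_size = 16L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(detector_config, args)
}

# ---- plateau learning-rate scheduler ---------------------------------------

#' Initialize a plateau learning-rate schedule
#'
#' The learning rate is divided by `factor` whenever the monitored loss has
#' not improved for `patience` consecutive epochs.  [lr_plateau_update()] is
#' called once per epoch with the monitored loss and returns the updated
#' state; `state$lr` is the rate to use for the following epoch.
#'
#' @param base_lr Starting learning rate.
#' @param patience Epochs without improvement before decay.
#' @param factor Decay divisor.
#' @return Schedule state (a list).
#' @export
lr_plateau_init <- function(base_lr, patience = 3L, factor = 10) {
  list(lr = base_lr, best = Inf, bad = 0L,
       patience = as.integer(patience), factor = factor)
}

#' Advance a plateau learning-rate schedule by one epoch
#'
#' @param state State from [lr_plateau_init()] or a previous update.
#' @param loss Monitored loss for the epoch just finished.
#' @return Updated state; `state$lr` holds the (possibly decayed) rate.
#' @export
lr_plateau_update <- function(state, loss) {
  if (loss < state$best) {
    state$best <- loss
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= state$patience) {
      state$lr <- state$lr / state$factor
      state$bad <- 0L
    }
  }
  state
}

# ---- training data ----------------------------------------------------------

#' Build a per-slice training dataset from volumes and annotations
#'
#' Preprocesses every axial slice of every volume to the detector input
#' raster (HU clip, resize, per-slice unit normalization) and attaches the
#' ground-truth box, rescaled analytically onto the same raster, where one
#' exists.
#'
#' @param volumes List of [ct_volume()] objects.
#' @param annotations An [annotation_set()] with boxes on the original
#'   rasters (`orig_rows`/`orig_cols` per annotation).
#' @param input_size Detector input raster side length.
#' @param hu_min,hu_max HU window applied before resizing.
#' @return An object of class `slice_dataset`: parallel lists `images` (unit
#'   matrices) and `boxes` ([bounding_box()] or `NULL`), vectors `scan_id`
#'   and `slice_index`.
#' @export
slice_dataset <- function(volumes, annotations, input_size,
                          hu_min = -200, hu_max = 600) {
  pp <- preprocess_config(hu_min, hu_max, input_size)
  images <- list()
  boxes <- list()
  scan_id <- character(0)
  slice_index <- integer(0)
  ann_df <- as.data.frame(annotations)
  for (vol in volumes) {
    prep <- preprocess_volume(vol, pp)
    n <- vol$n_slices
    idx <- length(images) + seq_len(n)
    images[idx] <- prep$images
    scan_id <- c(scan_id, rep(vol$scan_id, n))
    slice_index <- c(slice_index, seq_len(n) - 1L)
    vol_boxes <- rep(list(NULL), n)
    rows <- which(ann_df$scan_id == vol$scan_id)
    for (r in rows) {
      a <- ann_df[r, ]
      if (a$slice_index >= n) {
        abort_invalid(sprintf(
          "annotation slice %d out of range for scan '%s' (%d slices)",
          a$slice_index, vol$scan_id, n))
      }
      box <- rescale_box(bounding_box(a$x, a$y, a$w, a$h),
                         input_size / a$orig_cols, input_size / a$orig_rows)
      vol_boxes[[a$slice_index + 1L]] <- box
    }
    boxes[idx] <- vol_boxes
  }
  structure(list(images = images, boxes = boxes, scan_id = scan_id,
                 slice_index = slice_index, input_size = as.integer(input_size)),
            class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
  n_ann <- sum(!vapply(x$boxes, is.null, logical(1)))
  cat(sprintf("<slice_dataset> %d slices (%d annotated) at %d x %d px\n",
              length(x$images), n_ann, x$input_size, x$input_size))
  invisible(x)
}

# flip one image + box along a random axis (1 = horizontal/x, 2 = vertical/y)
flip_example <- function(img, box, axis, input_size) {
  if (axis == 1L) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(box)) box <- bounding_box(input_size - box$x - box$w, box$y, box$w, box$h)
  } else {
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    if (!is.null(box)) box <- bounding_box(box$x, input_size - box$y - box$h, box$w, box$h)
  }
  list(img = img, box = box)
}

# loss + head gradients for one batch; rows of X are image-major pixels
detector_batch <- function(net, anchors, images, boxes, config,
                           compute_grads = TRUE) {
  N <- length(images)
  A <- net$n_anchors_per_cell
  n_cells <- net$n_cells
  X <- do.call(rbind, lapply(images, img_to_row_major))
  fwd <- net_forward(net, X, N, keep_cache = compute_grads)
  dlogits <- if (compute_grads) matrix(0, nrow(fwd$logits), A) else NULL
  dbox <- if (compute_grads) matrix(0, nrow(fwd$box), 4L * A) else NULL
  total <- 0
  for (n in seq_len(N)) {
    rows_n <- (n - 1L) * n_cells + seq_len(n_cells)
    z <- as.vector(t(fwd$logits[rows_n, , drop = FALSE]))
    tg <- anchor_targets(anchors, boxes[[n]])
    norm <- max(1L, tg$n_pos)
    fl <- focal_from_logits(z, ifelse(is.na(tg$y), 0, tg$y),
                            config$focal_alpha, config$focal_gamma)
    keep <- !is.na(tg$y)
    cls_loss <- sum(fl$loss[keep]) / norm
    box_loss <- 0
    dz <- fl$dz
    dz[!keep] <- 0
    dD <- NULL
    if (tg$n_pos > 0) {
      D <- matrix(as.vector(t(fwd$box[rows_n, , drop = FALSE])),
                  ncol = 4L, byrow = TRUE)
      diff <- D[tg$pos, , drop = FALSE] - tg$treg
      sl1 <- smooth_l1(diff)
      box_loss <- sum(sl1$loss) / norm
      if (compute_grads) {
        dD <- matrix(0, nrow(D), 4L)
        dD[tg$pos, ] <- sl1$grad / (norm * N)
      }
    }
    total <- total + (cls_loss + box_loss) / N
    if (compute_grads) {
      dlogits[rows_n, ] <- matrix(dz / (norm * N), ncol = A, byrow = TRUE)
      if (!is.null(dD)) {
        dbox[rows_n, ] <- matrix(as.vector(t(dD)), ncol = 4L * A, byrow = TRUE)
      }
    }
  }
  out <- list(loss = total)
  if (compute_grads) {
    out$grads <- net_backward(net, fwd, dlogits, dbox, N)
  }
  out
}

dataset_loss <- function(net, anchors, data, config) {
  n <- length(data$images)
  bs <- config$batch_size
  total <- 0
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    b <- detector_batch(net, anchors, data$images[idx], data$boxes[idx],
                        config, compute_grads = FALSE)
    total <- total + b$loss * length(idx)
  }
  total / n
}

#' Train the compact detector
#'
#' Minimizes focal loss (anchor classification) plus smooth-L1 box
#' regression with Adam.  The learning rate follows a plateau schedule:
#' divided by `lr_decay_factor` whenever the monitored loss fails to improve
#' for `plateau_patience` consecutive epochs.  With `augment_flip`, each
#' example is flipped with probability 0.5 along a randomly chosen axis,
#' image and box together.  The run is fully reproducible from
#' `config$seed`.
#'
#' @param train_set,val_set [slice_dataset()] objects on the
#'   `config$input_size` raster.
#' @param config A [detector_config()].
#' @return List with `detector` (class `compact_detector`) and `history`
#'   (data frame `epoch, train_loss, val_loss, lr`).
#' @export
train_detector <- function(train_set, val_set, config) {
  stopifnot(inherits(train_set, "slice_dataset"), inherits(config, "detector_config"))
  n <- length(train_set$images)
  if (n == 0L) abort_invalid("training set is empty")
  if (!any(!vapply(train_set$boxes, is.null, logical(1)))) {
    abort_invalid("training set has no annotated slices; nothing to learn")
  }
  if (train_set$input_size != config$input_size) {
    abort_invalid("training set raster does not match config input_size")
  }
  anchors <- make_anchors(config$input_size, config$anchor_sizes,
                          config$aspect_ratios)
  size <- config$input_size
  withr::with_seed(config$seed, {
    net <- net_init(size, nrow(anchors) / (size %/% 8L)^2,
                    channels = config$channels)
    opt <- adam_init(net$layers)
    sched <- lr_plateau_init(config$base_lr, config$plateau_patience,
                             config$lr_decay_factor)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), lr = numeric(0))
    t_step <- 0L
    for (epoch in seq_len(config$epochs)) {
      lr <- sched$lr
      ord <- sample.int(n)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        imgs <- train_set$images[idx]
        boxes <- train_set$boxes[idx]
        if (config$augment_flip) {
          for (k in seq_along(idx)) {
            if (runif(1) < 0.5) {
              fl <- flip_example(imgs[[k]], boxes[[k]],
                                 sample(1:2, 1L), size)
              imgs[[k]] <- fl$img
              boxes[k] <- list(fl$box)
            }
          }
        }
        b <- detector_batch(net, anchors, imgs, boxes, config)
        t_step <- t_step + 1L
        upd <- adam_step(net$layers, b$grads, opt, lr, t_step)
        net$layers <- upd$layers
        opt <- upd$state
        epoch_loss <- epoch_loss + b$loss
        n_batches <- n_batches + 1L
      }
      train_loss <- epoch_loss / n_batches
      val_loss <- if (length(val_set$images)) {
        dataset_loss(net, anchors, val_set, config)
      } else NA_real_
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss, lr = lr
      ))
      monitored <- if (config$monitor == "val" && !is.na(val_loss)) val_loss else train_loss
      sched <- lr_plateau_update(sched, monitored)
      clog(sprintf("epoch %d/%d: train %.5f val %.5f lr %.2g",
                   epoch, config$epochs, train_loss, val_loss, lr))
    }
  })
  detector <- structure(
    list(net = net, anchors = anchors, input_size = size, config = config),
    class = c("compact_detector", "soi_detector")
  )
  list(detector = detector, history = history)
}

#' Construct an untrained compact detector
#'
#' Randomly initialized weights (seeded from `config$seed`); the
#' classification head starts at the focal-loss prior of 0.01 so an
#' untrained detector scores every anchor well below the positive-detection
#' threshold.  [train_detector()] builds its own detector internally; this
#' constructor exists for testing and for warm-start experiments.
#'
#' @param config A [detector_config()].
#' @return An untrained `compact_detector`.
#' @export
init_detector <- function(config) {
  stopifnot(inherits(config, "detector_config"))
  anchors <- make_anchors(config$input_size, config$anchor_sizes,
                          config$aspect_ratios)
  net <- withr::with_seed(config$seed, {
    net_init(config$input_size,
             nrow(anchors) / (config$input_size %/% 8L)^2,
             channels = config$channels)
  })
  structure(
    list(net = net, anchors = anchors, input_size = config$input_size,
         config = config),
    class = c("compact_detector", "soi_detector")
  )
}

#' @export
print.compact_detector <- function(x, ...) {
  cat(sprintf(
    "<compact_detector> input %d x %d px, %d anchors (%d/cell), channels %s\n",
    x$input_size, x$input_size, nrow(x$anchors), x$net$n_anchors_per_cell,
    paste(x$config$channels, collapse = "/")
  ))
  invisible(x)
}

# ---- inference --------------------------------------------------------------

#' Raw candidate boxes for one preprocessed slice
#'
#' The adapter seam between the localization/evaluation stack and any
#' detector implementation: given a preprocessed unit-range slice, return
#' every candidate box with its classification score, before thresholding
#' and non-maximum suppression.  External full-scale detectors plug in by
#' implementing this generic for their own class.
#'
#' @param detector A detector object (e.g. the `compact_detector` returned
#'   by [train_detector()]).
#' @param image Preprocessed square matrix in `[0, 1]`.
#' @return Data frame with columns `x, y, w, h, score`.
#' @export
predict_boxes <- function(detector, image) UseMethod("predict_boxes")

#' @export
predict_boxes.compact_detector <- function(detector, image) {
  net <- detector$net
  fwd <- net_forward(net, img_to_row_major(image), 1L, keep_cache = FALSE)
  scores <- 1 / (1 + exp(-as.vector(t(fwd$logits))))
  deltas <- matrix(as.vector(t(fwd$box)), ncol = 4L, byrow = TRUE)
  boxes <- decode_boxes(detector$anchors, deltas, detector$input_size)
  data.frame(x = boxes[, "x"], y = boxes[, "y"],
             w = boxes[, "w"], h = boxes[, "h"], score = scores)
}

#' Non-maximum suppression
#'
#' Greedy NMS: boxes are visited in descending score order; a box is
#' suppressed if its IoU with an already-kept box exceeds `iou_threshold`.
#'
#' @param boxes Data frame with columns `x, y, w, h`.
#' @param scores Numeric vector of scores, one per box.
#' @param iou_threshold Suppression threshold.
#' @return Integer indices of the surviving boxes, in descending score
#'   order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  ord <- order(-scores)
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      v <- iou_xywh(boxes$x[i], boxes$y[i], boxes$w[i], boxes$h[i],
                    boxes$x[j], boxes$y[j], boxes$w[j], boxes$h[j])
      if (v > iou_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}

empty_detections <- function() {
  data.frame(scan_id = character(0), slice_index = integer(0),
             x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
             score = numeric(0), class_label = character(0))
}

#' Detect the target structure in one preprocessed slice
#'
#' Runs the detector, keeps candidates with classification score at or above
#' `config$score_threshold` (the positive-detection rule), applies greedy
#' NMS at `config$nms_iou`, and returns the survivors sorted by descending
#' score.  An empty result means "no detection" for the slice.
#'
#' @param detector A detector implementing [predict_boxes()].
#' @param image Preprocessed square matrix with side `config$input_size`.
#' @param config A [detector_config()].
#' @return Data frame of detections (`x, y, w, h, score, class_label`,
#'   plus empty `scan_id`/`slice_index` columns filled by
#'   [detect_volume()]), zero rows if nothing scores above threshold.
#' @export
detect_slice <- function(detector, image, config) {
  if (!is.matrix(image) || nrow(image) != config$input_size ||
      ncol(image) != config$input_size) {
    abort_invalid(sprintf("image must be %d x %d to match the detector input",
                          config$input_size, config$input_size))
  }
  cand <- predict_boxes(detector, image)
  cand <- cand[cand$score >= config$score_threshold & cand$w > 0 & cand$h > 0, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty_detections())
  keep <- nms(cand, cand$score, config$nms_iou)
  out <- cand[keep, , drop = FALSE]
  data.frame(scan_id = rep(NA_character_, nrow(out)),
             slice_index = rep(NA_integer_, nrow(out)),
             x = out$x, y = out$y, w = out$w, h = out$h,
             score = out$score,
             class_label = rep("sternum", nrow(out)))
}

#' Save / load detector weights
#'
#' @param detector A `compact_detector`.
#' @param path File path for the serialized detector (RDS).
#' @return `path` (save) or the detector (load).
#' @export
save_detector <- function(detector, path) {
  saveRDS(detector, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  if (!file.exists(path)) abort_not_found(sprintf("weights file not found: %s", path))
  det <- readRDS(path)
  if (!inherits(det, "soi_detector")) abort_format("file does not contain a detector")
  det
}
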