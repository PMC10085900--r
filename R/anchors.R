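# Anchor machinery for the compact one-stage detector.
#
# Anchors live on the stride-8 feature grid; each cell carries one anchor per
# (size, aspect-ratio) combination.  Ordering is cell-major (row-major over
# grid cells), anchor-within-cell minor — the same order in which the head
# convolutions emit their outputs.

make_anchors <- function(input_size, sizes, ratios, stride = 8L) {
  S <- input_size %/% stride
  gr <- rep(seq_len(S), each = S)
  gc <- rep(seq_len(S), times = S)
  cx_cell <- (gc - 0.5) * stride
  cy_cell <- (gr - 0.5) * stride
  combos <- expand.grid(ratio = ratios, size = sizes)  # ratio varies fastest
  A <- nrow(combos)
  aw <- combos$size * sqrt(combos$ratio)  # ratio = w / h
  ah <- combos$size / sqrt(combos$ratio)
  n_cells <- S * S
  cbind(
    cx = rep(cx_cell, each = A),
    cy = rep(cy_cell, each = A),
    w = rep(aw, times = n_cells),
    h = rep(ah, times = n_cells)
  )
}

# vectorized IoU of center-form anchors against one corner-form gt box
anchor_iou <- function(anchors, gt) {
  ax1 <- anchors[, "cx"] - anchors[, "w"] / 2
  ay1 <- anchors[, "cy"] - anchors[, "h"] / 2
  ax2 <- ax1 + anchors[, "w"]
  ay2 <- ay1 + anchors[, "h"]
  iw <- pmax(0, pmin(ax2, gt$x + gt$w) - pmax(ax1, gt$x))
  ih <- pmax(0, pmin(ay2, gt$y + gt$h) - pmax(ay1, gt$y))
  inter <- iw * ih
  inter / (anchors[, "w"] * anchors[, "h"] + gt$w * gt$h - inter)
}

# label each anchor for one image: 1 positive, 0 negative, NA ignore;
# box-regression targets filled for positive anchors
anchor_targets <- function(anchors, gt_box, pos_iou = 0.5, neg_iou = 0.4) {
  n <- nrow(anchors)
  if (is.null(gt_box)) {
    return(list(y = rep(0, n), pos = integer(0),
                treg = matrix(0, 0, 4), n_pos = 0L))
  }
  ious <- anchor_iou(anchors, gt_box)
  y <- rep(NA_real_, n)
  y[ious < neg_iou] <- 0
  y[ious >= pos_iou] <- 1
  y[which.max(ious)] <- 1  # the best-matching anchor is always positive
  pos <- which(y == 1)
  gx <- gt_box$x + gt_box$w / 2
  gy <- gt_box$y + gt_box$h / 2
  treg <- cbind(
    (gx - anchors[pos, "cx"]) / anchors[pos, "w"],
    (gy - anchors[pos, "cy"]) / anchors[pos, "h"],
    log(gt_box$w / anchors[pos, "w"]),
    log(gt_box$h / anchors[pos, "h"])
  )
  list(y = y, pos = pos, treg = treg, n_pos = length(pos))
}

# decode regression deltas back to corner-form boxes, clipped to the raster
decode_boxes <- function(anchors, deltas, input_size, max_log_scale = 4) {
  dw <- pmin(deltas[, 3], max_log_scale)
  dh <- pmin(deltas[, 4], max_log_scale)
  cx <- anchors[, "cx"] + deltas[, 1] * anchors[, "w"]
  cy <- anchors[, "cy"] + deltas[, 2] * anchors[, "h"]
  w <- anchors[, "w"] * exp(dw)
  h <- anchors[, "h"] * exp(dh)
  x1 <- pmax(0, cx - w / 2)
  y1 <- pmax(0, cy - h / 2)
  x2 <- pmin(input_size, cx + w / 2)
  y2 <- pmin(input_size, cy + h / 2)
  cbind(x = x1, y = y1, w = x2 - x1, h = y2 - y1)
}
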