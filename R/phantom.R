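# Synthetic chest-CT phantoms.
#
# Each phantom is an air background containing an elliptical soft-tissue
# "body"; a bright bone-density target — two medial "clavicle" lobes meeting
# a central "sternum" block — occupies a run of consecutive axial slices in
# the anterior upper body, and distractor bone (a posterior "spine" column
# on every slice, plus a peripheral "rib" shell) forces the detector to
# learn shape rather than mere brightness.  Each target slice carries one
# ground-truth box tightly enclosing the drawn structure.

#' Phantom specification
#'
#' @param n_slices Axial slices per volume.
#' @param in_plane Square in-plane raster side length (pixels).
#' @param soi_span Number of consecutive slices containing the target.
#' @param soi_size_range Bounds (pixels) for the target box width; height is
#'   drawn as 0.35-0.5 of the width (the joint region is wide and flat).
#' @param hu_background Background HU (air).
#' @param hu_soft_tissue Soft-tissue HU range.
#' @param hu_bone Bone HU range for target and distractors.
#' @param noise_sd Gaussian HU noise standard deviation.
#' @param distractors Draw the distractor spine and rib shell.
#' @param seed Integer seed; a phantom is a pure function of its
#'   specification object.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 40L, in_plane = 128L, soi_span = 4L,
                         soi_size_range = c(28, 44), hu_background = -1000,
                         hu_soft_tissue = c(-100, 100), hu_bone = c(300, 1000),
                         noise_sd = 20, distractors = TRUE, seed = 1L) {
  if (soi_span < 1L || soi_span > n_slices) {
    abort_invalid("soi_span must satisfy 1 <= soi_span <= n_slices")
  }
  if (soi_size_range[2] > in_plane / 2) {
    abort_invalid("soi_size_range must keep the target box inside the raster")
  }
  structure(
    list(n_slices = as.integer(n_slices), in_plane = as.integer(in_plane),
         soi_span = as.integer(soi_span), soi_size_range = soi_size_range,
         hu_background = hu_background, hu_soft_tissue = hu_soft_tissue,
         hu_bone = hu_bone, noise_sd = noise_sd,
         distractors = isTRUE(distractors), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# draw the target structure mask for one slice; px/py are pixel-center grids
soi_mask <- function(px, py, cx, cy, w, h) {
  block <- abs(px - cx) <= 0.18 * w & abs(py - cy) <= h / 2
  lobe_l <- ((px - (cx - 0.33 * w)) / (0.17 * w))^2 +
    ((py - cy) / (0.35 * h))^2 <= 1
  lobe_r <- ((px - (cx + 0.33 * w)) / (0.17 * w))^2 +
    ((py - cy) / (0.35 * h))^2 <= 1
  block | lobe_l | lobe_r
}

#' Generate one synthetic chest-CT phantom
#'
#' Fully reproducible from `spec$seed`.  Returns the HU volume together
#' with one ground-truth annotation per target slice; boxes tightly enclose
#' the drawn structure on the original `in_plane` raster.
#'
#' @param spec A [phantom_spec()].
#' @param scan_id,patient_id Identifiers for the generated scan.
#' @return List with `volume` (a [ct_volume()]) and `annotations` (an
#'   [annotation_set()]).
#' @export
generate_phantom <- function(spec, scan_id = "phantom_001",
                             patient_id = scan_id) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec, scan_id, patient_id))
}

generate_phantom_impl <- function(spec, scan_id, patient_id) {
  N <- spec$in_plane
  # pixel-center grids: px[r, c] = c - 0.5 (x along columns), py[r, c] = r - 0.5
  px <- matrix(rep(seq_len(N) - 0.5, times = N), N, N, byrow = TRUE)
  py <- matrix(rep(seq_len(N) - 0.5, times = N), N, N, byrow = FALSE)

  body_cx <- N / 2
  body_cy <- N * 0.55
  body_a <- N * 0.42
  body_b <- N * 0.34
  body_r2 <- ((px - body_cx) / body_a)^2 + ((py - body_cy) / body_b)^2
  body <- body_r2 <= 1

  soft_hu <- runif(1, spec$hu_soft_tissue[1], spec$hu_soft_tissue[2])
  bone_hu <- runif(1, spec$hu_bone[1], spec$hu_bone[2])
  spine_hu <- runif(1, spec$hu_bone[1], spec$hu_bone[2])
  rib_hu <- runif(1, spec$hu_bone[1], spec$hu_bone[2])

  # target geometry: anterior upper body, fixed across its slice span
  w0 <- runif(1, spec$soi_size_range[1], spec$soi_size_range[2])
  h0 <- w0 * runif(1, 0.35, 0.5)
  cx <- N / 2 + runif(1, -0.06, 0.06) * N
  cy <- N * 0.38 + runif(1, -0.05, 0.05) * N
  s0 <- sample.int(spec$n_slices - spec$soi_span + 1L, 1L) - 1L  # 0-based start

  base <- matrix(spec$hu_background, N, N)
  base[body] <- soft_hu
  if (spec$distractors) {
    spine <- (px - (body_cx + runif(1, -2, 2)))^2 +
      (py - N * 0.78)^2 <= (0.06 * N)^2
    ribs <- body_r2 >= 0.90 & body_r2 <= 1
    base[ribs] <- rib_hu
    base[spine] <- spine_hu
  }

  voxels <- array(0, c(spec$n_slices, N, N))
  ann <- list()
  mid <- s0 + (spec$soi_span - 1) / 2
  for (s in seq_len(spec$n_slices) - 1L) {
    sl <- base
    if (s >= s0 && s < s0 + spec$soi_span) {
      # the structure tapers slightly toward the ends of its span
      f <- 1 - 0.12 * abs(s - mid) / max(1, spec$soi_span / 2)
      m <- soi_mask(px, py, cx, cy, w0 * f, h0 * f)
      sl[m] <- bone_hu
      rows <- which(rowSums(m) > 0)
      cols <- which(colSums(m) > 0)
      box <- bounding_box(x = min(cols) - 1, y = min(rows) - 1,
                          w = max(cols) - min(cols) + 1,
                          h = max(rows) - min(rows) + 1)
      ann[[length(ann) + 1L]] <- slice_annotation(
        scan_id, s, box, orig_rows = N, orig_cols = N
      )
    }
    voxels[s + 1L, , ] <- sl + matrix(rnorm(N * N, sd = spec$noise_sd), N, N)
  }
  list(volume = ct_volume(voxels, scan_id, patient_id),
       annotations = annotation_set(ann))
}

#' Generate a dataset of independent phantoms
#'
#' Per-volume seeds are derived deterministically from `seed`, so target
#' position, size, slice span placement and tissue intensities vary across
#' volumes while the whole dataset is reproducible.
#'
#' @param n_volumes Number of phantoms (>= 1).
#' @param spec A [phantom_spec()]; its own `seed` field is ignored here.
#' @param seed Dataset-level integer seed.
#' @param doublet_fraction Fraction of volumes to additionally re-render
#'   with fresh noise under the same patient id (emulating repeat scans of
#'   one patient); 0 disables.
#' @return List of `list(volume, annotations)` pairs.
#' @export
generate_dataset <- function(n_volumes, spec = phantom_spec(), seed = 1L,
                             doublet_fraction = 0) {
  if (n_volumes < 1L) abort_invalid("n_volumes must be >= 1")
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2L, n_volumes))
  out <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    sp <- spec
    sp$seed <- seeds[i]
    out[[i]] <- generate_phantom(sp, scan_id = sprintf("phantom_%03d", i),
                                 patient_id = sprintf("patient_%03d", i))
  }
  if (doublet_fraction > 0) {
    n_dup <- floor(doublet_fraction * n_volumes)
    picks <- withr::with_seed(seed + 1L, sample.int(n_volumes, n_dup))
    for (k in seq_along(picks)) {
      src <- out[[picks[k]]]
      dup_id <- sprintf("phantom_%03d_b", picks[k])
      vox <- src$volume$voxels +
        withr::with_seed(seed + 1L + k,
                         array(rnorm(length(src$volume$voxels), sd = spec$noise_sd),
                               dim(src$volume$voxels)))
      anns <- lapply(src$annotations$annotations, function(a) {
        a$scan_id <- dup_id
        a
      })
      out[[length(out) + 1L]] <- list(
        volume = ct_volume(vox, dup_id, src$volume$patient_id),
        annotations = annotation_set(anns)
      )
    }
  }
  out
}

#' Merge the annotation sets of a phantom dataset
#'
#' @param dataset List of `list(volume, annotations)` pairs.
#' @return A single [annotation_set()].
#' @export
dataset_annotations <- function(dataset) {
  annotation_set(unlist(lapply(dataset, function(d) d$annotations$annotations),
                        recursive = FALSE))
}

#' Split items into a training subset and a remainder
#'
#' The training subset has `floor(train_fraction * n)` items; the split is
#' over whole items (scans), never slices, so no scan can appear on both
#' sides.  With a seed the items are shuffled reproducibly first; without
#' one, the input order is kept.
#'
#' @param items Non-empty list or vector.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Optional integer seed for the shuffle.
#' @return List with `train` and `rest`.
#' @export
split_holdout <- function(items, train_fraction, seed = NULL) {
  n <- length(items)
  if (n == 0L) abort_invalid("cannot split an empty item list")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_invalid("train_fraction must be in (0, 1)")
  }
  ord <- if (is.null(seed)) seq_len(n) else withr::with_seed(seed, sample.int(n))
  n_train <- floor(train_fraction * n)
  list(train = items[ord[seq_len(n_train)]],
       rest = items[ord[setdiff(seq_len(n), seq_len(n_train))]])
}

#' Write a phantom dataset to disk
#'
#' One NIfTI volume per phantom plus a single annotations CSV.
#'
#' @param dataset List of `list(volume, annotations)` pairs.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in dataset) {
    write_volume(d$volume, file.path(dir, paste0(d$volume$scan_id, ".nii.gz")))
  }
  write_annotations(dataset_annotations(dataset),
                    file.path(dir, "annotations.csv"))
  invisible(dir)
}
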