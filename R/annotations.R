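# Ground-truth bounding boxes: one axial-plane box per annotated slice,
# single class "sternum" (the sternoclavicular joint region).
#
# Box convention: (x, y) = top-left corner in continuous pixel coordinates,
# origin at the top-left of the raster, x along columns, y along rows;
# w, h > 0.

#' Construct a bounding box
#'
#' @param x,y Top-left corner in continuous pixel coordinates (>= 0).
#' @param w,h Width and height in pixels (> 0).
#' @return An object of class `bounding_box` (named list `x, y, w, h`).
#' @export
bounding_box <- function(x, y, w, h) {
  if (any(!is.finite(c(x, y, w, h)))) abort_invalid("box parameters must be finite")
  if (w <= 0 || h <= 0) abort_invalid("box width and height must be > 0")
  if (x < 0 || y < 0) abort_invalid("box corner must satisfy x >= 0, y >= 0")
  structure(list(x = x, y = y, w = w, h = h), class = "bounding_box")
}

#' Box center
#'
#' @param box A [bounding_box()].
#' @return Numeric `c(x, y)` center in continuous pixel coordinates.
#' @export
box_center <- function(box) {
  c(x = box$x + box$w / 2, y = box$y + box$h / 2)
}

#' Rescale a box between rasters
#'
#' Multiplies `(x, w)` by `scale_x` and `(y, h)` by `scale_y`, the analytic
#' counterpart of resizing the raster a box is drawn on.
#'
#' @param box A [bounding_box()].
#' @param scale_x,scale_y Positive scale ratios.
#' @return The rescaled [bounding_box()].
#' @export
rescale_box <- function(box, scale_x, scale_y) {
  if (scale_x <= 0 || scale_y <= 0) abort_invalid("scale factors must be > 0")
  bounding_box(box$x * scale_x, box$y * scale_y, box$w * scale_x, box$h * scale_y)
}

#' Construct a per-slice annotation
#'
#' @param scan_id Scan identifier.
#' @param slice_index 0-based axial slice index.
#' @param box A [bounding_box()] on the annotation raster.
#' @param class_label Object class; the single class is `"sternum"`.
#' @param orig_rows,orig_cols In-plane shape of the raster the box
#'   coordinates refer to.
#' @return An object of class `slice_annotation`.
#' @export
slice_annotation <- function(scan_id, slice_index, box,
                             class_label = "sternum",
                             orig_rows = NA_integer_, orig_cols = NA_integer_) {
  if (slice_index < 0L) abort_invalid("slice_index must be >= 0")
  if (!identical(class_label, "sternum")) {
    abort_invalid("class_label must be \"sternum\" (single-class problem)")
  }
  structure(
    list(scan_id = as.character(scan_id), slice_index = as.integer(slice_index),
         box = box, class_label = class_label,
         orig_rows = as.integer(orig_rows), orig_cols = as.integer(orig_cols)),
    class = "slice_annotation"
  )
}

#' Build an annotation set
#'
#' An annotation set holds at most one box per `(scan_id, slice_index)` pair:
#' the target is a single merged structure containing both sternoclavicular
#' joints, so each annotated slice carries exactly one box.
#'
#' @param annotations List of [slice_annotation()] objects.
#' @return An object of class `annotation_set` with fields `annotations` and
#'   `scans` (mapping scan_id -> sorted annotated slice indices).
#' @export
annotation_set <- function(annotations = list()) {
  keys <- vapply(annotations, function(a) paste(a$scan_id, a$slice_index, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    dup <- annotations[[which(duplicated(keys))[1]]]
    abort_duplicate(sprintf(
      "duplicate annotation for scan '%s' slice %d", dup$scan_id, dup$slice_index
    ))
  }
  scan_ids <- vapply(annotations, `[[`, character(1), "scan_id")
  scans <- lapply(split(
    vapply(annotations, `[[`, integer(1), "slice_index"), scan_ids
  ), sort)
  structure(list(annotations = annotations, scans = scans),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d annotations across %d scans\n",
              length(x$annotations), length(x$scans)))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$annotations)

#' Annotations as a data frame
#'
#' @param x An [annotation_set()].
#' @param ... Unused.
#' @return Data frame with columns `scan_id, slice_index, x, y, w, h,
#'   class_label, orig_rows, orig_cols`.
#' @export
as.data.frame.annotation_set <- function(x, ...) {
  if (length(x$annotations) == 0L) {
    return(data.frame(
      scan_id = character(), slice_index = integer(), x = numeric(),
      y = numeric(), w = numeric(), h = numeric(), class_label = character(),
      orig_rows = integer(), orig_cols = integer()
    ))
  }
  do.call(rbind, lapply(x$annotations, function(a) {
    data.frame(scan_id = a$scan_id, slice_index = a$slice_index,
               x = a$box$x, y = a$box$y, w = a$box$w, h = a$box$h,
               class_label = a$class_label,
               orig_rows = a$orig_rows, orig_cols = a$orig_cols)
  }))
}

#' Read annotations from CSV
#'
#' Expected columns: `scan_id, slice_index, x, y, w, h, class_label,
#' orig_rows, orig_cols`.  Rows violating the box or class invariants are
#' rejected with a parse error naming the offending data row.
#'
#' @param path CSV file path.
#' @param target_size Optional square raster side length; when given, boxes
#'   are rescaled from their stored original raster (`orig_rows, orig_cols`)
#'   onto the `target_size` raster at load time.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, target_size = NULL) {
  if (!file.exists(path)) abort_not_found(sprintf("annotation file not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_parse(sprintf("cannot parse %s: %s",
                                                         path, conditionMessage(e))))
  required <- c("scan_id", "slice_index", "x", "y", "w", "h", "class_label",
                "orig_rows", "orig_cols")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_parse(sprintf("missing annotation columns: %s",
                        paste(missing_cols, collapse = ", ")))
  }
  anns <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    ok <- tryCatch({
      box <- bounding_box(row$x, row$y, row$w, row$h)
      if (!is.null(target_size)) {
        box <- rescale_box(box, target_size / row$orig_cols,
                           target_size / row$orig_rows)
      }
      anns[[i]] <- slice_annotation(row$scan_id, row$slice_index, box,
                                    row$class_label,
                                    orig_rows = row$orig_rows,
                                    orig_cols = row$orig_cols)
      TRUE
    }, clavloc_invalid_input = function(e) e, error = function(e) e)
    if (!isTRUE(ok)) {
      abort_parse(sprintf("invalid annotation in row %d of %s: %s",
                          i, path, conditionMessage(ok)))
    }
  }
  if (!is.null(target_size)) {
    ts <- as.integer(target_size)
    anns <- lapply(anns, function(a) { a$orig_rows <- ts; a$orig_cols <- ts; a })
  }
  annotation_set(anns)
}

#' Write annotations to CSV
#'
#' Round-trips with [read_annotations()]: reading a written file reproduces
#' the set exactly.
#'
#' @param set An [annotation_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  if (!dir.exists(dirname(path))) {
    abort_io(sprintf("output directory does not exist: %s", dirname(path)))
  }
  write.csv(as.data.frame(set), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export annotations as COCO-style JSON
#'
#' One image entry per annotated `(scan_id, slice_index)` pair, a single
#' category `"sternum"` with id 1, boxes in `[x, y, w, h]` order.
#'
#' @param set An [annotation_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations_coco <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  df <- as.data.frame(set)
  image_key <- if (nrow(df)) paste(df$scan_id, df$slice_index, sep = "_") else character()
  images <- lapply(seq_len(nrow(df)), function(i) {
    list(id = i, file_name = image_key[i], scan_id = df$scan_id[i],
         slice_index = df$slice_index[i],
         height = df$orig_rows[i], width = df$orig_cols[i])
  })
  annotations <- lapply(seq_len(nrow(df)), function(i) {
    list(id = i, image_id = i, category_id = 1L,
         bbox = c(df$x[i], df$y[i], df$w[i], df$h[i]),
         area = df$w[i] * df$h[i], iscrowd = 0L)
  })
  coco <- list(
    images = images,
    annotations = annotations,
    categories = list(list(id = 1L, name = "sternum"))
  )
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Annotations for one scan
#'
#' @param set An [annotation_set()].
#' @param scan_id Scan identifier.
#' @return List of [slice_annotation()] objects (possibly empty), ordered by
#'   slice index.
#' @export
annotations_for_scan <- function(set, scan_id) {
  anns <- Filter(function(a) a$scan_id == scan_id, set$annotations)
  anns[order(vapply(anns, `[[`, integer(1), "slice_index"))]
}
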