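test_that("annotation sets round-trip through CSV exactly", {
  anns <- list(
    slice_annotation("scan_a", 5L, bounding_box(10, 20, 30, 40),
                     orig_rows = 128L, orig_cols = 128L),
    slice_annotation("scan_a", 6L, bounding_box(11.5, 21.5, 29, 39),
                     orig_rows = 128L, orig_cols = 128L),
    slice_annotation("scan_b", 0L, bounding_box(40, 50, 12, 8),
                     orig_rows = 256L, orig_cols = 256L)
  )
  set <- annotation_set(anns)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.csv")
  write_annotations(set, path)
  back <- read_annotations(path)
  expect_equal(length(back), 3L)
  expect_equal(as.data.frame(back), as.data.frame(set))
  expect_equal(back$scans$scan_a, c(5L, 6L))

  # phantom-generated set round-trips too
  ph <- generate_phantom(phantom_spec(seed = 5), scan_id = "ph")
  write_annotations(ph$annotations, path)
  expect_equal(as.data.frame(read_annotations(path)),
               as.data.frame(ph$annotations))
})

test_that("an empty set writes a header-only file that reads back empty", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.csv")
  write_annotations(annotation_set(), path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(length(read_annotations(path)), 0L)
})

test_that("invalid rows and duplicate slice annotations are rejected", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  writeLines(c(
    "scan_id,slice_index,x,y,w,h,class_label,orig_rows,orig_cols",
    "s1,0,10,10,20,10,sternum,128,128",
    "s1,1,10,10,0,10,sternum,128,128"
  ), path)
  expect_error(read_annotations(path), "row 2", class = "clavloc_parse_error")

  writeLines(c(
    "scan_id,slice_index,x,y,w,h,class_label,orig_rows,orig_cols",
    "s1,3,10,10,20,10,sternum,128,128",
    "s1,3,12,12,20,10,sternum,128,128"
  ), path)
  expect_error(read_annotations(path), class = "clavloc_duplicate_error")

  expect_error(bounding_box(10, 10, -5, 10), class = "clavloc_invalid_input")
  expect_error(slice_annotation("s", 0L, bounding_box(1, 1, 2, 2), "rib"),
               class = "clavloc_invalid_input")
})

test_that("rescale_box is the expected linear map and inverts cleanly", {
  b <- bounding_box(10, 20, 30, 40)
  expect_equal(unclass(rescale_box(b, 2, 2)),
               list(x = 20, y = 40, w = 60, h = 80))
  expect_equal(rescale_box(b, 1, 1), b)
  expect_equal(unclass(rescale_box(b, 4, 2)),
               list(x = 40, y = 40, w = 120, h = 80))
  expect_error(rescale_box(b, 0, 1), class = "clavloc_invalid_input")

  set.seed(11)
  for (i in 1:25) {
    b <- bounding_box(runif(1, 0, 100), runif(1, 0, 100),
                      runif(1, 1, 50), runif(1, 1, 50))
    s <- runif(1, 0.1, 8); t <- runif(1, 0.1, 8)
    round_trip <- rescale_box(rescale_box(b, s, t), 1 / s, 1 / t)
    expect_equal(unlist(unclass(round_trip)), unlist(unclass(b)),
                 tolerance = 1e-9)
    # rescaling commutes with center extraction
    expect_equal(box_center(rescale_box(b, s, t)),
                 box_center(b) * c(s, t), tolerance = 1e-9)
  }
})

test_that("boxes can be rescaled onto the preprocessed raster at load time", {
  set <- annotation_set(list(
    slice_annotation("s1", 2L, bounding_box(32, 16, 64, 32),
                     orig_rows = 128L, orig_cols = 128L)
  ))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.csv")
  write_annotations(set, path)
  scaled <- read_annotations(path, target_size = 512)
  b <- scaled$annotations[[1]]$box
  expect_equal(unclass(b), list(x = 128, y = 64, w = 256, h = 128))
})

test_that("COCO export has single category 'sternum' and [x, y, w, h] boxes", {
  set <- annotation_set(list(
    slice_annotation("s1", 2L, bounding_box(5, 6, 7, 8),
                     orig_rows = 128L, orig_cols = 128L),
    slice_annotation("s2", 0L, bounding_box(1, 2, 3, 4),
                     orig_rows = 128L, orig_cols = 128L)
  ))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.json")
  write_annotations_coco(set, path)
  coco <- jsonlite::read_json(path)
  expect_length(coco$images, 2)
  expect_length(coco$annotations, 2)
  expect_equal(coco$categories[[1]]$name, "sternum")
  expect_equal(coco$categories[[1]]$id, 1L)
  expect_equal(unlist(coco$annotations[[1]]$bbox), c(5, 6, 7, 8))
  expect_equal(coco$annotations[[1]]$category_id, 1L)
})
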