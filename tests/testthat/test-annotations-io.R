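test_that("label matrices convert to calls in ascending label order", {
  mat <- matrix(0L, 4, 4)
  mat[1, 1] <- 1L; mat[1, 2] <- 1L   # label 1: 2 px
  mat[3, 4] <- 3L                    # label 3: 1 px
  calls <- calls_from_label_matrix(mat, "R1", "img1")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$call_index, c(0L, 1L))
  expect_equal(nrow(calls$mask[[1]]), 2L)  # label 1 first
  expect_equal(unname(calls$mask[[2]]), cbind(2L, 3L), ignore_attr = TRUE)

  empty <- calls_from_label_matrix(matrix(0L, 4, 4), "R1", "img1")
  expect_equal(nrow(empty), 0L)
})

test_that("label images round-trip through TIFF and PNG", {
  mat <- matrix(0L, 6, 8)
  mat[2:3, 2:4] <- 1L
  mat[5, 6:7] <- 7L
  for (ext in c("tif", "png")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_label_image(mat, path)
    expect_identical(read_label_image(path), mat)
  }
})

test_that("reading per-reader label files shares dims and flags mismatches", {
  dir <- withr::local_tempdir()
  m1 <- matrix(0L, 5, 5); m1[2:3, 2:3] <- 1L
  m2 <- matrix(0L, 5, 5); m2[2:4, 2:4] <- 1L
  write_label_image(m1, file.path(dir, "a.tif"))
  write_label_image(m2, file.path(dir, "b.tif"))
  manifest <- tibble::tibble(
    path = file.path(dir, c("a.tif", "b.tif")),
    reader_id = c("R1", "R2"), image_id = "img1"
  )
  res <- read_label_images(manifest)
  expect_equal(sort(unique(res$calls$reader_id)), c("R1", "R2"))
  expect_equal(res$dims$height, 5L)

  write_label_image(matrix(0L, 4, 4), file.path(dir, "c.tif"))
  manifest2 <- rbind(manifest,
                     tibble::tibble(path = file.path(dir, "c.tif"),
                                    reader_id = "R3", image_id = "img1"))
  expect_error(read_label_images(manifest2), "disagree")
})

test_that("label round trip reproduces the partition up to renumbering", {
  sc <- generate_scene(dims = c(96L, 96L), n_objects = 6L,
                       size_range = c(4, 8), seed = 3)
  noiseless <- reader_profile(miss_rate = 0, fp_rate = 0, jitter_px = 0L,
                              fragment_rate = 0)
  calls <- simulate_reader(sc, noiseless, "R1", seed = 9)
  mat <- label_matrix_from_calls(calls, "R1", sc$image_id, sc$dims)
  back <- calls_from_label_matrix(mat, "R1", sc$image_id)
  # same pixel partition, possibly renumbered
  orig <- lapply(calls$mask, function(m) sort(m[, 1] * 1e4 + m[, 2]))
  got <- lapply(back$mask, function(m) sort(m[, 1] * 1e4 + m[, 2]))
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(orig, paste, character(1), collapse = ","))
})

test_that("instance JSON round-trips calls and dims", {
  coh <- small_cohort(n_images = 2, n_readers = 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_instance_json(coh$calls, coh$dims, path)
  res <- read_instance_json(path)
  expect_equal(nrow(res$calls), nrow(coh$calls))
  key <- function(calls) {
    calls <- calls[order(calls$reader_id, calls$image_id, calls$call_index), ]
    vapply(calls$mask, function(m) {
      paste(sort(m[, 1] * 1e5 + m[, 2]), collapse = ",")
    }, character(1))
  }
  expect_identical(key(res$calls), key(coh$calls))
  expect_equal(res$dims[order(res$dims$image_id), ],
               coh$dims[order(coh$dims$image_id), ], ignore_attr = TRUE)
})

test_that("JSON and label-image loaders agree on equivalent inputs", {
  sc <- generate_scene(dims = c(64L, 64L), n_objects = 4L,
                       size_range = c(4, 7), seed = 21)
  noiseless <- reader_profile(miss_rate = 0, fp_rate = 0, jitter_px = 0L,
                              fragment_rate = 0)
  calls <- simulate_reader(sc, noiseless, "R1", seed = 2)
  dims <- tibble::tibble(image_id = sc$image_id, height = 64L, width = 64L)

  tif <- withr::local_tempfile(fileext = ".tif")
  write_label_image(label_matrix_from_calls(calls, "R1", sc$image_id,
                                            sc$dims), tif)
  via_labels <- read_label_images(tibble::tibble(
    path = tif, reader_id = "R1", image_id = sc$image_id))$calls

  js <- withr::local_tempfile(fileext = ".json")
  write_instance_json(calls, dims, js)
  via_json <- read_instance_json(js)$calls

  pixels <- function(calls) {
    sort(unlist(lapply(calls$mask, function(m) m[, 1] * 1e5 + m[, 2])))
  }
  expect_identical(pixels(via_labels), pixels(via_json))
  expect_equal(nrow(via_labels), nrow(via_json))
})

test_that("JSON schema violations are reported with their JSON path", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"reader_id":"R1","images":[{"image_id":"a","height":4,
    "width":4,"calls":[{"index":0,"bbox":[0,0,1,1]},
                       {"index":0,"bbox":[2,2,3,3]}]}]}]', path)
  expect_error(read_instance_json(path), "duplicate.*calls\\[1\\]")

  writeLines('[{"reader_id":"R1","images":[{"image_id":"a","height":4,
    "width":4,"calls":[{"index":0}]}]}]', path)
  expect_error(read_instance_json(path), "polygon/rle/bbox")
})

test_that("bbox-only JSON calls load without masks; overlapping same-reader
           calls are preserved", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"reader_id":"R1","images":[{"image_id":"a","height":8,
    "width":8,"calls":[{"index":0,"bbox":[0,0,3,3]},
                       {"index":1,"bbox":[1,1,4,4]}]}]}]', path)
  res <- read_instance_json(path)
  expect_equal(nrow(res$calls), 2L)
  expect_true(all(vapply(res$calls$mask, is.null, logical(1))))
  expect_equal(res$calls$bbox[[2]], c(1L, 1L, 4L, 4L))
})

test_that("polygon rasterization matches a winding-number oracle", {
  # unit square in pixel-corner coords -> exactly pixel (0,0)
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"reader_id":"R1","images":[{"image_id":"a","height":4,
    "width":4,"calls":[{"index":0,
      "polygon":[[0,0],[1,0],[1,1],[0,1]]}]}]}]', path)
  res <- read_instance_json(path)
  expect_equal(unname(res$calls$mask[[1]]), cbind(0L, 0L),
               ignore_attr = TRUE)

  # an irregular pentagon, checked pixel-by-pixel against the oracle
  xs <- c(0.4, 6.6, 7.2, 3.5, 0.8)
  ys <- c(1.2, 0.6, 5.4, 7.6, 4.9)
  poly_json <- paste0("[", paste(sprintf("[%g,%g]", xs, ys), collapse = ","),
                      "]")
  writeLines(sprintf('[{"reader_id":"R1","images":[{"image_id":"a",
    "height":9,"width":9,"calls":[{"index":0,"polygon":%s}]}]}]',
    poly_json), path)
  got <- read_instance_json(path)$calls$mask[[1]]
  grid <- expand.grid(row = 0:8, col = 0:8)
  want <- grid[mapply(function(r, c) {
    winding_inside(c + 0.5, r + 0.5, xs, ys)
  }, grid$row, grid$col), ]
  expect_setequal(got[, 1] * 9 + got[, 2], want$row * 9 + want$col)
})

test_that("bounding-box extraction is tight, handles single pixels, and is
           idempotent", {
  m <- rbind(c(0L, 0L), c(2L, 3L))
  colnames(m) <- c("row", "col")
  calls <- call_tbl("R1", "img1", mask = list(m))
  out <- extract_bounding_boxes(calls)
  expect_equal(out$bbox[[1]], c(0L, 0L, 3L, 2L))  # xmin,ymin,xmax,ymax

  single <- call_tbl("R1", "img1", mask = list(cbind(row = 5L, col = 7L)))
  expect_equal(extract_bounding_boxes(single)$bbox[[1]], c(7L, 5L, 7L, 5L))

  expect_identical(extract_bounding_boxes(out), out)
  no_geom <- tibble::tibble(reader_id = "R1", image_id = "i",
                            call_index = 0L, mask = list(NULL),
                            bbox = list(NULL))
  expect_error(extract_bounding_boxes(no_geom), "neither mask nor bbox")
})

test_that("metric tables round-trip with empty cells for undefined values", {
  records <- tibble::tibble(
    image_id = c("a", "b"),
    metric_name = c("multireader_jaccard", "jaccard"),
    iou_threshold = c(0.5, 0.25),
    reader_group = list(c("R1", "R2", "R3"), c("R1", "R2")),
    value = c(0.4, NA)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_table(records, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_false(grepl("nan|NA", lines[3], ignore.case = TRUE))
  back <- read_metric_table(path)
  expect_equal(back$value, records$value)
  expect_equal(back$reader_group, records$reader_group)
  expect_error(write_metric_table(records[0, ], path), "non-empty")
})

test_that("calls-table validation catches the structural invariants", {
  m <- rect_mask(0, 1, 0, 1)
  good <- call_tbl("R1", "img1", mask = list(m))
  expect_silent(validate_calls(good))

  gap <- good
  gap$call_index <- 1L
  expect_error(validate_calls(gap), "contiguous")

  loose_box <- good
  loose_box$bbox <- list(c(0L, 0L, 5L, 5L))
  expect_error(validate_calls(loose_box), "tight")

  dims <- tibble::tibble(image_id = "img1", height = 1L, width = 1L)
  expect_error(validate_calls(good, dims), "outside")
})
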