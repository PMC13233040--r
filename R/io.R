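# Readers and writers: label images (TIFF/PNG), instance JSON, metric CSVs.

#' Read a single label image
#'
#' Reads a single-channel integer label image (0 = background, positive
#' integers = object ids) from TIFF or PNG. Labels up to 65535 are supported.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return An integer matrix.
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      x <- png::readPNG(path, info = TRUE)
      bits <- attr(x, "info")$bit.depth %||% 8L
      round(x * (2^bits - 1))
    },
    stop("unsupported label-image format '", ext, "' for ", path,
         call. = FALSE)
  )
  if (length(dim(img)) != 2L) {
    stop("label image is not 2-D (single channel): ", path, call. = FALSE)
  }
  if (any(img < 0)) {
    stop("label image contains negative labels: ", path, call. = FALSE)
  }
  attributes(img) <- list(dim = dim(img))
  storage.mode(img) <- "integer"
  img
}

#' Write a single label image
#'
#' @param mat Integer label matrix. TIFF output is 16-bit (labels up to
#'   65535); PNG output is 8-bit (labels up to 255).
#' @param path Output path; format chosen by extension (`.tif`/`.png`).
#' @export
write_label_image <- function(mat, path) {
  ext <- tolower(tools::file_ext(path))
  if (any(mat < 0L)) stop("labels must be non-negative", call. = FALSE)
  switch(ext,
    tif = , tiff = {
      if (any(mat > 65535L)) stop("TIFF labels must be <= 65535",
                                  call. = FALSE)
      tiff::writeTIFF(mat / 65535, path, bits.per.sample = 16L)
    },
    png = {
      if (any(mat > 255L)) stop("PNG labels must be <= 255", call. = FALSE)
      png::writePNG(mat / 255, path)
    },
    stop("unsupported label-image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Convert a label matrix to calls
#'
#' Each distinct positive label becomes one call whose mask is that label's
#' pixel set; `call_index` is assigned in ascending label order. An all-zero
#' matrix yields zero calls.
#'
#' @param mat Integer label matrix.
#' @param reader_id,image_id Identifiers attached to the calls.
#' @return A calls table (possibly with zero rows).
#' @export
calls_from_label_matrix <- function(mat, reader_id, image_id) {
  labs <- sort(unique(mat[mat > 0L]))
  if (length(labs) == 0L) {
    return(tibble::tibble(reader_id = character(), image_id = character(),
                          call_index = integer(), mask = list(),
                          bbox = list()))
  }
  masks <- lapply(labs, function(l) {
    ij <- which(mat == l, arr.ind = TRUE)
    m <- cbind(row = ij[, 1L] - 1L, col = ij[, 2L] - 1L)
    storage.mode(m) <- "integer"
    m
  })
  extract_bounding_boxes(call_tbl(reader_id, image_id, mask = masks))
}

#' Read per-reader label images into a calls table
#'
#' @param manifest Tibble/data frame with columns `path`, `reader_id`,
#'   `image_id`, one row per label-image file.
#' @return A list with `calls` (the combined calls table) and `dims` (a
#'   tibble `image_id`, `height`, `width`). Files for the same `image_id`
#'   must agree on dimensions.
#' @export
read_label_images <- function(manifest) {
  stopifnot(all(c("path", "reader_id", "image_id") %in% names(manifest)))
  dims <- list()
  calls <- purrr::pmap(manifest[c("path", "reader_id", "image_id")],
    function(path, reader_id, image_id) {
      mat <- tryCatch(read_label_image(path), error = function(e) {
        stop("while reading '", path, "': ", conditionMessage(e),
             call. = FALSE)
      })
      d <- dims[[image_id]]
      if (is.null(d)) {
        dims[[image_id]] <<- dim(mat)
      } else if (!identical(d, dim(mat))) {
        stop("image dims of '", path, "' disagree with an earlier file for ",
             "image '", image_id, "'", call. = FALSE)
      }
      calls_from_label_matrix(mat, reader_id, image_id)
    })
  list(
    calls = dplyr::bind_rows(calls),
    dims = tibble::tibble(
      image_id = names(dims),
      height = unname(vapply(dims, `[`, integer(1), 1L)),
      width = unname(vapply(dims, `[`, integer(1), 2L))
    )
  )
}

#' Render calls of one reader on one image as a label matrix
#'
#' Labels are `call_index + 1`. Overlapping calls cannot be represented;
#' later calls overwrite earlier pixels, with a warning.
#'
#' @param calls A calls table.
#' @param reader,image Reader and image id to render.
#' @param dims `c(height, width)`.
#' @return Integer label matrix.
#' @export
label_matrix_from_calls <- function(calls, reader, image, dims) {
  mat <- matrix(0L, dims[1], dims[2])
  sub <- calls_of(calls, reader, image)
  overlap <- FALSE
  for (i in seq_len(nrow(sub))) {
    m <- sub$mask[[i]]
    if (is.null(m)) stop("call without mask cannot be rendered", call. = FALSE)
    lin <- m[, 1L] + 1L + m[, 2L] * dims[1]
    if (any(mat[lin] != 0L)) overlap <- TRUE
    mat[lin] <- sub$call_index[i] + 1L
  }
  if (overlap) {
    warning("overlapping calls from one reader collapsed in label image",
            call. = FALSE)
  }
  mat
}

# ---- instance JSON ----------------------------------------------------------

# Schema (one reader per top-level object; a file may hold one object or a
# list of them):
#   {"reader_id": "R1",
#    "images": [{"image_id": "img1", "height": 64, "width": 64,
#                "calls": [{"index": 0,
#                           "polygon": [[x1,y1],...]   # pixel-corner coords
#                           | "rle": [c0, c1, ...]     # row-major, starts bg
#                           | "bbox": [xmin,ymin,xmax,ymax]}]}]}

#' Read an instance-JSON annotation file
#'
#' Accepts per-call polygons (rasterized so that a pixel is foreground when
#' its center lies inside or on the polygon boundary), row-major run-length
#' encodings starting with a background count, or bare bounding boxes.
#' Unlike label images, JSON input can express overlapping calls from the
#' same reader; they are preserved as distinct calls.
#'
#' @param path Path to a JSON file following the documented schema.
#' @return A list with `calls` and `dims` as in [read_label_images()].
#' @export
read_instance_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc$reader_id)) doc <- list(doc)
  calls_rows <- list()
  dims <- list()
  seen <- character()
  for (ri in seq_along(doc)) {
    rd <- doc[[ri]]
    jp <- sprintf("$[%d]", ri - 1L)
    if (is.null(rd$reader_id)) stop("missing reader_id at ", jp, call. = FALSE)
    if (is.null(rd$images)) stop("missing images at ", jp, call. = FALSE)
    for (ii in seq_along(rd$images)) {
      im <- rd$images[[ii]]
      jpi <- sprintf("%s.images[%d]", jp, ii - 1L)
      for (f in c("image_id", "height", "width")) {
        if (is.null(im[[f]])) stop("missing ", f, " at ", jpi, call. = FALSE)
      }
      h <- as.integer(im$height); w <- as.integer(im$width)
      d0 <- dims[[im$image_id]]
      if (is.null(d0)) {
        dims[[im$image_id]] <- c(h, w)
      } else if (!identical(d0, c(h, w))) {
        stop("conflicting dims for image '", im$image_id, "' at ", jpi,
             call. = FALSE)
      }
      for (ci in seq_along(im$calls %||% list())) {
        cl <- im$calls[[ci]]
        jpc <- sprintf("%s.calls[%d]", jpi, ci - 1L)
        if (is.null(cl$index)) stop("missing index at ", jpc, call. = FALSE)
        key <- paste(rd$reader_id, im$image_id, cl$index)
        if (key %in% seen) {
          stop("duplicate (reader, image, index) at ", jpc, call. = FALSE)
        }
        seen <- c(seen, key)
        mask <- NULL
        bbox <- NULL
        if (!is.null(cl$polygon)) {
          poly <- do.call(rbind, lapply(cl$polygon, as.numeric))
          mask <- rasterize_polygon(poly, h, w)
          if (nrow(mask) == 0L) {
            stop("polygon rasterizes to an empty mask at ", jpc,
                 call. = FALSE)
          }
        } else if (!is.null(cl$rle)) {
          mask <- decode_rle(as.integer(unlist(cl$rle)), h, w)
          if (nrow(mask) == 0L) {
            stop("rle decodes to an empty mask at ", jpc, call. = FALSE)
          }
        } else if (!is.null(cl$bbox)) {
          bbox <- as.integer(unlist(cl$bbox))
          if (length(bbox) != 4L || bbox[1] > bbox[3] || bbox[2] > bbox[4]) {
            stop("malformed bbox at ", jpc, call. = FALSE)
          }
        } else {
          stop("call has none of polygon/rle/bbox at ", jpc, call. = FALSE)
        }
        calls_rows[[length(calls_rows) + 1L]] <- tibble::tibble(
          reader_id = as.character(rd$reader_id),
          image_id = as.character(im$image_id),
          call_index = as.integer(cl$index),
          mask = list(mask), bbox = list(bbox)
        )
      }
    }
  }
  calls <- dplyr::bind_rows(calls_rows)
  if (nrow(calls)) {
    calls <- calls[order(calls$reader_id, calls$image_id, calls$call_index), ]
    validate_calls(calls)
    calls <- extract_bounding_boxes_safe(calls)
  }
  list(calls = calls,
       dims = tibble::tibble(
         image_id = names(dims),
         height = unname(vapply(dims, `[`, integer(1), 1L)),
         width = unname(vapply(dims, `[`, integer(1), 2L))))
}

# bbox only for calls that have masks; leave box-only calls alone
extract_bounding_boxes_safe <- function(calls) {
  calls$bbox <- purrr::map2(calls$mask, calls$bbox, function(m, b) {
    if (is.null(m)) b else as.integer(mask_bbox(m))
  })
  calls
}

#' Write calls as instance JSON
#'
#' Masks are stored as row-major run-length encodings (counts alternating
#' background/foreground, starting with background); box-only calls store
#' their bbox.
#'
#' @param calls A calls table.
#' @param dims Tibble with `image_id`, `height`, `width` covering all images.
#' @param path Output path.
#' @export
write_instance_json <- function(calls, dims, path) {
  readers <- reader_ids(calls)
  doc <- lapply(readers, function(r) {
    imgs <- image_ids(calls[calls$reader_id == r, ])
    list(reader_id = r, images = lapply(imgs, function(img) {
      d <- dims[dims$image_id == img, ]
      if (nrow(d) != 1L) stop("no dims for image '", img, "'", call. = FALSE)
      sub <- calls_of(calls, r, img)
      list(image_id = img, height = d$height[1], width = d$width[1],
           calls = lapply(seq_len(nrow(sub)), function(i) {
             m <- sub$mask[[i]]
             if (is.null(m)) {
               list(index = sub$call_index[i], bbox = as.list(sub$bbox[[i]]))
             } else {
               list(index = sub$call_index[i],
                    rle = encode_rle(m, d$height[1], d$width[1]))
             }
           }))
    }))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Row-major RLE over the full grid; counts start with background.
encode_rle <- function(mask, height, width) {
  # row-major position: row * width + col, 0-based
  pos <- sort(mask[, 1L] * width + mask[, 2L])
  v <- integer(height * width)
  v[pos + 1L] <- 1L
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  as.list(counts)
}

decode_rle <- function(counts, height, width) {
  if (sum(counts) != height * width) {
    stop("rle counts do not cover the image grid", call. = FALSE)
  }
  vals <- rep(rep_len(c(0L, 1L), length(counts)), counts)
  pos <- which(vals == 1L) - 1L
  m <- cbind(row = pos %/% width, col = pos %% width)
  storage.mode(m) <- "integer"
  m
}

# A pixel (r, c) is foreground when its center (c + 0.5, r + 0.5) lies inside
# or on the boundary of the polygon (vertices in pixel-corner x, y coords).
rasterize_polygon <- function(poly, height, width) {
  xs <- poly[, 1L]; ys <- poly[, 2L]
  r0 <- max(0L, floor(min(ys) - 1)); r1 <- min(height - 1L, ceiling(max(ys)))
  c0 <- max(0L, floor(min(xs) - 1)); c1 <- min(width - 1L, ceiling(max(xs)))
  if (r1 < r0 || c1 < c0) {
    return(matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("row", "col"))))
  }
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  px <- grid$col + 0.5; py <- grid$row + 0.5
  keep <- point_in_polygon(px, py, xs, ys)
  m <- cbind(row = grid$row[keep], col = grid$col[keep])
  storage.mode(m) <- "integer"
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# Even-odd ray casting with an explicit on-boundary check.
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- n
  eps <- 1e-9
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (xi + t * dx - px)^2 + (yi + t * dy - py)^2
      onedge <- onedge | d2 < eps
    } else {
      onedge <- onedge | ((px - xi)^2 + (py - yi)^2 < eps)
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

# ---- metric tables ----------------------------------------------------------

.metric_cols <- c("image_id", "metric_name", "iou_threshold", "reader_group",
                  "value")

#' Write a metric table to CSV
#'
#' One row per record; `reader_group` list-columns are collapsed with `;`;
#' undefined values are written as empty cells. Round-trips losslessly with
#' [read_metric_table()].
#'
#' @param records Non-empty tibble with columns `image_id`, `metric_name`,
#'   `iou_threshold`, `reader_group` (list of character vectors), `value`.
#' @param path Output CSV path.
#' @export
write_metric_table <- function(records, path) {
  if (nrow(records) == 0L) stop("records must be non-empty", call. = FALSE)
  stopifnot(all(.metric_cols %in% names(records)))
  out <- records[.metric_cols]
  out$reader_group <- vapply(out$reader_group, paste, character(1),
                             collapse = ";")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a metric table written by [write_metric_table()]
#'
#' @param path CSV path.
#' @return A tibble with the same columns and types as the written records;
#'   empty cells come back as `NA`.
#' @export
read_metric_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    metric_name = readr::col_character(),
    iou_threshold = readr::col_double(),
    reader_group = readr::col_character(),
    value = readr::col_double()
  ))
  out$reader_group <- strsplit(out$reader_group, ";", fixed = TRUE)
  out
}
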