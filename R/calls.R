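#' The calls table
#'
#' The central data structure of mragree is the *calls table*: a tibble with
#' one row per call, i.e. one putative object delineated by one reader on one
#' image. Columns:
#'
#' * `reader_id` (character) — who made the call.
#' * `image_id` (character) — which image it is on.
#' * `call_index` (integer) — 0-based index, contiguous within each
#'   reader-by-image group.
#' * `mask` (list of integer matrices) — foreground pixels as (row, col)
#'   pairs, 0-based; may be `NULL` for box-only calls.
#' * `bbox` (list of integer vectors) — `c(xmin, ymin, xmax, ymax)` with
#'   `x = col`, `y = row`, inclusive at both ends; may be `NULL` when a mask
#'   is present.
#'
#' Every call carries at least one of `mask`/`bbox`; when both are present
#' the bbox is the tight bound of the mask. Label images cannot express
#' overlapping calls from one reader, but the instance-JSON reader can, and
#' the calls table permits them.
#'
#' @param reader_id,image_id Character vectors (recycled).
#' @param mask List of (row, col) integer matrices, or `NULL`.
#' @param bbox List of `c(xmin, ymin, xmax, ymax)` vectors, or `NULL`.
#' @param call_index Optional integer vector; defaults to 0-based order
#'   within each reader-by-image group.
#' @return A validated calls tibble.
#' @examples
#' sq <- cbind(row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L))
#' call_tbl(reader_id = "R1", image_id = "img1", mask = list(sq))
#' @export
call_tbl <- function(reader_id, image_id, mask = NULL, bbox = NULL,
                     call_index = NULL) {
  n <- max(length(reader_id), length(image_id),
           length(mask %||% list()), length(bbox %||% list()))
  tbl <- tibble::tibble(
    reader_id = rep_len(as.character(reader_id), n),
    image_id = rep_len(as.character(image_id), n),
    mask = if (is.null(mask)) rep(list(NULL), n) else mask,
    bbox = if (is.null(bbox)) rep(list(NULL), n) else bbox
  )
  if (is.null(call_index)) {
    tbl <- tbl |>
      dplyr::group_by(.data$reader_id, .data$image_id) |>
      dplyr::mutate(call_index = seq_len(dplyr::n()) - 1L) |>
      dplyr::ungroup()
  } else {
    tbl$call_index <- as.integer(rep_len(call_index, n))
  }
  tbl <- tbl[, c("reader_id", "image_id", "call_index", "mask", "bbox")]
  validate_calls(tbl)
  tbl
}

#' Validate a calls table
#'
#' Checks the structural invariants of a calls table: required columns,
#' contiguous 0-based `call_index` within each reader-by-image group,
#' mask/bbox presence, well-formed boxes, tight bboxes where both fields are
#' present, and (when `dims` is given) that all pixels are in bounds.
#'
#' @param calls A calls table.
#' @param dims Optional tibble with columns `image_id`, `height`, `width`.
#' @return `calls`, invisibly; errors describe the first violation found.
#' @export
validate_calls <- function(calls, dims = NULL) {
  need <- c("reader_id", "image_id", "call_index", "mask", "bbox")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols)) {
    stop("calls table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(calls$reader_id, calls$image_id, sep = "\r")
  for (grp in split(seq_len(nrow(calls)), key)) {
    idx <- sort(calls$call_index[grp])
    if (!identical(as.integer(idx), seq_along(idx) - 1L)) {
      stop("call_index values for reader '", calls$reader_id[grp[1]],
           "', image '", calls$image_id[grp[1]],
           "' are not contiguous 0-based", call. = FALSE)
    }
  }
  for (i in seq_len(nrow(calls))) {
    m <- calls$mask[[i]]
    b <- calls$bbox[[i]]
    if (is.null(m) && is.null(b)) {
      stop("call ", i, " has neither mask nor bbox", call. = FALSE)
    }
    if (!is.null(m)) {
      if (!is.matrix(m) || ncol(m) != 2L || nrow(m) == 0L) {
        stop("call ", i, " has a malformed or empty mask", call. = FALSE)
      }
      if (any(m < 0L)) stop("call ", i, " has negative pixel coordinates",
                            call. = FALSE)
    }
    if (!is.null(b)) {
      if (length(b) != 4L || b[1] > b[3] || b[2] > b[4]) {
        stop("call ", i, " has a malformed bbox", call. = FALSE)
      }
      if (!is.null(m) && !identical(as.integer(b), as.integer(mask_bbox(m)))) {
        stop("call ", i, ": bbox is not the tight bound of its mask",
             call. = FALSE)
      }
    }
    if (!is.null(dims) && !is.null(m)) {
      d <- dims[dims$image_id == calls$image_id[i], ]
      if (nrow(d) == 1L &&
          (max(m[, 1L]) >= d$height[1] || max(m[, 2L]) >= d$width[1])) {
        stop("call ", i, " on image '", calls$image_id[i],
             "' has pixels outside the image", call. = FALSE)
      }
    }
  }
  invisible(calls)
}

#' Add tight bounding boxes to every call
#'
#' Computes, for each call that has a mask, the tight inclusive bounding box
#' (minimum and maximum x and y pixel coordinates of the mask) and stores it
#' in the `bbox` column. Masks are retained; calls that already carry a tight
#' bbox are unchanged. This is how box-level comparisons with an object
#' detector are prepared from segmentation masks.
#'
#' @param calls A calls table in which every call has a mask.
#' @return The calls table with `bbox` filled in.
#' @export
extract_bounding_boxes <- function(calls) {
  calls$bbox <- purrr::map2(calls$mask, calls$bbox, function(m, b) {
    if (is.null(m)) {
      if (is.null(b)) stop("call has neither mask nor bbox", call. = FALSE)
      return(b)
    }
    as.integer(mask_bbox(m))
  })
  calls
}

# Calls of one reader on one image, ordered by call_index.
calls_of <- function(calls, reader, image) {
  out <- calls[calls$reader_id == reader & calls$image_id == image, ]
  out[order(out$call_index), ]
}

reader_ids <- function(calls) unique(calls$reader_id)
image_ids <- function(calls) unique(calls$image_id)
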