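# Pixel- and box-level overlap, the M x N agreement matrix, thresholded
# non-maximum suppression, and the two-reader (pairwise) indices.

#' Pixel-level overlap between two masks
#'
#' `mask_iou()` is the intersection over union |A∩B|/|A∪B|; `mask_dsc()` the
#' Dice–Sørensen coefficient 2|A∩B|/(|A|+|B|). Both are exact ratios of
#' integer pixel counts and satisfy `dsc = 2*iou/(1+iou)`.
#'
#' @param a,b Non-empty (row, col) integer mask matrices.
#' @return A fraction in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  check_mask(a); check_mask(b)
  ka <- px_key(a); kb <- px_key(b)
  ni <- sum(ka %in% kb)
  ni / (length(ka) + length(kb) - ni)
}

#' @rdname mask_iou
#' @export
mask_dsc <- function(a, b) {
  check_mask(a); check_mask(b)
  ka <- px_key(a); kb <- px_key(b)
  2 * sum(ka %in% kb) / (length(ka) + length(kb))
}

check_mask <- function(m) {
  if (is.null(m) || !is.matrix(m) || nrow(m) == 0L) {
    stop("overlap metrics require non-empty masks", call. = FALSE)
  }
  invisible(m)
}

#' Bounding-box intersection over union
#'
#' Boxes are `c(xmin, ymin, xmax, ymax)`, inclusive at both ends, so a box
#' covers `(xmax-xmin+1)*(ymax-ymin+1)` pixels.
#'
#' @param a,b Valid inclusive bboxes.
#' @return A fraction in `[0, 1]`.
#' @export
bbox_iou <- function(a, b) {
  check_bbox(a); check_bbox(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1]) + 1
  ih <- min(a[4], b[4]) - max(a[2], b[2]) + 1
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area <- function(z) (z[3] - z[1] + 1) * (z[4] - z[2] + 1)
  inter / (area(a) + area(b) - inter)
}

check_bbox <- function(b) {
  if (is.null(b) || length(b) != 4L || b[1] > b[3] || b[2] > b[4]) {
    stop("malformed bbox (need xmin <= xmax, ymin <= ymax)", call. = FALSE)
  }
  invisible(b)
}

.metric_kinds <- c("mask_iou", "mask_dsc", "bbox_iou")

#' Pairwise agreement matrix for two readers on one image
#'
#' Computes the M x N matrix of overlap scores between every call of reader A
#' (rows) and every call of reader B (columns), using the chosen pixel- or
#' box-level metric. For mask metrics, pairs whose tight bounding boxes do
#' not overlap are zero without computing the pixel intersection.
#'
#' @param calls A calls table.
#' @param image Image id.
#' @param reader_a,reader_b Reader ids.
#' @param metric One of `"mask_iou"`, `"mask_dsc"`, `"bbox_iou"`.
#' @return A numeric matrix with attributes `reader_a`, `reader_b`,
#'   `image_id`, `metric`, of class `"agreement_matrix"`. Rows/columns are
#'   ordered by `call_index`.
#' @export
agreement_matrix <- function(calls, image, reader_a, reader_b,
                             metric = c("mask_iou", "mask_dsc", "bbox_iou")) {
  metric <- match.arg(metric)
  ca <- calls_of(calls, reader_a, image)
  cb <- calls_of(calls, reader_b, image)
  m <- agreement_matrix_impl(ca$mask, cb$mask, ca$bbox, cb$bbox, metric)
  structure(m, reader_a = reader_a, reader_b = reader_b, image_id = image,
            metric = metric, class = c("agreement_matrix", class(m)))
}

agreement_matrix_impl <- function(masks_a, masks_b, bboxes_a, bboxes_b,
                                  metric) {
  M <- length(masks_a); N <- length(masks_b)
  s <- matrix(0, M, N)
  if (M == 0L || N == 0L) return(s)
  if (metric == "bbox_iou") {
    ba <- bboxes_a; bb <- bboxes_b
    if (any(vapply(ba, is.null, logical(1))) ||
        any(vapply(bb, is.null, logical(1)))) {
      stop("bbox_iou requires bboxes on every call", call. = FALSE)
    }
    for (i in seq_len(M)) for (j in seq_len(N)) {
      s[i, j] <- bbox_iou(ba[[i]], bb[[j]])
    }
    return(s)
  }
  if (any(vapply(masks_a, is.null, logical(1))) ||
      any(vapply(masks_b, is.null, logical(1)))) {
    stop("mask metric requires masks on every call", call. = FALSE)
  }
  keys_a <- lapply(masks_a, px_key)
  keys_b <- lapply(masks_b, px_key)
  tb_a <- lapply(masks_a, mask_bbox)
  tb_b <- lapply(masks_b, mask_bbox)
  for (i in seq_len(M)) {
    bi <- tb_a[[i]]; ki <- keys_a[[i]]
    for (j in seq_len(N)) {
      bj <- tb_b[[j]]
      if (bi[1] > bj[3] || bj[1] > bi[3] || bi[2] > bj[4] || bj[2] > bi[4]) {
        next
      }
      kj <- keys_b[[j]]
      ni <- sum(ki %in% kj)
      s[i, j] <- if (metric == "mask_iou") {
        ni / (length(ki) + length(kj) - ni)
      } else {
        2 * ni / (length(ki) + length(kj))
      }
    }
  }
  s
}

#' Thresholded non-maximum suppression on an agreement matrix
#'
#' Scores below the threshold are set to zero (the comparison is inclusive:
#' a score equal to the threshold survives). A pair (i, j) is retained iff
#' its score survives and is the maximum of row i and of column j among the
#' survivors. Exact ties are broken deterministically: among tied row maxima
#' the smallest column wins; among tied column maxima the smallest row wins.
#' Each call therefore appears in at most one retained pair. This resolves
#' fragmenting: when one reader splits another reader's object into several
#' calls, only the best-overlapping fragment is accepted as the agreement and
#' the remaining fragments stay unmatched.
#'
#' @param m An agreement matrix (plain matrix or [agreement_matrix()]).
#' @param threshold Fraction in (0, 1].
#' @return A tibble of class `"matched_pairs"` with columns `call_a`,
#'   `call_b` (0-based call indices) and `score`, plus a `threshold`
#'   attribute.
#' @export
suppress_nonmaximum <- function(m, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  s <- unclass(m)
  attributes(s) <- list(dim = dim(s))
  s[s < threshold] <- 0
  M <- nrow(s); N <- ncol(s)
  pairs <- tibble::tibble(call_a = integer(), call_b = integer(),
                          score = double())
  if (M > 0L && N > 0L) {
    row_win <- apply(s, 1L, which.max)   # first max: smaller column wins ties
    col_win <- apply(s, 2L, which.max)   # first max: smaller row wins ties
    keep_i <- integer(); keep_j <- integer()
    for (i in seq_len(M)) {
      j <- row_win[i]
      if (s[i, j] > 0 && col_win[j] == i) {
        keep_i <- c(keep_i, i); keep_j <- c(keep_j, j)
      }
    }
    pairs <- tibble::tibble(call_a = keep_i - 1L, call_b = keep_j - 1L,
                            score = s[cbind(keep_i, keep_j)])
  }
  structure(pairs, threshold = threshold,
            class = c("matched_pairs", class(pairs)))
}

#' Confusion counts from matched pairs
#'
#' Treats reader A as the reference: `tp` is the number of retained pairs,
#' `fn = n_calls_a - tp` (objects only A called), `fp = n_calls_b - tp`
#' (objects only B called). Swapping the readers swaps `fp` and `fn`; the
#' Jaccard and Sørensen indices are unaffected, so reader pairs are
#' commutable.
#'
#' @param pairs A `matched_pairs` tibble from [suppress_nonmaximum()].
#' @param n_calls_a,n_calls_b Total call counts of the two readers.
#' @return A tibble with columns `tp`, `fp`, `fn`.
#' @export
pairwise_confusion <- function(pairs, n_calls_a, n_calls_b) {
  tp <- nrow(pairs)
  if (tp > n_calls_a || tp > n_calls_b) {
    stop("internal inconsistency: more matches than calls", call. = FALSE)
  }
  tibble::tibble(tp = tp, fp = n_calls_b - tp, fn = n_calls_a - tp)
}

#' Pairwise Jaccard and Sørensen indices from confusion counts
#'
#' Jaccard = TP/(TP+FP+FN); Sørensen = 2TP/(2TP+FP+FN). True negatives are
#' undefined in object detection and never enter. When `tp+fp+fn = 0`
#' (neither reader called anything) both indices are undefined and returned
#' as `NA`, never silently 0 or 1.
#'
#' @param counts A tibble/list with elements `tp`, `fp`, `fn`.
#' @return A tibble with columns `jaccard`, `sorensen`.
#' @export
pairwise_indices <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  tot <- tp + fp + fn
  tibble::tibble(
    jaccard = ifelse(tot == 0, NA_real_, tp / tot),
    sorensen = ifelse(tot == 0, NA_real_, 2 * tp / (2 * tp + fp + fn))
  )
}

#' All unique pairwise comparisons, per image
#'
#' Runs the full two-reader pipeline (agreement matrix, thresholded NMS,
#' confusion counts, indices) for every unique reader pair on every image:
#' `n(n-1)/2` comparisons per image for `n` readers.
#'
#' @param calls A calls table with >= 2 readers.
#' @param metric Overlap metric, see [agreement_matrix()].
#' @param threshold Agreement threshold in (0, 1].
#' @return A tibble with one row per image x reader pair: `image_id`,
#'   `reader_a`, `reader_b`, `n_calls_a`, `n_calls_b`, `tp`, `fp`, `fn`,
#'   `jaccard`, `sorensen`, `metric`, `threshold`.
#' @export
pairwise_agreement <- function(calls, metric = "mask_iou", threshold = 0.5) {
  readers <- reader_ids(calls)
  if (length(readers) < 2L) stop("need >= 2 readers", call. = FALSE)
  pairs <- reader_pairs(readers)
  out <- purrr::map(image_ids(calls), function(img) {
    purrr::pmap(pairs, function(reader_a, reader_b) {
      am <- agreement_matrix(calls, img, reader_a, reader_b, metric)
      mp <- suppress_nonmaximum(am, threshold)
      cc <- pairwise_confusion(mp, nrow(am), ncol(am))
      dplyr::bind_cols(
        tibble::tibble(image_id = img, reader_a = reader_a,
                       reader_b = reader_b,
                       n_calls_a = nrow(am), n_calls_b = ncol(am)),
        cc, pairwise_indices(cc)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out$metric <- metric
  out$threshold <- threshold
  out
}
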