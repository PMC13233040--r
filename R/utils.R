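# Internal helpers shared across modules.

# Pixels are (row, col) pairs, 0-based, row-major; a mask is an integer
# matrix with columns "row" and "col". Keys pack a pixel into one integer
# (supports images up to 65536 px wide).
.KEY <- 65536L

px_key <- function(mask) mask[, 1L] * .KEY + mask[, 2L]

key_to_mask <- function(keys) {
  m <- cbind(row = keys %/% .KEY, col = keys %% .KEY)
  storage.mode(m) <- "integer"
  m
}

#' Tight bounding box of a pixel mask
#'
#' @param mask Integer matrix of (row, col) pixel coordinates, 0-based.
#' @return Integer vector `c(xmin, ymin, xmax, ymax)` with `x = col`,
#'   `y = row`, inclusive at both ends.
#' @export
mask_bbox <- function(mask) {
  if (is.null(mask) || nrow(mask) == 0L) {
    stop("mask must be a non-empty (row, col) matrix", call. = FALSE)
  }
  c(xmin = min(mask[, 2L]), ymin = min(mask[, 1L]),
    xmax = max(mask[, 2L]), ymax = max(mask[, 1L]))
}

# Deterministic substream seeds: fold indices into a 31-bit LCG state so that
# per-(image, reader) streams are independent of cohort size and reader order.
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

#' Unique reader pairs
#'
#' Enumerates the `n(n-1)/2` unique unordered reader pairs that the consensus
#' procedure compares, in a stable order.
#'
#' @param readers Character vector of reader ids (order is preserved).
#' @return A tibble with columns `reader_a`, `reader_b`.
#' @export
reader_pairs <- function(readers) {
  readers <- unique(as.character(readers))
  n <- length(readers)
  if (n < 2L) {
    return(tibble::tibble(reader_a = character(), reader_b = character()))
  }
  idx <- utils::combn(n, 2L)
  tibble::tibble(reader_a = readers[idx[1L, ]], reader_b = readers[idx[2L, ]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
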