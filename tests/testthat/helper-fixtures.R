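# Shared fixtures and independent oracles, all built in code.

# Axis-aligned rectangle mask covering rows r0..r1, cols c0..c1 (0-based).
rect_mask <- function(r0, r1, c0, c1) {
  g <- expand.grid(row = r0:r1, col = c0:c1)
  m <- cbind(row = g$row, col = g$col)
  storage.mode(m) <- "integer"
  m
}

# Disc mask of radius r centred at (cy, cx).
disc_mask <- function(cy, cx, r) {
  g <- expand.grid(row = (cy - r):(cy + r), col = (cx - r):(cx + r))
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= r^2
  m <- cbind(row = g$row[keep], col = g$col[keep])
  storage.mode(m) <- "integer"
  m
}

# Calls table from a named list: list(R1 = list(mask1, mask2), ...)
calls_from_masks <- function(masks_by_reader, image_id = "img1") {
  out <- lapply(names(masks_by_reader), function(r) {
    extract_bounding_boxes(
      call_tbl(r, image_id, mask = masks_by_reader[[r]])
    )
  })
  do.call(rbind, out)
}

# Independent brute-force oracle for thresholded NMS: explicit scans, written
# separately from the package's vectorized rule. A pair (i, j) is retained
# iff its score survives the inclusive threshold and (i, j) is the designated
# winner (smallest row, then column, among ties) of both its row and column.
nms_oracle <- function(m, threshold) {
  M <- nrow(m); N <- ncol(m)
  keep <- matrix(FALSE, M, N)
  s <- m
  s[s < threshold] <- 0
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      if (s[i, j] <= 0) next
      # row winner: first column attaining the row max
      rw <- 0
      for (jj in seq_len(N)) {
        if (s[i, jj] > rw) rw <- s[i, jj]
      }
      row_winner <- which(s[i, ] == rw)[1]
      # column winner: first row attaining the column max
      cw <- 0
      for (ii in seq_len(M)) {
        if (s[ii, j] > cw) cw <- s[ii, j]
      }
      col_winner <- which(s[, j] == cw)[1]
      keep[i, j] <- (row_winner == j) && (col_winner == i)
    }
  }
  which(keep, arr.ind = TRUE) - 1L
}

# Independent winding-number point-in-polygon oracle for rasterization tests.
winding_inside <- function(px, py, xs, ys) {
  n <- length(xs)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(ys[i] - py, xs[i] - px)
    a2 <- atan2(ys[j] - py, xs[j] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    total <- total + d
  }
  abs(total) > pi
}

# Small random two-reader fixture: each reader gets a few random rectangles
# in a 48x48 image (possibly overlapping across readers).
random_two_reader_calls <- function(seed, image_id = "img1") {
  withr::with_seed(seed, {
    masks <- lapply(c("A", "B"), function(r) {
      n <- sample(0:5, 1)
      lapply(seq_len(n), function(i) {
        r0 <- sample(0:40, 1); c0 <- sample(0:40, 1)
        rect_mask(r0, r0 + sample(2:7, 1), c0, c0 + sample(2:7, 1))
      })
    })
    names(masks) <- c("A", "B")
    masks <- masks[lengths(masks) > 0]
    if (length(masks) < 2) return(NULL)
    calls_from_masks(masks, image_id)
  })
}

# Small multi-reader cohort for fast consensus/metric tests.
small_cohort <- function(n_images = 4, n_readers = 3, seed = 5,
                         profiles = reader_profile()) {
  generate_cohort(n_images = n_images, n_readers = n_readers,
                  profiles = profiles, seed = seed,
                  dims = c(160L, 160L), n_objects = 8L,
                  size_range = c(4, 9))
}
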