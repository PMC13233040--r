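# The multireader generalizations: index computation from match-matrix
# tallies, the mean-pairwise baseline, and image-level aggregation.

#' Multireader count container
#'
#' Holds, for one image and one reader group, the calls per reader `C_j`
#' (j = 1..n_readers) and the consensus objects per agreement level `O_k`
#' (k = 1..n_readers, where `O_k` counts objects called by exactly `k`
#' readers). Call conservation (`sum(k * O_k) == sum(C_j)`) is enforced:
#' every call belongs to exactly one consensus object.
#'
#' @param calls_per_reader Non-negative integer vector `C_j`.
#' @param objects_by_k Non-negative integer vector `O_k`, length
#'   `length(calls_per_reader)`.
#' @return A list of class `"multireader_counts"`.
#' @export
multireader_counts <- function(calls_per_reader, objects_by_k) {
  C <- as.integer(calls_per_reader)
  O <- as.integer(objects_by_k)
  if (any(C < 0L) || any(O < 0L)) stop("counts must be non-negative",
                                       call. = FALSE)
  if (length(C) < 2L) stop("need >= 2 readers", call. = FALSE)
  if (length(O) != length(C)) {
    stop("objects_by_k must have one entry per agreement level 1..n_readers",
         call. = FALSE)
  }
  if (sum(seq_along(O) * O) != sum(C)) {
    stop("call conservation violated: sum(k * O_k) != sum(C_j)",
         call. = FALSE)
  }
  structure(list(n_readers = length(C), calls_per_reader = C,
                 objects_by_k = O), class = "multireader_counts")
}

#' Tally calls and consensus objects from a match matrix
#'
#' @param mm A [build_match_matrix()] result.
#' @return A [multireader_counts()] object: `C_j` is the number of calls of
#'   reader j, `O_k` the number of objects with exactly k member calls.
#' @export
count_calls_and_objects <- function(mm) {
  C <- vapply(mm$readers, function(r) {
    sum(mm$entries$reader_id == r)
  }, integer(1))
  k <- object_k(mm)
  O <- tabulate(k, nbins = length(mm$readers))
  multireader_counts(C, O)
}

#' Multireader Jaccard and Sørensen indices
#'
#' The multireader Jaccard index is
#' `(sum(C_j) - sum(O_k)) / ((n_readers - 1) * sum(O_k))`: the excess of
#' calls over consensus objects, normalized so that full agreement of all
#' readers on every object gives 1 and a cohort in which no two calls ever
#' match gives 0. The multireader Sørensen index follows from the relation
#' `S = n_R * J / (n_R - 1 + J)`, which for two readers reduces to the
#' familiar `S = 2J/(1+J)`; equivalently
#' `S = n_R(ΣC−ΣO) / ((n_R−1)^2 ΣO + ΣC − ΣO)`. For two readers both
#' indices reduce exactly to `TP/(TP+FP+FN)` and `2TP/(2TP+FP+FN)`.
#' When `sum(O_k) = 0` (no calls at all) the indices are undefined (`NA`).
#'
#' @param counts A [multireader_counts()] object.
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @export
multireader_jaccard <- function(counts) {
  stopifnot(inherits(counts, "multireader_counts"))
  total_calls <- sum(counts$calls_per_reader)
  total_objects <- sum(counts$objects_by_k)
  if (total_objects == 0L) return(NA_real_)
  (total_calls - total_objects) /
    ((counts$n_readers - 1) * total_objects)
}

#' @rdname multireader_jaccard
#' @export
multireader_sorensen <- function(counts) {
  stopifnot(inherits(counts, "multireader_counts"))
  total_calls <- sum(counts$calls_per_reader)
  total_objects <- sum(counts$objects_by_k)
  if (total_objects == 0L) return(NA_real_)
  n <- counts$n_readers
  # closed form of S = n*J/(n-1+J); exact integer ratio, so the two-reader
  # case reduces bit-for-bit to 2TP/(2TP+FP+FN)
  n * (total_calls - total_objects) /
    ((n - 1)^2 * total_objects + total_calls - total_objects)
}

#' Per-image multireader indices across thresholds
#'
#' Builds the match matrix for every image at every threshold and evaluates
#' both multireader indices. Computation is strictly per image; values are
#' never pooled across images (use [aggregate_over_images()] afterwards, or
#' [pooled_multireader_index()] for the explicit pooled-counts variant).
#'
#' @param calls A calls table with >= 2 readers.
#' @param metric Overlap metric, see [agreement_matrix()].
#' @param thresholds Numeric vector of agreement thresholds in (0, 1].
#' @param readers Optional reader subset.
#' @return A tibble: `image_id`, `threshold`, `n_readers`, `total_calls`,
#'   `total_objects`, `multireader_jaccard`, `multireader_sorensen`,
#'   `metric`.
#' @export
multireader_index <- function(calls, metric = "mask_iou",
                              thresholds = c(0.25, 0.5, 0.75),
                              readers = NULL) {
  readers <- readers %||% reader_ids(calls)
  out <- purrr::map(image_ids(calls), function(img) {
    purrr::map(thresholds, function(th) {
      mm <- build_match_matrix(calls, img, metric, th, readers)
      cnt <- count_calls_and_objects(mm)
      tibble::tibble(
        image_id = img, threshold = th, n_readers = cnt$n_readers,
        total_calls = sum(cnt$calls_per_reader),
        total_objects = sum(cnt$objects_by_k),
        multireader_jaccard = multireader_jaccard(cnt),
        multireader_sorensen = multireader_sorensen(cnt)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out$metric <- metric
  out
}

#' Pooled-counts multireader indices
#'
#' Sums calls and objects over all images before forming the indices. This
#' is not the default methodology (per-image computation with image-level
#' aggregation is); it is provided explicitly for datasets with many empty
#' or tiny images.
#'
#' @inheritParams multireader_index
#' @param threshold Single agreement threshold.
#' @return A one-row tibble with the pooled counts and indices.
#' @export
pooled_multireader_index <- function(calls, metric = "mask_iou",
                                     threshold = 0.5, readers = NULL) {
  readers <- readers %||% reader_ids(calls)
  C <- integer(length(readers)); O <- integer(length(readers))
  for (img in image_ids(calls)) {
    cnt <- count_calls_and_objects(
      build_match_matrix(calls, img, metric, threshold, readers)
    )
    C <- C + cnt$calls_per_reader
    O <- O + cnt$objects_by_k
  }
  cnt <- multireader_counts(C, O)
  tibble::tibble(threshold = threshold, n_readers = cnt$n_readers,
                 total_calls = sum(C), total_objects = sum(O),
                 multireader_jaccard = multireader_jaccard(cnt),
                 multireader_sorensen = multireader_sorensen(cnt),
                 metric = metric)
}

#' Mean of the unique pairwise comparisons, per image
#'
#' The pairwise baseline the multireader indices are contrasted with: the
#' mean of the `n(n-1)/2` unique pairwise Jaccard (and Sørensen) values on
#' each image. Undefined pairs (neither reader called anything) are
#' excluded; an image where all pairs are undefined yields `NA`.
#'
#' @inheritParams multireader_index
#' @param threshold Single agreement threshold.
#' @return A tibble: `image_id`, `threshold`, `mean_pairwise_jaccard`,
#'   `mean_pairwise_sorensen`, `n_pairs`, `n_pairs_defined`, `metric`.
#' @export
mean_pairwise_index <- function(calls, metric = "mask_iou", threshold = 0.5) {
  pw <- pairwise_agreement(calls, metric, threshold)
  pw |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      mean_pairwise_jaccard = if (all(is.na(.data$jaccard))) NA_real_ else
        mean(.data$jaccard, na.rm = TRUE),
      mean_pairwise_sorensen = if (all(is.na(.data$sorensen))) NA_real_ else
        mean(.data$sorensen, na.rm = TRUE),
      n_pairs = dplyr::n(),
      n_pairs_defined = sum(!is.na(.data$jaccard)),
      .groups = "drop"
    ) |>
    dplyr::mutate(threshold = threshold, metric = metric) |>
    dplyr::relocate("threshold", .after = "image_id")
}

#' Aggregate per-image metric values
#'
#' Mean of the defined values with a two-sided 95% (by default) t-interval
#' of the mean, reporting how many undefined values were excluded.
#'
#' @param values Numeric vector of per-image values; `NA` marks undefined.
#' @param conf Confidence level for the interval of the mean.
#' @return A one-row tibble: `mean`, `ci_low`, `ci_high`, `n`,
#'   `n_undefined`.
#' @export
aggregate_over_images <- function(values, conf = 0.95) {
  n_undef <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("all values are undefined", call. = FALSE)
  m <- mean(v)
  if (length(v) == 1L || stats::sd(v) == 0) {
    half <- 0
  } else {
    half <- stats::qt(1 - (1 - conf) / 2, length(v) - 1L) *
      stats::sd(v) / sqrt(length(v))
  }
  tibble::tibble(mean = m, ci_low = m - half, ci_high = m + half,
                 n = length(v), n_undefined = n_undef)
}

#' Agreement summary table across thresholds
#'
#' Convenience wrapper producing the standard summary: for each threshold,
#' the image-aggregated mean pairwise and multireader Jaccard and Sørensen
#' indices with confidence intervals.
#'
#' @inheritParams multireader_index
#' @param conf Confidence level.
#' @return A tibble with columns `threshold`, `statistic` (`mean_pairwise`
#'   or `multireader`), `index` (`jaccard`/`sorensen`), `mean`, `ci_low`,
#'   `ci_high`, `n`, `n_undefined`.
#' @export
agreement_summary <- function(calls, metric = "mask_iou",
                              thresholds = c(0.25, 0.5, 0.75), conf = 0.95) {
  mr <- multireader_index(calls, metric, thresholds)
  out <- purrr::map(thresholds, function(th) {
    pw <- mean_pairwise_index(calls, metric, th)
    mr_th <- mr[mr$threshold == th, ]
    dplyr::bind_rows(
      dplyr::mutate(aggregate_over_images(pw$mean_pairwise_jaccard, conf),
                    statistic = "mean_pairwise", index = "jaccard"),
      dplyr::mutate(aggregate_over_images(pw$mean_pairwise_sorensen, conf),
                    statistic = "mean_pairwise", index = "sorensen"),
      dplyr::mutate(aggregate_over_images(mr_th$multireader_jaccard, conf),
                    statistic = "multireader", index = "jaccard"),
      dplyr::mutate(aggregate_over_images(mr_th$multireader_sorensen, conf),
                    statistic = "multireader", index = "sorensen")
    ) |> dplyr::mutate(threshold = th)
  }) |> dplyr::bind_rows()
  out[c("threshold", "statistic", "index", "mean", "ci_low", "ci_high",
        "n", "n_undefined")]
}
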