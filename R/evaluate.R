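# Evaluation procedures: leave-one-reader-out quality analysis, candidate
# (algorithm-as-additional-reader) comparison with noninferiority bounds,
# ground-truth stringency curves, and thin wrappers around the standard
# nonparametric tests.

# Per-image multireader Jaccard for a reader subset, reusing precomputed
# pairwise match edges for the full group. Edges between subset readers are
# exactly the pairwise matches of the subset, so only linking is redone.
subset_jaccard <- function(nodes, edges, subset) {
  keep <- nodes$reader %in% subset
  sub_nodes <- list(ids = nodes$ids[keep], reader = nodes$reader[keep],
                    call_index = nodes$call_index[keep])
  sub_edges <- edges[edges$from %in% sub_nodes$ids &
                       edges$to %in% sub_nodes$ids, ]
  lk <- link_components(sub_nodes, sub_edges)
  total_calls <- length(sub_nodes$ids)
  total_objects <- length(unique(lk$membership))
  if (total_objects == 0L) return(NA_real_)
  (total_calls - total_objects) / ((length(subset) - 1) * total_objects)
}

# Per-image multireader Jaccard for several reader groups at once.
groupwise_jaccard <- function(calls, groups, metric, threshold) {
  readers <- reader_ids(calls)
  purrr::map(image_ids(calls), function(img) {
    edges <- pairwise_match_edges(calls, img, readers, metric, threshold)
    nodes <- node_ids(calls, img, readers)
    tibble::tibble(
      image_id = img,
      group = names(groups),
      value = unname(vapply(groups, function(g) {
        subset_jaccard(nodes, edges, g)
      }, double(1)))
    )
  }) |> dplyr::bind_rows()
}

#' Leave-one-reader-out quality analysis
#'
#' Compares the per-image multireader Jaccard index of the full reader group
#' with that of each unique subset of `n_readers - 1` readers (one
#' comparison per excluded reader). Each comparison is a Mann–Whitney U-test
#' of the one-sided alternative that the smaller group has the higher mean
#' (excluding a discordant reader raises agreement), Bonferroni-corrected
#' over the number of comparisons. A significant exclusion flags the
#' excluded reader as performing out of distribution relative to the group.
#'
#' @param calls A calls table with >= 3 readers.
#' @param metric Overlap metric, see [agreement_matrix()].
#' @param threshold Agreement threshold in (0, 1].
#' @param alpha Significance level applied to adjusted p-values.
#' @param m_comparisons Bonferroni correction count; defaults to the number
#'   of excluded-reader comparisons (use a larger value when the analysis is
#'   repeated across several thresholds).
#' @return An object of class `"mr_loo"` with `per_image` (long tibble of
#'   per-image values by group) and `comparisons` (one row per excluded
#'   reader with means, raw and adjusted p). `tidy()` returns the
#'   comparisons, `glance()` a one-row summary.
#' @export
leave_one_out <- function(calls, metric = "mask_iou", threshold = 0.5,
                          alpha = 0.05, m_comparisons = NULL) {
  readers <- reader_ids(calls)
  n <- length(readers)
  if (n < 3L) stop("leave-one-out needs >= 3 readers", call. = FALSE)
  groups <- c(list(full = readers),
              stats::setNames(lapply(readers, function(r) setdiff(readers, r)),
                              paste0("without_", readers)))
  per_image <- groupwise_jaccard(calls, groups, metric, threshold)
  m <- m_comparisons %||% n
  full_vals <- per_image$value[per_image$group == "full"]
  comparisons <- purrr::map(readers, function(r) {
    sub_vals <- per_image$value[per_image$group == paste0("without_", r)]
    p <- mwu_bonferroni(sub_vals, full_vals, m_comparisons = m,
                        alternative = "greater")
    tibble::tibble(
      excluded_reader = r,
      mean_full = mean(full_vals, na.rm = TRUE),
      mean_subset = mean(sub_vals, na.rm = TRUE),
      adjusted_p = p,
      significant = !is.na(p) && p < alpha
    )
  }) |> dplyr::bind_rows()
  structure(list(per_image = per_image, comparisons = comparisons,
                 metric = metric, threshold = threshold, alpha = alpha,
                 n_comparisons_for_correction = m),
            class = "mr_loo")
}

#' Compare a reader group with the group plus a candidate reader
#'
#' Treats a candidate annotation set (typically an algorithm's output) as an
#' additional reader: for each threshold, the per-image multireader index of
#' the original group is compared with that of the group plus the candidate.
#' Reported per threshold: a two-sided and a one-sided (original group
#' higher) Mann–Whitney U-test, Bonferroni-corrected, and the noninferiority
#' lower bound — the lower limit of the one-sided 90% confidence interval of
#' the per-image difference (group-with-candidate minus group-without). A
#' bound at or near zero indicates the candidate does not degrade group
#' agreement.
#'
#' @param calls Calls table of the original reader group (>= 2 readers).
#' @param candidate Calls table of the candidate reader (single reader id,
#'   images a subset of those in `calls`).
#' @param metric Overlap metric.
#' @param thresholds Agreement thresholds.
#' @param level Confidence level of the one-sided noninferiority interval.
#' @param n_boot Bootstrap replicates for the bound.
#' @param seed Seed for the bootstrap.
#' @param m_comparisons Bonferroni count; defaults to `length(thresholds)`.
#' @param alpha Significance level.
#' @return An object of class `"mr_candidate"` with `per_image` and
#'   `comparisons`; `tidy()`/`glance()` methods apply.
#' @export
compare_with_candidate <- function(calls, candidate, metric = "mask_iou",
                                   thresholds = c(0.25, 0.5, 0.75),
                                   level = 0.90, n_boot = 10000L, seed = 1L,
                                   m_comparisons = NULL, alpha = 0.05) {
  cand_readers <- reader_ids(candidate)
  if (length(cand_readers) != 1L) {
    stop("candidate must be a single reader", call. = FALSE)
  }
  if (cand_readers %in% reader_ids(calls)) {
    stop("candidate reader id collides with an existing reader",
         call. = FALSE)
  }
  extra <- setdiff(image_ids(candidate), image_ids(calls))
  if (length(extra)) {
    stop("candidate covers image(s) absent from the group: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  humans <- reader_ids(calls)
  combined <- dplyr::bind_rows(calls, candidate)
  m <- m_comparisons %||% length(thresholds)
  per_image <- purrr::map(thresholds, function(th) {
    groupwise_jaccard(
      combined,
      list(group = humans, with_candidate = c(humans, cand_readers)),
      metric, th
    ) |> dplyr::mutate(threshold = th)
  }) |> dplyr::bind_rows()
  comparisons <- purrr::map(thresholds, function(th) {
    sub <- per_image[per_image$threshold == th, ]
    wide <- tidyr::pivot_wider(sub, names_from = "group",
                               values_from = "value")
    diffs <- wide$with_candidate - wide$group
    tibble::tibble(
      threshold = th,
      mean_group = mean(wide$group, na.rm = TRUE),
      mean_with_candidate = mean(wide$with_candidate, na.rm = TRUE),
      p_two_sided = mwu_bonferroni(wide$group, wide$with_candidate,
                                   m_comparisons = m,
                                   alternative = "two.sided"),
      p_group_higher = mwu_bonferroni(wide$group, wide$with_candidate,
                                      m_comparisons = m,
                                      alternative = "greater"),
      noninferiority_lower_bound = noninferiority_lower_bound(
        diffs, level = level, n_boot = n_boot,
        seed = derive_seed(seed, round(th * 1000))
      ),
      n_images = sum(!is.na(diffs))
    )
  }) |> dplyr::bind_rows()
  structure(list(per_image = per_image, comparisons = comparisons,
                 candidate = cand_readers, metric = metric, level = level,
                 alpha = alpha, n_comparisons_for_correction = m),
            class = "mr_candidate")
}

#' Noninferiority lower bound of paired differences
#'
#' Lower limit of the one-sided `level` (default 90%) confidence interval of
#' the mean per-image difference in the multireader index when a candidate
#' joins the group. The default construction is a seeded percentile
#' bootstrap over images (distribution-free); a t-based interval is offered
#' as an alternative. Both are deterministic given the seed.
#'
#' @param diffs Paired per-image differences (with-candidate minus
#'   without); `NA`s are dropped.
#' @param level One-sided confidence level.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param method `"bootstrap"` (percentile) or `"t"`.
#' @return The lower bound, a single number.
#' @export
noninferiority_lower_bound <- function(diffs, level = 0.90,
                                       n_boot = 10000L, seed = 1L,
                                       method = c("bootstrap", "t")) {
  method <- match.arg(method)
  d <- diffs[!is.na(diffs)]
  if (length(d) < 2L) {
    stop("need >= 2 defined paired differences", call. = FALSE)
  }
  n <- length(d)
  if (method == "t") {
    return(mean(d) - stats::qt(level, n - 1L) * stats::sd(d) / sqrt(n))
  }
  withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    means <- colMeans(matrix(d[idx], nrow = n))
    stats::quantile(means, probs = 1 - level, names = FALSE)
  })
}

#' Candidate performance across ground-truth stringency levels
#'
#' Curates one ground-truth set per stringency level `k = 1..n_readers`
#' (objects called by at least `k` of the group's readers) and evaluates the
#' candidate against each with the pairwise Jaccard/Sørensen indices (the
#' curated set is a single reference, so the two-reader indices apply). A
#' Kruskal–Wallis test across the stringency levels asks whether apparent
#' candidate performance depends on how strictly ground truth is defined.
#'
#' @param calls Calls table of the reader group (>= 2 readers).
#' @param candidate Calls table of the candidate reader.
#' @param metric Overlap metric.
#' @param threshold Agreement threshold.
#' @return An object of class `"mr_stringency"` with `values` (per image and
#'   `min_calls`: confusion counts and indices) and `kruskal_p`.
#' @export
stringency_curve <- function(calls, candidate, metric = "mask_iou",
                             threshold = 0.5) {
  n_readers <- length(reader_ids(calls))
  if (n_readers < 2L) stop("need >= 2 group readers", call. = FALSE)
  cand_reader <- reader_ids(candidate)
  if (length(cand_reader) != 1L) {
    stop("candidate must be a single reader", call. = FALSE)
  }
  values <- purrr::map(image_ids(calls), function(img) {
    mm <- build_match_matrix(calls, img, metric, threshold)
    cand <- calls_of(candidate, cand_reader, img)
    purrr::map(seq_len(n_readers), function(k) {
      gt <- curate_from_match_matrix(mm, calls, k)
      s <- agreement_matrix_impl(gt$mask, cand$mask, gt$bbox, cand$bbox,
                                 metric)
      mp <- suppress_nonmaximum(s, threshold)
      cc <- pairwise_confusion(mp, nrow(gt), nrow(cand))
      dplyr::bind_cols(
        tibble::tibble(image_id = img, min_calls = k,
                       n_gt = nrow(gt), n_candidate = nrow(cand)),
        cc, pairwise_indices(cc)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  grps <- split(values$jaccard[!is.na(values$jaccard)],
                values$min_calls[!is.na(values$jaccard)])
  kp <- tryCatch(kruskal_wallis(grps), error = function(e) NA_real_)
  structure(list(values = values, kruskal_p = kp, metric = metric,
                 threshold = threshold),
            class = "mr_stringency")
}

#' Mann–Whitney U-test with Bonferroni correction
#'
#' Delegates to [stats::wilcox.test()] (normal approximation with continuity
#' correction) and multiplies the p-value by the number of comparisons,
#' capping at 1.
#'
#' @param sample_a,sample_b Non-empty numeric samples (`NA`s dropped).
#' @param m_comparisons Number of comparisons corrected for (>= 1).
#' @param alternative Passed to `wilcox.test()`; `"greater"` tests that
#'   `sample_a` is stochastically larger.
#' @return The adjusted p-value.
#' @export
mwu_bonferroni <- function(sample_a, sample_b, m_comparisons = 1L,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("samples must be non-empty", call. = FALSE)
  }
  if (m_comparisons < 1L) stop("m_comparisons must be >= 1", call. = FALSE)
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = FALSE)
  )$p.value
  min(1, p * m_comparisons)
}

#' Kruskal–Wallis test across groups
#'
#' Delegates to [stats::kruskal.test()]; the nonparametric analogue of a
#' one-way ANOVA, used for the stringency-curve analysis.
#'
#' @param groups A list of >= 2 non-empty numeric vectors.
#' @return The p-value.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(lengths(groups) == 0L)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (length(unique(unlist(groups))) < 2L) {
    stop("degenerate groups: all values identical", call. = FALSE)
  }
  stats::kruskal.test(groups)$p.value
}
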