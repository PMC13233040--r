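# broom-style tidiers for the fitted/comparison objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a match matrix into the objects-by-readers table
#'
#' @param x A [build_match_matrix()] result.
#' @param ... Unused.
#' @return A tibble with one row per consensus object: `object`, `k` (how
#'   many readers called it), and one column per reader holding the matched
#'   call index (`NA` where a reader missed the object).
#' @method tidy match_matrix
#' @export
tidy.match_matrix <- function(x, ...) {
  k <- object_k(x)
  wide <- tidyr::pivot_wider(x$entries, names_from = "reader_id",
                             values_from = "call_index")
  missing_readers <- setdiff(x$readers, names(wide))
  for (r in missing_readers) wide[[r]] <- NA_integer_
  wide$k <- as.integer(k[as.character(wide$object)])
  wide[c("object", "k", x$readers)]
}

#' @rdname tidy.match_matrix
#' @method glance match_matrix
#' @export
glance.match_matrix <- function(x, ...) {
  cnt <- count_calls_and_objects(x)
  tibble::tibble(
    image_id = x$image_id, n_readers = cnt$n_readers,
    total_calls = sum(cnt$calls_per_reader),
    total_objects = sum(cnt$objects_by_k),
    multireader_jaccard = multireader_jaccard(cnt),
    multireader_sorensen = multireader_sorensen(cnt),
    metric = x$metric, threshold = x$threshold
  )
}

#' Tidiers for leave-one-out results
#'
#' @param x An `"mr_loo"` object from [leave_one_out()].
#' @param ... Unused.
#' @return `tidy()`: the per-excluded-reader comparison table. `glance()`:
#'   a one-row summary with the full-group mean and the number of
#'   significant exclusions.
#' @method tidy mr_loo
#' @export
tidy.mr_loo <- function(x, ...) x$comparisons

#' @rdname tidy.mr_loo
#' @method glance mr_loo
#' @export
glance.mr_loo <- function(x, ...) {
  tibble::tibble(
    mean_full = x$comparisons$mean_full[1],
    n_readers = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant),
    flagged_reader = if (sum(x$comparisons$significant) == 1L) {
      x$comparisons$excluded_reader[x$comparisons$significant]
    } else NA_character_,
    metric = x$metric, threshold = x$threshold, alpha = x$alpha
  )
}

#' Tidiers for candidate-reader comparisons
#'
#' @param x An `"mr_candidate"` object from [compare_with_candidate()].
#' @param ... Unused.
#' @return `tidy()`: the per-threshold comparison table (means, adjusted
#'   p-values, noninferiority bounds). `glance()`: a one-row summary.
#' @method tidy mr_candidate
#' @export
tidy.mr_candidate <- function(x, ...) x$comparisons

#' @rdname tidy.mr_candidate
#' @method glance mr_candidate
#' @export
glance.mr_candidate <- function(x, ...) {
  tibble::tibble(
    candidate = x$candidate,
    n_thresholds = nrow(x$comparisons),
    min_noninferiority_bound = min(x$comparisons$noninferiority_lower_bound),
    any_significant_drop = any(x$comparisons$p_group_higher < x$alpha,
                               na.rm = TRUE),
    metric = x$metric, level = x$level
  )
}

#' Tidiers for stringency curves
#'
#' @param x An `"mr_stringency"` object from [stringency_curve()].
#' @param ... Unused.
#' @return `tidy()`: per-stringency summary (mean candidate Jaccard and
#'   Sørensen across images). `glance()`: one row with the Kruskal–Wallis
#'   p-value and the stringency with the highest mean Jaccard.
#' @method tidy mr_stringency
#' @export
tidy.mr_stringency <- function(x, ...) {
  x$values |>
    dplyr::group_by(.data$min_calls) |>
    dplyr::summarise(
      mean_jaccard = mean(.data$jaccard, na.rm = TRUE),
      mean_sorensen = mean(.data$sorensen, na.rm = TRUE),
      n_images = sum(!is.na(.data$jaccard)),
      .groups = "drop"
    )
}

#' @rdname tidy.mr_stringency
#' @method glance mr_stringency
#' @export
glance.mr_stringency <- function(x, ...) {
  s <- tidy.mr_stringency(x)
  tibble::tibble(
    kruskal_p = x$kruskal_p,
    best_min_calls = s$min_calls[which.max(s$mean_jaccard)],
    metric = x$metric, threshold = x$threshold
  )
}

#' @export
print.mr_loo <- function(x, ...) {
  cat("Leave-one-reader-out analysis (", x$metric, " >= ", x$threshold,
      ", Bonferroni m = ", x$n_comparisons_for_correction, ")\n", sep = "")
  print(x$comparisons)
  invisible(x)
}

#' @export
print.mr_candidate <- function(x, ...) {
  cat("Candidate-reader comparison ('", x$candidate, "' joining the group, ",
      x$metric, ")\n", sep = "")
  print(x$comparisons)
  invisible(x)
}

#' @export
print.mr_stringency <- function(x, ...) {
  cat("Stringency curve (", x$metric, " >= ", x$threshold,
      "), Kruskal-Wallis p = ", format.pval(x$kruskal_p), "\n", sep = "")
  print(tidy.mr_stringency(x))
  invisible(x)
}
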