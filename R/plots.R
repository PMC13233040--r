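# ggplot2 displays for the result objects.

#' Plot an agreement summary across thresholds
#'
#' Point-and-errorbar display of the [agreement_summary()] table: index
#' means with confidence intervals against the IOU threshold, split by
#' pairwise-mean vs multireader statistic.
#'
#' @param summary A tibble from [agreement_summary()].
#' @return A ggplot object.
#' @export
plot_agreement_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = factor(.data$threshold), y = .data$mean,
    colour = .data$statistic, group = .data$statistic
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2, position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = "IOU threshold", y = "index",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname leave_one_out
#' @param object An `"mr_loo"` object.
#' @param ... Unused.
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) {
  dat <- object$per_image
  dat$group <- factor(dat$group, levels = unique(dat$group))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "multireader Jaccard index",
                  title = "Group agreement without each reader") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname compare_with_candidate
#' @param object An `"mr_candidate"` object.
#' @param ... Unused.
#' @method autoplot mr_candidate
#' @export
autoplot.mr_candidate <- function(object, ...) {
  ggplot2::ggplot(object$per_image, ggplot2::aes(
    x = factor(.data$threshold), y = .data$value, fill = .data$group
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "IOU threshold", y = "multireader Jaccard index",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname stringency_curve
#' @param object An `"mr_stringency"` object.
#' @param ... Unused.
#' @method autoplot mr_stringency
#' @export
autoplot.mr_stringency <- function(object, ...) {
  ggplot2::ggplot(object$values, ggplot2::aes(
    x = factor(.data$min_calls), y = .data$jaccard
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(
      x = "minimum readers per ground-truth object (stringency)",
      y = "candidate Jaccard index vs curated set"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
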