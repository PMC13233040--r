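# A=B (2 shared calls); C has 2 calls disjoint from everyone.
loo_fixture <- function() {
  X <- rect_mask(0, 3, 0, 3)
  Y <- rect_mask(0, 3, 10, 13)
  calls_from_masks(list(
    A = list(X, Y), B = list(X, Y),
    C = list(rect_mask(20, 23, 0, 3), rect_mask(20, 23, 10, 13))
  ))
}

test_that("leave-one-out reproduces the hand-derived group values", {
  res <- leave_one_out(loo_fixture(), threshold = 0.5)
  per <- res$per_image
  expect_equal(per$value[per$group == "full"], 0.25)        # (6-4)/(2*4)
  expect_equal(per$value[per$group == "without_C"], 1.0)    # (4-2)/(1*2)
  expect_equal(per$value[per$group == "without_A"], 0.0)    # B vs C disjoint
  td <- tidy(res)
  expect_equal(td$excluded_reader[which.max(td$mean_subset)], "C")
})

test_that("identical readers tie at 1 with no significant exclusion", {
  sq1 <- rect_mask(0, 3, 0, 3); sq2 <- rect_mask(10, 13, 10, 13)
  calls <- calls_from_masks(list(A = list(sq1, sq2), B = list(sq1, sq2),
                                 C = list(sq1, sq2)))
  res <- leave_one_out(calls, threshold = 0.5)
  expect_true(all(res$per_image$value == 1))
  expect_false(any(tidy(res)$significant))
  expect_error(leave_one_out(calls[calls$reader_id != "C", ]),
               ">= 3 readers")
})

test_that("an injected outlier reader is the unique flagged exclusion", {
  base <- reader_profile()
  outlier <- reader_profile(miss_rate = 3 * base$miss_rate,
                            fp_rate = 3 * base$fp_rate,
                            jitter_px = base$jitter_px,
                            fragment_rate = base$fragment_rate)
  coh <- generate_cohort(n_images = 25, n_readers = 5,
                         profiles = c(rep(list(base), 4), list(outlier)),
                         seed = 61, dims = c(256L, 256L), n_objects = 12L,
                         size_range = c(4, 9))
  res <- suppressMessages(leave_one_out(coh$calls, threshold = 0.5))
  td <- tidy(res)
  expect_true(td$significant[td$excluded_reader == "R5"])
  expect_equal(sum(td$significant), 1L)
  expect_equal(glance(res)$flagged_reader, "R5")
})

test_that("exchangeable cohorts rarely flag anyone (type-I control)", {
  n_flagged <- 0L
  for (rep_seed in 1:6) {
    coh <- generate_cohort(n_images = 15, n_readers = 4,
                           seed = 100 + rep_seed, dims = c(192L, 192L),
                           n_objects = 8L, size_range = c(4, 8))
    res <- suppressMessages(leave_one_out(coh$calls, threshold = 0.5))
    if (any(tidy(res)$significant)) n_flagged <- n_flagged + 1L
  }
  expect_lte(n_flagged, 1L)
})

test_that("duplicating an existing reader never lowers group agreement", {
  coh <- small_cohort(n_images = 3, n_readers = 3, seed = 55)
  dup <- coh$calls[coh$calls$reader_id == "R1", ]
  dup$reader_id <- "algo"
  res <- suppressMessages(
    compare_with_candidate(coh$calls, dup, thresholds = 0.5,
                           n_boot = 500, seed = 3)
  )
  wide <- tidyr::pivot_wider(res$per_image, names_from = "group",
                             values_from = "value")
  expect_true(all(wide$with_candidate >= wide$group, na.rm = TRUE))
  expect_gte(tidy(res)$noninferiority_lower_bound, 0)
})

test_that("an empty extra reader strictly lowers agreement where it exists", {
  coh <- small_cohort(n_images = 2, n_readers = 3, seed = 57)
  for (img in unique(coh$calls$image_id)) {
    with_ghost <- count_calls_and_objects(suppressMessages(
      build_match_matrix(coh$calls, img, threshold = 0.5,
                         readers = c("R1", "R2", "R3", "ghost"))
    ))
    without <- count_calls_and_objects(suppressMessages(
      build_match_matrix(coh$calls, img, threshold = 0.5)
    ))
    expect_lt(multireader_jaccard(with_ghost),
              multireader_jaccard(without))
  }
})

test_that("a same-profile candidate is not flagged as inferior", {
  coh <- generate_cohort(n_images = 20, n_readers = 6, seed = 71,
                         dims = c(256L, 256L), n_objects = 10L,
                         size_range = c(4, 9))
  humans <- coh$calls[coh$calls$reader_id != "R6", ]
  cand <- coh$calls[coh$calls$reader_id == "R6", ]
  res <- suppressMessages(
    compare_with_candidate(humans, cand, thresholds = c(0.25, 0.5),
                           n_boot = 2000, seed = 5)
  )
  td <- tidy(res)
  expect_true(all(td$p_group_higher > 0.05))
  expect_false(glance(res)$any_significant_drop)
  # the bound is near zero: candidate behaves like one more group member
  expect_gt(min(td$noninferiority_lower_bound), -0.1)
})

test_that("candidate image coverage and id collisions are rejected", {
  coh <- small_cohort(n_images = 1, n_readers = 3, seed = 2)
  cand <- coh$calls[coh$calls$reader_id == "R1", ]
  expect_error(compare_with_candidate(coh$calls, cand), "collides")
  cand$reader_id <- "algo"
  cand$image_id <- "elsewhere"
  expect_error(compare_with_candidate(coh$calls, cand), "absent")
})

test_that("noninferiority bound handles degenerate and shifted inputs", {
  expect_equal(noninferiority_lower_bound(rep(0, 20), n_boot = 200), 0)
  expect_equal(noninferiority_lower_bound(rep(0.07, 20), n_boot = 200),
               0.07)
  withr::with_seed(19, d <- rnorm(40, 0, 0.05))
  b0 <- noninferiority_lower_bound(d, n_boot = 2000, seed = 11)
  b_shift <- noninferiority_lower_bound(d + 0.3, n_boot = 2000, seed = 11)
  expect_equal(b_shift, b0 + 0.3)
  expect_error(noninferiority_lower_bound(c(NA, NA, 0.1)), ">= 2")

  # t-based variant agrees with its closed form
  bt <- noninferiority_lower_bound(d, method = "t")
  expect_equal(bt, mean(d) - qt(0.9, 39) * sd(d) / sqrt(40))
})

test_that("stringency curves recover perfect agreement with the strict set", {
  X <- rect_mask(0, 3, 0, 3)      # called by all three readers
  Y <- rect_mask(0, 3, 10, 13)    # called by A and B
  Z <- rect_mask(10, 13, 0, 3)    # called by C only
  calls <- calls_from_masks(list(A = list(X, Y), B = list(X, Y),
                                 C = list(X, Z)))
  cand <- calls_from_masks(list(algo = list(X)))
  res <- stringency_curve(calls, cand, threshold = 0.5)
  td <- tidy(res)
  expect_equal(td$mean_jaccard[td$min_calls == 3], 1)      # gt = {X}
  expect_equal(td$mean_jaccard[td$min_calls == 1], 1 / 3)  # gt = {X,Y,Z}
  expect_equal(td$mean_jaccard[td$min_calls == 2], 1 / 2)  # gt = {X,Y}
  expect_equal(glance(res)$best_min_calls, 3L)
})

test_that("a median-reader candidate peaks at an intermediate stringency", {
  coh <- generate_cohort(n_images = 12, n_readers = 6, seed = 83,
                         dims = c(256L, 256L), n_objects = 10L,
                         size_range = c(4, 9))
  humans <- coh$calls[coh$calls$reader_id != "R6", ]
  cand <- coh$calls[coh$calls$reader_id == "R6", ]
  cand$reader_id <- "algo"
  res <- suppressMessages(stringency_curve(humans, cand, threshold = 0.5))
  td <- tidy(res)
  expect_equal(nrow(td), 5L)
  # performance varies with stringency, and the extremes do not both win
  expect_lt(res$kruskal_p, 0.05)
  expect_false(glance(res)$best_min_calls %in% c(1L, 5L) &&
                 diff(range(td$mean_jaccard)) < 0.01)
})

test_that("Mann-Whitney wrapper corrects and caps p-values", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4)
  expect_equal(mwu_bonferroni(a, b, m_comparisons = 5), 1)
  raw <- mwu_bonferroni(a, b + 10, m_comparisons = 1,
                        alternative = "two.sided")
  expect_equal(mwu_bonferroni(a, b + 10, m_comparisons = 3,
                              alternative = "two.sided"),
               min(1, raw * 3))
  sep_a <- seq(0.1, 0.3, length.out = 20)
  sep_b <- seq(0.7, 0.9, length.out = 20)
  expect_lt(mwu_bonferroni(sep_a, sep_b, m_comparisons = 3,
                           alternative = "two.sided"), 0.001)
  expect_error(mwu_bonferroni(numeric(0), b), "non-empty")
})

test_that("Kruskal-Wallis wrapper delegates and guards degenerate input", {
  g_same <- list(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(kruskal_wallis(g_same), 0.9)
  withr::with_seed(3, {
    g <- c(replicate(4, rnorm(15), simplify = FALSE),
           list(rnorm(15, mean = 3)))
  })
  expect_lt(kruskal_wallis(g), 0.001)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})
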