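# The reference synthetic study: 5 readers, 50 images of 512x512 px with
# ~20 nuclei each, default (moderate) error profile. Built once per test run
# and shared across the tests that use it.
.cohort_cache <- new.env(parent = emptyenv())

reference_cohort <- function() {
  if (is.null(.cohort_cache$coh)) {
    .cohort_cache$coh <- generate_cohort(n_images = 50, n_readers = 5,
                                         seed = 101)
  }
  .cohort_cache$coh
}

reference_multireader_index <- function() {
  if (is.null(.cohort_cache$mi)) {
    .cohort_cache$mi <- suppressMessages(
      multireader_index(reference_cohort()$calls,
                        thresholds = c(0.25, 0.5, 0.75))
    )
  }
  .cohort_cache$mi
}
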