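# Shared fixtures, built in code.  Corpora are cached per test run.

.fixtures <- new.env(parent = emptyenv())

# moderate corpus (~15k articles) for calibration checks at n >= 10000
big_bundle <- function() {
  if (is.null(.fixtures$big)) {
    truth <- ground_truth(seed = 42,
                          year_effects = seq(0.2, 1.2, length.out = 6))
    .fixtures$big <- simulate_corpus(8, 2012:2017, truth)
  }
  .fixtures$big
}

# tiny noise-free, error-free world: perfect classifiers, one article per
# trial, no cross-category outcome terms
clean_truth <- function(seed = 7, ...) {
  ground_truth(noise_sd = 0,
               task_precision = c(rct = 1, category = 1),
               task_recall = c(rct = 1, category = 1),
               articles_per_trial = 1, registry_coverage = 1,
               outcome_prob = 0, size_missing = 0, size_error_prob = 0,
               year_effects = seq(0.5, 1.5, length.out = 6),
               seed = seed, ...)
}

small_bundle <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_corpus(4, 2000:2005, clean_truth(),
                                       n_rct = 50, n_category = 50,
                                       n_size = 50)
  }
  .fixtures$small
}

# independent quantile oracle: explicit type-7 formula on sorted data
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
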