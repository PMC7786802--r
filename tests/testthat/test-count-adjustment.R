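test_that("adjust_count follows the precision/recall arithmetic", {
  expect_equal(adjust_count(1000, 1, 1), 1000)
  expect_equal(adjust_count(1000, 0.9, 0.75), 1200)
  expect_equal(adjust_count(500, 0.8, 1), 400)
  expect_error(adjust_count(100, 0.9, 0), "recall")
  expect_error(adjust_count(-1, 0.9, 0.9), "non-negative")

  # monotone increasing in precision, decreasing in recall, linear in raw
  set.seed(5)
  for (i in 1:20) {
    p <- runif(1, 0.2, 0.99); r <- runif(1, 0.2, 0.99); raw <- sample(1e5, 1)
    expect_gt(adjust_count(raw, min(p + 0.01, 1), r), adjust_count(raw, p, r))
    expect_lt(adjust_count(raw, p, min(r + 0.01, 1)), adjust_count(raw, p, r))
    expect_equal(adjust_count(3 * raw, p, r), 3 * adjust_count(raw, p, r))
  }
})

test_that("bootstrap_pr reproduces the sample operating point", {
  # all-positive, all-correct rows: every resample is TP-only
  perfect <- data.frame(predicted = rep(TRUE, 4), gold = rep(TRUE, 4))
  d <- bootstrap_pr(perfect, B = 50, seed = 1)
  expect_true(all(d$precision == 1) && all(d$recall == 1))

  # TP=8, FP=2, FN=2: compare the draw mean against the exact multinomial
  # expectation over all resample compositions of the 12-row sample
  v <- data.frame(predicted = c(rep(TRUE, 10), rep(FALSE, 2)),
                  gold = c(rep(TRUE, 8), FALSE, FALSE, TRUE, TRUE))
  probs <- c(tp = 8, fp = 2, fn = 2) / 12
  e_prec <- e_rec <- 0
  for (a in 0:12) for (b in 0:(12 - a)) {
    cc <- 12 - a - b
    w <- dmultinom(c(a, b, cc), prob = probs)
    adj <- if (a == 0) 0.5 else 0
    e_prec <- e_prec + w * (a + adj) / (a + b + 2 * adj)
    e_rec <- e_rec + w * (a + adj) / (a + cc + 2 * adj)
  }
  d2 <- bootstrap_pr(v, B = 10000, seed = 2)
  expect_lt(abs(mean(d2$precision) - e_prec), 4 * sd(d2$precision) / 100)
  expect_lt(abs(mean(d2$recall) - e_rec), 4 * sd(d2$recall) / 100)
  expect_equal(d2$precision_hat, 0.8)
  expect_equal(d2$recall_hat, 0.8)

  # B = 1 with a fixed seed is reproducible
  expect_identical(bootstrap_pr(v, B = 1, seed = 9),
                   bootstrap_pr(v, B = 1, seed = 9))

  expect_error(bootstrap_pr(data.frame(predicted = FALSE, gold = TRUE)),
               "predicted-positive")
  expect_error(bootstrap_pr(data.frame(predicted = TRUE, gold = FALSE)),
               "gold-positive")
})

test_that("small-sample percentile bounds match an independent per-draw reference", {
  v <- data.frame(predicted = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
                  gold = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  B <- 20
  d <- bootstrap_pr(v, B = B, seed = 77)
  pi <- prediction_interval(100, d)

  # reference: literal per-draw loop with explicit confusion tabulation
  set.seed(77)
  ref <- matrix(NA_real_, B, 2)
  for (b in 1:B) {
    idx <- sample.int(6, 6, replace = TRUE)
    pred <- v$predicted[idx]; gold <- v$gold[idx]
    tp <- sum(pred & gold); fp <- sum(pred & !gold); fn <- sum(!pred & gold)
    adj <- if (tp == 0) 0.5 else 0
    ref[b, ] <- c((tp + adj) / (tp + fp + 2 * adj),
                  (tp + adj) / (tp + fn + 2 * adj))
  }
  expect_equal(d$precision, ref[, 1])
  expect_equal(d$recall, ref[, 2])
  adj_ref <- 100 * ref[, 1] / ref[, 2]
  expect_equal(pi$lo95, quantile_oracle(adj_ref, 0.025))
  expect_equal(pi$hi95, quantile_oracle(adj_ref, 0.975))
})

test_that("prediction intervals behave under degeneracy, scaling and outliers", {
  ident <- pr_draws(rep(1, 100), rep(1, 100))
  pi <- prediction_interval(1234, ident)
  expect_equal(c(pi$lo95, pi$point, pi$hi95), c(1234, 1234, 1234))

  set.seed(11)
  d <- pr_draws(runif(500, 0.7, 1), runif(500, 0.7, 1))
  a1 <- prediction_interval(100, d)
  a5 <- prediction_interval(500, d)
  expect_equal(c(a5$point, a5$lo95, a5$hi95),
               5 * c(a1$point, a1$lo95, a1$hi95))

  # one wild pair among B = 10000 leaves the 2.5/97.5 percentiles in place
  set.seed(12)
  p <- runif(10000, 0.85, 0.95); r <- runif(10000, 0.85, 0.95)
  base <- prediction_interval(1000, pr_draws(p, r))
  p[1] <- 1; r[1] <- 0.01
  spiked <- prediction_interval(1000, pr_draws(p, r))
  expect_lt(abs(spiked$lo95 - base$lo95) / base$lo95, 0.001)
  expect_lt(abs(spiked$hi95 - base$hi95) / base$hi95, 0.001)

  # median point rule is always inside the interval
  pm <- prediction_interval(1000, pr_draws(p, r), point = "median")
  expect_true(pm$lo95 <= pm$point && pm$point <= pm$hi95)
})

test_that("chained task adjustments compose multiplicatively", {
  set.seed(21)
  d <- pr_draws(runif(200, 0.8, 1), runif(200, 0.8, 1))
  one <- chain_adjustment(1000, list(d))
  ref <- prediction_interval(1000, d)
  expect_equal(c(one$point, one$lo95, one$hi95),
               c(ref$point, ref$lo95, ref$hi95))

  ident <- pr_draws(rep(1, 200), rep(1, 200))
  two <- chain_adjustment(1000, list(ident, ident))
  expect_equal(c(two$point, two$lo95, two$hi95), c(1000, 1000, 1000))

  # two independent tasks at matched precision = recall stay centred on raw
  d1 <- pr_draws(rnorm(5000, 0.9, 0.01), rnorm(5000, 0.9, 0.01))
  d2 <- pr_draws(rnorm(5000, 0.9, 0.01), rnorm(5000, 0.9, 0.01))
  both <- chain_adjustment(1000, list(d1, d2))
  expect_lt(abs(both$point - 1000) / 1000, 0.02)
  expect_true(both$lo95 < 1000 && 1000 < both$hi95)

  expect_error(chain_adjustment(10, list(pr_draws(0.9, 0.9),
                                         pr_draws(c(0.9, 0.9), c(0.9, 0.9)))),
               "same number of bootstrap draws")
  expect_error(chain_adjustment(10, list()), "at least one task")
})

test_that("size error model is the multiset of signed extraction errors", {
  exact <- data.frame(predicted = c(10, 20), gold = c(10, 20))
  expect_equal(as.numeric(size_error_model(exact)), c(0, 0))
  mix <- data.frame(predicted = c(70, 100, NA), gold = c(72, 90, 50))
  err <- size_error_model(mix)
  expect_setequal(as.numeric(err), c(-2, 10))
  expect_length(err, 2)  # complete pairs only
  expect_error(size_error_model(data.frame(predicted = NA_real_, gold = 5)),
               "complete")
})

test_that("size-summary simulation collapses without error and clamps at one", {
  sizes <- c(32, 72, 195, NA, 40)
  zero <- simulate_size_summaries(sizes, structure(0, class = "size_errors"),
                                  B = 50, seed = 1)
  expect_equal(unname(zero$interval[, "lo95"]), unname(zero$interval[, "hi95"]))
  expect_equal(unname(zero$interval["median", "lo95"]), 56)
  expect_equal(unname(zero$observed[["n_missing"]]), 1)

  # perturbations that would push a size below one are clamped
  clamped <- simulate_size_summaries(c(1, 2), c(-100), B = 20, seed = 2)
  expect_equal(unname(clamped$interval["total", "lo95"]), 2)
})
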