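test_that("burden panel has the stated shape, SDI split and accounting identities", {
  truth <- ground_truth(seed = 1)
  b <- generate_burden(22, 1990:2017, truth)
  expect_equal(nrow(b), 22 * 28)
  expect_true(all(b$dalys > 0))
  expect_equal(b$yld + b$yll, b$dalys, tolerance = 1e-12)
  expect_equal(b$dalys_high_sdi + b$dalys_lowmid_sdi, b$dalys,
               tolerance = 1e-12)

  # a condition with all burden in high-SDI countries has zero low/mid DALYs
  t1 <- ground_truth(seed = 2, sdi_share = 1)
  b1 <- generate_burden(3, 2000:2004, t1)
  expect_true(all(b1$dalys_lowmid_sdi == 0))

  expect_error(generate_burden(22, integer(0), truth), "empty")
  expect_error(generate_burden(1, 1990:2000, truth), ">= 2")
})

test_that("generation is deterministic given the seed", {
  truth <- ground_truth(seed = 99, year_effects = 0.5)
  b1 <- generate_burden(3, 2010:2012, truth)
  b2 <- generate_burden(3, 2010:2012, truth)
  expect_identical(b1, b2)
  s1 <- simulate_corpus(3, 2010:2012, truth, n_rct = 20, n_category = 20,
                        n_size = 20)
  s2 <- simulate_corpus(3, 2010:2012, truth, n_rct = 20, n_category = 20,
                        n_size = 20)
  expect_identical(s1$articles, s2$articles)
  expect_identical(s1$validation, s2$validation)
  expect_identical(s1$burden, s2$burden)
})

test_that("noise-free, error-free corpora satisfy the publication law exactly", {
  bundle <- small_bundle()
  truth <- bundle$truth
  # observed gold counts per condition-year equal round(exp(eta)) with the
  # log equality holding exactly (DALY snapping)
  eta <- trialgap:::linear_predictor(bundle$burden, truth)
  expected <- round(exp(eta))
  counts <- merge(bundle$burden[c("condition", "year")],
                  bundle$truth_counts, all.x = TRUE)
  counts$n_articles[is.na(counts$n_articles)] <- 0
  counts <- counts[order(counts$condition, counts$year), ]
  expect_equal(counts$n_articles, expected, tolerance = 1e-12)
  expect_equal(log(counts$n_articles), eta, tolerance = 1e-10)
  # perfect classifiers: predictions equal gold
  expect_true(all(bundle$articles$pred_rct == bundle$articles$gold_rct))
  expect_true(all(bundle$articles$pop_terms == bundle$articles$gold_pop_term))
})

test_that("sample sizes, duplication and author geography match calibration targets", {
  a <- big_bundle()$articles
  expect_gte(nrow(a), 10000)

  # lognormal law: median matches 72 exactly in expectation; IQR near the
  # implied symmetric-log quartiles (spec'd approximation of 32-195)
  expect_lt(abs(median(a$gold_size, na.rm = TRUE) - 72), 3)
  q <- quantile(a$gold_size, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  expect_lt(abs(q[1] - 72 * exp(-0.6745 * trialgap:::size_sdlog(big_bundle()$truth))), 3)

  # 34% of RCT articles carry no extracted size
  frac_missing <- mean(is.na(a$size[a$gold_rct]))
  expect_lt(abs(frac_missing - 0.34), 3 * sqrt(0.34 * 0.66 / sum(a$gold_rct)))

  # mean articles per registered trial ~ 1.3
  reg <- a[!is.na(a$trial_id), ]
  expect_lt(abs(nrow(reg) / length(unique(reg$trial_id)) - 1.3), 0.03)

  # 82% of articles first-authored in top-quintile countries
  sh <- sdi_share(a, big_bundle()$countries)
  expect_lt(abs(sh$share[5] - 0.82), 3 * sqrt(0.82 * 0.18 / nrow(a)))
})

test_that("label corruption converges to the configured operating points", {
  bundle <- big_bundle()
  a <- bundle$articles
  p <- bundle$truth$task_precision[["rct"]]
  r <- bundle$truth$task_recall[["rct"]]
  prec <- sum(a$pred_rct & a$gold_rct) / sum(a$pred_rct)
  rec <- sum(a$pred_rct & a$gold_rct) / sum(a$gold_rct)
  expect_lt(abs(prec - p), 3 * sqrt(p * (1 - p) / sum(a$pred_rct)))
  expect_lt(abs(rec - r), 3 * sqrt(r * (1 - r) / sum(a$gold_rct)))

  # category task, term level: kept gold terms / injected spurious terms
  n_gold <- sum(a$gold_pop_term != "") + sum(!is.na(a$gold_out_term))
  pred_terms <- c(unlist(strsplit(a$pop_terms, "|", fixed = TRUE)),
                  unlist(strsplit(a$out_terms, "|", fixed = TRUE)))
  pred_terms <- pred_terms[pred_terms != ""]
  kept <- sum(a$pop_terms != "" &
                mapply(grepl, a$gold_pop_term, a$pop_terms, fixed = TRUE))
  pc <- bundle$truth$task_precision[["category"]]
  rc <- bundle$truth$task_recall[["category"]]
  expect_lt(abs(kept / nrow(a) - rc), 0.02)
  # overall precision of predicted term instances
  gold_out <- ifelse(is.na(a$gold_out_term), "", a$gold_out_term)
  correct <- kept + sum(gold_out != "" &
                          mapply(grepl, gold_out, a$out_terms, fixed = TRUE))
  expect_lt(abs(correct / length(pred_terms) - pc), 0.02)
})

test_that("validation sampling is uniform without replacement", {
  bundle <- big_bundle()
  n <- nrow(bundle$articles)
  v <- generate_validation(bundle$articles, n_rct = 500, n_category = 250,
                           n_size = 500, seed = 3)
  expect_equal(nrow(v$rct), 500)
  expect_equal(length(unique(v$rct$article_id)), 500)
  expect_equal(nrow(v$size), 500)

  # requesting the whole corpus returns it; more is an error
  v_all <- generate_validation(bundle$articles, n_rct = n, n_category = 1,
                               n_size = 1, seed = 1)
  expect_setequal(v_all$rct$article_id, bundle$articles$article_id)
  expect_error(generate_validation(bundle$articles, n_rct = n + 1),
               "exceeds corpus size")

  # overlap of two independent draws matches the hypergeometric law
  v2 <- generate_validation(bundle$articles, n_rct = 500, n_category = 1,
                            n_size = 1, seed = 4)
  ov <- length(intersect(v$rct$article_id, v2$rct$article_id))
  m <- 500 * 500 / n
  s <- sqrt(500 * (500 / n) * (1 - 500 / n) * (n - 500) / (n - 1))
  expect_lt(abs(ov - m), 4 * s)
})
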