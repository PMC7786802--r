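test_that("panels join counts to burden and reject incomplete inputs", {
  truth <- ground_truth(seed = 8)
  b <- generate_burden(22, 1990:2017, truth)
  counts <- data.frame(category = b$condition[1], year = 1990, n_total = 5)
  p <- build_panel(counts, b)
  expect_equal(nrow(p), 22 * 28)
  expect_equal(sum(p$rct_count), 5)  # unmatched cells are zero counts

  bad <- data.frame(category = "Atlantis fever", year = 1990, n_total = 1)
  expect_error(build_panel(bad, b), "Atlantis fever")
  bad2 <- data.frame(category = b$condition[1], year = 1800, n_total = 1)
  expect_error(build_panel(bad2, b), "1800")

  # key-join oracle on a noise-free bundle: panel equals generator truth
  bundle <- small_bundle()
  cnt <- bundle$truth_counts
  names(cnt)[1] <- "category"
  pp <- build_panel(cnt, bundle$burden)
  m <- merge(pp, cnt, by = c("category", "year"), all.x = TRUE)
  m$n_articles[is.na(m$n_articles)] <- 0
  expect_equal(m$rct_count, m$n_articles)
})

test_that("noise-free panels return the generating coefficients exactly", {
  # primary model
  p <- simulate_panel(22, 1990:2017, ground_truth(noise_sd = 0, seed = 11))
  f <- burden_fit(p)
  expect_lt(abs(coef(f)[["log_dalys"]] - 0.52), 1e-8)
  expect_gt(f$adj_r2, 1 - 1e-8)

  # counts proportional to DALYs: unit elasticity by construction
  ident <- data.frame(category = rep(c("a", "b", "c"), each = 4),
                      year = rep(2000:2003, 3),
                      rct_count = NA, dalys = exp(runif(12, 3, 8)))
  ident$rct_count <- ident$dalys
  expect_lt(abs(coef(burden_fit(ident))[["log_dalys"]] - 1), 1e-8)

  # location model
  tl <- ground_truth(noise_sd = 0, true_elasticity = 0.75,
                     location_effect = 0.44, seed = 12)
  fl <- burden_fit(simulate_panel(22, 1990:2017, tl), "location")
  expect_lt(abs(coef(fl)[["log_dalys"]] - 0.75), 1e-8)
  expect_lt(abs(coef(fl)[["log_ratio"]] - 0.44), 1e-8)

  # distributed lags with cumulative elasticity
  tg <- ground_truth(noise_sd = 0, lag_weights = c(0.3, 0.2, 0.1), seed = 13)
  fg <- burden_fit(simulate_panel(12, 1995:2017, tg), "lag", lags = 2)
  expect_lt(max(abs(coef(fg)[c("log_dalys", "log_dalys_lag1",
                               "log_dalys_lag2")] - c(0.3, 0.2, 0.1))), 1e-8)
  expect_lt(abs(fg$cumulative[["estimate"]] - 0.6), 1e-8)

  # random year effects recover the elasticity on noise-free data too
  # (lmer emits roundoff warnings on an exact fit)
  fr <- suppressWarnings(suppressMessages(burden_fit(p, effects = "random")))
  expect_lt(abs(coef(fr)[["log_dalys"]] - 0.52), 1e-6)
})

test_that("degenerate designs are rejected with clear errors", {
  p <- simulate_panel(4, 2000:2006, ground_truth(seed = 14))
  expect_error(burden_fit(p[p$category == p$category[1], ]), ">= 2 categories")
  pc <- p; pc$dalys <- 100
  expect_error(burden_fit(pc), "constant")
  pr <- p; pr$daly_ratio <- 2.5
  expect_error(burden_fit(pr, "location"), "collinear|constant")
  pn <- p; pn$daly_ratio <- NA
  expect_error(burden_fit(pn, "location"), "positive, finite")
  expect_error(burden_fit(p, lags = 2), "model = 'lag'")
  expect_error(burden_fit(p, "lag", lags = 20), "insufficient years")
})

test_that("a zero-lag fit on the common sample is the primary fit", {
  p <- simulate_panel(8, 1998:2017, ground_truth(seed = 15))
  f0 <- burden_fit(p, "primary", common_lags = 3)
  fl <- burden_fit(p, "lag", lags = 0, common_lags = 3)
  expect_equal(coef(f0), coef(fl))
  expect_equal(f0$aic, fl$aic)
})

test_that("model comparison requires a common sample and finds the true lag order", {
  p <- simulate_panel(8, 1998:2017, ground_truth(seed = 16))
  f_all <- burden_fit(p)
  f_cut <- burden_fit(p, common_lags = 3)
  expect_error(compare_models(f_all, f_cut), "different samples")

  tg <- ground_truth(noise_sd = 0.05, lag_weights = c(0.25, 0.2, 0.15),
                     daly_jitter = 0.15, seed = 17)
  pg <- simulate_panel(12, 1994:2017, tg)
  fits <- lapply(0:3, function(L)
    burden_fit(pg, if (L > 0) "lag" else "primary", lags = L,
               common_lags = 3))
  names(fits) <- paste0("L", 0:3)
  cmp <- compare_models(fits)
  best <- attr(cmp, "best")
  # generating structure has lags 0..2
  expect_equal(best$aic, "L2")
  expect_equal(best$bic, "L2")
  expect_equal(best$adj_r2, "L2")
})

test_that("the Hausman test is null on identical fits and detects violations", {
  p <- simulate_panel(10, 2000:2017, ground_truth(seed = 18, noise_sd = 0.5))
  fe <- burden_fit(p)
  h0 <- hausman_test(fe, fe)
  expect_equal(unname(h0$statistic), 0)
  expect_equal(h0$p.value, 1)

  # clean world: year effects are independent of the regressor, both
  # estimators consistent -> no rejection at this seed
  re <- burden_fit(p, effects = "random")
  h <- hausman_test(fe, re)
  expect_gt(h$p.value, 0.01)

  # year effects strongly correlated with log DALYs: RE is inconsistent
  set.seed(19)
  cats <- letters[1:10]
  grid <- expand.grid(category = cats, year = 2000:2017,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$dalys <- exp(3 + 0.12 * (grid$year - 2000) + rnorm(nrow(grid), 0, 0.1))
  eta <- 0.5 * log(grid$dalys) + 0.4 * (grid$year - 2000) +
    rnorm(nrow(grid), 0, 0.1)
  grid$rct_count <- exp(eta)
  hv <- hausman_test(burden_fit(grid), burden_fit(grid, effects = "random"))
  expect_lt(hv$p.value, 0.05)

  f_loc <- burden_fit(simulate_panel(10, 2000:2017,
                                     ground_truth(seed = 18, noise_sd = 0.5,
                                                  location_effect = 0.2)),
                      "location")
  expect_error(hausman_test(f_loc, re), "different burden covariates")
})

test_that("fitted-model accessors, prediction and simulation are coherent", {
  p <- simulate_panel(6, 2005:2017, ground_truth(seed = 20))
  f <- burden_fit(p)
  expect_equal(length(fitted(f)), f$n)
  expect_equal(fitted(f) + residuals(f), f$data$y)
  expect_equal(predict(f, type = "response"), exp(fitted(f)))
  expect_equal(predict(f, newdata = p), unname(fitted(f)), tolerance = 1e-10)
  ci <- confint(f)
  expect_true(all(ci[, 1] <= coef(f) & coef(f) <= ci[, 2]))
  sm <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sm), c(f$n, 5))
  expect_true(all(sm$sim_1 > 0))
  s <- summary(f)
  expect_s3_class(s, "summary.burden_fit")
  expect_output(print(s), "Burden coefficients")
})

test_that("elasticity conversion has its unit and monotonicity laws", {
  expect_equal(elasticity(0, 10), 0)
  expect_equal(elasticity(1, 10), 10)
  expect_equal(elasticity(0.5, 0), 0)
  expect_error(elasticity(0.5, -100), "greater than -100")
  set.seed(22)
  betas <- sort(runif(20, -1, 2))
  expect_true(all(diff(elasticity(betas, 10)) > 0))
})

test_that("expected-vs-observed differences vanish on noise-free data and bins sum to totals", {
  p <- simulate_panel(6, 1990:2017, ground_truth(noise_sd = 0, seed = 23))
  f <- burden_fit(p)
  evo <- expected_vs_observed(f)
  expect_lt(max(abs(evo$difference)), 1e-6)
  expect_setequal(setdiff(unique(evo$period), "total"),
                  sprintf("%d-%d", seq(1990, 2014, 4), seq(1993, 2017, 4)))

  # stochastic case: bins sum to total per category
  p2 <- simulate_panel(6, 1990:2017, ground_truth(seed = 24))
  evo2 <- expected_vs_observed(burden_fit(p2))
  for (cat in unique(evo2$category)) {
    rows <- evo2[evo2$category == cat, ]
    expect_equal(sum(rows$difference[rows$period != "total"]),
                 rows$difference[rows$period == "total"])
  }

  # a category whose counts are double the law shows a positive excess
  p3 <- p
  dbl <- p3$category == p3$category[1]
  p3$rct_count[dbl] <- p3$rct_count[dbl] * 2
  evo3 <- expected_vs_observed(burden_fit(p3))
  tot <- evo3[evo3$period == "total", ]
  expect_gt(tot$difference[tot$category == p3$category[1]],
            max(tot$difference[tot$category != p3$category[1]]))
})

test_that("duplicate-publication discounting shifts only the intercept under uniform duplication", {
  p <- simulate_panel(5, 2000:2012, ground_truth(noise_sd = 0, seed = 25))
  # registry table with exactly 1.3 articles per trial in every category:
  # 10 trials, three publishing twice
  arts <- do.call(rbind, lapply(unique(p$category), function(cat) {
    tid <- sprintf("%s-%02d", cat, c(1:10, 8:10))
    data.frame(article_id = paste0(cat, seq_along(tid)), condition = cat,
               trial_id = tid, stringsAsFactors = FALSE)
  }))
  base <- burden_fit(p)
  disc <- discounted_reanalysis(p, arts)
  expect_equal(disc$duplication$articles_per_trial, rep(1.3, 5))
  expect_lt(abs(coef(disc$fit)[["log_dalys"]] - coef(base)[["log_dalys"]]),
            1e-8)
  expect_lt(abs(coef(disc$fit)[["(Intercept)"]] -
                  (coef(base)[["(Intercept)"]] - log(1.3))), 1e-8)

  # unique trials leave the fit untouched
  uniq <- arts[!duplicated(arts$trial_id), ]
  disc2 <- discounted_reanalysis(p, uniq)
  expect_equal(coef(disc2$fit), coef(base))

  noreg <- arts; noreg$trial_id <- NA_character_
  expect_error(discounted_reanalysis(p, noreg), "registry")
})

test_that("confidence intervals attain close to nominal coverage across replicates", {
  hits <- 0; reps <- 80
  for (r in seq_len(reps)) {
    t <- ground_truth(seed = 3000 + r)
    f <- burden_fit(simulate_panel(12, 2000:2017, t))
    ci <- confint(f)["log_dalys", ]
    hits <- hits + (ci[1] <= 0.52 && 0.52 <= ci[2])
  }
  expect_gte(hits / reps, 0.87)
})
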