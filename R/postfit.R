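#' Hausman specification test: fixed versus random year effects
#'
#' Computes \eqn{H = (b_{FE} - b_{RE})^\top (V_{FE} - V_{RE})^{+}
#' (b_{FE} - b_{RE})} over the burden coefficients common to both fits,
#' using the Moore--Penrose pseudo-inverse of the variance difference; the
#' degrees of freedom equal its rank.  A significant statistic indicates the
#' random-effects assumption (year intercepts uncorrelated with the
#' regressors) fails, favouring fixed effects.
#'
#' @param fit_fixed,fit_random [burden_fit()] results with `effects =
#'   "fixed"` and `"random"` on the same panel and specification.
#' @return An object of class `"htest"`.
#' @export
hausman_test <- function(fit_fixed, fit_random) {
  stopifnot(inherits(fit_fixed, "burden_fit"), inherits(fit_random, "burden_fit"))
  common <- intersect(fit_fixed$focal, fit_random$focal)
  if (!length(common))
    stop("fits share no burden coefficients; cannot align")
  if (!setequal(fit_fixed$focal, fit_random$focal))
    stop("fits have different burden covariates; cannot align")
  b1 <- fit_fixed$coefficients[common]
  b2 <- fit_random$coefficients[common]
  d <- b1 - b2
  V <- fit_fixed$vcov[common, common, drop = FALSE] -
    fit_random$vcov[common, common, drop = FALSE]
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-10
  keep <- abs(eg$values) > tol
  dof <- sum(keep)
  if (dof == 0) {
    H <- 0
    dof <- length(common)
    p <- 1
  } else {
    Vinv <- eg$vectors[, keep, drop = FALSE] %*%
      diag(1 / eg$values[keep], dof) %*% t(eg$vectors[, keep, drop = FALSE])
    H <- max(0, as.numeric(t(d) %*% Vinv %*% d))
    p <- pchisq(H, df = dof, lower.tail = FALSE)
  }
  structure(list(statistic = c(H = H), parameter = c(df = dof),
                 p.value = p,
                 method = "Hausman test of fixed vs random year effects",
                 data.name = paste(deparse(substitute(fit_fixed)), "vs",
                                   deparse(substitute(fit_random))),
                 alternative = "random-effects estimator is inconsistent"),
            class = "htest")
}

#' Rank candidate models by adjusted R-squared, AIC and BIC
#'
#' All fits must be estimated on the identical sample (same condition-year
#' rows), otherwise information criteria are not comparable and an error is
#' raised.  The per-criterion best model is reported; criteria may disagree
#' and no single winner is forced.
#'
#' @param ... [burden_fit()] objects (or a single list of them), optionally
#'   named.
#' @return Object of class `"burden_fit_comparison"`: a data.frame of
#'   criteria with attributes `best` (named list per criterion).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "burden_fit")) fits <- fits[[1]]
  for (f in fits) stopifnot(inherits(f, "burden_fit"))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f)
      sprintf("%s(L=%d,%s)", f$model, f$lags, f$effects), character(1))
  keys <- lapply(fits, function(f) paste(f$data$category, f$data$year))
  base <- sort(keys[[1]])
  for (k in keys)
    if (!identical(sort(k), base))
      stop("fits are estimated on different samples; refit with a common ",
           "`common_lags` before comparing")
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) length(f$coefficients), numeric(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  best <- list(adj_r2 = tab$model[which.max(tab$adj_r2)],
               aic = tab$model[which.min(tab$aic)],
               bic = tab$model[which.min(tab$bic)])
  structure(tab, best = best, class = c("burden_fit_comparison", "data.frame"))
}

#' @export
print.burden_fit_comparison <- function(x, ...) {
  cat("Model comparison (common estimation sample):\n")
  print.data.frame(x, digits = 4)
  b <- attr(x, "best")
  cat(sprintf("best by adjusted R^2: %s; by AIC: %s; by BIC: %s\n",
              b$adj_r2, b$aic, b$bic))
  if (length(unique(unlist(b))) > 1)
    cat("note: criteria disagree; no single winner is forced\n")
  invisible(x)
}

#' Convert a log-log coefficient to an implied percentage change
#'
#' In a log-log model with coefficient `beta`, a `pct` percent change in the
#' predictor implies a `100 * ((1 + pct/100)^beta - 1)` percent change in
#' the outcome.  For example, a 10\% DALY increase under the published
#' primary coefficient 0.52 implies `elasticity(0.52, 10)` = 5.08, reported
#' as a 5\% increase in annual RCT publications.
#'
#' @param beta Log-log regression coefficient(s).
#' @param pct Percent change in the predictor (> -100). Default 10.
#' @return Implied percent change in the outcome (vectorised over `beta`).
#' @export
#' @examples
#' elasticity(0.52, 10)
#' elasticity(c(0.33, 0.70), 10)  # CI bounds
elasticity <- function(beta, pct = 10) {
  if (any(pct <= -100)) stop("pct must be greater than -100")
  100 * ((1 + pct / 100)^beta - 1)
}

#' Expected versus observed publication counts
#'
#' Compares observed RCT counts per category with those predicted by a
#' fitted model, aggregated into consecutive year bins (4-year bins by
#' default, giving 1990--1993 ... 2014--2017 on the usual panel) plus a
#' grand total.  Predicted counts are the naive exponentiation of the fitted
#' log count; Duan's smearing correction is available via `smearing = TRUE`.
#' Differences are signed observed minus predicted: negative means fewer
#' articles than the burden model predicts.
#'
#' @param fit A [burden_fit()] result.
#' @param bin_width Width of the year bins. Default 4.
#' @param smearing Apply the smearing back-transform correction.
#' @return Data.frame `category`, `period` (e.g. `"1990-1993"` or
#'   `"total"`), `observed`, `predicted`, `difference`; bins sum to the
#'   total exactly (before any rounding by the caller).
#' @export
expected_vs_observed <- function(fit, bin_width = 4, smearing = FALSE) {
  stopifnot(inherits(fit, "burden_fit"))
  d <- fit$data
  pred <- predict(fit, type = "response", smearing = smearing)
  y0 <- min(d$year)
  bin_lo <- y0 + bin_width * ((d$year - y0) %/% bin_width)
  period <- sprintf("%d-%d", bin_lo, bin_lo + bin_width - 1)
  agg <- aggregate(cbind(observed = d$rct_count, predicted = pred),
                   by = list(category = d$category, period = period), FUN = sum)
  tot <- aggregate(cbind(observed = d$rct_count, predicted = pred),
                   by = list(category = d$category), FUN = sum)
  tot$period <- "total"
  out <- rbind(agg, tot[names(agg)])
  out$difference <- out$observed - out$predicted
  out <- out[order(out$category, out$period != "total", out$period), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sensitivity reanalysis discounting duplicate publications
#'
#' One trial can yield several articles ("salami slicing"), inflating
#' publication counts.  Using the subset of articles that carry a registry
#' identifier, the mean number of articles per unique trial is estimated for
#' each category; panel counts are divided by that category's factor (falling
#' back to the global mean for categories without any registered trials) and
#' the primary regression is refitted.
#'
#' @param panel Panel data.frame (see [burden_fit()]).
#' @param articles Article table with `condition` and `trial_id` columns
#'   (`NA` trial_id = no registry identifier).
#' @param ... Passed to [burden_fit()].
#' @return List with `fit` (the discounted [burden_fit()]), `duplication`
#'   (data.frame `category`, `n_articles`, `n_trials`, `articles_per_trial`)
#'   and `global_articles_per_trial`.
#' @export
discounted_reanalysis <- function(panel, articles, ...) {
  reg <- articles[!is.na(articles$trial_id), , drop = FALSE]
  if (nrow(reg) == 0)
    stop("no registry identifiers present in the article table")
  dup <- aggregate(list(n_articles = reg$article_id),
                   by = list(category = reg$condition), FUN = length)
  ntr <- aggregate(list(n_trials = reg$trial_id),
                   by = list(category = reg$condition),
                   FUN = function(x) length(unique(x)))
  dup <- merge(dup, ntr, by = "category")
  dup$articles_per_trial <- dup$n_articles / dup$n_trials
  global <- nrow(reg) / length(unique(reg$trial_id))
  f <- dup$articles_per_trial[match(panel$category, dup$category)]
  f[is.na(f)] <- global
  panel2 <- panel
  panel2$rct_count <- panel$rct_count / f
  list(fit = burden_fit(panel2, ...),
       duplication = dup,
       global_articles_per_trial = global)
}
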