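#' Fit a burden--publication regression model
#'
#' The central model of the package: ordinary least squares of log annual
#' RCT article counts on log disability-adjusted life years (DALYs) across a
#' condition-year panel, with calendar-year effects.  Three specifications
#' are available:
#'
#' \describe{
#'   \item{`"primary"`}{\eqn{\log N_{it} = \beta \log D_{it} + \alpha_t +
#'     \epsilon_{it}} — same-year DALY elasticity.}
#'   \item{`"lag"`}{finite distributed lag: \eqn{\log N_{it} = \sum_{j=0}^{L}
#'     \beta_j \log D_{i,t-j} + \alpha_t + \epsilon_{it}}; the cumulative
#'     elasticity \eqn{\sum_j \beta_j} is reported with a delta-method CI.}
#'   \item{`"location"`}{adds the burden-location covariate \eqn{\beta_{loc}
#'     \log R_{it}}, where \eqn{R_{it}} is the ratio of DALYs in high-SDI to
#'     low/middle-SDI countries.}
#' }
#'
#' Year effects \eqn{\alpha_t} enter either as categorical fixed effects
#' (`effects = "fixed"`, the default) or as year-level random intercepts
#' (`effects = "random"`, via [lme4::lmer()] with `REML = FALSE` so that
#' AIC/BIC are comparable across specifications); [hausman_test()] compares
#' the two.  Zero counts are handled by the continuity rule `log(0.5)` (the
#' affected rows are flagged in the returned data).  Confidence intervals
#' are normal-theory Wald intervals.
#'
#' For lag-order comparison, `common_lags` restricts estimation to years
#' with at least that many lags available, so that models with different `L`
#' are fitted on an identical sample and their AIC/BIC are comparable.
#'
#' @param panel Panel data.frame from [build_panel()] or [simulate_panel()]
#'   (columns `category`, `year`, `rct_count`, `dalys`, and `daly_ratio` for
#'   the location model).
#' @param model `"primary"`, `"lag"` or `"location"`.
#' @param lags Maximum lag \eqn{L} for `model = "lag"` (0 reduces to the
#'   primary specification).
#' @param effects `"fixed"` or `"random"` calendar-year effects.
#' @param common_lags Years dropped from the start of the panel to define
#'   the estimation sample (default `lags`); set to the largest lag under
#'   comparison when ranking models.
#' @param zero_offset Count substituted inside the log for zero-article
#'   rows. Default 0.5.
#' @return An object of class `"burden_fit"` with components `coefficients`
#'   (full named vector), `se`, `focal` (names of the burden terms),
#'   `cumulative` (lag models: estimate, se, lo95, hi95), `adj_r2`, `aic`,
#'   `bic`, `n`, `data` (estimation sample with `.fitted`, `.resid`,
#'   `.zero`), `fit` (the underlying `lm`/`merMod`), and metadata.  Methods:
#'   `print`, `summary`, `coef`, `confint`, `predict`, `fitted`,
#'   `residuals`, `simulate`, `plot`.
#' @seealso [hausman_test()], [compare_models()], [elasticity()],
#'   [expected_vs_observed()], [discounted_reanalysis()]
#' @export
#' @examples
#' truth <- ground_truth(noise_sd = 0, seed = 11)
#' panel <- simulate_panel(6, 2000:2010, truth)
#' fit <- burden_fit(panel)
#' fit
#' coef(fit)[["log_dalys"]]
burden_fit <- function(panel, model = c("primary", "lag", "location"),
                       lags = 0L, effects = c("fixed", "random"),
                       common_lags = lags, zero_offset = 0.5) {
  model <- match.arg(model)
  effects <- match.arg(effects)
  lags <- as.integer(lags)
  if (model != "lag" && lags > 0)
    stop("lags > 0 requires model = 'lag'")
  req <- c("category", "year", "rct_count", "dalys")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop("panel lacks columns: ", paste(miss, collapse = ", "))
  if (length(unique(panel$category)) < 2) stop("need >= 2 categories")
  if (length(unique(panel$year)) < 2) stop("need >= 2 years")
  if (any(panel$dalys <= 0)) stop("dalys must be positive")
  if (any(panel$rct_count < 0)) stop("counts must be non-negative")

  d <- panel[order(panel$category, panel$year), , drop = FALSE]
  d$.zero <- d$rct_count == 0
  d$y <- ifelse(d$.zero, log(zero_offset), log(d$rct_count))
  d$log_dalys <- log(d$dalys)

  lag_names <- character(0)
  if (lags > 0) {
    yrs <- sort(unique(d$year))
    if (length(yrs) < lags + 2) stop("insufficient years for lag ", lags)
    for (j in seq_len(lags)) {
      nm <- paste0("log_dalys_lag", j)
      lag_names <- c(lag_names, nm)
      d[[nm]] <- ave(d$log_dalys, d$category,
                     FUN = function(v) c(rep(NA_real_, j),
                                         v[seq_len(length(v) - j)]))
    }
  }
  if (model == "location") {
    if (!"daly_ratio" %in% names(d) || any(!is.finite(d$daly_ratio)) ||
        any(d$daly_ratio <= 0))
      stop("location model requires a positive, finite daly_ratio for all rows")
    d$log_ratio <- log(d$daly_ratio)
  }

  cut_year <- min(d$year) + max(common_lags, lags)
  samp <- d[d$year >= cut_year, , drop = FALSE]
  samp <- samp[complete.cases(samp[c("y", "log_dalys", lag_names)]), ,
               drop = FALSE]
  if (length(unique(samp$year)) < 2)
    stop("estimation sample spans fewer than 2 years")
  if (sd(samp$log_dalys) < 1e-12) stop("log DALYs are constant: degenerate design")
  if (model == "location" && sd(samp$log_ratio) < 1e-12)
    stop("daly_ratio is constant across the panel: collinear with the intercept")

  focal <- c("log_dalys", lag_names, if (model == "location") "log_ratio")
  samp$yearf <- factor(samp$year)
  rhs <- paste(focal, collapse = " + ")

  if (effects == "fixed") {
    fml <- stats::as.formula(paste("y ~", rhs, "+ yearf"))
    fit <- lm(fml, data = samp)
    beta <- coef(fit)
    V <- suppressWarnings(vcov(fit))  # vcov.lm warns via summary.lm on exact fits
    adj_r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    fitted_v <- fitted(fit)
  } else {
    fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | yearf)"))
    fit <- lme4::lmer(fml, data = samp, REML = FALSE)
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    fitted_v <- fitted(fit)
    # adjusted R^2 from conditional fitted values; k = fixed coefficients
    r2 <- 1 - sum((samp$y - fitted_v)^2) / sum((samp$y - mean(samp$y))^2)
    k <- length(beta)
    adj_r2 <- 1 - (1 - r2) * (nrow(samp) - 1) / (nrow(samp) - k - 1)
  }
  se <- sqrt(diag(V))
  samp$.fitted <- as.numeric(fitted_v)
  samp$.resid <- samp$y - fitted_v

  cumulative <- NULL
  if (model == "lag") {
    terms_l <- c("log_dalys", lag_names)
    est <- sum(beta[terms_l])
    vsum <- sum(V[terms_l, terms_l])
    cumulative <- c(estimate = est, se = sqrt(vsum),
                    lo95 = est - qnorm(0.975) * sqrt(vsum),
                    hi95 = est + qnorm(0.975) * sqrt(vsum))
  }

  structure(list(
    call = match.call(), model = model, lags = lags, effects = effects,
    coefficients = beta, se = se, vcov = V, focal = focal,
    cumulative = cumulative,
    adj_r2 = adj_r2, aic = AIC(fit), bic = BIC(fit),
    n = nrow(samp), zero_offset = zero_offset,
    data = samp[c("category", "year", "rct_count", "dalys",
                  intersect("daly_ratio", names(samp)),
                  "y", ".fitted", ".resid", ".zero")],
    fit = fit
  ), class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  spec <- switch(x$model,
                 primary = "log(RCTs) ~ log(DALYs) + year",
                 lag = sprintf("log(RCTs) ~ log(DALYs) lags 0..%d + year", x$lags),
                 location = "log(RCTs) ~ log(DALYs) + log(DALY location ratio) + year")
  cat("Burden-publication regression (", x$effects, " year effects)\n",
      "  ", spec, "\n", sep = "")
  ci <- confint(x)
  for (nm in x$focal)
    cat(sprintf("  %-16s %6.3f  (95%% CI %6.3f to %6.3f)\n",
                nm, x$coefficients[[nm]], ci[nm, 1], ci[nm, 2]))
  if (!is.null(x$cumulative))
    cat(sprintf("  %-16s %6.3f  (95%% CI %6.3f to %6.3f)\n", "cumulative",
                x$cumulative[["estimate"]], x$cumulative[["lo95"]],
                x$cumulative[["hi95"]]))
  cat(sprintf("  n = %d, adj R^2 = %.3f, AIC = %.1f, BIC = %.1f\n",
              x$n, x$adj_r2, x$aic, x$bic))
  invisible(x)
}

#' @export
coef.burden_fit <- function(object, ...) object$coefficients

#' @export
vcov.burden_fit <- function(object, ...) object$vcov

#' @export
confint.burden_fit <- function(object, parm = NULL, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  ci <- cbind(est - z * object$se, est + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.burden_fit <- function(object, ...) object$data$.fitted

#' @export
residuals.burden_fit <- function(object, ...) object$data$.resid

#' @export
#' @rdname burden_fit
#' @param object,x A `burden_fit` object.
#' @param newdata Optional panel data.frame; defaults to the estimation
#'   sample.
#' @param type `"link"` for predicted log counts, `"response"` for predicted
#'   counts.
#' @param smearing For `type = "response"`, apply Duan's nonparametric
#'   smearing factor (mean of exponentiated residuals) to correct the naive
#'   back-transform.
#' @param ... Unused.
predict.burden_fit <- function(object, newdata = NULL,
                               type = c("link", "response"),
                               smearing = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$data$.fitted
  } else {
    nd <- newdata[order(newdata$category, newdata$year), , drop = FALSE]
    nd$log_dalys <- log(nd$dalys)
    if (object$lags > 0)
      for (j in seq_len(object$lags)) {
        nm <- paste0("log_dalys_lag", j)
        nd[[nm]] <- ave(nd$log_dalys, nd$category,
                        FUN = function(v) c(rep(NA_real_, j),
                                            v[seq_len(length(v) - j)]))
      }
    if (object$model == "location") nd$log_ratio <- log(nd$daly_ratio)
    nd$yearf <- factor(nd$year)
    eta <- if (object$effects == "fixed")
      as.numeric(predict(object$fit, newdata = nd))
    else as.numeric(predict(object$fit, newdata = nd,
                            allow.new.levels = TRUE))
  }
  if (type == "link") return(eta)
  f <- if (smearing) mean(exp(object$data$.resid)) else 1
  f * exp(eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
simulate.burden_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(sum(object$data$.resid^2) / (object$n - length(object$coefficients)))
  out <- replicate(nsim, exp(object$data$.fitted +
                               rnorm(object$n, 0, sigma)))
  colnames(out) <- paste0("sim_", seq_len(nsim))
  cbind(object$data[c("category", "year")], as.data.frame(out))
}

#' @export
plot.burden_fit <- function(x, ...) {
  graphics::plot(x$data$.fitted, x$data$y,
                 xlab = "fitted log RCT count", ylab = "observed log RCT count",
                 main = sprintf("burden_fit (%s, %s effects)", x$model, x$effects),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
summary.burden_fit <- function(object, ...) {
  ci <- confint(object)
  tab <- data.frame(estimate = object$coefficients[object$focal],
                    se = object$se[object$focal],
                    lo95 = ci[object$focal, 1], hi95 = ci[object$focal, 2])
  structure(list(fit = object, table = tab), class = "summary.burden_fit")
}

#' @export
print.summary.burden_fit <- function(x, ...) {
  print(x$fit)
  cat("\nBurden coefficients:\n")
  print(round(x$table, 4))
  if (any(x$fit$data$.zero))
    cat(sprintf("\n%d zero-count rows entered as log(%.2g)\n",
                sum(x$fit$data$.zero), x$fit$zero_offset))
  invisible(x)
}
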