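#' Bootstrap the precision and recall of a labelling task
#'
#' Resamples the rows of a manually labelled validation sample with
#' replacement `B` times and computes, for each resample, precision
#' \eqn{TP/(TP+FP)} and recall \eqn{TP/(TP+FN)} of the predicted labels
#' against gold.  If a resample contains no true positive, 0.5 is added to
#' every confusion cell for that draw only (a Jeffreys-style continuity
#' correction), so draws always lie in (0, 1].
#'
#' Rows are drawn literally with `sample.int`, one block of `n` indices per
#' bootstrap iteration, so results are reproducible draw-by-draw from the
#' seed.
#'
#' @param sample Data.frame with logical columns `predicted` and `gold`
#'   (e.g. `validation$rct` or `validation$category` from
#'   [generate_validation()]).
#' @param B Number of bootstrap draws (published analyses use 10 000).
#' @param seed RNG seed.
#' @return Object of class `"pr_draws"`: list with numeric vectors
#'   `precision` and `recall` of length `B`, the full-sample (plug-in)
#'   operating point `precision_hat`/`recall_hat`, `B`, and `seed`.
#' @export
#' @examples
#' v <- data.frame(predicted = c(rep(TRUE, 10), rep(FALSE, 2)),
#'                 gold = c(rep(TRUE, 8), FALSE, FALSE, TRUE, TRUE))
#' d <- bootstrap_pr(v, B = 1000, seed = 1)
#' d
bootstrap_pr <- function(sample, B = 10000, seed = 1L) {
  stopifnot(is.data.frame(sample),
            all(c("predicted", "gold") %in% names(sample)))
  pred <- as.logical(sample$predicted)
  gold <- as.logical(sample$gold)
  if (anyNA(pred) || anyNA(gold)) stop("labels must be non-missing logicals")
  n <- length(pred)
  if (!any(pred)) stop("validation sample has no predicted-positive rows")
  if (!any(gold)) stop("validation sample has no gold-positive rows")

  tp <- pred & gold
  fp <- pred & !gold
  fn <- !pred & gold

  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
  TP <- colSums(matrix(tp[idx], nrow = n))
  FP <- colSums(matrix(fp[idx], nrow = n))
  FN <- colSums(matrix(fn[idx], nrow = n))
  corr <- TP == 0
  a <- ifelse(corr, 0.5, 0)
  prec <- (TP + a) / (TP + FP + 2 * a)
  rec <- (TP + a) / (TP + FN + 2 * a)

  structure(list(precision = prec, recall = rec,
                 precision_hat = sum(tp) / sum(pred),
                 recall_hat = sum(tp) / sum(gold),
                 B = B, seed = seed),
            class = "pr_draws")
}

#' Construct precision/recall draws directly
#'
#' Low-level constructor, mainly for composing adjustments from external
#' draws or for testing percentile machinery against known quantile oracles.
#'
#' @param precision,recall Numeric vectors of equal length with values in
#'   (0, 1].
#' @param precision_hat,recall_hat Plug-in operating point (defaults: the
#'   draw medians).
#' @return A `"pr_draws"` object.
#' @export
pr_draws <- function(precision, recall,
                     precision_hat = median(precision),
                     recall_hat = median(recall)) {
  stopifnot(length(precision) == length(recall))
  if (any(precision <= 0 | precision > 1) || any(recall <= 0 | recall > 1))
    stop("precision and recall draws must lie in (0, 1]")
  structure(list(precision = precision, recall = recall,
                 precision_hat = precision_hat, recall_hat = recall_hat,
                 B = length(precision), seed = NA_integer_),
            class = "pr_draws")
}

#' @export
print.pr_draws <- function(x, ...) {
  cat(sprintf("Precision/recall bootstrap draws (B = %d)\n", x$B))
  cat(sprintf("  plug-in precision %.4f, recall %.4f\n",
              x$precision_hat, x$recall_hat))
  cat(sprintf("  draw means: precision %.4f, recall %.4f\n",
              mean(x$precision), mean(x$recall)))
  invisible(x)
}

#' Misclassification-adjusted count
#'
#' Adjusts a predicted-positive count for classifier error: the estimated
#' number of true positives is `raw * precision / recall` (predictions kept
#' at their positive predictive value, inflated for missed positives).
#'
#' @param raw Non-negative predicted-positive count (vectorised).
#' @param precision,recall Operating point in (0, 1].
#' @return Adjusted count estimate.
#' @export
#' @examples
#' adjust_count(1000, 0.9, 0.75)  # 1200
adjust_count <- function(raw, precision, recall) {
  if (any(raw < 0)) stop("raw count must be non-negative")
  if (any(precision <= 0 | precision > 1))
    stop("precision must lie in (0, 1]")
  if (any(recall <= 0 | recall > 1))
    stop("recall must lie in (0, 1]; recall = 0 is not adjustable")
  raw * precision / recall
}

new_adjusted_count <- function(raw, point, lo95, hi95, B, point_method) {
  structure(list(raw = raw, point = point, lo95 = lo95, hi95 = hi95,
                 B = B, point_method = point_method),
            class = "adjusted_count")
}

#' @export
print.adjusted_count <- function(x, ...) {
  cat(sprintf("Adjusted count: %.1f (95%% PI %.1f to %.1f; raw %.0f, %s point, B = %d)\n",
              x$point, x$lo95, x$hi95, x$raw, x$point_method, x$B))
  invisible(x)
}

#' 95% prediction interval for a misclassification-adjusted count
#'
#' Applies [adjust_count()] to a raw count under every bootstrap draw of the
#' operating point and reports the 2.5th and 97.5th empirical percentiles
#' (linear interpolation between order statistics).  The point estimate is,
#' by default, the plug-in adjustment at the full-sample precision/recall;
#' `point = "median"` switches to the draw median, in which case
#' `lo95 <= point <= hi95` is guaranteed.
#'
#' @param raw Non-negative predicted-positive count.
#' @param draws A [bootstrap_pr()] / [pr_draws()] object.
#' @param point `"plugin"` (default) or `"median"`.
#' @return An `"adjusted_count"` object with fields `raw`, `point`, `lo95`,
#'   `hi95`.
#' @export
prediction_interval <- function(raw, draws, point = c("plugin", "median")) {
  stopifnot(inherits(draws, "pr_draws"))
  point <- match.arg(point)
  adj <- adjust_count(raw, draws$precision, draws$recall)
  q <- quantile(adj, c(0.025, 0.975), names = FALSE, type = 7)
  pt <- if (point == "plugin")
    adjust_count(raw, draws$precision_hat, draws$recall_hat)
  else median(adj)
  new_adjusted_count(raw, pt, q[1], q[2], draws$B, point)
}

#' Chain misclassification adjustments across labelling tasks
#'
#' Composes several validated tasks (e.g. RCT-in-humans status and category
#' assignment): per bootstrap iteration `b` the raw count is multiplied by
#' \eqn{\prod_k p_{kb} / r_{kb}} over tasks, pairing draws by index, and the
#' percentile interval is taken over the composed draws.
#'
#' @param raw Non-negative predicted-positive count.
#' @param draws_by_task List of `"pr_draws"` objects (>= 1), all with the
#'   same `B`.
#' @inheritParams prediction_interval
#' @return An `"adjusted_count"` object.
#' @export
chain_adjustment <- function(raw, draws_by_task, point = c("plugin", "median")) {
  point <- match.arg(point)
  if (!length(draws_by_task)) stop("at least one task is required")
  for (d in draws_by_task) stopifnot(inherits(d, "pr_draws"))
  Bs <- vapply(draws_by_task, function(d) d$B, numeric(1))
  if (length(unique(Bs)) != 1)
    stop("all tasks must have the same number of bootstrap draws; got ",
         paste(Bs, collapse = ", "))
  factor_b <- rep(1, Bs[1])
  factor_hat <- 1
  for (d in draws_by_task) {
    factor_b <- factor_b * d$precision / d$recall
    factor_hat <- factor_hat * d$precision_hat / d$recall_hat
  }
  adj <- raw * factor_b
  q <- quantile(adj, c(0.025, 0.975), names = FALSE, type = 7)
  pt <- if (point == "plugin") raw * factor_hat else median(adj)
  new_adjusted_count(raw, pt, q[1], q[2], Bs[1], point)
}

#' Empirical extraction-error distribution for sample sizes
#'
#' From validation pairs of (extracted, gold) participant counts, returns the
#' empirical multiset of signed absolute errors `extracted - gold` over
#' complete pairs.
#'
#' @param sample Data.frame with numeric columns `predicted` and `gold`
#'   (either may be `NA`).
#' @return Numeric vector of errors, class `"size_errors"`.
#' @export
#' @examples
#' size_error_model(data.frame(predicted = c(70, 100), gold = c(72, 90)))
size_error_model <- function(sample) {
  stopifnot(is.data.frame(sample),
            all(c("predicted", "gold") %in% names(sample)))
  ok <- complete.cases(sample[c("predicted", "gold")])
  if (!any(ok)) stop("no complete (predicted, gold) size pairs")
  if (any(sample$predicted[ok] <= 0) || any(sample$gold[ok] <= 0))
    stop("sizes must be positive")
  structure(sample$predicted[ok] - sample$gold[ok], class = "size_errors")
}

#' Simulate extraction error in participant-count summaries
#'
#' Per bootstrap iteration, each extracted size is perturbed by an error
#' resampled with replacement from the empirical error distribution (clamped
#' so sizes stay >= 1), and the median, quartiles and total are recomputed;
#' reported are the 2.5th/97.5th percentiles of each summary across
#' iterations.
#'
#' @param sizes Numeric vector of extracted participant counts (`NA` =
#'   unreported; ignored).
#' @param errors A [size_error_model()] result (or numeric vector of
#'   errors).
#' @param B Bootstrap iterations.
#' @param seed RNG seed.
#' @return List with `observed` (named vector: median, q1, q3, total,
#'   n, n_missing) and `interval` (matrix with rows median/q1/q3/total and
#'   columns lo95/hi95).
#' @export
simulate_size_summaries <- function(sizes, errors, B = 10000, seed = 1L) {
  err <- as.numeric(errors)
  s <- sizes[!is.na(sizes)]
  if (!length(s)) stop("no non-missing sizes")
  set.seed(seed_for(seed, "sizes"))
  summarise <- function(x) c(median = median(x),
                             q1 = quantile(x, 0.25, names = FALSE, type = 7),
                             q3 = quantile(x, 0.75, names = FALSE, type = 7),
                             total = sum(x))
  obs <- summarise(s)
  draws <- matrix(NA_real_, nrow = B, ncol = 4)
  m <- length(s)
  for (b in seq_len(B)) {
    pert <- pmax(1, s + err[sample.int(length(err), m, replace = TRUE)])
    draws[b, ] <- summarise(pert)
  }
  interval <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975),
                      names = FALSE, type = 7))
  dimnames(interval) <- list(c("median", "q1", "q3", "total"),
                             c("lo95", "hi95"))
  list(observed = c(obs, n = m, n_missing = sum(is.na(sizes))),
       interval = interval, B = B)
}
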