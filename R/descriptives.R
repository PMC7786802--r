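#' Per-category, per-year trial counts split by treatment/prevention role
#'
#' The total count per category-year is the size of the union of the
#' treatment and prevention article sets (an article relevant through both
#' roles is counted once), alongside the role-specific counts.
#'
#' @param relevance Output of [assign_relevance()].
#' @param articles Article table supplying `article_id` and `year`.
#' @return Data.frame `category`, `year`, `n_total`, `n_treatment`,
#'   `n_prevention`, sorted by category and year.
#' @export
count_by_category_year <- function(relevance, articles) {
  rel <- merge(relevance, articles[c("article_id", "year")], by = "article_id")
  if (nrow(rel) == 0)
    return(data.frame(category = character(0), year = integer(0),
                      n_total = integer(0), n_treatment = integer(0),
                      n_prevention = integer(0)))
  agg <- aggregate(cbind(n_total = rep(1L, nrow(rel)),
                         n_treatment = as.integer(rel$is_treatment),
                         n_prevention = as.integer(rel$is_prevention)),
                   by = list(category = rel$category, year = rel$year),
                   FUN = sum)
  agg <- agg[order(agg$category, agg$year), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Participant-count summaries
#'
#' Median and quartiles (linear-interpolation definition, `quantile`
#' type 7) of extracted participant counts, with unreported sizes counted
#' separately — mirroring headline reporting such as "median 72 (IQR
#' 32–195)".
#'
#' @param articles Article table with a `size` column (`NA` = unreported).
#' @param by Optional name of a grouping column in `articles` (e.g.
#'   `"condition"`); `NULL` for a single overall summary.
#' @return Data.frame with columns `group` (`"all"` when `by` is `NULL`),
#'   `median`, `q1`, `q3`, `n`, `n_missing`. Summary columns are `NA` where
#'   every size is missing.
#' @export
#' @examples
#' participant_summary(data.frame(size = c(32, 72, 195)))
participant_summary <- function(articles, by = NULL) {
  groups <- if (is.null(by)) rep("all", nrow(articles)) else articles[[by]]
  one <- function(s) {
    ok <- !is.na(s)
    if (!any(ok))
      return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
               n = 0, n_missing = sum(!ok)))
    q <- quantile(s[ok], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(median = q[2], q1 = q[1], q3 = q[3], n = sum(ok), n_missing = sum(!ok))
  }
  res <- do.call(rbind, lapply(split(articles$size, groups), one))
  out <- data.frame(group = rownames(res), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Share of articles by first-author SDI quintile
#'
#' Uses the country of the first author as a proxy for who organised or
#' funded each trial.  Shares are normalised over articles whose country is
#' in the lookup table; unmapped countries are reported as a separate `NA`
#' bucket, and `share_all` additionally gives shares over the full
#' denominator.
#'
#' @param articles Article table with a `country` column.
#' @param country_table Data.frame `country`, `sdi_quintile` (1 = least,
#'   5 = most developed), e.g. [generate_countries()].
#' @return Data.frame `sdi_quintile` (1–5 and `NA` for unknown), `n`,
#'   `share` (known-country denominator; `NA` for the unknown bucket),
#'   `share_all`.
#' @export
sdi_share <- function(articles, country_table) {
  if (nrow(articles) == 0)
    return(data.frame(sdi_quintile = integer(0), n = integer(0),
                      share = numeric(0), share_all = numeric(0)))
  q <- country_table$sdi_quintile[match(articles$country,
                                        country_table$country)]
  tab <- table(factor(q, levels = 1:5), useNA = "always")
  n <- as.integer(tab)
  known <- sum(n[1:5])
  data.frame(
    sdi_quintile = c(1:5, NA),
    n = n,
    share = c(if (known > 0) n[1:5] / known else rep(NA_real_, 5), NA),
    share_all = n / nrow(articles)
  )
}
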