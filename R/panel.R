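#' Join publication counts with burden data into a regression panel
#'
#' The burden table defines the panel frame (every condition-year it
#' contains); counts are joined onto it, with condition-years that produced
#' no articles entered as zero counts.  A count for a category or
#' category-year absent from the burden table is an error naming the
#' offending keys.
#'
#' @param counts Data.frame with `category`, `year` and a count column
#'   (`n_total` from [count_by_category_year()] or `rct_count`).
#' @param burden Data.frame from [generate_burden()] (columns `condition`,
#'   `year`, `dalys`, `dalys_high_sdi`, `dalys_lowmid_sdi`) or any table with
#'   `category` instead of `condition`.
#' @return Panel data.frame: `category`, `year`, `rct_count`, `dalys`,
#'   `dalys_high_sdi`, `dalys_lowmid_sdi`, `daly_ratio` (high-SDI over
#'   low/middle-SDI DALYs; `NA` when the denominator is zero).
#' @export
build_panel <- function(counts, burden) {
  b <- burden
  if (!"category" %in% names(b) && "condition" %in% names(b))
    names(b)[names(b) == "condition"] <- "category"
  req <- c("category", "year", "dalys", "dalys_high_sdi", "dalys_lowmid_sdi")
  miss <- setdiff(req, names(b))
  if (length(miss)) stop("burden table lacks columns: ",
                         paste(miss, collapse = ", "))
  cnt_col <- intersect(c("n_total", "rct_count", "n_articles"), names(counts))
  if (!length(cnt_col)) stop("counts table lacks a count column")
  cnt <- counts[c("category", "year", cnt_col[1])]
  names(cnt)[3] <- "rct_count"

  missing_cat <- setdiff(unique(cnt$category), unique(b$category))
  if (length(missing_cat))
    stop("categories missing from burden data: ",
         paste(missing_cat, collapse = ", "))
  key_b <- paste(b$category, b$year)
  key_c <- paste(cnt$category, cnt$year)
  orphan <- setdiff(key_c, key_b)
  if (length(orphan))
    stop("burden rows missing for: ", paste(head(orphan, 5), collapse = "; "))

  panel <- merge(b[req], cnt, by = c("category", "year"), all.x = TRUE)
  panel$rct_count[is.na(panel$rct_count)] <- 0
  panel$daly_ratio <- ifelse(panel$dalys_lowmid_sdi > 0,
                             panel$dalys_high_sdi / panel$dalys_lowmid_sdi,
                             NA_real_)
  panel <- panel[order(panel$category, panel$year),
                 c("category", "year", "rct_count", "dalys",
                   "dalys_high_sdi", "dalys_lowmid_sdi", "daly_ratio")]
  rownames(panel) <- NULL
  panel
}
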