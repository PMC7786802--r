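norm_term <- function(x) tolower(trimws(x))

#' Load and validate a term-to-GBD-category mapping table
#'
#' Reads a CSV with columns `term_id`, `term_label`, `gbd_category` (the
#' field's curated MeSH-to-GBD lookup, e.g. the published mapping of 5256
#' parent terms).  Category names must come from the closed set of 22
#' [gbd_categories()] (synthetic category labels produced by
#' [generate_mapping()] are also accepted when `extra_categories` is given).
#' Term matching downstream is exact on case-folded, trimmed identifiers.
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @param extra_categories Additional category names to accept beyond the 22.
#' @return Validated data.frame of class `"mapping_table"`. Exact duplicate
#'   rows (same term, same category) are dropped silently with a message;
#'   a term mapped to two different categories is an error listing offenders.
#' @export
#' @examples
#' f <- system.file("extdata", "mapping_example.csv", package = "trialgap")
#' m <- load_mapping(f)
#' head(m)
load_mapping <- function(path, extra_categories = character(0)) {
  m <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  req <- c("term_id", "term_label", "gbd_category")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("mapping table lacks required columns: ",
                         paste(miss, collapse = ", "))
  allowed <- c(gbd_categories(), extra_categories)
  bad <- setdiff(unique(m$gbd_category), allowed)
  if (length(bad)) stop("unknown GBD categories in mapping: ",
                        paste(bad, collapse = ", "))
  m$term_id <- norm_term(m$term_id)
  dup <- duplicated(m[c("term_id", "gbd_category")])
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate mapping rows (same term, same category)")
    m <- m[!dup, , drop = FALSE]
  }
  conflict <- unique(m$term_id[duplicated(m$term_id)])
  if (length(conflict))
    stop("terms mapped to conflicting categories: ",
         paste(head(conflict, 10), collapse = ", "))
  rownames(m) <- NULL
  class(m) <- c("mapping_table", "data.frame")
  m
}

#' Assign per-category treatment/prevention relevance to articles
#'
#' A condition term found among an article's population-role terms marks the
#' article as a treatment trial for that term's category; a term among the
#' outcome-role terms marks it as a prevention trial (e.g. a trial recruiting
#' people with diabetes and measuring subsequent coronary events is relevant
#' to both the diabetes category, as treatment, and the cardiovascular
#' category, as prevention).  A category reached through both roles yields a
#' single relevance row with both flags.  Terms absent from the mapping are
#' not errors; they are ignored and counted in the `unmapped_terms`
#' attribute.
#'
#' @param articles Article table with `article_id` and `|`-separated term
#'   columns (see `role_cols`).
#' @param mapping A [load_mapping()] table (or any data.frame with `term_id`
#'   and `gbd_category`).
#' @param role_cols Named character vector mapping the roles `treatment` and
#'   `prevention` to article columns holding the population- and outcome-role
#'   terms. Defaults to the predicted extractions (`pop_terms`,
#'   `out_terms`); point at `gold_pop_term`/`gold_out_term` to run on gold.
#' @return Data.frame `article_id`, `category`, `is_treatment`,
#'   `is_prevention` with attribute `unmapped_terms` (count of ignored term
#'   occurrences).
#' @export
assign_relevance <- function(articles, mapping,
                             role_cols = c(treatment = "pop_terms",
                                           prevention = "out_terms")) {
  stopifnot(all(c("treatment", "prevention") %in% names(role_cols)))
  term_cat <- setNames(mapping$gbd_category, norm_term(mapping$term_id))
  unmapped <- 0L
  one_role <- function(col) {
    x <- articles[[col]]
    x[is.na(x)] <- ""
    terms <- strsplit(x, "|", fixed = TRUE)
    nt <- lengths(terms)
    if (sum(nt) == 0)
      return(data.frame(article_id = character(0), category = character(0)))
    df <- data.frame(article_id = rep(articles$article_id, nt),
                     term = norm_term(unlist(terms)), stringsAsFactors = FALSE)
    df <- df[df$term != "", , drop = FALSE]
    df$category <- term_cat[df$term]
    unmapped <<- unmapped + sum(is.na(df$category))
    df <- df[!is.na(df$category), c("article_id", "category")]
    unique(df)
  }
  trt <- one_role(role_cols[["treatment"]])
  prv <- one_role(role_cols[["prevention"]])
  trt$is_treatment <- rep(TRUE, nrow(trt))
  prv$is_prevention <- rep(TRUE, nrow(prv))
  rel <- merge(trt, prv, by = c("article_id", "category"), all = TRUE)
  rel$is_treatment[is.na(rel$is_treatment)] <- FALSE
  rel$is_prevention[is.na(rel$is_prevention)] <- FALSE
  rel <- rel[order(rel$article_id, rel$category), , drop = FALSE]
  rownames(rel) <- NULL
  attr(rel, "unmapped_terms") <- unmapped
  rel
}
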