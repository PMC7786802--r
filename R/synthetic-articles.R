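#' Generate a synthetic term-to-category mapping table
#'
#' Produces the mapping-table analogue of a curated MeSH-to-GBD lookup: each
#' category receives `terms_per_category` distinct term identifiers.
#'
#' @param categories Character vector of category names (subset of
#'   [gbd_categories()] or synthetic labels).
#' @param terms_per_category Terms per category (default 12).
#' @param seed RNG seed (term identifiers are deterministic anyway).
#' @return Data.frame with columns `term_id`, `term_label`, `gbd_category`.
#' @export
generate_mapping <- function(categories, terms_per_category = 12, seed = 1L) {
  set.seed(seed_for(seed, "mapping"))
  k <- terms_per_category
  data.frame(
    term_id = sprintf("T%04d", seq_len(length(categories) * k)),
    term_label = sprintf("%s term %02d",
                         rep(categories, each = k), rep(seq_len(k), length(categories))),
    gbd_category = rep(categories, each = k),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic country-to-SDI-quintile table
#'
#' @param n_per_quintile Countries per Sociodemographic Index quintile
#'   (quintile 5 = most developed).
#' @param seed RNG seed (unused; table is deterministic).
#' @return Data.frame with columns `country`, `sdi_quintile`.
#' @export
generate_countries <- function(n_per_quintile = 20, seed = 1L) {
  n <- 5 * n_per_quintile
  data.frame(
    country = sprintf("C%03d", seq_len(n)),
    sdi_quintile = rep(1:5, each = n_per_quintile),
    stringsAsFactors = FALSE
  )
}

join_terms <- function(a, b) {
  out <- ifelse(a == "" | is.na(a), ifelse(is.na(b), "", b),
                ifelse(b == "" | is.na(b), a, paste(a, b, sep = "|")))
  ifelse(is.na(out), "", out)
}

#' Generate synthetic article records from a burden panel
#'
#' For each condition-year, draws the number of RCT articles from the
#' publication law encoded in `truth` (see [ground_truth()]), then builds one
#' record per article: a trial (registry) identifier with the configured
#' duplication rate, population- and outcome-role condition terms, a
#' participant count from the calibrated lognormal law, a first-author
#' country weighted towards high-SDI quintiles, and predicted labels corrupted
#' from gold at the configured precision/recall.  False-positive records
#' (articles that are not RCTs but are predicted as such) are injected so the
#' corpus-level precision of the RCT flag converges to its target.
#'
#' @param burden Data.frame from [generate_burden()].
#' @param truth A [ground_truth()] object.
#' @param mapping Optional mapping table (default: [generate_mapping()] over
#'   the burden's conditions).
#' @param countries Optional country table (default: [generate_countries()]).
#' @return Data.frame with one row per article: `article_id`, `trial_id`
#'   (registry identifier, `NA` when unregistered/hidden), `condition` (gold
#'   primary condition), `year`, `country`, `gold_rct`, `pred_rct`,
#'   `gold_pop_term`, `gold_out_term`, `pop_terms`, `out_terms` (predicted,
#'   `|`-separated), `gold_categories`, `pred_categories`, `gold_size`,
#'   `size` (extracted participant count, `NA` when unreported/missed).
#' @export
#' @examples
#' truth <- ground_truth(seed = 2, year_effects = 1)
#' b <- generate_burden(3, 2000:2002, truth)
#' a <- generate_articles(b, truth)
#' table(a$gold_rct, a$pred_rct)
generate_articles <- function(burden, truth, mapping = NULL, countries = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(burden) == 0) stop("burden table is empty")
  conds <- unique(burden$condition)
  if (is.null(mapping))
    mapping <- generate_mapping(conds, truth$terms_per_category, truth$seed)
  if (is.null(countries)) countries <- generate_countries(seed = truth$seed)

  set.seed(seed_for(truth$seed, "articles"))
  cnt <- draw_counts(burden, truth)
  apt <- rep_len(truth$articles_per_trial, length(conds))
  names(apt) <- conds

  # expand condition-year cells into trials and articles
  cells <- cnt[cnt$count > 0, , drop = FALSE]
  art_cond <- character(0); art_year <- integer(0); art_trial <- character(0)
  trial_counter <- 0L
  cond_list <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    n <- cells$count[k]
    a <- apt[[cells$condition[k]]]
    if (a <= 1) {
      sizes_k <- rep(1L, n)
    } else {
      sizes_k <- integer(0)
      while (sum(sizes_k) < n)
        sizes_k <- c(sizes_k, 1L + rpois(max(8L, ceiling(n / a)), a - 1))
      keep <- which(cumsum(sizes_k) >= n)[1]
      sizes_k <- sizes_k[seq_len(keep)]
      sizes_k[keep] <- sizes_k[keep] - (sum(sizes_k) - n)
      sizes_k <- sizes_k[sizes_k > 0]
    }
    ids <- sprintf("TR%07d", trial_counter + seq_along(sizes_k))
    trial_counter <- trial_counter + length(sizes_k)
    cond_list[[k]] <- data.frame(
      condition = cells$condition[k], year = cells$year[k],
      trial_id = rep(ids, times = sizes_k), stringsAsFactors = FALSE
    )
  }
  arts <- do.call(rbind, cond_list)
  if (is.null(arts)) arts <- data.frame(condition = character(0),
                                        year = integer(0),
                                        trial_id = character(0))
  n_art <- nrow(arts)
  arts$gold_rct <- rep(TRUE, n_art)

  # hide registry ids for uncovered trials (decided per trial)
  if (n_art > 0) {
    trials <- unique(arts$trial_id)
    covered <- trials[runif(length(trials)) < truth$registry_coverage]
    arts$trial_id[!(arts$trial_id %in% covered)] <- NA_character_
  }

  # RCT-status prediction: misses at 1 - recall; false positives injected to
  # hit target precision in expectation
  p_rct <- truth$task_precision[["rct"]]
  r_rct <- truth$task_recall[["rct"]]
  arts$pred_rct <- runif(n_art) < r_rct
  n_tp <- sum(arts$pred_rct)
  n_fp <- if (p_rct < 1 && n_tp > 0) rpois(1, n_tp * (1 - p_rct) / p_rct) else 0L
  if (n_fp > 0) {
    src <- sample.int(n_art, n_fp, replace = TRUE)
    fp <- data.frame(condition = arts$condition[src], year = arts$year[src],
                     trial_id = NA_character_, gold_rct = FALSE,
                     pred_rct = TRUE, stringsAsFactors = FALSE)
    arts <- rbind(arts, fp)
  }
  n_art <- nrow(arts)
  arts$article_id <- sprintf("A%07d", seq_len(n_art))

  # condition terms (gold): one population-role term for the article's own
  # condition; with probability outcome_prob an outcome-role term for a
  # uniformly drawn (possibly identical) condition
  terms_by_cat <- split(mapping$term_id, mapping$gbd_category)
  pick_term <- function(cats) {
    idx <- vapply(terms_by_cat[cats], length, integer(1))
    vapply(seq_along(cats), function(i)
      terms_by_cat[[cats[i]]][sample.int(idx[i], 1)], character(1))
  }
  # vectorised term pick: sample a slot uniformly within each category
  pick_term_fast <- function(cats) {
    k <- lengths(terms_by_cat)[cats]
    slot <- 1L + as.integer(floor(runif(length(cats)) * k))
    mapply(function(cat, s) terms_by_cat[[cat]][s], cats, slot, USE.NAMES = FALSE)
  }
  arts$gold_pop_term <- if (n_art) pick_term_fast(arts$condition) else character(0)
  has_out <- runif(n_art) < truth$outcome_prob
  out_cond <- rep(NA_character_, n_art)
  out_cond[has_out] <- sample(conds, sum(has_out), replace = TRUE)
  arts$gold_out_term <- NA_character_
  if (any(has_out)) arts$gold_out_term[has_out] <- pick_term_fast(out_cond[has_out])

  # predicted terms: gold terms kept at the category-task recall, spurious
  # terms injected at a per-article Poisson rate targeting the precision
  p_cat <- truth$task_precision[["category"]]
  r_cat <- truth$task_recall[["category"]]
  keep_pop <- runif(n_art) < r_cat
  keep_out <- has_out & (runif(n_art) < r_cat)
  g <- 1L + as.integer(has_out)
  lam_sp <- if (p_cat < 1) r_cat * g * (1 - p_cat) / p_cat else 0
  n_sp <- rpois(n_art, lam_sp)
  pop_pred <- ifelse(keep_pop, arts$gold_pop_term, "")
  out_pred <- ifelse(keep_out, arts$gold_out_term, "")
  if (sum(n_sp) > 0) {
    owner <- rep(seq_len(n_art), times = n_sp)
    sp_term <- mapping$term_id[sample.int(nrow(mapping), sum(n_sp), replace = TRUE)]
    sp_role <- sample(c("pop", "out"), sum(n_sp), replace = TRUE)
    for (role in c("pop", "out")) {
      sel <- sp_role == role
      if (!any(sel)) next
      add <- vapply(split(sp_term[sel], owner[sel]), paste,
                    character(1), collapse = "|")
      who <- as.integer(names(add))
      if (role == "pop") pop_pred[who] <- join_terms(pop_pred[who], add)
      else out_pred[who] <- join_terms(out_pred[who], add)
    }
  }
  arts$pop_terms <- pop_pred
  arts$out_terms <- ifelse(is.na(out_pred), "", out_pred)

  # bookkeeping category sets (gold and predicted)
  term_cat <- setNames(mapping$gbd_category, mapping$term_id)
  cats_of <- function(pop, out) {
    all_terms <- join_terms(pop, out)
    vapply(strsplit(all_terms, "|", fixed = TRUE), function(tt) {
      tt <- tt[tt != ""]
      if (!length(tt)) return("")
      paste(sort(unique(term_cat[tt])), collapse = "|")
    }, character(1))
  }
  arts$gold_categories <- cats_of(arts$gold_pop_term,
                                  ifelse(is.na(arts$gold_out_term), "",
                                         arts$gold_out_term))
  arts$pred_categories <- cats_of(arts$pop_terms, arts$out_terms)

  # participant counts: lognormal calibrated to median/IQR; extraction is
  # missing for a fraction of articles and in error for a further fraction
  gold_size <- rep(NA_real_, n_art)
  is_rct <- arts$gold_rct
  gold_size[is_rct] <- pmax(1, round(rlnorm(sum(is_rct),
                                            log(truth$size_median),
                                            size_sdlog(truth))))
  miss <- runif(n_art) < truth$size_missing
  err <- runif(n_art) < truth$size_error_prob
  noise <- round(rnorm(n_art, 0, truth$size_error_sd))
  size <- ifelse(miss | !is_rct, NA_real_,
                 pmax(1, gold_size + ifelse(err, noise, 0)))
  arts$gold_size <- gold_size
  arts$size <- size

  # first-author country: top quintile with probability country_high_share,
  # remainder split over quintiles 1-4 with increasing weight
  qw <- c(0.11, 0.22, 0.28, 0.39) * (1 - truth$country_high_share)
  quint <- sample(1:5, n_art, replace = TRUE,
                  prob = c(qw, truth$country_high_share))
  by_quint <- split(countries$country, countries$sdi_quintile)
  nq <- lengths(by_quint)[quint]
  slot <- 1L + as.integer(floor(runif(n_art) * nq))
  arts$country <- mapply(function(q, s) by_quint[[q]][s], quint, slot,
                         USE.NAMES = FALSE)
  if (!n_art) arts$country <- character(0)

  rownames(arts) <- NULL
  arts[c("article_id", "trial_id", "condition", "year", "country",
         "gold_rct", "pred_rct", "gold_pop_term", "gold_out_term",
         "pop_terms", "out_terms", "gold_categories", "pred_categories",
         "gold_size", "size")]
}

#' Draw validation samples with gold labels
#'
#' Emulates the manual labelling exercise: uniform random subsets of the
#' corpus, without replacement, for each labelling task.  Defaults mirror the
#' published validation design (500 abstracts for RCT status, 250 for GBD
#' category, 500 for participant numbers).
#'
#' @param articles Article table from [generate_articles()].
#' @param n_rct,n_category,n_size Validation sample sizes per task.
#' @param seed RNG seed.
#' @return An object of class `"validation_samples"`: a list with data.frames
#'   `rct` (`article_id`, `predicted`, `gold`; logicals), `category`
#'   (`article_id`, `category`, `predicted`, `gold`; one row per
#'   article-category link predicted or gold), and `size` (`article_id`,
#'   `predicted`, `gold`; participant counts, possibly `NA`).
#' @export
generate_validation <- function(articles, n_rct = 500, n_category = 250,
                                n_size = 500, seed = 1L) {
  n <- nrow(articles)
  for (req in c(n_rct, n_category, n_size))
    if (req > n) stop("requested validation sample of ", req,
                      " exceeds corpus size ", n)
  set.seed(seed_for(seed, "validation"))

  take <- function(k) articles[sample.int(n, k), , drop = FALSE]

  s_rct <- take(n_rct)
  rct <- data.frame(article_id = s_rct$article_id,
                    predicted = s_rct$pred_rct, gold = s_rct$gold_rct,
                    stringsAsFactors = FALSE)

  s_cat <- take(n_category)
  split_cats <- function(x) lapply(strsplit(x, "|", fixed = TRUE),
                                   function(v) v[v != ""])
  gold_sets <- split_cats(s_cat$gold_categories)
  pred_sets <- split_cats(s_cat$pred_categories)
  cat_rows <- lapply(seq_len(n_category), function(i) {
    cats <- union(gold_sets[[i]], pred_sets[[i]])
    if (!length(cats)) return(NULL)
    data.frame(article_id = s_cat$article_id[i], category = cats,
               predicted = cats %in% pred_sets[[i]],
               gold = cats %in% gold_sets[[i]], stringsAsFactors = FALSE)
  })
  category <- do.call(rbind, cat_rows)
  if (is.null(category))
    category <- data.frame(article_id = character(0), category = character(0),
                           predicted = logical(0), gold = logical(0))

  s_sz <- take(n_size)
  size <- data.frame(article_id = s_sz$article_id,
                     predicted = s_sz$size, gold = s_sz$gold_size,
                     stringsAsFactors = FALSE)

  structure(list(rct = rct, category = category, size = size),
            class = "validation_samples")
}

#' @export
print.validation_samples <- function(x, ...) {
  cat("Validation samples:\n")
  cat(sprintf("  rct:      %d articles\n", nrow(x$rct)))
  cat(sprintf("  category: %d article-category links (%d articles)\n",
              nrow(x$category), length(unique(x$category$article_id))))
  cat(sprintf("  size:     %d articles (%d complete pairs)\n", nrow(x$size),
              sum(complete.cases(x$size[c("predicted", "gold")]))))
  invisible(x)
}
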