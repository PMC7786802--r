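#' Simulate a complete synthetic evidence corpus
#'
#' One call produces every input the analysis pipeline consumes — article
#' records, per-task validation samples, the burden panel, the
#' term-to-category mapping, the country table — together with the
#' [ground_truth()] that generated them and the gold per-condition-year
#' article counts.  Every category referenced by an article exists in both
#' the burden and the mapping table by construction.
#'
#' @inheritParams generate_burden
#' @param n_rct,n_category,n_size Validation sample sizes (defaults mirror
#'   the published design: 500/250/500).
#' @return An object of class `"synthetic_bundle"`: list with elements
#'   `articles`, `validation`, `burden`, `mapping`, `countries`, `truth`,
#'   `truth_counts` (gold RCT articles per condition-year).
#' @export
#' @examples
#' bundle <- simulate_corpus(4, 2008:2012,
#'                           ground_truth(year_effects = 1, seed = 5))
#' bundle
simulate_corpus <- function(n_conditions = 22, years = 1990:2017,
                            truth = ground_truth(),
                            n_rct = 500, n_category = 250, n_size = 500) {
  burden <- generate_burden(n_conditions, years, truth)
  mapping <- generate_mapping(unique(burden$condition),
                              truth$terms_per_category, truth$seed)
  countries <- generate_countries(seed = truth$seed)
  articles <- generate_articles(burden, truth, mapping, countries)
  n <- nrow(articles)
  validation <- generate_validation(articles,
                                    n_rct = min(n_rct, n),
                                    n_category = min(n_category, n),
                                    n_size = min(n_size, n),
                                    seed = truth$seed)
  gold <- articles[articles$gold_rct, , drop = FALSE]
  truth_counts <- aggregate(list(n_articles = gold$article_id),
                            by = list(condition = gold$condition,
                                      year = gold$year), FUN = length)
  truth_counts <- truth_counts[order(truth_counts$condition,
                                     truth_counts$year), , drop = FALSE]
  rownames(truth_counts) <- NULL
  structure(list(articles = articles, validation = validation,
                 burden = burden, mapping = mapping, countries = countries,
                 truth = truth, truth_counts = truth_counts),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic evidence corpus\n")
  cat(sprintf("  %d articles (%d gold RCT, %d predicted RCT)\n",
              nrow(x$articles), sum(x$articles$gold_rct),
              sum(x$articles$pred_rct)))
  cat(sprintf("  %d conditions x %d years of burden data\n",
              length(unique(x$burden$condition)),
              length(unique(x$burden$year))))
  cat(sprintf("  mapping of %d terms; %d countries; seed %d\n",
              nrow(x$mapping), nrow(x$countries), x$truth$seed))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Articles are written both as CSV and as JSON-lines (one record per line);
#' burden, mapping, country and validation tables as CSV with headers; and a
#' manifest JSON recording the generator configuration and seed.
#'
#' @param bundle A [simulate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_corpus <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    articles_csv = file.path(dir, "articles.csv"),
    articles_jsonl = file.path(dir, "articles.jsonl"),
    burden = file.path(dir, "burden.csv"),
    mapping = file.path(dir, "mapping.csv"),
    countries = file.path(dir, "countries.csv"),
    validation = file.path(dir, "validation.csv"),
    manifest = file.path(dir, "corpus_manifest.json")
  )
  write.csv(bundle$articles, paths[["articles_csv"]], row.names = FALSE)
  con <- file(paths[["articles_jsonl"]], "w")
  on.exit(close(con))
  apply_rows <- split(bundle$articles, seq_len(nrow(bundle$articles)))
  writeLines(vapply(apply_rows, function(r)
    as.character(jsonlite::toJSON(as.list(r), auto_unbox = TRUE, na = "null")),
    character(1)), con)
  write.csv(bundle$burden, paths[["burden"]], row.names = FALSE)
  write.csv(bundle$mapping, paths[["mapping"]], row.names = FALSE)
  write.csv(bundle$countries, paths[["countries"]], row.names = FALSE)
  write.csv(validation_frame(bundle$validation), paths[["validation"]],
            row.names = FALSE)
  manifest <- list(truth = unclass(bundle$truth),
                   n_articles = nrow(bundle$articles),
                   generated = "trialgap synthetic corpus")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(paths)
}

# long-format single-file representation of the validation samples
validation_frame <- function(validation) {
  rbind(
    data.frame(task = "rct", article_id = validation$rct$article_id,
               label = NA_character_,
               predicted = as.character(validation$rct$predicted),
               gold = as.character(validation$rct$gold),
               stringsAsFactors = FALSE),
    data.frame(task = "category", article_id = validation$category$article_id,
               label = validation$category$category,
               predicted = as.character(validation$category$predicted),
               gold = as.character(validation$category$gold),
               stringsAsFactors = FALSE),
    data.frame(task = "size", article_id = validation$size$article_id,
               label = NA_character_,
               predicted = as.character(validation$size$predicted),
               gold = as.character(validation$size$gold),
               stringsAsFactors = FALSE)
  )
}
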