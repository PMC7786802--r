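#' The 22 GBD level-2 cause categories
#'
#' The Global Burden of Disease (GBD) study organises all causes of death and
#' disability into a hierarchy; its 22 "level 2" categories (e.g.
#' "Cardiovascular diseases", "Mental disorders") are the unit of analysis
#' throughout this package.  Every mapping table and burden table must use
#' category names drawn from this closed set.
#'
#' @return Character vector of length 22.
#' @export
#' @examples
#' gbd_categories()
gbd_categories <- function() {
  c(
    "Cardiovascular diseases",
    "Chronic respiratory diseases",
    "Diabetes and kidney diseases",
    "Digestive diseases",
    "Enteric infections",
    "HIV/AIDS and sexually transmitted infections",
    "Maternal and neonatal disorders",
    "Mental disorders",
    "Musculoskeletal disorders",
    "Neglected tropical diseases and malaria",
    "Neoplasms",
    "Neurological disorders",
    "Nutritional deficiencies",
    "Other infectious diseases",
    "Other non-communicable diseases",
    "Respiratory infections and tuberculosis",
    "Self-harm and interpersonal violence",
    "Sense organ diseases",
    "Skin and subcutaneous diseases",
    "Substance use disorders",
    "Transport injuries",
    "Unintentional injuries"
  )
}

# Condition labels used by the synthetic generator: the first n of the real
# category names, so that small synthetic worlds still speak GBD vocabulary.
condition_names <- function(n) {
  cats <- gbd_categories()
  if (n <= length(cats)) return(cats[seq_len(n)])
  c(cats, sprintf("Synthetic condition %02d", seq_len(n - length(cats))))
}
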