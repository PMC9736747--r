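#' Health-factor categories and their graph labels
#'
#' Every health factor extracted from an EMR belongs to one of nine closed
#' categories. Each category determines the relationship label placed on the
#' patient-to-factor edge in the property graph (e.g. a `Condition` factor is
#' attached via `HAS_CONDITION`). Short codes (`dac`, `smp`, ...) are the
#' compact spellings used in graph queries and exported tables; both the full
#' and the short spelling are accepted anywhere a category is read.
#'
#' @return A tibble with columns `category` (canonical name), `short`
#'   (two/three-letter code) and `rel_label` (patient-edge relationship label).
#' @examples
#' factor_categories()
#' @export
factor_categories <- function() {
  tibble(
    category = c(
      "Condition", "Symptom", "Observation", "History", "RiskFactor",
      "Labtest", "Procedure", "Medication", "Treatment"
    ),
    short = c("dac", "smp", "obs", "his", "rf", "lab", "pro", "med", "trt"),
    rel_label = c(
      "HAS_CONDITION", "HAS_SYMPTOM", "HAS_OBSERVATION", "HAS_HISTORY",
      "HAS_RISKFACTOR", "HAS_LABTEST", "HAS_PROCEDURE", "HAS_MEDICATION",
      "HAS_TREATMENT"
    )
  )
}

# Map a vector of category spellings (full names or short codes, any case)
# to canonical full names. Unknown spellings -> parse error listing the
# admissible set.
normalize_category <- function(x) {
  cats <- factor_categories()
  lookup <- c(
    stats::setNames(cats$category, tolower(cats$category)),
    stats::setNames(cats$category, cats$short)
  )
  out <- unname(lookup[tolower(trimws(x))])
  if (anyNA(out[!is.na(x)])) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    stop_parse(c(
      paste0(
        "Unknown factor categor", if (length(bad) > 1) "ies: " else "y: ",
        paste0("'", bad, "'", collapse = ", ")
      ),
      i = paste(
        "Admissible categories:",
        paste(cats$category, collapse = ", "),
        "or short codes:", paste(cats$short, collapse = ", ")
      )
    ))
  }
  out
}

category_short <- function(category) {
  cats <- factor_categories()
  unname(stats::setNames(cats$short, cats$category)[category])
}

category_rel_label <- function(category) {
  cats <- factor_categories()
  unname(stats::setNames(cats$rel_label, cats$category)[category])
}

# Composite node key for a factor-value pair node.
factor_key <- function(category, code, converted_value) {
  paste(category, code, converted_value, sep = "|")
}
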