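#' Value-conversion rules for continuous EMR data
#'
#' The property graph stores only categorical values, so continuous numeric
#' data must be binned or thresholded before graph construction. A rules
#' object bundles three mechanisms:
#'
#' * **age bins** — ordered half-open intervals \[30,50), \[50,70), \[70,Inf)
#'   labelled `"30-50"`, `"50-70"`, `">70"`. Half-open intervals make the
#'   ranges a partition of \[30, Inf); the labels keep the conventional
#'   clinical spelling.
#' * **threshold rules** — per-code numeric thresholds with a strict `>`
#'   comparator mapping to `"true"`/`"false"` (e.g. smoking is `"true"` when
#'   the patient smokes more than 1 cigarette per day, drinking when they
#'   consume more than 1 drink per day).
#' * **categorical passthrough** — values already categorical in the EMR
#'   (lab flags such as normal/abnormal, true/false, positive/negative,
#'   high/medium/low, up/down/normal) pass through unchanged apart from
#'   case-folding to lower case.
#'
#' @param age_bins Tibble with columns `lower`, `upper`, `label`; intervals
#'   are \[lower, upper). Must tile \[30, Inf) without gaps.
#' @param age_codes Character vector of factor codes treated as ages.
#' @param thresholds Tibble with columns `code`, `threshold`, `true_label`,
#'   `false_label`. Comparator is strict `>`. Thresholds must be positive.
#' @param categorical Character vector of admissible categorical values.
#' @return An object of class `conversion_rules`.
#' @seealso [convert_value()]
#' @examples
#' rules <- conversion_rules()
#' convert_value(rules, "age", 63)
#' convert_value(rules, "smoking", 0)
#' @export
conversion_rules <- function(age_bins = NULL,
                             age_codes = c("age", "C-age"),
                             thresholds = NULL,
                             categorical = NULL) {
  if (is.null(age_bins)) {
    age_bins <- tibble(
      lower = c(30, 50, 70),
      upper = c(50, 70, Inf),
      label = c("30-50", "50-70", ">70")
    )
  }
  age_bins <- as_tibble(age_bins)
  if (nrow(age_bins)) {
    ord <- order(age_bins$lower)
    age_bins <- age_bins[ord, ]
    if (any(age_bins$upper[-nrow(age_bins)] != age_bins$lower[-1])) {
      stop_config("Age bins must tile their range without gaps or overlaps.")
    }
  }
  if (is.null(thresholds)) {
    thresholds <- tibble(
      code = c("smoking", "C-902187", "drinking"),
      threshold = 1,
      true_label = "true",
      false_label = "false"
    )
  }
  thresholds <- as_tibble(thresholds)
  if (nrow(thresholds) && any(thresholds$threshold <= 0)) {
    stop_config("Threshold rules must use strictly positive thresholds.")
  }
  if (is.null(categorical)) {
    categorical <- c(
      "normal", "abnormal", "true", "false", "positive", "negative",
      "high", "medium", "low", "up", "down"
    )
  }
  structure(
    list(
      age_bins = age_bins,
      age_codes = age_codes,
      thresholds = thresholds,
      categorical = tolower(categorical)
    ),
    class = "conversion_rules"
  )
}

#' Convert raw EMR values to categorical values
#'
#' Applies the [conversion_rules()] to one or more raw values, vectorised
#' over `code` and `raw`. Age codes are binned, threshold codes are compared
#' with strict `>`, and values already in the admissible categorical set pass
#' through (lower-cased). A numeric value with no applicable rule raises a
#' conversion error: silent passthrough of raw numbers would create spurious
#' factor-value nodes.
#'
#' @param rules A `conversion_rules` object.
#' @param code Character vector of factor codes.
#' @param raw Raw values (character or numeric), recycled against `code`.
#' @return Character vector of converted categorical values.
#' @examples
#' rules <- conversion_rules()
#' convert_value(rules, "age", c(35, 63, 81))
#' convert_value(rules, "lab1", "Abnormal")
#' @export
convert_value <- function(rules, code, raw) {
  stopifnot(inherits(rules, "conversion_rules"))
  n <- max(length(code), length(raw))
  code <- rep_len(as.character(code), n)
  raw <- rep_len(raw, n)
  raw_chr <- trimws(as.character(raw))
  num <- suppressWarnings(as.numeric(raw_chr))

  thr <- rules$thresholds
  out <- character(n)
  for (i in seq_len(n)) {
    if (code[[i]] %in% rules$age_codes && !is.na(num[[i]])) {
      out[[i]] <- bin_age(rules$age_bins, num[[i]], code[[i]])
    } else if (code[[i]] %in% thr$code && !is.na(num[[i]])) {
      r <- thr[match(code[[i]], thr$code), ]
      out[[i]] <- if (num[[i]] > r$threshold) r$true_label else r$false_label
    } else if (tolower(raw_chr[[i]]) %in% rules$categorical) {
      out[[i]] <- tolower(raw_chr[[i]])
    } else if (!is.na(num[[i]])) {
      stop_conversion(paste0(
        "Numeric value ", raw_chr[[i]], " for code '", code[[i]],
        "' has no conversion rule and is not an admissible categorical value."
      ))
    } else if (!nzchar(raw_chr[[i]]) || is.na(raw_chr[[i]])) {
      stop_conversion(paste0("Empty value for code '", code[[i]], "'."))
    } else {
      # Non-numeric, non-standard category (e.g. an age range already
      # labelled): pass through unchanged.
      out[[i]] <- raw_chr[[i]]
    }
  }
  out
}

bin_age <- function(bins, value, code) {
  hit <- which(value >= bins$lower & value < bins$upper)
  if (!length(hit)) {
    stop_conversion(paste0(
      "Age value ", value, " for code '", code,
      "' falls outside the configured bins ([",
      min(bins$lower), ", ", max(bins$upper), "))."
    ))
  }
  bins$label[[hit[[1]]]]
}

#' @export
print.conversion_rules <- function(x, ...) {
  cat("<conversion_rules>\n")
  cat("  age bins:   ", paste(x$age_bins$label, collapse = ", "),
      " (codes: ", paste(x$age_codes, collapse = ", "), ")\n", sep = "")
  cat("  thresholds: ", nrow(x$thresholds), " code(s), strict '>'\n", sep = "")
  cat("  categorical:", paste(x$categorical, collapse = ", "), "\n")
  invisible(x)
}
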