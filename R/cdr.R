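#' Count target and background patient connections per factor node
#'
#' For each factor-value node, counts the distinct target patients (TPC,
#' label 1) and distinct background patients (BPC, label 0) adjacent to it.
#' Each patient contributes at most one connection per factor node, so the
#' counts are cohort prevalences, not encounter counts.
#'
#' @param graph A `patient_graph`.
#' @param factors Optional character vector of factor node keys
#'   (`"category|code|converted_value"`) to restrict to; unknown keys raise
#'   a not-found error. Default: all factor nodes in the graph.
#' @return A tibble with the factor identity columns plus `tpc` and `bpc`.
#' @examples
#' pts <- tibble::tibble(virtual_id = c("_1", "_2", "_3"), label = c(1L, 1L, 0L))
#' obs <- tibble::tibble(
#'   virtual_id = pts$virtual_id, category = "Condition", code = "C-765209",
#'   term = "Obstructive pneumonia", value = "true", unit = "",
#'   converted_value = "true", date = as.Date("2021-01-01")
#' )
#' count_connections(build_patient_graph(pts, obs))
#' @export
count_connections <- function(graph, factors = NULL) {
  stopifnot(inherits(graph, "patient_graph"))
  keys <- graph$factors
  if (!is.null(factors)) {
    unknown <- setdiff(factors, keys$factor_id)
    if (length(unknown)) {
      stop_not_found(paste0(
        "Unknown factor node key(s): ", paste(head(unknown, 5), collapse = ", ")
      ))
    }
    keys <- filter(keys, .data$factor_id %in% factors)
  }
  counts <- graph$edges |>
    distinct(.data$virtual_id, .data$factor_id) |>
    inner_join(graph$patients, by = "virtual_id") |>
    group_by(.data$factor_id) |>
    summarise(
      tpc = sum(.data$label == 1L),
      bpc = sum(.data$label == 0L),
      .groups = "drop"
    )
  keys |>
    left_join(counts, by = "factor_id") |>
    mutate(
      tpc = as.integer(tidyr::replace_na(.data$tpc, 0L)),
      bpc = as.integer(tidyr::replace_na(.data$bpc, 0L))
    ) |>
    select(
      "factor_id", "category", "code", "term", "converted_value",
      "tpc", "bpc"
    )
}

#' Connection delta ratio
#'
#' The ranking statistic of the health-factor distribution:
#' \deqn{CDR = (TPC - BPC) / (TPC + BPC)}
#' where TPC and BPC are the distinct target- and background-patient
#' connection counts of a factor node. CDR lies in \[-1, 1\]: values between
#' 0 and 1 mean the factor is more prevalent among target patients (1 =
#' exclusively so); negative values mean it is more prevalent among
#' background patients. With equal cohort sizes and attachment probabilities
#' `p_t`, `p_b`, the empirical CDR converges to
#' `(p_t - p_b) / (p_t + p_b)`.
#'
#' @param tpc,bpc Non-negative integer vectors (recycled). Every pair must
#'   satisfy `tpc + bpc >= 1`; a zero total is an error, never silently 0.
#' @return Numeric vector of ratios in \[-1, 1\].
#' @examples
#' cdr(12, 0) # 1.00 — factor exclusive to the target cohort
#' cdr(30, 10) # 0.50
#' @export
cdr <- function(tpc, bpc) {
  n <- max(length(tpc), length(bpc))
  tpc <- rep_len(as.numeric(tpc), n)
  bpc <- rep_len(as.numeric(bpc), n)
  if (any(tpc < 0 | bpc < 0) || anyNA(tpc) || anyNA(bpc)) {
    stop_config("Connection counts must be non-negative and non-missing.")
  }
  if (any(tpc + bpc == 0)) {
    stop_config(
      "CDR is undefined for a factor with zero patient connections (TPC + BPC = 0)."
    )
  }
  (tpc - bpc) / (tpc + bpc)
}

#' Configure the health-factor distribution filters
#'
#' @param cdr_cutoff Strict lower bound on CDR (default 0.5): a factor
#'   enters the distribution only if its CDR is strictly greater. Must lie
#'   in (-1, 1).
#' @param min_target_connections Minimum TPC (default 10): high CDRs on a
#'   handful of patients are unreliable, so a factor must connect to at
#'   least this many target patients.
#' @param excluded_categories Categories dropped wholesale (default
#'   Procedure, Medication, Treatment — for risk-factor interpretation these
#'   reflect care of the disease, not antecedents of it).
#' @param excluded_patterns Case-insensitive regular expressions matched
#'   against term and code; matching factors are dropped (default: cancer,
#'   carcinoma, neoplasm, tumo(u)r — diagnoses of the target disease itself).
#' @param pattern_categories Categories the pattern blocklist applies to
#'   (default `"Condition"`): a cancer *diagnosis* is circular as a risk
#'   factor, but a lab marker merely named after a carcinoma (tumour-antigen
#'   assays, say) is a legitimate finding and is kept.
#' @return A `distribution_config` object.
#' @export
distribution_config <- function(cdr_cutoff = 0.5,
                                min_target_connections = 10,
                                excluded_categories = c(
                                  "Procedure", "Medication", "Treatment"
                                ),
                                excluded_patterns = c(
                                  "cancer", "carcinoma", "neoplasm", "tumou?r"
                                ),
                                pattern_categories = "Condition") {
  if (!is.numeric(cdr_cutoff) || cdr_cutoff <= -1 || cdr_cutoff >= 1) {
    stop_config("cdr_cutoff must lie in the open interval (-1, 1).")
  }
  if (min_target_connections < 0) {
    stop_config("min_target_connections must be non-negative.")
  }
  if (length(excluded_categories)) {
    excluded_categories <- normalize_category(excluded_categories)
  }
  if (length(pattern_categories)) {
    pattern_categories <- normalize_category(pattern_categories)
  }
  structure(
    list(
      cdr_cutoff = cdr_cutoff,
      min_target_connections = as.integer(min_target_connections),
      excluded_categories = excluded_categories,
      excluded_patterns = excluded_patterns,
      pattern_categories = pattern_categories
    ),
    class = "distribution_config"
  )
}

#' Build the ranked health-factor distribution
#'
#' Computes TPC, BPC and CDR for every factor-value node of the patient
#' graph, applies the distribution filters (strict CDR cutoff, minimum
#' target-patient support, category and term/code exclusions) and returns
#' the surviving factors sorted by CDR descending. Ties break by larger TPC,
#' then lexicographic code, making the order deterministic. CDR values are
#' kept at full double precision; rounding happens only at export.
#'
#' Factors with `bpc = 0` reach CDR exactly 1 and may reflect testing bias
#' (a test ordered only for suspected cases connects to no background
#' patient); they are flagged with a warning but retained.
#'
#' @param graph A `patient_graph`.
#' @param config A [distribution_config()].
#' @return A `cdr_distribution`: a tibble with the factor identity columns,
#'   `tpc`, `bpc`, `cdr` and `rank`, sorted by CDR descending, with the
#'   config stored as an attribute. Zero rows is a valid result.
#' @export
build_distribution <- function(graph, config = distribution_config()) {
  stopifnot(inherits(graph, "patient_graph"),
            inherits(config, "distribution_config"))
  counts <- count_connections(graph) |>
    filter(.data$tpc + .data$bpc >= 1L)
  entries <- counts |>
    mutate(cdr = cdr(.data$tpc, .data$bpc)) |>
    filter(
      .data$cdr > config$cdr_cutoff,
      .data$tpc >= config$min_target_connections,
      !.data$category %in% config$excluded_categories
    )
  if (length(config$excluded_patterns) && length(config$pattern_categories)) {
    pat <- paste0("(", paste(config$excluded_patterns, collapse = ")|("), ")")
    entries <- filter(
      entries,
      !(.data$category %in% config$pattern_categories &
          (stringr::str_detect(tolower(.data$term), pat) |
             stringr::str_detect(tolower(.data$code), pat)))
    )
  }
  entries <- entries |>
    arrange(desc(.data$cdr), desc(.data$tpc), .data$code) |>
    mutate(rank = dplyr::row_number()) |>
    select(
      "rank", "category", "code", "term", "converted_value",
      "tpc", "bpc", "cdr"
    )
  n_bias <- sum(entries$bpc == 0L)
  if (n_bias > 0) {
    warn(paste0(
      n_bias, " factor(s) have zero background connections (CDR = 1); ",
      "consider whether testing bias explains them before interpretation."
    ))
  }
  structure(
    entries,
    config = config,
    class = c("cdr_distribution", class(entries))
  )
}

#' Export the health-factor distribution table
#'
#' Writes the distribution as a delimited file with the conventional column
#' set `Category` (short code), `Local code`, `Term`, `Value`
#' (`true`/`false` upper-cased), `Connection delta ratio` (rounded, default
#' 2 decimals) and `Tag`. Tags come from an optional user-supplied
#' annotation map (literature verification is a manual step); absent codes
#' get an empty tag.
#'
#' @param entries A `cdr_distribution`.
#' @param path Output file path.
#' @param tags Optional named character vector mapping factor codes to tags
#'   (e.g. `c("C-902187" = "confirmed")`).
#' @param digits Decimal places for the exported CDR (default 2).
#' @param delim Field delimiter (default `,`).
#' @return Invisibly, `path`.
#' @export
export_distribution <- function(entries, path, tags = NULL, digits = 2,
                                delim = ",") {
  stopifnot(inherits(entries, "cdr_distribution"))
  out <- tibble(
    Category = category_short(entries$category),
    `Local code` = entries$code,
    Term = entries$term,
    Value = ifelse(
      entries$converted_value %in% c("true", "false"),
      toupper(entries$converted_value), entries$converted_value
    ),
    `Connection delta ratio` = sprintf(
      paste0("%.", digits, "f"), round(entries$cdr, digits)
    ),
    Tag = if (is.null(tags)) "" else {
      dplyr::coalesce(unname(tags[entries$code]), "")
    }
  )
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}
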