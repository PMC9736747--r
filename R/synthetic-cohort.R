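#' Configure a synthetic case/control EMR cohort
#'
#' Describes a two-cohort EMR extract with Bernoulli factor attachment: each
#' factor-value pair attaches independently to every target patient with
#' probability `p_t` and to every background patient with probability `p_b`.
#' The defaults mirror a hospital lung-cancer extract with 1397 patients per
#' arm. Under equal arm sizes the expected connection delta ratio of a factor
#' is `(p_t - p_b) / (p_t + p_b)`, which makes generated cohorts a ground
#' truth for the whole downstream pipeline.
#'
#' @param factor_specs Data frame with one row per factor-value pair and
#'   columns `category`, `code`, `term`, `converted_value`, `p_t`, `p_b`.
#'   The `(category, code, converted_value)` triples must be unique and both
#'   probabilities must lie in \[0, 1\].
#' @param n_target,n_background Positive cohort sizes (default 1397 each).
#' @param seed Integer seed; identical seeds give byte-identical output files.
#' @return A `cohort_config` object.
#' @examples
#' spec <- tibble::tibble(
#'   category = "RiskFactor", code = "C-902187", term = "Smoking",
#'   converted_value = "true", p_t = 0.6, p_b = 0.2
#' )
#' cohort_config(spec, n_target = 100, n_background = 100, seed = 1)
#' @export
cohort_config <- function(factor_specs,
                          n_target = 1397,
                          n_background = 1397,
                          seed = 1L) {
  factor_specs <- as_tibble(factor_specs)
  required <- c("category", "code", "term", "converted_value", "p_t", "p_b")
  missing_cols <- setdiff(required, names(factor_specs))
  if (length(missing_cols)) {
    stop_config(paste(
      "factor_specs is missing column(s):",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (n_target < 1 || n_background < 1) {
    stop_config("Cohort sizes must be at least 1 in each arm.")
  }
  probs <- c(factor_specs$p_t, factor_specs$p_b)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_config("Attachment probabilities p_t and p_b must lie in [0, 1].")
  }
  factor_specs$category <- normalize_category(factor_specs$category)
  key <- factor_key(
    factor_specs$category, factor_specs$code, factor_specs$converted_value
  )
  if (anyDuplicated(key)) {
    stop_config("Factor (category, code, converted_value) triples must be unique.")
  }
  structure(
    list(
      factor_specs = factor_specs,
      n_target = as.integer(n_target),
      n_background = as.integer(n_background),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic EMR cohort extract
#'
#' Draws the patient-factor attachments described by a [cohort_config()] and
#' returns the two import tables of a standardized EMR extract: a patient
#' table (`virtual_id`, `label`, `factor_count`) and a factor-observation
#' table (`virtual_id`, `category`, `code`, `term`, `value`, `unit`,
#' `converted_value`, `date`). Virtual ids are zero-padded integers prefixed
#' `"_"`. Each patient carries a single deterministic encounter date; dates
#' only matter downstream for latest-value selection, which these single
#' encounters never trigger.
#'
#' The drawn attachments are also returned as a ledger so round-trip tests
#' can compare graph edges against the exact draws.
#'
#' @param config A [cohort_config()].
#' @return An `emr_cohort` list with elements `patients`, `factors`
#'   (both tibbles in import-file column order), `attachments` (the draw
#'   ledger: one row per patient-factor attachment, with the patient label)
#'   and `config`.
#' @examples
#' spec <- tibble::tibble(
#'   category = "Symptom", code = "C-549780", term = "Pain",
#'   converted_value = "true", p_t = 1, p_b = 0
#' )
#' coh <- generate_cohort(cohort_config(spec, 5, 5, seed = 7))
#' coh$patients
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_t <- config$n_target
  n_b <- config$n_background
  n <- n_t + n_b
  patients <- tibble(
    virtual_id = sprintf("_%010d", seq_len(n)),
    label = rep(c(1L, 0L), c(n_t, n_b))
  )
  # One RNG stream seeded from the config seed; restored on exit so the
  # generator never perturbs the caller's RNG state.
  specs <- config$factor_specs
  attachments <- withr::with_seed(config$seed, {
    purrr::pmap_dfr(specs, function(category, code, term, converted_value,
                                    p_t, p_b, ...) {
      draw <- c(rbinom(n_t, 1L, p_t), rbinom(n_b, 1L, p_b)) == 1L
      tibble(
        virtual_id = patients$virtual_id[draw],
        label = patients$label[draw],
        category = category, code = code, term = term,
        converted_value = converted_value
      )
    })
  })
  if (nrow(attachments) == 0) {
    attachments <- tibble(
      virtual_id = character(), label = integer(), category = character(),
      code = character(), term = character(), converted_value = character()
    )
  }
  encounter_date <- as.Date("2020-01-01") +
    (match(attachments$virtual_id, patients$virtual_id) - 1L) %% 366L
  factors <- tibble(
    virtual_id = attachments$virtual_id,
    category = attachments$category,
    code = attachments$code,
    term = attachments$term,
    value = attachments$converted_value,
    unit = "",
    converted_value = attachments$converted_value,
    date = encounter_date
  ) |>
    arrange(.data$virtual_id, .data$code, .data$converted_value)
  counts <- factors |> count(.data$virtual_id, name = "factor_count")
  patients <- patients |>
    left_join(counts, by = "virtual_id") |>
    mutate(factor_count = as.integer(tidyr::replace_na(.data$factor_count, 0L)))
  structure(
    list(
      patients = patients,
      factors = factors,
      attachments = as_tibble(attachments),
      config = config
    ),
    class = "emr_cohort"
  )
}

#' Serialise a synthetic cohort to import-file text
#'
#' Renders the two cohort tables as comma-delimited text with a header row,
#' exactly as [read_patient_file()] and [read_factor_file()] expect them.
#'
#' @param cohort An `emr_cohort` from [generate_cohort()].
#' @return A list with character scalars `patients` and `factors`.
#' @export
cohort_csv <- function(cohort) {
  stopifnot(inherits(cohort, "emr_cohort"))
  list(
    patients = readr::format_csv(cohort$patients),
    factors = readr::format_csv(cohort$factors)
  )
}

#' Write a synthetic cohort's import files
#'
#' @param cohort An `emr_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths written (`patients.csv`,
#'   `factors.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  txt <- cohort_csv(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "factors.csv"))
  writeLines(sub("\n$", "", txt$patients), paths[[1]])
  writeLines(sub("\n$", "", txt$factors), paths[[2]])
  invisible(paths)
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort> ", sum(x$patients$label == 1L), " target + ",
      sum(x$patients$label == 0L), " background patients, ",
      nrow(x$config$factor_specs), " factor spec(s), ",
      nrow(x$factors), " observations (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
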