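#' Read a patient import file
#'
#' Parses the comma-delimited patient table of an EMR extract: one patient
#' per line with a virtual id, a binary target label (1 = target case,
#' 0 = background control) and the patient's factor count. Header names are
#' matched case-insensitively and tolerate the hyphenated spellings used in
#' export tools (`virtual-id`, `LC-label`, `factor-count`).
#'
#' @param file Path to a CSV file, or a literal CSV string.
#' @return A tibble with columns `virtual_id` (character), `label` (integer
#'   0/1) and `factor_count` (integer).
#' @examples
#' read_patient_file("virtual_id,label,factor_count\n_01,1,2\n_02,0,0\n")
#' @export
read_patient_file <- function(file) {
  df <- read_emr_csv(file)
  names(df) <- normalize_header(names(df))
  names(df)[names(df) == "lc_label"] <- "label"
  required <- c("virtual_id", "label", "factor_count")
  check_header(df, required, "patient import file")
  if (nrow(df) == 0) {
    return(tibble(
      virtual_id = character(), label = integer(), factor_count = integer()
    ))
  }
  if (!all(df$label %in% c(0, 1, "0", "1"))) {
    bad <- unique(df$label[!df$label %in% c(0, 1, "0", "1")])
    stop_parse(paste0(
      "Patient labels must be 0 (background) or 1 (target); found: ",
      paste(bad, collapse = ", ")
    ))
  }
  dup <- unique(df$virtual_id[duplicated(df$virtual_id)])
  if (length(dup)) {
    stop_integrity(paste0(
      "Duplicate virtual_id(s) in patient file: ",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  tibble(
    virtual_id = as.character(df$virtual_id),
    label = as.integer(df$label),
    factor_count = as.integer(df$factor_count)
  )
}

#' Read a factor import file
#'
#' Parses the comma-delimited factor-observation table: one row per
#' patient-factor datum with columns virtual id, category, code, term, raw
#' value, unit, converted value and date. Categories must come from the
#' closed nine-category set ([factor_categories()]); both full names and
#' short codes are accepted and normalised to the full spelling.
#'
#' @param file Path to a CSV file, or a literal CSV string.
#' @return A tibble of factor observations with `date` parsed as `Date`.
#' @export
read_factor_file <- function(file) {
  df <- read_emr_csv(file)
  names(df) <- normalize_header(names(df))
  required <- c(
    "virtual_id", "category", "code", "term", "value", "unit",
    "converted_value", "date"
  )
  check_header(df, required, "factor import file")
  if (nrow(df) == 0) {
    return(tibble(
      virtual_id = character(), category = character(), code = character(),
      term = character(), value = character(), unit = character(),
      converted_value = character(), date = as.Date(character())
    ))
  }
  tibble(
    virtual_id = as.character(df$virtual_id),
    category = normalize_category(df$category),
    code = as.character(df$code),
    term = as.character(df$term),
    value = as.character(df$value),
    unit = dplyr::coalesce(as.character(df$unit), ""),
    converted_value = as.character(df$converted_value),
    date = parse_emr_date(df$date)
  )
}

read_emr_csv <- function(file) {
  input <- if (is.character(file) && length(file) == 1 &&
                 !grepl("\n", file) && file.exists(file)) {
    file
  } else {
    I(paste(file, collapse = "\n"))
  }
  readr::read_csv(
    input,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
}

normalize_header <- function(x) {
  gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
}

check_header <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_parse(paste0(
      "The ", what, " header is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
}

parse_emr_date <- function(x) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(bad)) {
    stop_parse(paste0(
      "Unparseable date(s): ", paste(head(unique(x[bad]), 5), collapse = ", "),
      " (expected ISO-8601 YYYY-MM-DD)."
    ))
  }
  out
}

#' Keep only the latest observation of each factor per patient
#'
#' A patient's diagnosis journey can record the same factor at several
#' encounters; only the most recent value before diagnosis is analysed.
#' Keeps, for every `(virtual_id, code)` pair, the observation with the
#' maximum date. Ties on the date break by file order: the last row wins,
#' which makes the operation deterministic and idempotent.
#'
#' @param observations A factor-observation tibble ([read_factor_file()]).
#' @return The filtered tibble, original row order preserved.
#' @export
select_latest_per_patient <- function(observations) {
  observations <- as_tibble(observations)
  if (nrow(observations) == 0) return(observations)
  observations |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$virtual_id, .data$code) |>
    filter(.data$date == max(.data$date)) |>
    filter(.data$.row == max(.data$.row)) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row")
}

#' Drop factors observed in too few target patients
#'
#' A factor code is retained only if it is held by at least
#' `min_target_patients` distinct target (label 1) patients; support in the
#' background arm is irrelevant. Rare codes produce unreliable connection
#' counts, so the hospital analysis kept roughly the 550 codes seen in at
#' least 10 target patients out of over 3000 collected.
#'
#' @param observations A factor-observation tibble.
#' @param patients A patient tibble supplying a label for every
#'   `virtual_id` referenced by `observations`.
#' @param min_target_patients Minimum number of distinct target patients
#'   (default 10). Zero keeps everything.
#' @return The observations of surviving codes, original order preserved.
#' @export
filter_min_support <- function(observations, patients,
                               min_target_patients = 10) {
  observations <- as_tibble(observations)
  patients <- as_tibble(patients)
  unknown <- setdiff(observations$virtual_id, patients$virtual_id)
  if (length(unknown)) {
    stop_integrity(paste0(
      "Observation(s) reference unknown patient(s): ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  if (min_target_patients <= 0 || nrow(observations) == 0) {
    return(observations)
  }
  support <- observations |>
    inner_join(select(patients, "virtual_id", "label"), by = "virtual_id") |>
    filter(.data$label == 1L) |>
    distinct(.data$code, .data$virtual_id) |>
    count(.data$code, name = "n_target")
  keep <- support$code[support$n_target >= min_target_patients]
  filter(observations, .data$code %in% keep)
}
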