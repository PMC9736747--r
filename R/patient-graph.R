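#' Build the patient-centered health-factor graph
#'
#' Constructs the labeled property graph linking patients to factor-value
#' pair nodes. Each patient record becomes a `Patient` node; each distinct
#' `(category, code, converted_value)` triple becomes one factor node (the
#' triple is the unique node key, so a code observed with two values — say
#' `up` and `down` — yields two nodes); each observation becomes one edge
#' whose relationship label is determined by the factor's category
#' (`HAS_CONDITION`, `HAS_LABTEST`, ...). Duplicate patient-factor pairs
#' collapse to a single edge.
#'
#' Observations are expected to be latest-selected
#' ([select_latest_per_patient()]) and support-filtered
#' ([filter_min_support()]) first.
#'
#' @param patients Patient tibble (`virtual_id`, `label`, ...).
#' @param observations Factor-observation tibble.
#' @return A `patient_graph` object: list of tibbles `patients`, `factors`
#'   (with a `factor_id` node key) and `edges` (`virtual_id`, `factor_id`,
#'   `rel_label`).
#' @examples
#' pts <- tibble::tibble(virtual_id = c("_1", "_2"), label = c(1L, 0L))
#' obs <- tibble::tibble(
#'   virtual_id = c("_1", "_2"), category = "Symptom", code = "C-549780",
#'   term = "Pain", value = "true", unit = "", converted_value = "true",
#'   date = as.Date("2020-06-01")
#' )
#' g <- build_patient_graph(pts, obs)
#' glance(g)
#' @export
build_patient_graph <- function(patients, observations) {
  patients <- as_tibble(patients)
  observations <- as_tibble(observations)
  stopifnot(all(c("virtual_id", "label") %in% names(patients)))
  if (anyDuplicated(patients$virtual_id)) {
    stop_integrity("Patient virtual_ids must be unique.")
  }
  unknown <- setdiff(observations$virtual_id, patients$virtual_id)
  if (length(unknown)) {
    stop_integrity(paste0(
      "Observation(s) reference unknown patient(s): ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  observations$category <- normalize_category(observations$category)
  if (!"term" %in% names(observations)) observations$term <- ""
  # One display term per code: first occurrence wins; divergent spellings
  # are tolerated but flagged, since the node key excludes the term.
  terms <- observations |>
    distinct(.data$code, .data$term) |>
    group_by(.data$code) |>
    summarise(
      term = dplyr::first(.data$term), n_terms = dplyr::n(), .groups = "drop"
    )
  if (any(terms$n_terms > 1)) {
    warn(paste0(
      "Code(s) with inconsistent terms (first spelling kept): ",
      paste(head(terms$code[terms$n_terms > 1], 5), collapse = ", ")
    ))
  }
  factors <- observations |>
    distinct(.data$category, .data$code, .data$converted_value) |>
    left_join(select(terms, "code", "term"), by = "code") |>
    mutate(
      factor_id = factor_key(.data$category, .data$code, .data$converted_value)
    ) |>
    select("factor_id", "category", "code", "term", "converted_value")
  edges <- observations |>
    transmute(
      virtual_id = .data$virtual_id,
      factor_id = factor_key(.data$category, .data$code, .data$converted_value),
      rel_label = category_rel_label(.data$category)
    ) |>
    distinct(.data$virtual_id, .data$factor_id, .keep_all = TRUE)
  new_patient_graph(
    select(patients, "virtual_id", "label"), factors, edges
  )
}

new_patient_graph <- function(patients, factors, edges) {
  structure(
    list(patients = patients, factors = factors, edges = edges),
    class = "patient_graph"
  )
}

#' @export
print.patient_graph <- function(x, ...) {
  cat("<patient_graph> ", nrow(x$patients), " patient nodes (",
      sum(x$patients$label == 1L), " target), ",
      nrow(x$factors), " factor-value nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build a factor query specification
#'
#' Describes a disjunctive graph search over factor nodes, in the style of
#' property-graph queries: each clause names a factor `code` and optionally
#' a `converted_value`. A clause with a value matches only that
#' factor-value node; a clause without one matches every value of the code.
#' Clauses combine with OR.
#'
#' @param clauses A data frame with column `code` and optional column
#'   `converted_value` (`NA` = any value), or a character vector of codes.
#' @param label Optional patient-label filter: 1 restricts to target
#'   patients, 0 to background, `NULL` (default) matches both.
#' @return A `factor_query` object.
#' @examples
#' factor_query(c("C-389764", "C-172569"), label = 1)
#' @export
factor_query <- function(clauses, label = NULL) {
  if (is.character(clauses)) {
    clauses <- tibble(code = clauses, converted_value = NA_character_)
  }
  clauses <- as_tibble(clauses)
  if (!"code" %in% names(clauses) || nrow(clauses) == 0) {
    stop_config("A factor query needs at least one clause with a 'code'.")
  }
  if (!"converted_value" %in% names(clauses)) {
    clauses$converted_value <- NA_character_
  }
  if (!is.null(label) && !label %in% c(0, 1)) {
    stop_config("label filter must be 0, 1 or NULL.")
  }
  structure(
    list(clauses = clauses, label = if (is.null(label)) NULL else as.integer(label)),
    class = "factor_query"
  )
}

#' Search the patient graph with a factor query
#'
#' Returns the subgraph of patients matching a [factor_query()]: with
#' `match = "any"` (the query style of disjunctive clause lists) a patient
#' matches if connected to at least one clause-matching factor node; with
#' `match = "all"` the patient must be connected to a match of every clause
#' (factors shared by patients). Only matched factor nodes and the edges
#' between matched patients and matched factors are returned. A clause whose
#' code is absent from the graph matches nothing and is reported as a
#' message, not an error.
#'
#' @param graph A `patient_graph`.
#' @param query A [factor_query()] (a character vector of codes is coerced).
#' @param match `"any"` (OR over clauses, default) or `"all"` (AND).
#' @return A `patient_graph` containing the matched subgraph.
#' @export
query_patients_with_factors <- function(graph, query, match = c("any", "all")) {
  stopifnot(inherits(graph, "patient_graph"))
  if (!inherits(query, "factor_query")) query <- factor_query(query)
  match <- match.arg(match)
  clauses <- mutate(query$clauses, .clause = dplyr::row_number())
  matched_factors <- clauses |>
    left_join(
      graph$factors, by = "code", suffix = c(".q", ""),
      relationship = "many-to-many"
    ) |>
    filter(
      !is.na(.data$factor_id),
      is.na(.data$converted_value.q) |
        .data$converted_value.q == .data$converted_value
    )
  missing_clauses <- setdiff(clauses$.clause, matched_factors$.clause)
  if (length(missing_clauses)) {
    inform(paste0(
      "Clause(s) with no matching factor node: ",
      paste(clauses$code[missing_clauses], collapse = ", ")
    ))
  }
  pts <- graph$patients
  if (!is.null(query$label)) pts <- filter(pts, .data$label == query$label)
  hits <- graph$edges |>
    filter(.data$virtual_id %in% pts$virtual_id) |>
    inner_join(
      distinct(matched_factors, .data$factor_id, .data$.clause),
      by = "factor_id", relationship = "many-to-many"
    )
  matched_ids <- if (match == "any") {
    unique(hits$virtual_id)
  } else {
    hits |>
      distinct(.data$virtual_id, .data$.clause) |>
      count(.data$virtual_id) |>
      filter(.data$n == nrow(clauses)) |>
      pull(.data$virtual_id)
  }
  sub_edges <- graph$edges |>
    filter(
      .data$virtual_id %in% matched_ids,
      .data$factor_id %in% matched_factors$factor_id
    )
  new_patient_graph(
    filter(pts, .data$virtual_id %in% matched_ids),
    filter(graph$factors, .data$factor_id %in% unique(sub_edges$factor_id) |
             .data$factor_id %in% matched_factors$factor_id),
    sub_edges
  )
}
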