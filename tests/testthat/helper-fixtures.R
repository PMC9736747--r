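# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately use base-R loops over the raw edge list so they share no code
# with the graph implementation they check.

# A graph with one factor-value node wired to a chosen number of target and
# background patients, for exact CDR arithmetic.
toy_count_graph <- function(tpc, bpc, category = "Condition",
                            code = "C-0001", value = "true",
                            term = "Toy factor") {
  n <- tpc + bpc
  patients <- tibble::tibble(
    virtual_id = sprintf("_%04d", seq_len(max(n, 1))),
    label = rep(c(1L, 0L), c(tpc, bpc))[seq_len(max(n, 1))]
  )
  if (n == 0) patients <- patients[0, ]
  obs <- tibble::tibble(
    virtual_id = patients$virtual_id[seq_len(n)],
    category = category, code = code, term = term,
    value = value, unit = "", converted_value = value,
    date = as.Date("2021-06-01")
  )
  build_patient_graph(patients, obs)
}

# Random labeled-property-graph fixture: a handful of codes, some observed
# with two converted values, random patient-factor attachments.
random_graph_fixture <- function(n_patients = 30, n_codes = 6,
                                 p_edge = 0.3) {
  cats <- factor_categories()$category
  patients <- tibble::tibble(
    virtual_id = sprintf("_%04d", seq_len(n_patients)),
    label = sample(c(0L, 1L), n_patients, replace = TRUE)
  )
  codes <- sprintf("C-%06d", sample(1e5, n_codes))
  fac <- tibble::tibble(
    category = sample(cats, n_codes, replace = TRUE),
    code = codes,
    term = paste("Factor", codes),
    converted_value = sample(c("true", "up", "down"), n_codes, replace = TRUE)
  )
  # duplicate one code with a second value to exercise factor-value splitting
  fac <- dplyr::bind_rows(
    fac,
    dplyr::mutate(fac[1, ], converted_value = "abnormal")
  )
  grid <- tidyr::expand_grid(virtual_id = patients$virtual_id, row = seq_len(nrow(fac)))
  keep <- stats::runif(nrow(grid)) < p_edge
  obs <- dplyr::bind_cols(
    grid[keep, "virtual_id"],
    fac[grid$row[keep], ]
  ) |>
    dplyr::mutate(
      value = converted_value, unit = "", date = as.Date("2021-01-01")
    )
  list(
    patients = patients,
    observations = obs,
    graph = build_patient_graph(patients, obs)
  )
}

# Brute-force connection counts: scan the edge list, tally distinct
# patients per factor key and label.
oracle_counts <- function(graph) {
  labels <- stats::setNames(graph$patients$label, graph$patients$virtual_id)
  out <- list()
  seen <- character()
  for (i in seq_len(nrow(graph$edges))) {
    vid <- graph$edges$virtual_id[[i]]
    fid <- graph$edges$factor_id[[i]]
    pair <- paste(vid, fid)
    if (pair %in% seen) next
    seen <- c(seen, pair)
    if (is.null(out[[fid]])) out[[fid]] <- c(tpc = 0L, bpc = 0L)
    slot <- if (labels[[vid]] == 1L) "tpc" else "bpc"
    out[[fid]][[slot]] <- out[[fid]][[slot]] + 1L
  }
  out
}

# Brute-force disjunctive query: which patients hold at least one factor
# matching any clause (code + optional value), subject to a label filter.
oracle_query_patients <- function(graph, clauses, label = NULL) {
  labels <- stats::setNames(graph$patients$label, graph$patients$virtual_id)
  fac <- graph$factors
  hits <- character()
  for (i in seq_len(nrow(graph$edges))) {
    vid <- graph$edges$virtual_id[[i]]
    if (!is.null(label) && labels[[vid]] != label) next
    f <- fac[fac$factor_id == graph$edges$factor_id[[i]], ]
    for (j in seq_len(nrow(clauses))) {
      ok <- f$code == clauses$code[[j]] &&
        (is.na(clauses$converted_value[[j]]) ||
           f$converted_value == clauses$converted_value[[j]])
      if (ok) hits <- c(hits, vid)
    }
  }
  sort(unique(hits))
}

# The mock ontology with one biological and one medical neighbour plus
# distractor relations, used across the ontology-side tests.
mock_lc_ontology <- function() {
  extra <- tibble::tibble(
    cui = c("C0017337", "C0699142", "C0032285"),
    term = c("EGFR gene", "Cisplatin", "Pneumonia"),
    source_code = ""
  )
  concepts <- dplyr::bind_rows(lung_cancer_concepts(), extra)
  lc <- lung_cancer_concepts()$cui
  mock_ontology_config(
    concepts,
    hierarchy_edges = tibble::tibble(
      parent = "C0242379", child = setdiff(lc, "C0242379")
    ),
    horizontal_edges = tibble::tibble(
      cui1 = c("C0017337", "C0699142", "C0032285", "C0032285"),
      cui2 = c("C0242379", "C0007131", "C0242379", "C0242379"),
      rela = c(
        "gene_mapped_to_disease", "may_treat", "co-occurs_with", "inverse_isa"
      )
    )
  )
}
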