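#' Integrate the patient graph with a disease knowledge subgraph
#'
#' Splices the EMR patient graph onto the ontology side of the integrated
#' graph model through a single `AbstractPatient` node. The ontology side
#' follows the fixed four-level schema:
#'
#' * every `Patient` gets an `INSTANCE_OF` edge to the one `AbstractPatient`;
#' * `AbstractPatient` gets a `MAY_HAVE_TARGET` edge to every target
#'   (disease) concept;
#' * each target gets a `HAS_RELCAT` edge to one `RelCat` node per relation
#'   category (`biorel`/`medrel`) it actually uses;
#' * each `RelCat` node gets a `HAS_RELA` edge to every related concept,
#'   carrying the relationship attribute as an edge property.
#'
#' @param graph A [build_patient_graph()] result.
#' @param targets Target concepts: tibble with `cui` and `term`.
#' @param relations Classified horizontal relations from
#'   [find_horizontal_relations()].
#' @param concepts Concept tibble supplying terms for the related concepts
#'   (every `concept_cui` in `relations` must appear here).
#' @return An `integrated_graph` object: the patient graph plus tibbles
#'   `targets`, `relcats` (node key `relcat_id = cui × category`),
#'   `concepts` (related concepts only) and `ontology_edges`
#'   (`from`, `to`, `rel_label`, `rela`).
#' @export
build_integrated_graph <- function(graph, targets, relations, concepts) {
  stopifnot(inherits(graph, "patient_graph"))
  targets <- as_tibble(targets)
  relations <- as_tibble(relations)
  concepts <- as_tibble(concepts)
  missing_cui <- setdiff(
    c(relations$concept_cui, relations$target_cui),
    c(concepts$cui, targets$cui)
  )
  if (length(missing_cui)) {
    stop_integrity(paste0(
      "Relation(s) reference CUI(s) absent from the concept set: ",
      paste(head(missing_cui, 5), collapse = ", ")
    ))
  }
  if (nrow(relations) &&
        length(setdiff(relations$target_cui, targets$cui))) {
    stop_integrity("Every relation must start from a target concept.")
  }
  relcats <- relations |>
    distinct(.data$target_cui, .data$relcat) |>
    mutate(relcat_id = paste(.data$target_cui, .data$relcat, sep = "|"))
  related <- concepts |>
    filter(.data$cui %in% setdiff(relations$concept_cui, targets$cui)) |>
    distinct(.data$cui, .keep_all = TRUE)
  ontology_edges <- bind_rows(
    tibble(
      from = graph$patients$virtual_id, to = "AbstractPatient",
      rel_label = "INSTANCE_OF", rela = NA_character_
    ),
    tibble(
      from = "AbstractPatient", to = targets$cui,
      rel_label = "MAY_HAVE_TARGET", rela = NA_character_
    ),
    tibble(
      from = relcats$target_cui, to = relcats$relcat_id,
      rel_label = "HAS_RELCAT", rela = NA_character_
    ),
    relations |>
      mutate(relcat_id = paste(.data$target_cui, .data$relcat, sep = "|")) |>
      transmute(
        from = .data$relcat_id, to = .data$concept_cui,
        rel_label = "HAS_RELA", rela = .data$rela
      ) |>
      distinct()
  )
  structure(
    list(
      patient_graph = graph,
      targets = select(targets, dplyr::any_of(c("cui", "term", "source_code"))),
      relcats = relcats,
      concepts = related,
      relations = relations,
      ontology_edges = ontology_edges
    ),
    class = "integrated_graph"
  )
}

#' @export
print.integrated_graph <- function(x, ...) {
  cat("<integrated_graph> ", nrow(x$patient_graph$patients),
      " patients | AbstractPatient | ", nrow(x$targets),
      " target concepts, ", nrow(x$relcats), " RelCat nodes, ",
      nrow(x$concepts), " related concepts (",
      nrow(x$relations), " horizontal relations)\n", sep = "")
  invisible(x)
}

#' Profile one patient across the EMR and ontology sides
#'
#' The single-patient search of the integrated graph: returns the patient's
#' own factor nodes (EMR side) together with the full ontology chain
#' AbstractPatient -> TargetConcept -> RelCat -> Concept, i.e. everything a
#' clinician sees when asking for one patient's health factors next to the
#' curated disease knowledge.
#'
#' @param graph A `patient_graph` (the EMR side; usually
#'   `integrated$patient_graph`).
#' @param integrated An `integrated_graph`.
#' @param virtual_id The patient's id.
#' @return A `patient_profile` list: `patient` (one-row tibble), `factors`
#'   and `factor_edges` (EMR side), plus `targets`, `relcats`, `concepts`
#'   and `ontology_edges` (ontology side, including this patient's
#'   `INSTANCE_OF` edge only).
#' @export
patient_profile <- function(graph, integrated, virtual_id) {
  stopifnot(inherits(graph, "patient_graph"),
            inherits(integrated, "integrated_graph"))
  if (!virtual_id %in% graph$patients$virtual_id) {
    stop_not_found(paste0("Unknown patient virtual_id: ", virtual_id))
  }
  own_edges <- filter(graph$edges, .data$virtual_id == !!virtual_id)
  structure(
    list(
      patient = filter(graph$patients, .data$virtual_id == !!virtual_id),
      factors = filter(graph$factors, .data$factor_id %in% own_edges$factor_id),
      factor_edges = own_edges,
      targets = integrated$targets,
      relcats = integrated$relcats,
      concepts = integrated$concepts,
      ontology_edges = filter(
        integrated$ontology_edges,
        .data$rel_label != "INSTANCE_OF" | .data$from == !!virtual_id
      )
    ),
    class = "patient_profile"
  )
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile> ", x$patient$virtual_id, " (label ",
      x$patient$label, "): ", nrow(x$factors), " factor node(s); ontology: ",
      nrow(x$targets), " target(s), ", nrow(x$relcats), " RelCat(s), ",
      nrow(x$concepts), " concept(s)\n", sep = "")
  invisible(x)
}
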