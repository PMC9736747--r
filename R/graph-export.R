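#' Convert a graph object to an igraph
#'
#' Flattens the labeled property graph into an [igraph::igraph] with vertex
#' attributes `node_label`, `category`, `code`, `term`, `converted_value`,
#' `target_label` and edge attribute `rel_label` (plus `rela` on ontology
#' edges). Used for GraphML serialisation and ad-hoc network analysis.
#'
#' @param x A `patient_graph` or `integrated_graph`.
#' @param ... Unused.
#' @return An igraph object.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @rdname as_igraph
#' @export
as_igraph.patient_graph <- function(x, ...) {
  nodes <- graph_node_table(x)
  edges <- graph_edge_table(x)
  igraph::graph_from_data_frame(
    select(edges, "from", "to", "rel_label"),
    directed = TRUE, vertices = nodes
  )
}

#' @rdname as_igraph
#' @export
as_igraph.integrated_graph <- function(x, ...) {
  nodes <- bind_rows(graph_node_table(x$patient_graph), ontology_node_table(x))
  edges <- bind_rows(
    mutate(graph_edge_table(x$patient_graph), rela = NA_character_),
    select(x$ontology_edges, from = "from", to = "to", "rel_label", "rela")
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

graph_node_table <- function(graph) {
  bind_rows(
    transmute(
      graph$patients,
      id = .data$virtual_id, node_label = "Patient",
      category = NA_character_, code = NA_character_, term = NA_character_,
      converted_value = NA_character_,
      target_label = as.character(.data$label)
    ),
    transmute(
      graph$factors,
      id = .data$factor_id, node_label = .data$category,
      category = .data$category, code = .data$code, term = .data$term,
      converted_value = .data$converted_value, target_label = NA_character_
    )
  )
}

graph_edge_table <- function(graph) {
  transmute(
    graph$edges,
    from = .data$virtual_id, to = .data$factor_id, rel_label = .data$rel_label
  )
}

ontology_node_table <- function(x) {
  bind_rows(
    tibble(
      id = "AbstractPatient", node_label = "AbstractPatient",
      term = NA_character_
    ),
    transmute(
      x$targets, id = .data$cui, node_label = "TargetConcept", term = .data$term
    ),
    transmute(
      x$relcats, id = .data$relcat_id, node_label = "RelCat",
      term = .data$relcat
    ),
    transmute(
      x$concepts, id = .data$cui, node_label = "Concept", term = .data$term
    )
  ) |>
    mutate(
      category = NA_character_, code = NA_character_,
      converted_value = NA_character_, target_label = NA_character_
    )
}

#' Export a graph for bulk import or inspection
#'
#' Serialises a `patient_graph` or `integrated_graph` in one of three
#' formats:
#'
#' * `"csv"` — bulk-import node/edge tables (`nodes.csv`, `edges.csv`) whose
#'   columns carry the node-key fields; [import_graph_csv()] reconstructs an
#'   isomorphic patient graph from them.
#' * `"graphml"` — a single GraphML file (via igraph).
#' * `"cypher"` — a property-graph statement script: uniqueness constraints,
#'   one `CREATE` per node and one `MATCH ... CREATE` per relationship,
#'   using the compact property names of the query dialect (`vpid`, `label`,
#'   `cat`, `code`, `valcvt`).
#'
#' @param x A `patient_graph` or `integrated_graph`.
#' @param path Output directory for `"csv"`; output file otherwise.
#' @param format `"csv"`, `"graphml"` or `"cypher"`.
#' @return Invisibly, the path(s) written.
#' @export
export_graph <- function(x, path, format = c("csv", "graphml", "cypher")) {
  format <- tryCatch(
    match.arg(format),
    error = function(e) stop_config(paste0(
      "Unknown export format '", format[[1]],
      "'; use 'csv', 'graphml' or 'cypher'."
    ))
  )
  pg <- if (inherits(x, "integrated_graph")) x$patient_graph else x
  stopifnot(inherits(pg, "patient_graph"))
  switch(format,
    csv = {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      nodes <- if (inherits(x, "integrated_graph")) {
        bind_rows(graph_node_table(pg), ontology_node_table(x))
      } else {
        graph_node_table(pg)
      }
      edges <- if (inherits(x, "integrated_graph")) {
        bind_rows(
          mutate(graph_edge_table(pg), rela = NA_character_),
          select(x$ontology_edges, from = "from", to = "to", "rel_label", "rela")
        )
      } else {
        graph_edge_table(pg)
      }
      paths <- file.path(path, c("nodes.csv", "edges.csv"))
      readr::write_csv(nodes, paths[[1]], progress = FALSE)
      readr::write_csv(edges, paths[[2]], progress = FALSE)
      invisible(paths)
    },
    graphml = {
      igraph::write_graph(as_igraph(x), path, format = "graphml")
      invisible(path)
    },
    cypher = {
      writeLines(cypher_script(x), path)
      invisible(path)
    }
  )
}

#' Re-import a bulk-exported patient graph
#'
#' Reads the `nodes.csv`/`edges.csv` pair written by
#' `export_graph(format = "csv")` and reconstructs the patient graph
#' (ontology rows, if present, are ignored — rebuild the integrated graph
#' from its inputs instead).
#'
#' @param dir Directory containing `nodes.csv` and `edges.csv`.
#' @return A `patient_graph`.
#' @export
import_graph_csv <- function(dir) {
  nodes <- readr::read_csv(
    file.path(dir, "nodes.csv"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  edges <- readr::read_csv(
    file.path(dir, "edges.csv"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  patients <- nodes |>
    filter(.data$node_label == "Patient") |>
    transmute(
      virtual_id = .data$id, label = as.integer(.data$target_label)
    )
  factors <- nodes |>
    filter(.data$node_label %in% factor_categories()$category) |>
    select(
      factor_id = "id", "category", "code", "term", "converted_value"
    )
  pg_edges <- edges |>
    filter(.data$rel_label %in% factor_categories()$rel_label) |>
    select(virtual_id = "from", factor_id = "to", "rel_label")
  new_patient_graph(patients, factors, pg_edges)
}

cypher_script <- function(x) {
  pg <- if (inherits(x, "integrated_graph")) x$patient_graph else x
  q <- function(s) paste0("'", gsub("'", "\\\\'", s), "'")
  out <- c(
    "CREATE CONSTRAINT patient_key IF NOT EXISTS FOR (p:Patient) REQUIRE p.vpid IS UNIQUE;",
    sprintf(
      "CREATE (:Patient {vpid: %s, label: %s});",
      q(pg$patients$virtual_id), q(as.character(pg$patients$label))
    ),
    sprintf(
      "CREATE (:%s {cat: %s, code: %s, term: %s, valcvt: %s});",
      pg$factors$category, q(category_short(pg$factors$category)),
      q(pg$factors$code), q(pg$factors$term), q(pg$factors$converted_value)
    )
  )
  ek <- pg$edges |> left_join(pg$factors, by = "factor_id")
  out <- c(out, sprintf(
    paste0(
      "MATCH (p:Patient {vpid: %s}), (f:%s {code: %s, valcvt: %s}) ",
      "CREATE (p)-[:%s]->(f);"
    ),
    q(ek$virtual_id), ek$category, q(ek$code), q(ek$converted_value),
    ek$rel_label
  ))
  if (inherits(x, "integrated_graph")) {
    out <- c(
      out,
      "CREATE (:AbstractPatient {name: 'AbstractPatient'});",
      sprintf(
        "CREATE (:TargetConcept {cui: %s, term: %s});",
        q(x$targets$cui), q(x$targets$term)
      ),
      sprintf(
        "CREATE (:RelCat {id: %s, name: %s});",
        q(x$relcats$relcat_id), q(x$relcats$relcat)
      ),
      sprintf(
        "CREATE (:Concept {cui: %s, term: %s});",
        q(x$concepts$cui), q(x$concepts$term)
      )
    )
  }
  out
}
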