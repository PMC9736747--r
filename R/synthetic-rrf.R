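#' The expanded lung-cancer concept set
#'
#' The eight UMLS concepts that the lung-cancer hierarchy expands to,
#' starting from the malignant-neoplasm-of-lung concept `C0242379`: the
#' suspected, small-cell, non-small-cell, adeno-, squamous-cell, primary and
#' secondary lung-cancer concepts. Shipped as a built-in table because it is
#' the canonical worked example for hierarchy expansion and the default seed
#' set for mock-ontology fixtures.
#'
#' @return A tibble with columns `cui`, `term`, `source_code` (SNOMED CT).
#' @examples
#' lung_cancer_concepts()
#' @export
lung_cancer_concepts <- function() {
  tibble(
    cui = c(
      "C0581834", "C0242379", "C0149925", "C0007131",
      "C0152013", "C0149782", "C1306460", "C0153676"
    ),
    term = c(
      "Suspected lung cancer",
      "Malignant neoplasm of lung",
      "Small cell carcinoma of lung",
      "Non-Small Cell Lung Carcinoma",
      "Adenocarcinoma of lung (disorder)",
      "Squamous cell carcinoma of lung",
      "Primary malignant neoplasm of lung",
      "Secondary malignant neoplasm of lung"
    ),
    source_code = c(
      "162573006", "363358000", "254632001", "254637007",
      "254626006", "254634000", "93880001", "94391008"
    )
  )
}

#' Relation-category (RelCat) attribute lists
#'
#' Loads the editable vocabulary of UMLS relationship attributes (RELA) kept
#' when filtering horizontal disease relations, split into biological
#' (`biorel`: gene-disease associations, biomarkers, cytogenetic and
#' molecular abnormalities) and medical (`medrel`: treatments, findings,
#' associated diseases, co-occurrence) relation categories. The two lists
#' must be disjoint; this is asserted at load.
#'
#' @param path Path to a YAML file with top-level keys `biorel` and
#'   `medrel`; defaults to the vocabulary shipped with the package.
#' @return A named list of two character vectors, classes `biorel` and
#'   `medrel`.
#' @export
relcat_attributes <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "relcat_attributes.yaml", package = "cdrgraph")
  lists <- yaml::read_yaml(path)
  if (!all(c("biorel", "medrel") %in% names(lists))) {
    stop_config("Attribute file must define 'biorel' and 'medrel' lists.")
  }
  lists <- lapply(lists[c("biorel", "medrel")], as.character)
  if (length(intersect(lists$biorel, lists$medrel))) {
    stop_config("biorel and medrel attribute lists must be disjoint.")
  }
  lists
}

#' Configure a mock UMLS-style ontology
#'
#' Describes a miniature concept/relation release used to exercise the RRF
#' parsers, hierarchy expansion and relation filtering without a licensed
#' ontology download. Defaults to the lung-cancer concept set with the
#' hierarchy rooted at `C0242379`.
#'
#' @param concepts Tibble with columns `cui`, `term` and optionally
#'   `source_code`.
#' @param hierarchy_edges Tibble with columns `parent`, `child` (CUIs).
#' @param horizontal_edges Tibble with columns `cui1`, `cui2`, `rela`
#'   (relationship attribute string; distractor values are allowed and will
#'   be filtered downstream).
#' @param seed_cuis CUIs used as expansion starting points.
#' @return A `mock_ontology_config` object.
#' @examples
#' cfg <- mock_ontology_config()
#' nrow(cfg$concepts)
#' @export
mock_ontology_config <- function(concepts = lung_cancer_concepts(),
                                 hierarchy_edges = NULL,
                                 horizontal_edges = NULL,
                                 seed_cuis = "C0242379") {
  concepts <- as_tibble(concepts)
  if (!all(c("cui", "term") %in% names(concepts))) {
    stop_config("concepts must have columns 'cui' and 'term'.")
  }
  if (!"source_code" %in% names(concepts)) concepts$source_code <- ""
  if (is.null(hierarchy_edges)) {
    lc <- lung_cancer_concepts()
    hierarchy_edges <- if (identical(concepts$cui, lc$cui)) {
      tibble(parent = "C0242379", child = setdiff(lc$cui, "C0242379"))
    } else {
      tibble(parent = character(), child = character())
    }
  }
  hierarchy_edges <- as_tibble(hierarchy_edges)
  horizontal_edges <- as_tibble(
    horizontal_edges %||%
      tibble(cui1 = character(), cui2 = character(), rela = character())
  )
  referenced <- c(
    hierarchy_edges$parent, hierarchy_edges$child,
    horizontal_edges$cui1, horizontal_edges$cui2, seed_cuis
  )
  unknown <- setdiff(referenced, concepts$cui)
  if (length(unknown)) {
    stop_config(paste(
      "Edge or seed references unknown CUI(s):",
      paste(unknown, collapse = ", ")
    ))
  }
  structure(
    list(
      concepts = concepts,
      hierarchy_edges = hierarchy_edges,
      horizontal_edges = horizontal_edges,
      seed_cuis = seed_cuis
    ),
    class = "mock_ontology_config"
  )
}

# RRF dialect: pipe-delimited, trailing pipe, no header.
# MRCONSO has 18 fields (CUI first, STR 15th), MRREL 16 fields
# (CUI1, AUI1, STYPE1, REL, RELA, CUI2, ...).
rrf_line <- function(fields, n_fields) {
  fields <- c(fields, rep("", n_fields - length(fields)))
  paste0(paste(fields, collapse = "|"), "|")
}

#' Generate mock MRCONSO/MRREL file content
#'
#' Emits the configured concepts and relations in the rich release format
#' dialect: pipe-delimited rows with a trailing pipe and the standard column
#' layout (18 columns for the concept file with the term string in the STR
#' position; 16 for the relation file with CUI1/REL/RELA/CUI2). Hierarchy
#' edges are written as `CUI1 = parent, REL = CHD, CUI2 = child` (REL being
#' the relation of the second concept to the first); horizontal edges get
#' `REL = RO` and their configured RELA.
#'
#' @param config A [mock_ontology_config()].
#' @return A list with character scalars `mrconso` and `mrrel` (file
#'   content, one row per line).
#' @examples
#' rrf <- generate_mock_rrf(mock_ontology_config())
#' length(strsplit(rrf$mrconso, "\n")[[1]])
#' @export
generate_mock_rrf <- function(config) {
  stopifnot(inherits(config, "mock_ontology_config"))
  con <- config$concepts
  i <- seq_len(nrow(con))
  conso <- purrr::map_chr(i, function(k) {
    rrf_line(c(
      con$cui[[k]], "ENG", "P", sprintf("L%07d", k), "PF",
      sprintf("S%07d", k), "Y", sprintf("A%07d", k), "", "", "",
      "SNOMEDCT_US", "PT", con$source_code[[k]], con$term[[k]], "0", "N", ""
    ), 18)
  })
  hier <- config$hierarchy_edges
  horiz <- config$horizontal_edges
  rel_rows <- c(
    purrr::map_chr(seq_len(nrow(hier)), function(k) {
      rrf_line(c(
        hier$parent[[k]], "", "CUI", "CHD", "", hier$child[[k]], "", "CUI",
        sprintf("R%07d", k), "", "SNOMEDCT_US", "SNOMEDCT_US", "", "", "N", ""
      ), 16)
    }),
    purrr::map_chr(seq_len(nrow(horiz)), function(k) {
      rrf_line(c(
        horiz$cui1[[k]], "", "CUI", "RO", horiz$rela[[k]], horiz$cui2[[k]],
        "", "CUI", sprintf("R%07d", nrow(hier) + k), "", "NCI", "NCI",
        "", "", "N", ""
      ), 16)
    })
  )
  list(
    mrconso = paste0(paste(conso, collapse = "\n"), "\n"),
    mrrel = if (length(rel_rows)) {
      paste0(paste(rel_rows, collapse = "\n"), "\n")
    } else {
      ""
    }
  )
}

#' Write mock RRF files to disk
#'
#' @param config A [mock_ontology_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of `MRCONSO.RRF` and `MRREL.RRF`.
#' @export
write_mock_rrf <- function(config, dir) {
  rrf <- generate_mock_rrf(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("MRCONSO.RRF", "MRREL.RRF"))
  writeLines(sub("\n$", "", rrf$mrconso), paths[[1]])
  writeLines(sub("\n$", "", rrf$mrrel), paths[[2]])
  invisible(paths)
}
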