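#' Parse an MRCONSO-dialect concept file
#'
#' Reads the pipe-delimited, trailing-pipe concept file of a rich release
#' format (RRF) distribution: 18 columns with the concept unique identifier
#' (CUI) first, the language (LAT) second, the source vocabulary code (CODE)
#' fourteenth and the term string (STR) fifteenth. Rows are filtered to one
#' language and deduplicated to one preferred term per CUI, taken as the
#' first retained row in file order (only display strings depend on this
#' choice).
#'
#' @param file Path to an RRF file, or literal file content.
#' @param language Language rows to keep (default `"ENG"`); `NULL` keeps all.
#' @return A tibble with columns `cui`, `term`, `source_code`, `language`.
#' @export
parse_mrconso <- function(file, language = "ENG") {
  rows <- read_rrf(file, n_fields = 18, what = "MRCONSO")
  if (nrow(rows) == 0) {
    return(tibble(
      cui = character(), term = character(),
      source_code = character(), language = character()
    ))
  }
  out <- tibble(
    cui = rows[[1]], language = rows[[2]],
    source_code = rows[[14]], term = rows[[15]]
  )
  if (!is.null(language)) out <- filter(out, .data$language == !!language)
  out |>
    distinct(.data$cui, .keep_all = TRUE) |>
    select("cui", "term", "source_code", "language")
}

#' Parse an MRREL-dialect relation file
#'
#' Reads the 16-column RRF relation file: CUI1 first, the coarse relation
#' type REL fourth (the relation of the second concept to the first), the
#' fine-grained relationship attribute RELA fifth and CUI2 sixth.
#' Self-relations (CUI1 = CUI2) are dropped with a message. Classification
#' into hierarchical versus horizontal relations is deferred to
#' [expand_target_concepts()] and [find_horizontal_relations()].
#'
#' @param file Path to an RRF file, or literal file content.
#' @return A tibble with columns `cui1`, `rel`, `rela`, `cui2`.
#' @export
parse_mrrel <- function(file) {
  rows <- read_rrf(file, n_fields = 16, what = "MRREL")
  if (nrow(rows) == 0) {
    return(tibble(
      cui1 = character(), rel = character(),
      rela = character(), cui2 = character()
    ))
  }
  out <- tibble(
    cui1 = rows[[1]], rel = rows[[4]], rela = rows[[5]], cui2 = rows[[6]]
  )
  n_self <- sum(out$cui1 == out$cui2)
  if (n_self > 0) {
    inform(paste0("Dropped ", n_self, " self-relation(s) (CUI1 = CUI2)."))
  }
  filter(out, .data$cui1 != .data$cui2)
}

# Shared RRF reader: tolerant of the trailing pipe, strict on column count.
read_rrf <- function(file, n_fields, what) {
  lines <- if (is.character(file) && length(file) == 1 &&
                 !grepl("\n", file) && file.exists(file)) {
    readr::read_lines(file, progress = FALSE)
  } else {
    readr::read_lines(I(paste(file, collapse = "\n")), progress = FALSE)
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(as_tibble(matrix(character(), 0, n_fields), .name_repair = "minimal"))
  }
  parts <- strsplit(lines, "|", fixed = TRUE)
  # A well-formed row "f1|f2|...|fn|" carries exactly n_fields pipes (one
  # per field, the last one trailing). strsplit drops empty trailing
  # fields, so validate on the pipe count and pad the split.
  n_pipes <- nchar(lines) - nchar(gsub("|", "", lines, fixed = TRUE))
  bad <- which(n_pipes != n_fields | !endsWith(lines, "|"))
  if (length(bad)) {
    stop_parse(paste0(
      what, " row(s) with wrong column count or missing trailing pipe ",
      "at line(s): ", paste(head(bad, 5), collapse = ", "),
      " (expected ", n_fields, " pipe-delimited fields)."
    ))
  }
  mat <- t(vapply(
    parts, function(p) c(p, rep("", n_fields - length(p))),
    character(n_fields)
  ))
  colnames(mat) <- paste0("V", seq_len(n_fields))
  as_tibble(mat)
}

#' Expand seed disease concepts over the ontology hierarchy
#'
#' Starting from one or more seed CUIs, follows hierarchical relations
#' (coarse relation types `PAR`/`CHD` by default) transitively and returns
#' the seeds plus every concept reached, restricted to the supplied concept
#' set. The traversal uses a visited set, so cyclic fixtures terminate. By
#' default edges are followed in both directions (`direction = "both"`),
#' which captures sibling and suspected-disease concepts that a strict
#' descendant walk would miss; `"down"`/`"up"` restrict to
#' children/parents of the seeds.
#'
#' @param seeds Character vector of seed CUIs; each must appear in
#'   `concepts`.
#' @param concepts Concept tibble from [parse_mrconso()].
#' @param relations Relation tibble from [parse_mrrel()].
#' @param direction `"both"` (default), `"down"` or `"up"`.
#' @param hier_rel Coarse relation types treated as hierarchical.
#' @return The subset of `concepts` reachable from the seeds (seeds first,
#'   then expansion order).
#' @examples
#' rrf <- generate_mock_rrf(mock_ontology_config())
#' con <- parse_mrconso(rrf$mrconso)
#' rel <- parse_mrrel(rrf$mrrel)
#' expand_target_concepts("C0242379", con, rel)
#' @export
expand_target_concepts <- function(seeds, concepts, relations,
                                   direction = c("both", "down", "up"),
                                   hier_rel = c("PAR", "CHD")) {
  direction <- match.arg(direction)
  unknown <- setdiff(seeds, concepts$cui)
  if (length(unknown)) {
    stop_not_found(paste0(
      "Seed CUI(s) not present in the concept set: ",
      paste(unknown, collapse = ", ")
    ))
  }
  hier <- filter(relations, .data$rel %in% hier_rel)
  # Orient every hierarchy row parent -> child: REL is the relation of CUI2
  # to CUI1, so REL = CHD means CUI2 is a child of CUI1.
  down <- tibble(
    from = ifelse(hier$rel == "CHD", hier$cui1, hier$cui2),
    to = ifelse(hier$rel == "CHD", hier$cui2, hier$cui1)
  )
  edges <- switch(direction,
    down = down,
    up = tibble(from = down$to, to = down$from),
    both = tibble(from = c(down$from, down$to), to = c(down$to, down$from))
  )
  visited <- character()
  frontier <- unique(seeds)
  while (length(frontier)) {
    visited <- c(visited, frontier)
    nxt <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(nxt, visited)
  }
  found <- intersect(visited, concepts$cui)
  concepts[match(found, concepts$cui), ]
}

#' Find and classify horizontal disease relations
#'
#' Scans the relation table for non-hierarchical relations linking a target
#' concept to any other concept, keeps only those whose relationship
#' attribute (RELA) belongs to the configured biological or medical
#' vocabulary ([relcat_attributes()]), classifies each as `biorel` or
#' `medrel`, and collapses bidirectional duplicates to one undirected record
#' per (target, other, RELA) triple. Relations between two targets and
#' hierarchical rows are excluded; unmatched RELA values are counted in a
#' message.
#'
#' @param targets Character vector of target CUIs, or a concept tibble with
#'   a `cui` column.
#' @param relations Relation tibble from [parse_mrrel()].
#' @param attributes The RELA vocabulary, a list with elements `biorel` and
#'   `medrel` (default: the shipped lists).
#' @param hier_rel Coarse relation types treated as hierarchical.
#' @return A tibble with columns `target_cui`, `relcat` (`"biorel"` or
#'   `"medrel"`), `concept_cui`, `rela`.
#' @export
find_horizontal_relations <- function(targets, relations,
                                      attributes = relcat_attributes(),
                                      hier_rel = c("PAR", "CHD")) {
  if (is.data.frame(targets)) targets <- targets$cui
  if (!length(targets)) stop_config("targets must be non-empty.")
  horiz <- relations |>
    filter(
      !.data$rel %in% hier_rel,
      xor(.data$cui1 %in% targets, .data$cui2 %in% targets)
    )
  vocab <- c(attributes$biorel, attributes$medrel)
  n_unmatched <- sum(!horiz$rela %in% vocab)
  if (n_unmatched > 0) {
    inform(paste0(
      n_unmatched, " horizontal relation(s) dropped: RELA outside the ",
      "biorel/medrel vocabulary."
    ))
  }
  horiz |>
    filter(.data$rela %in% vocab) |>
    mutate(
      target_cui = ifelse(.data$cui1 %in% targets, .data$cui1, .data$cui2),
      concept_cui = ifelse(.data$cui1 %in% targets, .data$cui2, .data$cui1),
      relcat = ifelse(.data$rela %in% attributes$biorel, "biorel", "medrel")
    ) |>
    distinct(.data$target_cui, .data$concept_cui, .data$rela, .keep_all = TRUE) |>
    select("target_cui", "relcat", "concept_cui", "rela")
}
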