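test_that("MRCONSO parsing recovers the concept fixture", {
  rrf <- generate_mock_rrf(mock_ontology_config())
  con <- parse_mrconso(rrf$mrconso)
  expect_equal(nrow(con), 8)
  expect_equal(con$cui, lung_cancer_concepts()$cui)
  expect_equal(con$term, lung_cancer_concepts()$term)
  expect_equal(con$source_code, lung_cancer_concepts()$source_code)

  expect_equal(nrow(parse_mrconso("")), 0)
})

test_that("MRCONSO keeps one preferred term per CUI and honours the language filter", {
  two_rows <- paste0(
    "C0000001|ENG|P|L1|PF|S1|Y|A1||||SRC|PT|X|First term|0|N||\n",
    "C0000001|ENG|S|L2|PF|S2|N|A2||||SRC|SY|X|Second term|0|N||\n",
    "C0000002|FRE|P|L3|PF|S3|Y|A3||||SRC|PT|X|Terme|0|N||"
  )
  con <- parse_mrconso(two_rows)
  expect_equal(nrow(con), 1)
  expect_equal(con$term, "First term")
  expect_equal(nrow(parse_mrconso(two_rows, language = NULL)), 2)
})

test_that("malformed RRF rows fail with the offending line number", {
  bad <- "C0000001|ENG|P|L1|PF|S1|Y|A1||||SRC|PT|X|Term|0|N||\nC0000002|ENG|broken"
  err <- tryCatch(parse_mrconso(bad), error = identity)
  expect_s3_class(err, "cdrgraph_parse_error")
  expect_match(conditionMessage(err), "2")
})

test_that("MRREL parsing drops self-relations and keeps REL/RELA", {
  rrf <- generate_mock_rrf(mock_lc_ontology())
  rel <- parse_mrrel(rrf$mrrel)
  expect_true(all(rel$cui1 != rel$cui2))
  expect_setequal(unique(rel$rel), c("CHD", "RO"))

  selfrow <- "C0000001||CUI|RO|related_to|C0000001||CUI|R1||SRC|SRC|||N||"
  expect_message(out <- parse_mrrel(selfrow), regexp = "self-relation")
  expect_equal(nrow(out), 0)
})

test_that("hierarchy expansion reaches the full concept family once", {
  rrf <- generate_mock_rrf(mock_lc_ontology())
  con <- parse_mrconso(rrf$mrconso)
  rel <- parse_mrrel(rrf$mrrel)
  targets <- expand_target_concepts("C0242379", con, rel)
  expect_equal(nrow(targets), 8)
  expect_setequal(targets$cui, lung_cancer_concepts()$cui)
  expect_equal(anyDuplicated(targets$cui), 0)
})

test_that("expansion handles isolated seeds, cycles, and unknown seeds", {
  con <- tibble::tibble(
    cui = c("A", "B", "C", "D"), term = letters[1:4],
    source_code = "", language = "ENG"
  )
  # cycle A->B->C->A (parent->child), D isolated
  rel <- tibble::tibble(
    cui1 = c("A", "B", "C"), rel = "CHD", rela = "",
    cui2 = c("B", "C", "A")
  )
  got <- expand_target_concepts("A", con, rel)
  expect_setequal(got$cui, c("A", "B", "C"))
  lone <- expand_target_concepts("D", con, rel)
  expect_equal(lone$cui, "D")
  expect_error(expand_target_concepts("Z", con, rel),
               class = "cdrgraph_not_found_error")
})

test_that("expansion is monotone in seeds and idempotent", {
  rrf <- generate_mock_rrf(mock_lc_ontology())
  con <- parse_mrconso(rrf$mrconso)
  rel <- parse_mrrel(rrf$mrrel)
  small <- expand_target_concepts("C0149925", con, rel, direction = "up")
  bigger <- expand_target_concepts(c("C0149925", "C0242379"), con, rel,
                                   direction = "up")
  expect_true(all(small$cui %in% bigger$cui))
  again <- expand_target_concepts(small$cui, con, rel, direction = "up")
  expect_setequal(again$cui, small$cui)
})

test_that("horizontal relations are attribute-filtered, classified and deduplicated", {
  cfg <- mock_lc_ontology()
  rrf <- generate_mock_rrf(cfg)
  con <- parse_mrconso(rrf$mrconso)
  rel <- parse_mrrel(rrf$mrrel)
  targets <- expand_target_concepts("C0242379", con, rel)
  expect_message(
    hr <- find_horizontal_relations(targets, rel),
    regexp = "vocabulary"
  ) # the inverse_isa distractor is dropped
  expect_equal(nrow(hr), 3)
  expect_equal(
    hr$relcat[hr$rela == "gene_mapped_to_disease"], "biorel"
  )
  expect_equal(hr$relcat[hr$rela == "may_treat"], "medrel")
  expect_false("inverse_isa" %in% hr$rela)
})

test_that("bidirectional duplicate rows collapse to one undirected record", {
  rel <- tibble::tibble(
    cui1 = c("C1", "C9", "C1", "C2"),
    rel = "RO",
    rela = c("may_treat", "may_treat", "co-occurs_with", "may_treat"),
    cui2 = c("C9", "C1", "C9", "C1")
  )
  hr <- find_horizontal_relations("C1", rel)
  expect_equal(nrow(hr), 3)
  expect_equal(sum(hr$rela == "may_treat" & hr$concept_cui == "C9"), 1)
  expect_true(all(hr$target_cui == "C1"))
})

test_that("relations between two targets and empty target sets are rejected", {
  rel <- tibble::tibble(
    cui1 = "C1", rel = "RO", rela = "may_treat", cui2 = "C2"
  )
  hr <- find_horizontal_relations(c("C1", "C2"), rel)
  expect_equal(nrow(hr), 0)
  expect_error(find_horizontal_relations(character(), rel),
               class = "cdrgraph_config_error")
})

test_that("the shipped biorel and medrel vocabularies are disjoint and complete", {
  attrs <- relcat_attributes()
  expect_length(attrs$biorel, 7)
  expect_length(attrs$medrel, 11)
  expect_length(intersect(attrs$biorel, attrs$medrel), 0)
  expect_true(all(c("gene_mapped_to_disease", "may_treat") %in%
                    unlist(attrs)))
})

test_that("the integrated graph follows the four-level ontology schema", {
  cfg <- mock_lc_ontology()
  rrf <- generate_mock_rrf(cfg)
  con <- parse_mrconso(rrf$mrconso)
  rel <- parse_mrrel(rrf$mrrel)
  targets <- expand_target_concepts("C0242379", con, rel)
  hr <- suppressMessages(find_horizontal_relations(targets, rel))
  pg <- toy_count_graph(2, 1)
  ig <- build_integrated_graph(pg, targets, hr, con)

  # no-relation case: targets but no RelCat nodes
  bare <- build_integrated_graph(pg, targets, hr[0, ], con)
  expect_equal(nrow(bare$relcats), 0)
  expect_equal(nrow(bare$concepts), 0)
  expect_equal(sum(bare$ontology_edges$rel_label == "MAY_HAVE_TARGET"), 8)

  # one biorel + one medrel neighbour of C0242379 -> 2 RelCat nodes there
  expect_equal(sum(ig$relcats$target_cui == "C0242379"), 2)
  expect_equal(nrow(ig$concepts), 3)
  expect_true(all(ig$ontology_edges$rel_label %in%
                    c("INSTANCE_OF", "MAY_HAVE_TARGET", "HAS_RELCAT", "HAS_RELA")))
  # every patient hooks onto the single AbstractPatient
  inst <- ig$ontology_edges[ig$ontology_edges$rel_label == "INSTANCE_OF", ]
  expect_setequal(inst$from, pg$patients$virtual_id)
  expect_equal(unique(inst$to), "AbstractPatient")
})

test_that("every ontology node is within four hops of AbstractPatient", {
  cfg <- mock_lc_ontology()
  rrf <- generate_mock_rrf(cfg)
  con <- parse_mrconso(rrf$mrconso)
  rel <- parse_mrrel(rrf$mrrel)
  targets <- expand_target_concepts("C0242379", con, rel)
  hr <- suppressMessages(find_horizontal_relations(targets, rel))
  ig <- build_integrated_graph(toy_count_graph(1, 1), targets, hr, con)
  net <- as_igraph(ig)
  d <- igraph::distances(net, v = "AbstractPatient", mode = "out")
  onto_ids <- c(ig$targets$cui, ig$relcats$relcat_id, ig$concepts$cui)
  expect_true(all(d[1, onto_ids] <= 4))
})

test_that("relations referencing unknown concepts are an integrity error", {
  targets <- lung_cancer_concepts()
  hr <- tibble::tibble(
    target_cui = "C0242379", relcat = "medrel",
    concept_cui = "C404NOPE", rela = "may_treat"
  )
  expect_error(
    build_integrated_graph(toy_count_graph(1, 1), targets, hr,
                           lung_cancer_concepts()),
    class = "cdrgraph_integrity_error"
  )
})

test_that("a patient profile pairs the EMR side with the full ontology chain", {
  cfg <- mock_lc_ontology()
  rrf <- generate_mock_rrf(cfg)
  con <- parse_mrconso(rrf$mrconso)
  rel <- parse_mrrel(rrf$mrrel)
  targets <- expand_target_concepts("C0242379", con, rel)
  hr <- suppressMessages(find_horizontal_relations(targets, rel))
  pg <- toy_count_graph(3, 2, code = "C-765209", term = "Obstructive pneumonia")
  ig <- build_integrated_graph(pg, targets, hr, con)
  pp <- patient_profile(pg, ig, "_0001")
  expect_equal(nrow(pp$factors), 1)
  expect_equal(nrow(pp$concepts), 3)
  expect_equal(sum(pp$ontology_edges$rel_label == "INSTANCE_OF"), 1)
  expect_error(patient_profile(pg, ig, "_nope"),
               class = "cdrgraph_not_found_error")

  # zero-factor patient: only the ontology side comes back
  pts <- dplyr::bind_rows(pg$patients,
                          tibble::tibble(virtual_id = "_lone", label = 1L))
  pg2 <- build_patient_graph(
    pts,
    tibble::tibble(
      virtual_id = pg$edges$virtual_id, category = "Condition",
      code = "C-765209", term = "Obstructive pneumonia", value = "true",
      unit = "", converted_value = "true", date = as.Date("2021-01-01")
    )
  )
  ig2 <- build_integrated_graph(pg2, targets, hr, con)
  lone <- patient_profile(pg2, ig2, "_lone")
  expect_equal(nrow(lone$factors), 0)
  expect_equal(nrow(lone$targets), 8)
})

test_that("profile connects patient and concepts in one component", {
  cfg <- mock_lc_ontology()
  rrf <- generate_mock_rrf(cfg)
  con <- parse_mrconso(rrf$mrconso)
  rel <- parse_mrrel(rrf$mrrel)
  targets <- expand_target_concepts("C0242379", con, rel)
  hr <- suppressMessages(find_horizontal_relations(targets, rel))
  pg <- toy_count_graph(1, 1)
  ig <- build_integrated_graph(pg, targets, hr, con)
  net <- as_igraph(ig)
  comp <- igraph::components(net, mode = "weak")
  expect_equal(
    comp$membership[["_0001"]],
    comp$membership[[ig$concepts$cui[[1]]]]
  )
})
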