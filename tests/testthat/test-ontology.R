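test_that("parse_obo builds the term DAG from stanzas", {
  empty <- parse_obo(text = character())
  expect_equal(n_terms(empty), 0L)

  g <- parse_obo(text = chain_obo())
  expect_equal(n_terms(g), 3L)
  expect_equal(igraph::gsize(g$graph), 2L)
  expect_equal(g$roots, "GO:0000001")

  with_obsolete <- c(chain_obo(),
                     "[Term]", "id: GO:0000004", "name: gone",
                     "namespace: biological_process", "is_obsolete: true")
  expect_equal(n_terms(parse_obo(text = with_obsolete)), 3L)
})

test_that("parse_obo honours alt_id, part_of and rejects bad input", {
  txt <- c("[Term]", "id: GO:0000001", "name: root",
           "namespace: biological_process", "alt_id: GO:0099999",
           "[Term]", "id: GO:0000002", "name: part",
           "namespace: biological_process",
           "relationship: part_of GO:0000001 ! root",
           "[Term]", "id: GO:0000003", "name: reg",
           "namespace: biological_process",
           "is_a: GO:0000001 ! root",
           "relationship: regulates GO:0000002 ! part")
  expect_message(g <- parse_obo(text = txt), "ignored 1 relationship")
  expect_equal(unname(g$alt_ids["GO:0099999"]), "GO:0000001")
  rel <- igraph::E(g$graph)$relation
  expect_setequal(rel, c("part_of", "is_a"))

  expect_error(parse_obo(text = c("[Term]", "name: anonymous")),
               "stanza 1 has no id")
  cyc <- c("[Term]", "id: A", "name: a", "namespace: biological_process",
           "is_a: B", "[Term]", "id: B", "name: b",
           "namespace: biological_process", "is_a: A")
  expect_error(parse_obo(text = cyc), "cycle involving terms")
})

test_that("extract_aspect induces the single-aspect subgraph", {
  txt <- c(chain_obo(),
           "[Term]", "id: GO:0000010", "name: mf root",
           "namespace: molecular_function")
  g <- parse_obo(text = txt)
  bp <- extract_aspect(g, "biological_process")
  expect_equal(n_terms(bp), 3L)
  expect_equal(bp$aspect, "biological_process")
  mf <- extract_aspect(g, "molecular_function")
  expect_equal(n_terms(mf), 1L)
  # aspects partition the node set
  expect_equal(n_terms(bp) + n_terms(mf), n_terms(g))
  expect_error(extract_aspect(bp0 <- parse_obo(text = chain_obo()),
                              "cellular_component"),
               "empty graph")
})

test_that("parse_gaf reads GAF 2.x, drops NOT rows, keeps taxa", {
  expect_equal(nrow(parse_gaf(text = c("!gaf-version: 2.2", "! comment"))),
               0L)
  lines <- c("!gaf-version: 2.2",
             gaf_line("g1", "GO:0000001"),
             gaf_line("g2", "GO:0000002", evidence = "IEA"),
             gaf_line("g3", "GO:0000002", qualifier = "NOT|involved_in"),
             gaf_line("g4", "GO:0000003", taxon = 8355),
             gaf_line("g5", "GO:0000001", aspect = "F"))
  rec <- parse_gaf(text = lines)
  expect_equal(nrow(rec), 4L)              # NOT row dropped
  expect_setequal(unique(rec$taxon_id), c(8364L, 8355L))
  expect_equal(rec$aspect[rec$gene_id == "g5"], "molecular_function")

  expect_error(parse_gaf(text = c("!h", "a\tb\tc")), "line 2")
})

test_that("filter_annotations applies evidence/taxon/aspect filters", {
  rec <- make_records(gene = sprintf("g%d", 1:10),
                      term = rep(c("GO:0000001", "GO:0000002"), 5),
                      evidence = rep(c("IEA", "IDA", "IEA", "EXP", "IMP"), 2),
                      taxon = rep(c(8364L, 8355L), each = 5))
  co <- filter_annotations(rec, exclude_evidence = "IEA")
  expect_equal(length(co$genes), 6L)
  # no-op filter keeps everything
  expect_equal(length(filter_annotations(rec)$genes), 10L)
  # taxon restriction
  co2 <- filter_annotations(rec, taxa = 8364)
  expect_true(all(co2$gene_taxon == 8364L))
  expect_equal(co2$taxa, 8364L)
  # empty result warns, does not throw
  expect_warning(co3 <- filter_annotations(rec, evidence = "TAS"),
                 "empty corpus")
  expect_equal(length(co3$genes), 0L)
})

test_that("corpus maps are bidirectionally consistent and filter idempotent", {
  set.seed(7)
  rec <- make_records(gene = sample(sprintf("g%d", 1:8), 30, replace = TRUE),
                      term = sample(sprintf("GO:%07d", 1:6), 30,
                                    replace = TRUE),
                      evidence = sample(c("IDA", "IEA", "EXP"), 30,
                                        replace = TRUE))
  co <- filter_annotations(rec, exclude_evidence = "IEA")
  for (g in names(co$gene2terms))
    for (t in co$gene2terms[[g]])
      expect_true(g %in% co$term2genes[[t]])
  for (t in names(co$term2genes))
    for (g in co$term2genes[[t]])
      expect_true(t %in% co$gene2terms[[g]])
  co2 <- filter_annotations(co, exclude_evidence = "IEA")
  expect_identical(co$gene2terms, co2$gene2terms)
  expect_identical(co$records, co2$records)
})

test_that("annotate_graph propagates annotations by the true-path rule", {
  og <- extract_aspect(parse_obo(text = chain_obo()), "biological_process")
  corpus <- filter_annotations(make_records("g1", "GO:0000003"))
  a <- annotate_graph(og, corpus, propagate = TRUE)
  expect_equal(unname(a$annotation$prop_count[c("GO:0000001", "GO:0000002",
                                                "GO:0000003")]),
               c(1, 1, 1))
  expect_equal(a$annotation$prop_genes[["GO:0000001"]], "g1")
  # without propagation only the direct term counts
  expect_equal(unname(a$annotation$direct_count[c("GO:0000001",
                                                  "GO:0000003")]),
               c(0L, 1L))
  # siblings: shared parent accumulates both genes
  st <- extract_aspect(parse_obo(text = star_obo()), "biological_process")
  co2 <- filter_annotations(make_records(c("g1", "g2"),
                                         c("GO:0000002", "GO:0000003")))
  a2 <- annotate_graph(st, co2)
  expect_equal(unname(a2$annotation$prop_count["GO:0000001"]), 2)
  # unresolvable terms are skipped with a message
  co3 <- filter_annotations(make_records(c("g1", "g2"),
                                         c("GO:0000003", "GO:0999999")))
  expect_message(a3 <- annotate_graph(og, co3, propagate = TRUE),
                 "skipped 1")
  expect_equal(a3$annotation$n_instances, 1L)
})

test_that("propagated counts are monotone along edges", {
  spec <- synth_spec(seed = 11, dag_extra_parents = 0.3)
  og <- extract_aspect(parse_obo(text = generate_ontology(spec)),
                       "biological_process")
  ann <- generate_annotations(spec)
  co <- filter_annotations(parse_gaf(text = ann$gaf))
  a <- annotate_graph(og, co)
  e <- igraph::ends(a$graph, igraph::E(a$graph), names = TRUE)
  cnt <- a$annotation$prop_count
  expect_true(all(cnt[e[, 2]] >= cnt[e[, 1]]))   # parent >= child
})

test_that("trim_graph keeps exactly the annotated closure and is idempotent", {
  og <- extract_aspect(parse_obo(text = chain_obo()), "biological_process")
  co <- filter_annotations(make_records("g1", "GO:0000003"))
  t1 <- trim_graph(annotate_graph(og, co))
  expect_equal(n_terms(t1), 3L)              # ancestors kept by propagation
  expect_true(igraph::is_dag(t1$graph))

  st <- extract_aspect(parse_obo(text = star_obo()), "biological_process")
  co2 <- filter_annotations(make_records("g1", "GO:0000002"))
  t2 <- trim_graph(annotate_graph(st, co2))
  expect_equal(n_terms(t2), 2L)
  expect_true("GO:0000001" %in% term_ids(t2))  # root retained

  t3 <- trim_graph(t2)
  expect_identical(term_ids(t3), term_ids(t2))
  expect_identical(t3$annotation$prop_count, t2$annotation$prop_count)

  # a fully annotated graph trims to itself
  co4 <- filter_annotations(make_records(c("g1", "g2", "g3"),
                                         c("GO:0000002", "GO:0000003",
                                           "GO:0000004")))
  t4 <- trim_graph(annotate_graph(st, co4))
  expect_setequal(term_ids(t4), term_ids(st))

  expect_error(suppressMessages(trim_graph(annotate_graph(
    og, suppressWarnings(filter_annotations(make_records("g", "GO:0000003"),
                                            evidence = "TAS"))))),
    "no terms carry annotations")
})

test_that("add_comention_edges links terms sharing gene products", {
  st <- extract_aspect(parse_obo(text = star_obo()), "biological_process")
  # one gene on two sibling leaves -> one auxiliary edge
  co <- filter_annotations(make_records(c("g1", "g1"),
                                        c("GO:0000002", "GO:0000003")))
  a <- trim_graph(annotate_graph(st, co))
  before <- igraph::gsize(a$graph)
  aug <- add_comention_edges(a, co)
  expect_equal(igraph::gsize(aug$graph), before + 1L)
  expect_true("co_mention" %in% igraph::E(aug$graph)$relation)

  # disjoint gene sets -> no edges added
  co2 <- filter_annotations(make_records(c("g1", "g2"),
                                         c("GO:0000002", "GO:0000003")))
  a2 <- trim_graph(annotate_graph(st, co2))
  expect_equal(igraph::gsize(add_comention_edges(a2, co2)$graph),
               igraph::gsize(a2$graph))

  # three terms pairwise sharing one gene -> three edges, minus any
  # already-adjacent pair (root-leaf pairs are adjacent in the star)
  co3 <- filter_annotations(make_records(rep("g1", 3),
                                         c("GO:0000002", "GO:0000003",
                                           "GO:0000004")))
  a3 <- trim_graph(annotate_graph(st, co3))
  aug3 <- add_comention_edges(a3, co3)
  expect_equal(sum(igraph::E(aug3$graph)$relation == "co_mention"), 3L)
  # pipeline remains functional on the augmented graph
  ic <- information_content(a3)
  w <- weight_edges(aug3, ic)
  expect_true(all(igraph::E(w$graph)$weight >= 0))
})
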