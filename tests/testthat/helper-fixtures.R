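# Shared fixtures and independent oracles, built in code.

# Minimal OBO text for a chain root <- b <- c (is_a), biological_process.
chain_obo <- function() c(
  "format-version: 1.2",
  "[Term]", "id: GO:0000001", "name: root",
  "namespace: biological_process",
  "[Term]", "id: GO:0000002", "name: b",
  "namespace: biological_process", "is_a: GO:0000001 ! root",
  "[Term]", "id: GO:0000003", "name: c",
  "namespace: biological_process", "is_a: GO:0000002 ! b")

# Star: root with three leaf children.
star_obo <- function() c(
  "[Term]", "id: GO:0000001", "name: root",
  "namespace: biological_process",
  unlist(lapply(2:4, function(i) c(
    "[Term]", sprintf("id: GO:%07d", i), sprintf("name: leaf%d", i),
    "namespace: biological_process", "is_a: GO:0000001 ! root"))))

# Annotation records data frame in the shape parse_gaf() returns.
make_records <- function(gene, term, taxon = 8364L, evidence = "IDA",
                         aspect = "biological_process") {
  data.frame(gene_id = gene, taxon_id = as.integer(taxon), term_id = term,
             evidence_code = evidence, aspect = aspect,
             stringsAsFactors = FALSE)
}

# A GAF line with 17 columns; qualifier/evidence/taxon/aspect injectable.
gaf_line <- function(gene, term, evidence = "IDA", taxon = 8364,
                     qualifier = "", aspect = "P") {
  paste(c("DB", gene, gene, qualifier, term, "REF:1", evidence, "",
          aspect, gene, "", "gene", paste0("taxon:", taxon), "20260101",
          "DB", "", ""), collapse = "\t")
}

# The 3-term fixture with annotation instance counts {root:4, b:3, c:1}:
# one gene directly on the root, two on b, one on c.
chain_counts_fixture <- function() {
  og <- extract_aspect(parse_obo(text = chain_obo()), "biological_process")
  rec <- make_records(gene = c("gA", "gB1", "gB2", "gC"),
                      term = c("GO:0000001", "GO:0000002", "GO:0000002",
                               "GO:0000003"))
  corpus <- filter_annotations(rec)
  list(og = trim_graph(annotate_graph(og, corpus)), corpus = corpus)
}

# Independent all-pairs shortest-path oracle: exhaustive relaxation
# (Floyd-Warshall) on the undirected view of a weighted igraph.
fw_apsp <- function(g) {
  n <- igraph::gorder(g)
  ids <- igraph::V(g)$name
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  if (igraph::gsize(g) > 0) {
    e <- igraph::ends(g, igraph::E(g), names = FALSE)
    w <- igraph::E(g)$weight
    for (i in seq_along(w)) {
      a <- e[i, 1]; b <- e[i, 2]
      D[a, b] <- min(D[a, b], w[i]); D[b, a] <- D[a, b]
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Random weighted graph with named vertices, deterministic under seed.
rand_weighted_graph <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("T%02d", seq_len(n))
  if (igraph::gsize(g) > 0)
    igraph::E(g)$weight <- round(stats::runif(igraph::gsize(g), 0, 2), 6)
  g
}

# Brute-force gene distance oracle: double loop over all term pairs.
brute_gene_dist <- function(term_matrix, gene2terms) {
  genes <- names(gene2terms)
  n <- length(genes)
  D <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    best <- Inf
    for (t1 in gene2terms[[i]]) for (t2 in gene2terms[[j]])
      best <- min(best, term_matrix[t1, t2])
    D[i, j] <- if (i == j) 0 else best
  }
  D
}

# Run the full pipeline on synthetic fixtures; returns partition + truth.
run_synth_pipeline <- function(spec, k = spec$n_modules, seed = spec$seed) {
  d <- file.path(tempfile("synthrun"))
  fx <- write_synth_fixtures(spec, d)
  cfg <- run_config(obo = fx[["obo"]], gaf = fx[["gaf"]], out_dir = d,
                    k = k, seed = seed)
  res <- suppressMessages(run_pipeline(cfg, quiet = TRUE))
  truth <- utils::read.delim(fx[["truth"]], stringsAsFactors = FALSE)
  list(res = res, truth = truth, dir = d, config = cfg)
}

# ARI of recovered modules against planted truth, unrelated genes excluded.
recovery_ari <- function(partition, truth) {
  m <- merge(partition, truth, by = "gene_id")
  m <- m[m$module.y != "unrelated", ]
  mclust::adjustedRandIndex(m$module.x, m$module.y)
}

# Five-term view fixture whose constructed term matrix has exactly 8
# finite candidate term-term distances with distinct values.
viz_fixture_acceptance <- function() {
  obo <- c("[Term]", "id: GO:0000001", "name: root",
           "namespace: biological_process",
           unlist(lapply(2:5, function(i) c(
             "[Term]", sprintf("id: GO:%07d", i),
             sprintf("name: term %d", i),
             "namespace: biological_process",
             sprintf("is_a: GO:%07d ! parent", if (i <= 3) 1 else i - 2)))))
  og <- extract_aspect(parse_obo(text = obo), "biological_process")
  rec <- make_records(gene = c("gA", "gA", "gB", "gC", "gD", "gE"),
                      term = c("GO:0000002", "GO:0000004", "GO:0000003",
                               "GO:0000004", "GO:0000005", "GO:0000001"))
  corpus <- filter_annotations(rec)
  og <- trim_graph(annotate_graph(og, corpus))
  ids <- sprintf("GO:%07d", 1:5)
  tm <- matrix(0, 5, 5, dimnames = list(ids, ids))
  tm[upper.tri(tm)] <- seq(0.1, 1.0, by = 0.1)
  tm <- tm + t(tm)
  tm[1, 2] <- tm[2, 1] <- Inf
  tm[3, 4] <- tm[4, 3] <- Inf
  part <- structure(
    data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"), module = "0",
               stringsAsFactors = FALSE),
    class = c("module_partition", "data.frame"))
  set <- assemble_gene_sets(part, corpus)[[1]]
  list(og = og, tm = tm, set = set)
}
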