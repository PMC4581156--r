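#' Specification for the synthetic ontology/annotation generator
#'
#' Defines the study conditions for the planted-module benchmark: a
#' rooted single-aspect term tree, one disjoint subtree per module, genes
#' annotated inside their module subtree, a fraction of annotation lines
#' redirected to uniformly random terms (noise), and a pool of unrelated
#' genes annotated uniformly over the whole tree. Defaults emulate a
#' small multi-taxon study: 3 modules of 20 genes on depth-2 subtrees of
#' a branching-3 tree, 4 annotations per gene, 5% noise, 5 unrelated
#' genes split over two taxa.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes per module.
#' @param annotations_per_gene GAF lines per gene.
#' @param noise_rate Fraction of annotation lines redirected to a
#'   uniformly random term, in `[0, 1]`.
#' @param n_unrelated Unrelated genes annotated uniformly at random.
#' @param branching Children per internal term of the ontology tree.
#' @param depth Levels below the root (a complete tree has
#'   `(branching^(depth+1) - 1) / (branching - 1)` terms).
#' @param n_terms Optional truncation: keep only the first `n_terms`
#'   terms in breadth-first order.
#' @param dag_extra_parents Probability of giving a non-root term a
#'   second random parent, exercising true-DAG code paths.
#' @param taxa Taxon ids assigned to genes round-robin.
#' @param evidence_codes Evidence codes sampled uniformly per line.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A validated `synth_spec` list.
#' @export
synth_spec <- function(n_modules = 3L, genes_per_module = 20L,
                       annotations_per_gene = 4L, noise_rate = 0.05,
                       n_unrelated = 5L, branching = 3L, depth = 3L,
                       n_terms = NULL, dag_extra_parents = 0,
                       taxa = c(8364L, 8355L),
                       evidence_codes = c("IDA", "IMP", "EXP"),
                       seed = 1L) {
  stopifnot(n_modules >= 1, genes_per_module >= 1,
            annotations_per_gene >= 1, n_unrelated >= 0,
            branching >= 1, depth >= 1,
            noise_rate >= 0, noise_rate <= 1,
            dag_extra_parents >= 0, dag_extra_parents <= 1,
            length(taxa) >= 1)
  if (n_modules > branching)
    stop("synth_spec: n_modules must not exceed branching (one disjoint ",
         "subtree per module)", call. = FALSE)
  structure(list(n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 annotations_per_gene = as.integer(annotations_per_gene),
                 noise_rate = noise_rate,
                 n_unrelated = as.integer(n_unrelated),
                 branching = as.integer(branching),
                 depth = as.integer(depth),
                 n_terms = if (is.null(n_terms)) NULL else as.integer(n_terms),
                 dag_extra_parents = dag_extra_parents,
                 taxa = as.integer(taxa),
                 evidence_codes = evidence_codes,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

synth_term_id <- function(i) sprintf("GO:%07d", i)

synth_tree <- function(spec) {
  # breadth-first complete tree; node 1 is the root
  n_full <- sum(spec$branching^(0:spec$depth))
  n <- if (is.null(spec$n_terms)) n_full else min(spec$n_terms, n_full)
  parent <- integer(n)
  level <- integer(n)
  nxt <- 2L
  queue_lo <- 1L
  while (nxt <= n) {
    p <- queue_lo
    for (b in seq_len(spec$branching)) {
      if (nxt > n) break
      if (level[p] >= spec$depth) break
      parent[nxt] <- p
      level[nxt] <- level[p] + 1L
      nxt <- nxt + 1L
    }
    queue_lo <- queue_lo + 1L
  }
  list(n = n, parent = parent, level = level)
}

#' Generate a synthetic ontology as OBO text
#'
#' Builds a rooted single-aspect (biological_process) term tree with
#' `is_a` edges, breadth-first ids, deterministic under the spec seed.
#' With `dag_extra_parents > 0` random additional parents turn the tree
#' into a proper DAG.
#'
#' @param spec A `synth_spec`.
#' @return Character vector of OBO lines (parseable by [parse_obo()]).
#' @export
generate_ontology <- function(spec) {
  tr <- synth_tree(spec)
  extra <- vector("list", tr$n)
  if (spec$dag_extra_parents > 0 && tr$n > 2) {
    with_local_seed(spec$seed, {
      for (i in 3:tr$n) {
        if (stats::runif(1) < spec$dag_extra_parents) {
          anc <- i
          repeat {
            anc <- c(anc, tr$parent[anc[length(anc)]])
            if (anc[length(anc)] == 1L || tr$parent[anc[length(anc)]] == 0L)
              break
          }
          cand <- setdiff(which(tr$level < tr$level[i]), anc)
          if (length(cand))
            extra[[i]] <- cand[sample.int(length(cand), 1L)]
        }
      }
    })
  }
  out <- c("format-version: 1.2", "ontology: synthetic")
  for (i in seq_len(tr$n)) {
    stanza <- c("", "[Term]",
                paste0("id: ", synth_term_id(i)),
                paste0("name: synthetic term ", i),
                "namespace: biological_process")
    parents <- c(if (tr$parent[i] > 0L) tr$parent[i], extra[[i]])
    for (p in parents)
      stanza <- c(stanza, paste0("is_a: ", synth_term_id(p),
                                 " ! synthetic term ", p))
    out <- c(out, stanza)
  }
  out
}

subtree_members <- function(tr, root_node) {
  members <- root_node
  frontier <- root_node
  repeat {
    kids <- which(tr$parent %in% frontier)
    if (length(kids) == 0L) break
    members <- c(members, kids)
    frontier <- kids
  }
  sort(members)
}

#' Generate synthetic annotations with planted modules
#'
#' Assigns each module the subtree rooted at one child of the root, draws
#' each module gene's annotations uniformly from its subtree, then
#' redirects a `noise_rate` fraction of all annotation lines to uniformly
#' random terms. Unrelated genes are annotated uniformly over the whole
#' tree. The output GAF has exactly
#' `(n_modules * genes_per_module + n_unrelated) * annotations_per_gene`
#' annotation lines; ground truth labels each gene with its module or
#' `unrelated`.
#'
#' @param spec A `synth_spec`.
#' @return List with `gaf` (character vector of GAF 2.2 lines) and
#'   `truth` (data frame `gene_id`, `module`, `taxon_id`).
#' @export
generate_annotations <- function(spec) {
  tr <- synth_tree(spec)
  root_children <- which(tr$parent == 1L)
  if (length(root_children) < spec$n_modules)
    stop("generate_annotations: tree has fewer root children than modules",
         call. = FALSE)
  pools <- lapply(root_children[seq_len(spec$n_modules)],
                  function(ch) subtree_members(tr, ch))

  genes <- character(); module <- character()
  for (m in seq_len(spec$n_modules)) {
    gm <- sprintf("gene_m%d_%03d", m, seq_len(spec$genes_per_module))
    genes <- c(genes, gm)
    module <- c(module, rep(paste0("module_", m), length(gm)))
  }
  if (spec$n_unrelated > 0) {
    gu <- sprintf("gene_u_%03d", seq_len(spec$n_unrelated))
    genes <- c(genes, gu)
    module <- c(module, rep("unrelated", length(gu)))
  }
  taxon <- spec$taxa[((seq_along(genes) - 1L) %% length(spec$taxa)) + 1L]

  apg <- spec$annotations_per_gene
  gaf_gene <- rep(genes, each = apg)
  gaf_taxon <- rep(taxon, each = apg)
  term_node <- integer(length(gaf_gene))
  with_local_seed(spec$seed + 1L, {
    k <- 1L
    for (i in seq_along(genes)) {
      pool <- if (module[i] == "unrelated") seq_len(tr$n)
              else pools[[as.integer(sub("module_", "", module[i]))]]
      term_node[k:(k + apg - 1L)] <-
        pool[sample.int(length(pool), apg, replace = TRUE)]
      k <- k + apg
    }
    flip <- stats::runif(length(term_node)) < spec$noise_rate
    if (any(flip))
      term_node[flip] <- sample.int(tr$n, sum(flip), replace = TRUE)
    evid <- spec$evidence_codes[
      sample.int(length(spec$evidence_codes), length(term_node),
                 replace = TRUE)]
  })

  lines <- sprintf(paste0("SYNTH\t%s\t%s\t\t%s\tSYNTH:0000001\t%s\t\tP\t%s",
                          "\t\tgene\ttaxon:%d\t20260101\tSYNTH\t\t"),
                   gaf_gene, gaf_gene, synth_term_id(term_node), evid,
                   gaf_gene, gaf_taxon)
  list(gaf = c("!gaf-version: 2.2", lines),
       truth = data.frame(gene_id = genes, module = module,
                          taxon_id = taxon, stringsAsFactors = FALSE))
}

#' Write synthetic fixtures to a directory
#'
#' Writes `synthetic.obo`, `synthetic.gaf` and `truth.tsv` for a given
#' spec.
#'
#' @param spec A `synth_spec`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synth_fixtures <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obo <- file.path(out_dir, "synthetic.obo")
  gaf <- file.path(out_dir, "synthetic.gaf")
  truth <- file.path(out_dir, "truth.tsv")
  writeLines(generate_ontology(spec), obo)
  ann <- generate_annotations(spec)
  writeLines(ann$gaf, gaf)
  utils::write.table(ann$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(obo = obo, gaf = gaf, truth = truth))
}
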