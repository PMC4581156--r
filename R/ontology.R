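#' @import igraph
NULL

ASPECTS <- c("biological_process", "molecular_function", "cellular_component")

new_ontology_graph <- function(graph, roots, aspect = NA_character_,
                               alt_ids = character(), annotation = NULL) {
  structure(list(graph = graph, roots = roots, aspect = aspect,
                 alt_ids = alt_ids, annotation = annotation),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", igraph::gorder(x$graph), " terms, ",
      igraph::gsize(x$graph), " edges",
      if (!is.na(x$aspect)) paste0(", aspect: ", x$aspect) else "",
      "\n", sep = "")
  if (!is.null(x$annotation))
    cat("  annotated: ", x$annotation$n_instances, " annotation instances (",
        if (x$annotation$propagate) "propagated" else "direct", ")\n", sep = "")
  invisible(x)
}

#' Number of terms in an ontology graph
#' @param og An `ontology_graph`.
#' @return Integer count of terms.
#' @export
n_terms <- function(og) igraph::gorder(og$graph)

#' Term accessions of an ontology graph
#' @param og An `ontology_graph`.
#' @return Character vector of term ids.
#' @export
term_ids <- function(og) igraph::V(og$graph)$name

assert_dag <- function(g) {
  if (igraph::gorder(g) == 0L) return(invisible(TRUE))
  if (any(igraph::which_loop(g))) {
    e <- igraph::ends(g, igraph::E(g)[igraph::which_loop(g)][1])
    stop("cyclic ontology: self relationship on term ", e[1], call. = FALSE)
  }
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    big <- which(comp$csize > 1)[1]
    members <- names(comp$membership)[comp$membership == big]
    stop("cyclic ontology: cycle involving terms ",
         paste(members, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

find_roots <- function(g) {
  if (igraph::gorder(g) == 0L) return(character())
  igraph::V(g)$name[igraph::degree(g, mode = "out") == 0L]
}

obo_lines <- function(file, text) {
  if (!is.null(text)) {
    return(unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE))
  }
  readLines(file, warn = FALSE)
}

#' Parse an OBO flat file into an ontology graph
#'
#' Reads `[Term]` stanzas of an OBO 1.2/1.4 file and builds a directed
#' acyclic graph with one edge per `is_a` line and per
#' `relationship: part_of` line, child pointing to parent. Other
#' relationship types (e.g. `regulates`) are ignored with a message.
#' Obsolete terms are dropped; `alt_id` accessions are recorded so that
#' annotations against them can later be remapped to the canonical term.
#'
#' @param file Path to an OBO file.
#' @param text Alternatively, the OBO content as a single string or a
#'   character vector of lines.
#' @return An `ontology_graph`: the term DAG over all aspects present in
#'   the file, with `is_a`/`part_of` relations retained as the edge
#'   attribute `relation`.
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root")
#' g <- parse_obo(text = obo)
#' n_terms(g)
#' @export
parse_obo <- function(file = NULL, text = NULL) {
  lines <- obo_lines(file, text)
  lines <- sub("\r$", "", lines)
  hdr <- grep("^\\[[^]]+\\]\\s*$", lines)
  kinds <- gsub("^\\[|\\]\\s*$", "", lines[hdr])
  term_starts <- hdr[kinds == "Term"]
  bounds <- c(hdr, length(lines) + 1L)

  ids <- names <- aspects <- character()
  obsolete <- logical()
  alt_from <- alt_to <- character()
  e_child <- e_parent <- e_rel <- character()
  n_other_rel <- 0L

  ordinal <- 0L
  for (s in term_starts) {
    ordinal <- ordinal + 1L
    end <- bounds[which(bounds > s)[1]] - 1L
    body <- lines[(s + 1L):end]
    body <- body[nzchar(trimws(body))]
    kv <- regmatches(body, regexpr("^[A-Za-z_]+:", body))
    keys <- sub(":$", "", kv)
    vals <- trimws(sub("^[A-Za-z_]+:", "", body))
    vals <- trimws(sub("\\s*!.*$", "", vals))  # strip trailing OBO comments

    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id))
      stop("malformed OBO: [Term] stanza ", ordinal, " has no id", call. = FALSE)
    obs <- any(keys == "is_obsolete" & vals == "true")
    ids <- c(ids, id)
    names <- c(names, vals[keys == "name"][1])
    aspects <- c(aspects, vals[keys == "namespace"][1])
    obsolete <- c(obsolete, obs)

    alts <- vals[keys == "alt_id"]
    if (length(alts)) {
      alt_from <- c(alt_from, alts)
      alt_to <- c(alt_to, rep(id, length(alts)))
    }
    isa <- vals[keys == "is_a"]
    if (length(isa)) {
      e_child <- c(e_child, rep(id, length(isa)))
      e_parent <- c(e_parent, isa)
      e_rel <- c(e_rel, rep("is_a", length(isa)))
    }
    rel <- vals[keys == "relationship"]
    if (length(rel)) {
      parts <- strsplit(rel, "\\s+")
      for (p in parts) {
        if (length(p) >= 2 && p[1] == "part_of") {
          e_child <- c(e_child, id)
          e_parent <- c(e_parent, p[2])
          e_rel <- c(e_rel, "part_of")
        } else {
          n_other_rel <- n_other_rel + 1L
        }
      }
    }
  }
  if (n_other_rel > 0L)
    message("parse_obo: ignored ", n_other_rel,
            " relationship line(s) other than part_of")
  if (anyDuplicated(ids))
    stop("malformed OBO: duplicated term id ", ids[duplicated(ids)][1],
         call. = FALSE)

  keep <- !obsolete
  vdf <- data.frame(name = ids[keep], label = names[keep],
                    aspect = aspects[keep], stringsAsFactors = FALSE)
  ok <- e_child %in% vdf$name & e_parent %in% vdf$name
  if (any(!ok) && length(ok))
    message("parse_obo: dropped ", sum(!ok),
            " edge(s) referencing obsolete or absent terms")
  edf <- data.frame(from = e_child[ok], to = e_parent[ok],
                    relation = e_rel[ok], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  assert_dag(g)
  alt <- alt_to[alt_to %in% vdf$name]
  names(alt) <- alt_from[alt_to %in% vdf$name]
  new_ontology_graph(g, roots = find_roots(g), alt_ids = alt)
}

#' Restrict an ontology graph to a single aspect
#'
#' Takes the induced subgraph on the terms of one GO aspect
#' (`biological_process`, `molecular_function` or `cellular_component`).
#' Edges crossing aspects are dropped with the excluded terms. The result
#' must be a DAG with a single root.
#'
#' @param og An `ontology_graph` as returned by [parse_obo()].
#' @param aspect One of the three GO namespaces.
#' @return An `ontology_graph` restricted to `aspect`.
#' @export
extract_aspect <- function(og, aspect = ASPECTS) {
  aspect <- match.arg(aspect)
  g <- og$graph
  va <- igraph::vertex_attr(g, "aspect")
  vids <- which(!is.na(va) & va == aspect)
  if (length(vids) == 0L)
    stop("empty graph: no terms with aspect '", aspect, "'", call. = FALSE)
  sub <- igraph::induced_subgraph(g, vids)
  assert_dag(sub)
  roots <- find_roots(sub)
  if (length(roots) != 1L)
    stop("aspect subgraph for '", aspect, "' has ", length(roots),
         " roots; expected exactly one", call. = FALSE)
  new_ontology_graph(sub, roots = roots, aspect = aspect,
                     alt_ids = og$alt_ids)
}

GAF_ASPECT <- c(P = "biological_process", F = "molecular_function",
                C = "cellular_component")

#' Parse a GAF 2.x gene association file
#'
#' Reads the 17-column tab-separated Gene Association File format. Comment
#' lines (starting with `!`) are skipped; rows whose qualifier contains
#' `NOT` are dropped rather than treated as negative evidence.
#'
#' @param file Path to a GAF file.
#' @param text Alternatively, GAF content as a string or character vector.
#' @return A data frame of annotation records with columns `gene_id`,
#'   `taxon_id`, `term_id`, `evidence_code`, `aspect`.
#' @export
parse_gaf <- function(file = NULL, text = NULL) {
  lines <- obo_lines(file, text)
  lines <- sub("\r$", "", lines)
  body_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  empty <- data.frame(gene_id = character(), taxon_id = integer(),
                      term_id = character(), evidence_code = character(),
                      aspect = character(), stringsAsFactors = FALSE)
  if (length(body_idx) == 0L) return(empty)
  body <- lines[body_idx]
  nf <- nchar(gsub("[^\t]", "", body)) + 1L   # strsplit drops trailing empties
  bad <- which(nf != 17L)
  if (length(bad))
    stop("GAF parse error at line ", body_idx[bad[1]], ": expected 17 ",
         "tab-separated columns, found ", nf[bad[1]], call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) c(f, rep("", 17L - length(f))))
  m <- do.call(rbind, fields)
  keep <- !grepl("(^|\\|)NOT(\\||$)", m[, 4])
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)
  taxon <- sub("^taxon:", "", vapply(strsplit(m[, 13], "|", fixed = TRUE),
                                     `[`, character(1), 1L))
  data.frame(gene_id = m[, 2], taxon_id = as.integer(taxon),
             term_id = m[, 5], evidence_code = m[, 7],
             aspect = unname(GAF_ASPECT[m[, 9]]),
             stringsAsFactors = FALSE)
}

new_annotation_corpus <- function(records, aspect = NA_character_) {
  genes <- sort(unique(records$gene_id))
  pairs <- unique(records[, c("gene_id", "term_id")])
  gene2terms <- split(pairs$term_id, factor(pairs$gene_id, levels = genes))
  terms <- sort(unique(pairs$term_id))
  term2genes <- split(pairs$gene_id, factor(pairs$term_id, levels = terms))
  gt <- records[!duplicated(records$gene_id), c("gene_id", "taxon_id")]
  gene_taxon <- stats::setNames(gt$taxon_id, gt$gene_id)[genes]
  structure(list(genes = genes,
                 taxa = sort(unique(records$taxon_id)),
                 gene2terms = lapply(gene2terms, unique),
                 term2genes = lapply(term2genes, unique),
                 gene_taxon = gene_taxon,
                 records = records,
                 aspect = aspect),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("<annotation_corpus> ", length(x$genes), " genes, ",
      length(x$term2genes), " terms, taxa: ",
      paste(x$taxa, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Filter annotation records into an annotation corpus
#'
#' Applies evidence-code, taxon and aspect filters to GAF records and
#' assembles the gene space, taxa space and the bidirectional
#' gene-to-term maps. Either an include list (`evidence`) or an exclude
#' list (`exclude_evidence`, e.g. `"IEA"` to drop electronically inferred
#' annotations) may be given; by default all codes are kept.
#'
#' @param records Data frame from [parse_gaf()], or an existing
#'   `annotation_corpus` (filtering is idempotent).
#' @param evidence Character vector of evidence codes to keep, or `NULL`
#'   for all.
#' @param exclude_evidence Character vector of evidence codes to drop.
#' @param taxa Integer vector of NCBI taxon ids to keep, or `NULL` for all.
#' @param aspect Optional aspect restriction.
#' @return An `annotation_corpus`. If no records survive, the corpus is
#'   empty and carries a warning rather than failing.
#' @export
filter_annotations <- function(records, evidence = NULL,
                               exclude_evidence = NULL, taxa = NULL,
                               aspect = NULL) {
  if (inherits(records, "annotation_corpus")) records <- records$records
  keep <- rep(TRUE, nrow(records))
  if (!is.null(evidence)) keep <- keep & records$evidence_code %in% evidence
  if (!is.null(exclude_evidence))
    keep <- keep & !(records$evidence_code %in% exclude_evidence)
  if (!is.null(taxa)) keep <- keep & records$taxon_id %in% as.integer(taxa)
  if (!is.null(aspect)) keep <- keep & records$aspect %in% aspect
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("empty corpus: no annotation records match the filters",
            call. = FALSE)
  new_annotation_corpus(out, aspect = if (is.null(aspect)) NA_character_
                        else aspect)
}

ancestors_incl_self <- function(g, term) {
  igraph::V(g)$name[igraph::subcomponent(g, term, mode = "out")]
}

#' Annotate ontology terms with genes
#'
#' Attaches annotation instances from a corpus to the terms of the graph.
#' An annotation instance is a distinct (gene, term) pair after filtering.
#' With `propagate = TRUE` (the true-path rule) every instance is also
#' counted at every ancestor of its term, which guarantees that a parent's
#' count is at least each child's and makes the information content
#' monotone along edges. Terms in the corpus that cannot be resolved in
#' the graph (directly or via `alt_id`) are skipped with a message.
#'
#' @param og An `ontology_graph` (typically aspect-restricted).
#' @param corpus An `annotation_corpus`.
#' @param propagate Apply the true-path rule (default `TRUE`).
#' @return The graph with an `annotation` component holding per-term
#'   direct and propagated instance counts and gene sets.
#' @export
annotate_graph <- function(og, corpus, propagate = TRUE) {
  g <- og$graph
  ids <- igraph::V(g)$name
  pairs <- unique(corpus$records[, c("gene_id", "term_id")])
  resolved <- pairs$term_id
  miss <- !(resolved %in% ids)
  if (any(miss)) {
    via_alt <- og$alt_ids[resolved[miss]]
    resolved[miss] <- unname(via_alt)
  }
  skip <- is.na(resolved) | !(resolved %in% ids)
  if (any(skip))
    message("annotate_graph: skipped ", sum(skip),
            " annotation(s) to unresolvable terms")
  pairs$term_id <- resolved
  pairs <- unique(pairs[!skip, , drop = FALSE])

  direct_count <- stats::setNames(integer(length(ids)), ids)
  tab <- table(pairs$term_id)
  direct_count[names(tab)] <- as.integer(tab)
  direct_genes <- stats::setNames(vector("list", length(ids)), ids)
  direct_genes[] <- list(character())
  sp <- split(pairs$gene_id, pairs$term_id)
  direct_genes[names(sp)] <- lapply(sp, sort)

  prop_count <- as.numeric(direct_count)
  names(prop_count) <- ids
  prop_genes <- direct_genes
  used <- names(sp)
  for (u in used) {
    anc <- setdiff(ancestors_incl_self(g, u), u)
    if (length(anc)) {
      prop_count[anc] <- prop_count[anc] + direct_count[u]
      for (a in anc)
        prop_genes[[a]] <- union(prop_genes[[a]], direct_genes[[u]])
    }
  }
  prop_genes <- lapply(prop_genes, sort)
  og$annotation <- list(direct_count = direct_count,
                        prop_count = prop_count,
                        direct_genes = direct_genes,
                        prop_genes = prop_genes,
                        n_instances = nrow(pairs),
                        propagate = propagate,
                        n_skipped = sum(skip))
  og
}

#' Trim unannotated terms from an annotated graph
#'
#' Retains exactly the terms carrying at least one propagated annotation
#' instance and the induced edges among them. Because propagation keeps
#' every ancestor of an annotated term, the result is a DAG in which every
#' retained term still reaches the retained root. Trimming is idempotent.
#'
#' @param og An annotated `ontology_graph` (see [annotate_graph()]).
#' @return The trimmed annotated graph.
#' @export
trim_graph <- function(og) {
  if (is.null(og$annotation))
    stop("trim_graph: graph is not annotated", call. = FALSE)
  ann <- og$annotation
  keep <- names(ann$prop_count)[ann$prop_count > 0]
  if (length(keep) == 0L)
    stop("empty graph: no terms carry annotations after filtering",
         call. = FALSE)
  sub <- igraph::induced_subgraph(og$graph, keep)
  ids <- igraph::V(sub)$name
  og$graph <- sub
  og$roots <- find_roots(sub)
  og$annotation$direct_count <- ann$direct_count[ids]
  og$annotation$prop_count <- ann$prop_count[ids]
  og$annotation$direct_genes <- ann$direct_genes[ids]
  og$annotation$prop_genes <- ann$prop_genes[ids]
  og
}

#' Default co-mention weight rule: Jaccard distance of the gene sets
#'
#' @param genes_a,genes_b Character vectors of gene ids annotated to the
#'   two terms.
#' @return A non-negative edge weight; terms sharing all genes get 0.
#' @export
comention_jaccard <- function(genes_a, genes_b) {
  1 - length(intersect(genes_a, genes_b)) / length(union(genes_a, genes_b))
}

#' Augment the term graph with co-mention edges
#'
#' Adds one auxiliary edge between every pair of terms that share at least
#' one directly annotated gene product and are not already adjacent. The
#' edge weight is set by `weight_rule` on the two direct gene sets; the
#' original `is_a`/`part_of` edges are untouched. Co-mention edges take
#' part in shortest-path computation with their assigned weight.
#'
#' @param og An annotated `ontology_graph`.
#' @param corpus The `annotation_corpus` used for annotation.
#' @param weight_rule Function of two gene-id vectors returning a
#'   non-negative weight; defaults to [comention_jaccard()].
#' @return The graph with added edges of relation `co_mention`.
#' @export
add_comention_edges <- function(og, corpus, weight_rule = comention_jaccard) {
  g <- og$graph
  ids <- igraph::V(g)$name
  t2g <- corpus$term2genes[names(corpus$term2genes) %in% ids]
  g2t <- list()
  for (t in names(t2g)) for (gn in t2g[[t]]) g2t[[gn]] <- c(g2t[[gn]], t)
  pair_a <- pair_b <- character()
  for (ts in g2t) {
    ts <- sort(unique(ts))
    if (length(ts) >= 2) {
      cmb <- utils::combn(ts, 2)
      pair_a <- c(pair_a, cmb[1, ])
      pair_b <- c(pair_b, cmb[2, ])
    }
  }
  if (length(pair_a) == 0L) return(og)
  key <- paste(pair_a, pair_b)
  dup <- duplicated(key)
  pair_a <- pair_a[!dup]; pair_b <- pair_b[!dup]
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  already <- mapply(function(a, b) adj[a, b] > 0 || adj[b, a] > 0,
                    pair_a, pair_b)
  pair_a <- pair_a[!already]; pair_b <- pair_b[!already]
  if (length(pair_a) == 0L) return(og)
  w <- mapply(function(a, b) weight_rule(t2g[[a]], t2g[[b]]), pair_a, pair_b)
  el <- rbind(pair_a, pair_b)
  g <- igraph::add_edges(g, as.vector(el),
                         attr = list(relation = rep("co_mention",
                                                    length(pair_a)),
                                     weight = as.numeric(w)))
  og$graph <- g
  og
}
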