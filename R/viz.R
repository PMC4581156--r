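#' Build a renderable view of a gene set
#'
#' Assembles the annotated network of one functional module: its terms as
#' square nodes ranked by number of connections, its genes as circular
#' nodes coloured by taxon, all gene-term annotation edges, and the
#' term-term semantic-distance edges whose distance falls at or below the
#' chosen percentile of the candidate distances (nearest-rank rule; the
#' default 25th percentile keeps the closest quarter). Edge display width
#' scales inversely with distance.
#'
#' @param set One gene set from a `gene_set_collection`.
#' @param og The annotated (trimmed) `ontology_graph`.
#' @param term_matrix Term distance matrix from
#'   [all_pairs_shortest_paths()].
#' @param percentile Percentile cutoff in `(0, 100]` for term-term edges.
#' @return A `gene_set_view` with node and edge tables and legend
#'   entries.
#' @export
build_view <- function(set, og, term_matrix, percentile = 25) {
  if (is.null(set$genes) || length(set$genes) == 0L)
    stop("build_view: empty gene set", call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("parameter error: percentile must be in (0, 100]", call. = FALSE)
  dg <- og$annotation$direct_genes
  terms <- sort(names(dg)[vapply(dg, function(gs) any(set$genes %in% gs),
                                 logical(1))])
  terms <- intersect(terms, rownames(term_matrix))
  if (length(terms) == 0L)
    stop("build_view: no terms annotate this gene set", call. = FALSE)

  gene_edges <- do.call(rbind, lapply(terms, function(t) {
    gs <- intersect(dg[[t]], set$genes)
    data.frame(gene = gs, term = rep(t, length(gs)),
               stringsAsFactors = FALSE)
  }))

  term_edges <- data.frame(from = character(), to = character(),
                           distance = numeric(), width = numeric(),
                           stringsAsFactors = FALSE)
  n_candidates <- 0L
  if (length(terms) >= 2L) {
    cmb <- utils::combn(terms, 2)
    d <- term_matrix[cbind(cmb[1, ], cmb[2, ])]
    fin <- is.finite(d)
    cmb <- cmb[, fin, drop = FALSE]; d <- d[fin]
    n_candidates <- length(d)
    if (n_candidates > 0L) {
      srt <- sort(d)
      thr <- srt[max(1L, ceiling(percentile / 100 * n_candidates))]
      show <- d <= thr
      d_show <- d[show]
      rng <- range(d_show)
      width <- if (diff(rng) > 0)
        0.5 + 2.5 * (rng[2] - d_show) / diff(rng) else rep(1.5, length(d_show))
      term_edges <- data.frame(from = cmb[1, show], to = cmb[2, show],
                               distance = d_show, width = width,
                               stringsAsFactors = FALSE)
    }
  }

  deg <- stats::setNames(integer(length(terms)), terms)
  tt <- table(c(term_edges$from, term_edges$to))
  deg[names(tt)] <- deg[names(tt)] + as.integer(tt)
  gt <- table(gene_edges$term)
  deg[names(gt)] <- deg[names(gt)] + as.integer(gt)
  ord <- order(-deg, terms)
  rank <- integer(length(terms)); rank[ord] <- seq_along(terms)

  labs <- igraph::V(og$graph)$label[match(terms, igraph::V(og$graph)$name)]
  term_nodes <- data.frame(id = terms, name = labs, degree = as.integer(deg),
                           rank = rank, stringsAsFactors = FALSE)

  genes <- sort(unique(gene_edges$gene))
  taxa <- if (!is.null(set$taxa)) set$taxa[genes] else
    stats::setNames(rep(NA_integer_, length(genes)), genes)
  utaxa <- sort(unique(taxa[!is.na(taxa)]))
  pal <- grDevices::hcl.colors(max(2L, length(utaxa)), "Dark 3")
  col <- pal[match(taxa, utaxa)]
  col[is.na(col)] <- "grey70"
  gene_nodes <- data.frame(id = genes, taxon = unname(taxa),
                           color = col, stringsAsFactors = FALSE)

  structure(list(term_nodes = term_nodes, gene_nodes = gene_nodes,
                 term_edges = term_edges, gene_edges = gene_edges,
                 percentile = percentile, n_candidates = n_candidates,
                 taxon_colors = stats::setNames(pal[seq_along(utaxa)],
                                                utaxa),
                 set_id = set$set_id),
            class = "gene_set_view")
}

view_to_igraph <- function(view) {
  vdf <- data.frame(
    name = c(view$term_nodes$id, view$gene_nodes$id),
    kind = c(rep("term", nrow(view$term_nodes)),
             rep("gene", nrow(view$gene_nodes))),
    label = c(as.character(view$term_nodes$rank), view$gene_nodes$id),
    color = c(rep("lightsteelblue", nrow(view$term_nodes)),
              view$gene_nodes$color),
    shape = c(rep("square", nrow(view$term_nodes)),
              rep("circle", nrow(view$gene_nodes))),
    stringsAsFactors = FALSE)
  edf <- rbind(
    data.frame(from = view$term_edges$from, to = view$term_edges$to,
               width = view$term_edges$width, stringsAsFactors = FALSE),
    data.frame(from = view$gene_edges$gene, to = view$gene_edges$term,
               width = 0.5, stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Render a gene set view to an image file
#'
#' Draws the network with a force-directed layout under a fixed seed, so
#' repeated calls with the same seed give identical coordinates.
#'
#' @param view A `gene_set_view`.
#' @param path Output file path.
#' @param format One of `"png"`, `"pdf"`, `"svg"`.
#' @param seed Layout seed.
#' @param width,height Device size in inches.
#' @return The layout coordinate matrix, invisibly.
#' @export
render_view <- function(view, path, format = c("png", "pdf", "svg"),
                        seed = 42L, width = 8, height = 8) {
  format <- match.arg(format)
  g <- view_to_igraph(view)
  lay <- with_local_seed(seed, igraph::layout_with_fr(g))
  switch(format,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  igraph::plot.igraph(g, layout = lay,
                      vertex.size = ifelse(igraph::V(g)$kind == "term", 7, 5),
                      vertex.label.cex = 0.6,
                      edge.width = igraph::E(g)$width,
                      main = view$set_id)
  legend_terms <- sprintf("%d: %s", view$term_nodes$rank,
                          view$term_nodes$name)
  legend_terms <- legend_terms[order(view$term_nodes$rank)]
  graphics::legend("topleft", legend = utils::head(legend_terms, 12),
                   bty = "n", cex = 0.55)
  if (length(view$taxon_colors))
    graphics::legend("bottomright",
                     legend = paste("taxon", names(view$taxon_colors)),
                     col = view$taxon_colors, pch = 19, bty = "n",
                     cex = 0.7)
  invisible(lay)
}

#' Export a gene set view as edge and node tables
#'
#' Writes tab-separated tables consumable by external network tools such
#' as Cytoscape: an edge list (`source`, `target`, `type`, `weight`) with
#' `type` in `{term-term, gene-term}`, and a node table (`id`, `kind`,
#' `label`, `taxon`, `rank`).
#'
#' @param view A `gene_set_view`.
#' @param edges_file,nodes_file Output paths.
#' @return Invisibly, the two paths.
#' @export
export_network <- function(view, edges_file, nodes_file) {
  edges <- rbind(
    data.frame(source = view$term_edges$from, target = view$term_edges$to,
               type = "term-term", weight = view$term_edges$distance,
               stringsAsFactors = FALSE),
    data.frame(source = view$gene_edges$gene, target = view$gene_edges$term,
               type = "gene-term", weight = 1,
               stringsAsFactors = FALSE))
  nodes <- rbind(
    data.frame(id = view$term_nodes$id, kind = "term",
               label = view$term_nodes$name, taxon = NA_integer_,
               rank = view$term_nodes$rank, stringsAsFactors = FALSE),
    data.frame(id = view$gene_nodes$id, kind = "gene",
               label = view$gene_nodes$id, taxon = view$gene_nodes$taxon,
               rank = NA_integer_, stringsAsFactors = FALSE))
  utils::write.table(edges, edges_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nodes, nodes_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = edges_file, nodes = nodes_file))
}
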