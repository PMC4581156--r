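#' Information content of annotated terms
#'
#' Computes `IC(t) = -ln P(t)` in nats, where `P(t)` is the number of
#' annotation instances of the term divided by the total number of
#' annotation instances. With the default propagated counts (true-path
#' rule) the total equals the count at the aspect root, so the root has
#' IC 0 and IC is non-decreasing from parent to child. With
#' `mode = "direct"` the raw per-term instance counts are used instead;
#' terms without direct annotations then get `+Inf`.
#'
#' @param og An annotated (typically trimmed) `ontology_graph`.
#' @param mode `"propagated"` (default) or `"direct"` counts.
#' @return Named numeric vector of information contents (nats).
#' @export
information_content <- function(og, mode = c("propagated", "direct")) {
  mode <- match.arg(mode)
  ann <- og$annotation
  if (is.null(ann))
    stop("information_content: graph is not annotated", call. = FALSE)
  N <- ann$n_instances
  if (N < 1) stop("information_content: no annotation instances",
                  call. = FALSE)
  n <- if (mode == "propagated") ann$prop_count
       else stats::setNames(as.numeric(ann$direct_count),
                            names(ann$direct_count))
  ic <- -log(n / N)
  ic[n == 0] <- Inf
  ic
}

#' Weight ontology edges by semantic distance
#'
#' Assigns every `is_a`/`part_of` edge the weight
#' `|IC(parent) - IC(child)|`, the semantic distance between a
#' parent-child term pair. Co-mention edges keep the weight given by
#' their weight rule. Weights are non-negative by construction and the
#' graph is treated as undirected by the shortest-path solver.
#'
#' @param og An annotated `ontology_graph`.
#' @param ic Named IC vector from [information_content()].
#' @return The graph with edge attribute `weight` set.
#' @export
weight_edges <- function(og, ic) {
  g <- og$graph
  if (igraph::gsize(g) > 0L) {
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    w <- abs(ic[ends[, 2]] - ic[ends[, 1]])
    rel <- igraph::E(g)$relation
    old <- igraph::edge_attr(g, "weight")
    if (!is.null(old)) w[rel == "co_mention"] <- old[rel == "co_mention"]
    igraph::E(g)$weight <- as.numeric(w)
  }
  og$graph <- g
  og
}

#' All-pairs shortest paths over the weighted term graph
#'
#' Computes the symmetric matrix of shortest-path distances between all
#' term pairs using Dijkstra's algorithm on the undirected view of the
#' weighted DAG (paths may traverse edges against their direction, e.g.
#' through a common ancestor). Disconnected pairs get `+Inf`. Work can be
#' split over `workers` processes by source vertex; the result is
#' identical for any worker count.
#'
#' @param og An `ontology_graph` with edge weights (see [weight_edges()]),
#'   or a weighted `igraph` object.
#' @param workers Number of parallel workers (source-vertex parallelism).
#' @return Symmetric numeric matrix with term ids as dimnames; zero
#'   diagonal; `Inf` marks disconnected pairs.
#' @export
all_pairs_shortest_paths <- function(og, workers = 1L) {
  g <- if (inherits(og, "ontology_graph")) og$graph else og
  w <- igraph::edge_attr(g, "weight")
  if (igraph::gsize(g) > 0L) {
    if (is.null(w) || anyNA(w))
      stop("all_pairs_shortest_paths: edges are not weighted", call. = FALSE)
    if (any(w < 0))
      stop("contract violation: negative edge weight encountered",
           call. = FALSE)
  }
  nv <- igraph::gorder(g)
  if (nv == 0L) return(matrix(numeric(0), 0, 0))
  workers <- max(1L, as.integer(workers))
  if (workers == 1L) {
    D <- igraph::distances(g, mode = "all", weights = w,
                           algorithm = "dijkstra")
  } else {
    chunks <- split(seq_len(nv), cut(seq_len(nv), workers, labels = FALSE))
    parts <- parallel::mclapply(chunks, function(ix) {
      igraph::distances(g, v = igraph::V(g)[ix], mode = "all", weights = w,
                        algorithm = "dijkstra")
    }, mc.cores = workers)
    D <- do.call(rbind, parts)
    D <- D[igraph::V(g)$name, , drop = FALSE]
  }
  D
}

#' Map term-term distances into gene space
#'
#' The distance between two genes is the shortest path among all
#' term-term paths connecting them: the minimum of the term distance over
#' every pair of terms annotated to the two genes. Genes sharing a term
#' get distance 0; gene pairs whose terms lie in different components get
#' `+Inf`. Genes with no term surviving the trim are excluded with a
#' message.
#'
#' @param term_matrix Symmetric term distance matrix from
#'   [all_pairs_shortest_paths()].
#' @param corpus An `annotation_corpus`.
#' @return Symmetric gene distance matrix with zero diagonal.
#' @export
term_to_gene_distances <- function(term_matrix, corpus) {
  if (length(corpus$genes) == 0L)
    stop("term_to_gene_distances: empty corpus", call. = FALSE)
  terms <- rownames(term_matrix)
  idx <- lapply(corpus$gene2terms, function(ts) {
    match(intersect(ts, terms), terms)
  })
  has <- lengths(idx) > 0L
  if (any(!has))
    message("term_to_gene_distances: excluded ", sum(!has),
            " gene(s) with no term in the trimmed graph")
  genes <- corpus$genes[has]
  idx <- idx[has]
  n <- length(genes)
  D <- matrix(0, n, n, dimnames = list(genes, genes))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      ti <- idx[[i]]
      for (j in seq.int(i + 1L, n)) {
        D[i, j] <- D[j, i] <- min(term_matrix[ti, idx[[j]]])
      }
    }
  }
  D
}

#' Write / read a distance matrix as TSV
#'
#' Square tab-separated matrix with a header row and a leading id column;
#' infinite distances are serialized as the literal `inf`.
#'
#' @param m Numeric matrix with dimnames.
#' @param file Output path.
#' @return `write_distance_matrix` returns `file` invisibly;
#'   `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(m, file) {
  fmt <- function(x) {
    out <- sprintf("%.12g", x)
    out[is.infinite(x) & x > 0] <- "inf"
    out
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), con)
  invisible(file)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(file) {
  lines <- readLines(file)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  n <- length(lines) - 1L
  m <- matrix(NA_real_, n, length(header))
  rn <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    rn[i] <- f[1]
    v <- f[-1]
    x <- suppressWarnings(as.numeric(v))
    x[v == "inf"] <- Inf
    m[i, ] <- x
  }
  dimnames(m) <- list(rn, header)
  m
}
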