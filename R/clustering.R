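with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Convert a gene distance matrix to a Gaussian affinity matrix
#'
#' `a(i,j) = exp(-d(i,j)^2 / (2 sigma^2))`; infinite distances map to
#' affinity 0 and the diagonal is 1. The default bandwidth is the median
#' of the positive finite distances, a scale-free choice.
#'
#' @param gene_matrix Symmetric distance matrix with zero diagonal.
#' @param sigma Kernel bandwidth (> 0), or `NULL` for the median default.
#' @return Affinity matrix in `[0, 1]` with attribute `sigma`.
#' @export
distance_to_affinity <- function(gene_matrix, sigma = NULL) {
  if (is.null(sigma)) {
    d <- gene_matrix[upper.tri(gene_matrix)]
    d <- d[is.finite(d) & d > 0]
    sigma <- if (length(d)) stats::median(d) else 1
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("parameter error: sigma must be a positive number", call. = FALSE)
  A <- exp(-gene_matrix^2 / (2 * sigma^2))
  A[is.infinite(gene_matrix)] <- 0
  diag(A) <- 1
  attr(A, "sigma") <- sigma
  A
}

spectral_embedding <- function(A, k) {
  dvec <- rowSums(A)
  dis <- 1 / sqrt(dvec)
  M <- A * (dis %o% dis)          # D^{-1/2} A D^{-1/2}, symmetric
  e <- eigen(M, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U / rn
}

#' Partition genes by spectral clustering
#'
#' Normalized spectral clustering in the Ng-Jordan-Weiss style: symmetric
#' normalization of the affinity, top-k eigenvectors, row normalization,
#' then k-means with a fixed seed (10 restarts). Genes whose affinity to
#' every other gene is zero are reported with the reserved label
#' `unclustered` rather than forced into a module. Deterministic given
#' `(affinity, k, seed)`.
#'
#' @param affinity Symmetric non-negative affinity matrix (see
#'   [distance_to_affinity()]).
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed for the k-means restarts.
#' @return A `module_partition`: data frame with columns `gene_id` and
#'   `module` (labels `"0" .. "k-1"` or `"unclustered"`), with attributes
#'   `k`, `seed`, `sigma` and mean `silhouette` on the embedding.
#' @export
spectral_partition <- function(affinity, k, seed = 1L) {
  if (k < 2) stop("parameter error: k must be >= 2", call. = FALSE)
  genes <- rownames(affinity)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(affinity)))
  off <- affinity
  diag(off) <- 0
  isolated <- rowSums(off) == 0
  B <- affinity[!isolated, !isolated, drop = FALSE]
  if (k > nrow(B))
    stop("parameter error: k (", k, ") exceeds the ", nrow(B),
         " non-isolated genes", call. = FALSE)
  U <- spectral_embedding(B, k)
  km <- with_local_seed(seed,
    stats::kmeans(U, centers = k, nstart = 10, iter.max = 100))
  lab <- match(km$cluster, unique(km$cluster)) - 1L   # stable relabeling
  sil <- if (nrow(U) > k) {
    s <- cluster::silhouette(km$cluster, stats::dist(U))
    mean(s[, "sil_width"])
  } else NA_real_
  module <- rep("unclustered", length(genes))
  module[!isolated] <- as.character(lab)
  out <- data.frame(gene_id = genes, module = module,
                    stringsAsFactors = FALSE)
  structure(out, class = c("module_partition", "data.frame"),
            k = k, seed = seed, sigma = attr(affinity, "sigma"),
            silhouette = sil)
}

#' Scan clustering parameters
#'
#' Evaluates a grid of cluster counts and kernel bandwidths, scoring each
#' partition by the mean silhouette width on the spectral embedding. The
#' best-scoring row is flagged.
#'
#' @param gene_matrix Symmetric gene distance matrix.
#' @param k_values Integer vector of cluster counts to try.
#' @param sigma_values Numeric vector of bandwidths, or `NULL` for the
#'   median default only.
#' @param seed Integer seed.
#' @return Data frame with columns `k`, `sigma`, `silhouette`, `best`.
#' @export
scan_parameters <- function(gene_matrix, k_values, sigma_values = NULL,
                            seed = 1L) {
  if (length(k_values) == 0L)
    stop("parameter error: empty k grid", call. = FALSE)
  if (is.null(sigma_values)) {
    A0 <- distance_to_affinity(gene_matrix)
    sigma_values <- attr(A0, "sigma")
  }
  grid <- expand.grid(k = as.integer(k_values), sigma = sigma_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$silhouette <- NA_real_
  for (i in seq_len(nrow(grid))) {
    A <- distance_to_affinity(gene_matrix, sigma = grid$sigma[i])
    p <- spectral_partition(A, k = grid$k[i], seed = seed)
    grid$silhouette[i] <- attr(p, "silhouette")
  }
  grid$best <- FALSE
  if (any(is.finite(grid$silhouette)))
    grid$best[which.max(grid$silhouette)] <- TRUE
  grid
}

#' Write a module partition with its JSON sidecar
#'
#' The partition is written as two-column tab-separated text
#' (`gene_id`, `module_id`); clustering metadata (k, sigma, seed, mean
#' silhouette) goes to a JSON sidecar next to it.
#'
#' @param partition A `module_partition`.
#' @param file Output path for the TSV; the sidecar gets extension
#'   `.json`.
#' @return `file`, invisibly.
#' @export
write_partition <- function(partition, file) {
  con <- file(file, "w")
  writeLines(c("gene_id\tmodule_id",
               paste(partition$gene_id, partition$module, sep = "\t")), con)
  close(con)
  meta <- list(k = attr(partition, "k"), sigma = attr(partition, "sigma"),
               seed = attr(partition, "seed"),
               silhouette = attr(partition, "silhouette"))
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", file),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
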