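#' Parse standard 12-column BLAST tabular output
#'
#' Reads BLAST+ `-outfmt 6` (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore).
#'
#' @param file Path to a BLAST tabular file.
#' @param text Alternatively, content as a string or character vector.
#' @return Data frame of hits with one row per hit line; e-values in
#'   scientific notation are parsed numerically.
#' @export
parse_blast_tabular <- function(file = NULL, text = NULL) {
  lines <- obo_lines(file, text)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character()), 12), cols),
                         stringsAsFactors = FALSE)
    num <- setdiff(cols, c("qseqid", "sseqid"))
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    stop("BLAST tabular parse error at line ", bad[1], ": expected 12 ",
         "columns, found ", nf[bad[1]], call. = FALSE)
  m <- do.call(rbind, fields)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  num <- lapply(3:12, function(j) as.numeric(m[, j]))
  names(num) <- cols[3:12]
  out <- cbind(out, as.data.frame(num))
  if (any(out$evalue < 0))
    stop("BLAST tabular parse error: negative e-value", call. = FALSE)
  out
}

#' Best-hit transcript-to-gene mapping
#'
#' For every query transcript keeps the hit with the smallest e-value at
#' or below `evalue_max`; ties are broken by higher bit score, then by
#' lexicographic subject id, so the map is deterministic and independent
#' of input order. An optional id map translates BLAST subject ids into
#' the gene namespace of the annotation corpus.
#'
#' @param hits Data frame from [parse_blast_tabular()].
#' @param evalue_max Maximum e-value to accept (default `1e-5`).
#' @param subject_map Optional named character vector (or two-column
#'   data frame `subject_id`, `gene_id`) mapping subject ids to gene ids.
#' @return Named character vector: transcript id -> gene id. Queries with
#'   no passing hit are absent.
#' @export
best_hit_map <- function(hits, evalue_max = 1e-5, subject_map = NULL) {
  if (!is.numeric(evalue_max) || evalue_max <= 0)
    stop("parameter error: evalue_max must be > 0", call. = FALSE)
  h <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(h) == 0L) return(stats::setNames(character(), character()))
  ord <- order(h$qseqid, h$evalue, -h$bitscore, h$sseqid)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  subj <- h$sseqid
  if (!is.null(subject_map)) {
    if (is.data.frame(subject_map))
      subject_map <- stats::setNames(subject_map[[2]], subject_map[[1]])
    subj <- unname(subject_map[subj])
  }
  ok <- !is.na(subj)
  stats::setNames(subj[ok], h$qseqid[ok])
}

#' Read a two-column subject-to-gene id mapping file
#' @param file Tab-separated file with columns `subject_id`, `gene_id`.
#' @return Named character vector suitable for [best_hit_map()].
#' @export
read_id_map <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

new_gene_set_collection <- function(sets) {
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x), " set(s)\n", sep = "")
  for (s in x)
    cat("  ", s$set_id, ": ", length(s$genes), " genes\n", sep = "")
  invisible(x)
}

#' Assemble gene sets from a module partition
#'
#' Creates one gene set per module label. Genes with the reserved
#' `unclustered` label are excluded unless requested, and sets smaller
#' than `min_size` are dropped.
#'
#' @param partition A `module_partition`.
#' @param corpus The `annotation_corpus` (source of per-gene taxa).
#' @param min_size Minimum members per set (default 1).
#' @param include_unclustered Also emit a set for unclustered genes.
#' @return A `gene_set_collection`: list of sets, each with `set_id`,
#'   `description`, `genes`, per-gene `taxa` and (initially empty)
#'   `transcripts`.
#' @export
assemble_gene_sets <- function(partition, corpus, min_size = 1L,
                               include_unclustered = FALSE) {
  if (nrow(partition) == 0L)
    stop("assemble_gene_sets: empty partition", call. = FALSE)
  labels <- unique(partition$module)
  labels <- labels[labels != "unclustered"]
  labels <- labels[order(suppressWarnings(as.integer(labels)), labels)]
  if (include_unclustered && any(partition$module == "unclustered"))
    labels <- c(labels, "unclustered")
  sets <- list()
  for (lb in labels) {
    genes <- sort(partition$gene_id[partition$module == lb])
    if (length(genes) < min_size) next
    taxa <- corpus$gene_taxon[genes]
    sid <- if (lb == "unclustered") "unclustered" else paste0("module_", lb)
    sets[[sid]] <- list(set_id = sid,
                        description = paste0("functional module (n=",
                                             length(genes), ")"),
                        genes = genes,
                        taxa = taxa,
                        transcripts = character())
  }
  new_gene_set_collection(sets)
}

#' Attach transcript-level membership to gene sets
#'
#' Each transcript joins every set containing its mapped gene; transcripts
#' whose gene belongs to no set are returned in the `unmapped` attribute.
#'
#' @param collection A `gene_set_collection`.
#' @param transcript_map Named character vector transcript -> gene from
#'   [best_hit_map()].
#' @return The collection with `transcripts` filled per set and an
#'   `unmapped` attribute listing unplaced transcripts.
#' @export
map_transcripts_to_sets <- function(collection, transcript_map) {
  placed <- rep(FALSE, length(transcript_map))
  for (i in seq_along(collection)) {
    hit <- transcript_map %in% collection[[i]]$genes
    collection[[i]]$transcripts <- sort(names(transcript_map)[hit])
    placed <- placed | hit
  }
  attr(collection, "unmapped") <- sort(names(transcript_map)[!placed])
  collection
}

#' Write / read gene sets in GMT format
#'
#' One set per line: `set_id TAB description TAB member1 TAB member2 ...`.
#' Reading back a written file reproduces set ids, descriptions and
#' members (per-gene taxon labels are not representable in GMT and are
#' not serialized).
#'
#' @param collection A `gene_set_collection`.
#' @param file Output (or input) path.
#' @param use_transcripts Write transcript members instead of genes where
#'   present.
#' @return `write_gmt` returns `file` invisibly; `read_gmt` a
#'   `gene_set_collection`.
#' @export
write_gmt <- function(collection, file, use_transcripts = FALSE) {
  lines <- vapply(collection, function(s) {
    members <- if (use_transcripts && length(s$transcripts))
      s$transcripts else s$genes
    paste(c(s$set_id, s$description, members), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), file)
  invisible(file)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2)
      stop("GMT parse error: line with fewer than 2 fields", call. = FALSE)
    sets[[f[1]]] <- list(set_id = f[1], description = f[2],
                         genes = if (length(f) > 2) f[-(1:2)] else character(),
                         taxa = NULL, transcripts = character())
  }
  new_gene_set_collection(sets)
}
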