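#' Build a pipeline run configuration
#'
#' Validates paths and parameters for [run_pipeline()]. Input paths must
#' exist before any compute starts; violations raise a `config_error`.
#'
#' @param obo Path to the ontology OBO file.
#' @param gaf Character vector of GAF paths (one per taxon source).
#' @param out_dir Output directory for all artifacts.
#' @param k Number of modules for spectral clustering.
#' @param aspect GO aspect to analyse.
#' @param taxa Optional taxon restriction.
#' @param evidence,exclude_evidence Evidence include / exclude lists
#'   (e.g. `exclude_evidence = "IEA"`).
#' @param propagate Apply the true-path rule (default `TRUE`).
#' @param ic_mode `"propagated"` or `"direct"` counts for IC.
#' @param comention Add co-mention edges before path finding.
#' @param workers Dijkstra workers.
#' @param sigma Affinity bandwidth, `NULL` for the median default.
#' @param seed Seed for clustering (and manifest provenance).
#' @param min_size Minimum gene-set size kept at export.
#' @param blast Optional BLAST tabular path for transcript mapping.
#' @param id_map Optional two-column subject-to-gene mapping path.
#' @param evalue_max Best-hit e-value threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(obo, gaf, out_dir, k,
                       aspect = "biological_process", taxa = NULL,
                       evidence = NULL, exclude_evidence = NULL,
                       propagate = TRUE, ic_mode = "propagated",
                       comention = FALSE, workers = 1L, sigma = NULL,
                       seed = 1L, min_size = 1L, blast = NULL,
                       id_map = NULL, evalue_max = 1e-5) {
  cfg_err <- function(...) {
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
  }
  for (p in c(obo, gaf, blast, id_map))
    if (!file.exists(p)) cfg_err("config error: input not found: ", p)
  if (!aspect %in% ASPECTS) cfg_err("config error: unknown aspect ", aspect)
  if (!is.numeric(k) || k < 2) cfg_err("config error: k must be >= 2")
  if (!ic_mode %in% c("propagated", "direct"))
    cfg_err("config error: ic_mode must be propagated or direct")
  if (!is.null(sigma) && sigma <= 0) cfg_err("config error: sigma must be > 0")
  structure(list(obo = obo, gaf = gaf, out_dir = out_dir, k = as.integer(k),
                 aspect = aspect, taxa = taxa, evidence = evidence,
                 exclude_evidence = exclude_evidence, propagate = propagate,
                 ic_mode = ic_mode, comention = comention,
                 workers = as.integer(workers), sigma = sigma,
                 seed = as.integer(seed), min_size = as.integer(min_size),
                 blast = blast, id_map = id_map, evalue_max = evalue_max),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path Path to a JSON object with [run_config()] fields.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full gene-set generation pipeline
#'
#' Executes the whole chain: parse ontology and annotations, restrict to
#' one aspect, filter by evidence and taxa, annotate and trim the term
#' DAG, compute information content, weight edges by
#' `|IC(parent) - IC(child)|`, solve all-pairs shortest paths, map term
#' distances to gene space, convert to a Gaussian affinity, partition by
#' spectral clustering, and export the modules as GMT. Every stage's
#' output is persisted under `out_dir` together with a manifest recording
#' input checksums, parameters, seed and package version. A stage failure
#' aborts with the stage name; artifacts of completed stages remain on
#' disk.
#'
#' @param config A `run_config` (or path to a JSON config).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the computed objects
#'   (`graph`, `ic`, `term_matrix`, `gene_matrix`, `partition`,
#'   `collection`, `transcript_map`) and `paths` to the artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[funcmodules] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list(
    manifest = file.path(config$out_dir, "manifest.json"),
    term_dist = file.path(config$out_dir, "term_distances.tsv"),
    gene_dist = file.path(config$out_dir, "gene_distances.tsv"),
    partition = file.path(config$out_dir, "partition.tsv"),
    gmt = file.path(config$out_dir, "gene_sets.gmt"),
    transcript_map = file.path(config$out_dir, "transcript_map.tsv"))

  inputs <- c(config$obo, config$gaf, config$blast, config$id_map)
  manifest <- list(
    package = "funcmodules",
    version = as.character(utils::packageVersion("funcmodules")),
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs)),
    parameters = config[setdiff(names(config),
                                c("obo", "gaf", "blast", "id_map",
                                  "out_dir"))],
    seed = config$seed)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  say("parsing ontology: ", config$obo)
  og <- stage("parse_obo", parse_obo(config$obo))
  og <- stage("extract_aspect", extract_aspect(og, config$aspect))

  say("parsing ", length(config$gaf), " GAF file(s)")
  records <- stage("parse_gaf",
                   do.call(rbind, lapply(config$gaf, parse_gaf)))
  corpus <- stage("filter_annotations",
                  filter_annotations(records, evidence = config$evidence,
                                     exclude_evidence =
                                       config$exclude_evidence,
                                     taxa = config$taxa,
                                     aspect = config$aspect))
  say("gene space: ", length(corpus$genes), " genes, taxa: ",
      paste(corpus$taxa, collapse = ","))

  og <- stage("annotate", annotate_graph(og, corpus,
                                         propagate = config$propagate))
  og <- stage("trim", trim_graph(og))
  if (isTRUE(config$comention))
    og <- stage("comention", add_comention_edges(og, corpus))
  say("trimmed graph: ", n_terms(og), " annotated terms")

  ic <- stage("information_content", information_content(og, config$ic_mode))
  og <- stage("weight_edges", weight_edges(og, ic))
  say("solving all-pairs shortest paths (", config$workers, " worker(s))")
  tm <- stage("apsp", all_pairs_shortest_paths(og, workers = config$workers))
  write_distance_matrix(tm, paths$term_dist)

  gm <- stage("gene_distances", term_to_gene_distances(tm, corpus))
  write_distance_matrix(gm, paths$gene_dist)

  A <- stage("affinity", distance_to_affinity(gm, sigma = config$sigma))
  say("spectral clustering: k=", config$k, ", sigma=",
      signif(attr(A, "sigma"), 4))
  part <- stage("spectral_partition",
                spectral_partition(A, k = config$k, seed = config$seed))
  write_partition(part, paths$partition)

  coll <- stage("gene_sets",
                assemble_gene_sets(part, corpus, min_size = config$min_size))
  tmap <- NULL
  if (!is.null(config$blast)) {
    say("mapping transcripts via BLAST best hits")
    hits <- stage("parse_blast", parse_blast_tabular(config$blast))
    smap <- if (!is.null(config$id_map)) read_id_map(config$id_map) else NULL
    tmap <- stage("best_hit_map",
                  best_hit_map(hits, evalue_max = config$evalue_max,
                               subject_map = smap))
    coll <- stage("map_transcripts", map_transcripts_to_sets(coll, tmap))
    utils::write.table(
      data.frame(transcript = names(tmap), gene = unname(tmap)),
      paths$transcript_map, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gmt(coll, paths$gmt)
  say("wrote ", length(coll), " gene set(s) to ", paths$gmt)

  invisible(list(graph = og, ic = ic, term_matrix = tm, gene_matrix = gm,
                 partition = part, collection = coll,
                 transcript_map = tmap, paths = paths))
}
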