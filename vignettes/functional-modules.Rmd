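---
title: "Generating functional gene modules from ontology semantic distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating functional gene modules from ontology semantic distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcmodules)
```

## The problem

Gene set analysis (GSA/GSEA) needs gene sets before any statistics can be
run, and for non-model organisms the curated pathway collections that
model-organism communities enjoy simply do not exist. `funcmodules`
generates gene sets directly from annotation data: the user names a gene
space (a genome, a transcriptome, or any gene list) and one or more taxa
whose Gene Ontology annotations should inform it, and the package
partitions the genes into *functional modules* — groups of genes whose
annotations place them close together in the ontology. The modules can
then be tested for enrichment by any downstream GSA tool via the standard
GMT format.

## The model

The pipeline operates on one GO aspect at a time (default
`biological_process`), represented as a directed acyclic graph whose
edges are the `is_a` and `part_of` relations, both treated as a single
edge class for reachability. Genes attach to terms through GAF
annotation records, filtered by taxon and evidence code (excluding `IEA`
is a single switch; whether electronic annotations help or hurt is a
project-level decision, so the default keeps all codes).

**Annotation counts.** An *annotation instance* is a distinct
(gene, term) pair after filtering; repeated evidence lines for the same
pair count once. Under the true-path rule (the default) an instance is
also counted at every ancestor of its term, so a parent's count is at
least each child's.

**Information content.** For a term $t$ with $n_t$ instances out of
$N$ total,
$$ IC(t) = -\ln P(t), \qquad P(t) = n_t / N . $$
With propagated counts $N$ equals the count at the aspect root
(equivalently the total number of direct instances), the root has
$IC = 0$, and $IC$ increases monotonically from root to leaves — rarer,
more specific terms are more informative. A `mode = "direct"` switch is
provided for the literal direct-count reading; it sacrifices
monotonicity (zero-count interior terms get $+\infty$) and is not the
default.

**Semantic distance.** Each parent–child edge is weighted
$$ \mathrm{dist}(t_p, t_c) = |IC(t_p) - IC(t_c)| , $$
and the distance between arbitrary terms is the shortest path over the
undirected view of the weighted DAG (paths through a common ancestor
must traverse edges against their direction, which is why the view is
undirected). Dijkstra's algorithm is run from every source; the work can
be split over workers by source vertex, which cannot change the values.
Zero-weight edges (equal ICs) are legal and need no epsilon inflation.
Disconnected pairs are $+\infty$, never a sentinel value. Optionally the
graph can first be augmented with *co-mention* edges between
non-adjacent terms sharing a gene product; their weight rule is
user-supplied and defaults to the Jaccard distance of the two direct
gene sets, a bounded [0, 1] quantity comparable to small IC differences.

**Gene distances.** The distance between two genes is the minimum term
distance over all pairs of their annotated terms. Genes sharing a term
are at distance 0. Note this mapping is single-linkage-like: it is
symmetric with a zero diagonal and is dominated by the term matrix, but
it need not satisfy the triangle inequality — which is harmless for the
kernel-based clustering that consumes it, and is why the partitioning
step works on affinities rather than assuming a metric embedding.

**Clustering.** Distances become affinities through a Gaussian kernel,
$a_{ij} = \exp(-d_{ij}^2 / 2\sigma^2)$, with $a_{ij} = 0$ for infinite
distances. Spectral clustering then follows the normalized
(Ng–Jordan–Weiss) recipe: symmetric normalization
$D^{-1/2} A D^{-1/2}$, top-$k$ eigenvectors, row normalization, and
seeded k-means with 10 restarts. Genes with an all-zero affinity row are
reported with the reserved label `unclustered` instead of being forced
into a module.

## Parameters that matter

* `sigma` (affinity bandwidth, in nats — the unit of IC differences):
  defaults to the median of the positive finite gene distances, a
  scale-free choice that adapts to the annotation density of the gene
  space. Too-small values fragment the affinity graph, too-large values
  blur module boundaries; `scan_parameters()` evaluates a grid.
* `k` (module count): a user decision. No automatic eigengap selection
  is imposed; `scan_parameters()` reports the mean silhouette width on
  the spectral embedding per `(k, sigma)` and flags the best row as an
  advisory statistic.
* `seed`: fixes the k-means restarts (and only those — everything else
  is deterministic), so a run is exactly reproducible from its manifest.
* evidence filters: include-list or exclude-list on GAF evidence codes;
  `exclude_evidence = "IEA"` reproduces the common "curated only"
  configuration.
* `workers`: source-vertex parallelism for the all-pairs shortest
  paths, the computationally intensive step on real ontologies; results
  are identical for any worker count.

## Numerical and design choices

* NOT-qualified GAF rows are dropped, never used as negative evidence.
* Annotations to `alt_id` accessions are remapped to the canonical term;
  term ids that cannot be resolved in the graph are skipped with a
  counted message rather than failing, since release mismatches between
  ontology and annotation files are routine.
* Trimming keeps exactly the terms with at least one propagated
  instance; by construction every retained term still reaches the root,
  and trimming is idempotent.
* k-means label numbers are canonicalized by first appearance, so
  reruns are byte-identical; labels are otherwise arbitrary and all
  recovery scores use the adjusted Rand index, which is
  relabeling-invariant.
* Distance matrices are serialized as TSV with `inf` literals;
  round-trips are exact to write precision (12 significant digits).
* Term–term edges in a gene-set view are cut at a percentile of the
  candidate distances using the nearest-rank rule
  (`ceiling(p/100 * n)`-th smallest value); the default 25th percentile
  displays the closest quarter. Term rank labels count both displayed
  term–term and gene–term connections, ties broken by term id.

## The synthetic benchmark

Because the pipeline's inputs are public flat files that cannot be
bundled, the package ships a generator (`synth_spec()`,
`generate_ontology()`, `generate_annotations()`) that emulates them: a
rooted single-aspect term tree (optionally a DAG via random extra
parents), modules planted on disjoint subtrees, per-gene annotations
drawn from the module subtree, a noise fraction of annotation lines
redirected to uniformly random terms, and a pool of unrelated genes
annotated uniformly. The defaults — 3 modules of 20 genes on the
depth-2 subtrees of a branching-3, depth-3 tree (40 terms), 4
annotations per gene, 5% noise, 5 unrelated genes, two taxa assigned
round-robin — are the conditions under which recovery is benchmarked:
small enough to run in seconds, structured enough that failure is
informative. Recovery is scored as the adjusted Rand index between
recovered and planted modules over the genes that carry a true module
label; unrelated genes have no meaningful true class among the
k clusters and are excluded from the score (their presence still
perturbs the clustering, which is the point of including them).

What the generator does *not* emulate: the scale of real ontologies
(tens of thousands of terms), the highly skewed annotation-depth
distribution of real GAFs, inter-aspect structure, and correlated
annotation errors. A clean pass on the benchmark therefore demonstrates
the machinery is correct, not that any particular `(k, sigma)` is right
for a real transcriptome — that remains a `scan_parameters()` plus
domain-knowledge decision.

## Known limitations

* All-pairs shortest paths are held densely in memory; this is fine up
  to a few thousand annotated terms (the trimmed graph of a focused
  gene space), while whole-aspect runs against full GO releases need
  the worker-parallel path and patience.
* Orthology versus paralogy among BLAST best hits is reported, not
  resolved; with multiple taxa the per-transcript report should be
  inspected before enrichment testing.
* Per-gene taxon labels are not representable in GMT lines and are
  dropped on GMT round-trips.

## A worked run

```{r example, eval = FALSE}
spec <- synth_spec(seed = 4)
fx <- write_synth_fixtures(spec, "demo")
cfg <- run_config(obo = fx[["obo"]], gaf = fx[["gaf"]],
                  out_dir = "demo/out", k = 3, seed = 4)
res <- run_pipeline(cfg)
#> [funcmodules] trimmed graph: 40 annotated terms
#> [funcmodules] solving all-pairs shortest paths (1 worker(s))
#> [funcmodules] spectral clustering: k=3, sigma=3.505
#> [funcmodules] wrote 3 gene set(s) to demo/out/gene_sets.gmt

v <- build_view(res$collection[[1]], res$graph, res$term_matrix,
                percentile = 25)
render_view(v, "demo/module_0.png")
```
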