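# magcurate

Human-in-the-loop refinement of metagenome-assembled genomes (MAGs),
as a headless R toolkit.

Automatic binners (MaxBin, MetaBAT, DASTool, ...) group assembled
contigs into candidate genomes, but their plans routinely contain
misplaced contigs, chimeric bins and split genomes. Curators fix these
by inspecting contigs in a 2D composition embedding, selecting suspect
clusters, and moving contigs between bins — then quantifying whether
the plan actually improved. `magcurate` implements the computational
core of that workflow for scripts and pipelines: a typed per-contig
property table, editable binning plans with full undo, selection
operators (polygon, histogram range, attribute search), k-mer
frequency embeddings, and the evaluation metrics that make curation
auditable.

## What it computes

* **Silhouette coefficient** of a binning plan in a chosen feature
  space (default: the 2D embedding, standardized):
  `s(i) = (b(i) − a(i)) / max(a(i), b(i))`, where `a(i)` is the mean
  distance from contig *i* to its own bin's other members and `b(i)`
  the smallest mean distance to any other bin. Singleton bins score 0.
* **Adjusted Rand index** between two plans over their shared binned
  contigs: `ARI = (Index − E[Index]) / (Max − E[Index])` with
  `Index = Σ_ij C(n_ij, 2)` over the bin-by-bin contingency table.
* **Completeness / redundancy** of any contig selection from a flat
  single-copy marker catalog *G*: `comp = 100·|found|/|G|`,
  `redund = 100·(copies − |found|)/|G|` (no collocation model — a
  fast first-pass check, not a CheckM replacement).
* **MAG quality tiers** per the community reporting standard
  (high ≥ 90% complete & < 5% contaminated; medium ≥ 50% & < 10%;
  low < 50% & < 10%; ≥ 10% contamination excluded).
* **Length-weighted bin overlap** (Jaccard and containments), k-mer
  frequency matrices (canonical, row-stochastic) and PCA / Barnes-Hut
  t-SNE / UMAP 2D embeddings with PCA-50 pre-reduction.

Converters are included for SPAdes/MegaHit FASTA headers, Kraken
classifications, GTDB lineage strings, GFF3 feature annotations,
marker-gene maps, typed contig-table TSVs and plan TSVs, plus JSON
checkpoints that restore a whole session exactly.

## Worked example

Everything below runs offline: the package ships a synthetic-community
generator with known ground truth.

```r
library(magcurate)

com <- generate_community(community_spec(n_genomes = 5, seed = 1,
                                         composition_divergence = 0.6))
com$table
#> <contig_table: 117 contigs, 7 columns (0 masked, 0 highlighted)>
#>   columns: length [n], gc [n], genome [c], cov_s1 [n], cov_s2 [n], cov_s3 [n], markers [f]

# tetranucleotide embedding and a deliberately degraded plan
emb      <- embed_contigs(kmer_freq_matrix(com$sequences, k = 4), "pca")
degraded <- perturb_plan(com$truth, "random_swap", intensity = 0.3, seed = 1)

glance(adjusted_rand(com$truth, degraded))
#>     ari n_shared
#> 1 0.398      117
glance(silhouette_scores(emb, degraded))
#>   overall_mean n_used n_bins
#> 1        0.150    117      5
```

An ARI of 0.398 says the degraded plan agrees only weakly with the
truth; the low mean silhouette (0.150) says many contigs now sit
closer to another bin's cluster than to their own — exactly the signal
a curator uses to spot misplaced contigs. Marker-based quality of one
genome's true contig set:

```r
g1 <- tidy(com$truth) |> dplyr::filter(bin == "G01")
completeness_redundancy(com$table, g1$contig, com$markers, "markers")
#>   completeness redundancy n_found n_total_hits group_size
#> 1          100          0      20           20         20

classify_quality(c(95, 55, 30, 80), c(3, 8, 5, 12))
#> [1] high     medium   low      excluded
```

Selecting a cluster with the polygon tool, assigning it to a bin and
undoing are one-liners (`select_polygon`, `edit_plan`, `undo_plan`);
`plot_contigs` / `export_scatter` render the five-aesthetic scatter
(x, y, size, opacity, color), and `save_checkpoint` /
`load_checkpoint` round-trip the whole session as JSON.

## Scope

The interactive browser GUI this workflow comes from is out of scope,
as is running assemblers/binners/classifiers themselves: `magcurate`
consumes their outputs and evaluates/edits plans. Marker-based
completeness here deliberately ignores marker collocation; run a
dedicated tool (e.g. CheckM) before publishing MAGs.
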