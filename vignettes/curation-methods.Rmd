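---
title: "Models and methods behind magcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcurate)
```

`magcurate` is a headless toolkit for refining metagenome bins. This
vignette explains the models and conventions it implements, the
parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical choices made where more than one
convention exists in the field.

## The data model

A contig table is a tibble with one row per contig and typed columns:
**numeric** (lengths, GC, coverages, embedding coordinates),
**categorical** (taxonomic ranks, user labels), **feature set**
(multisets of gene identifiers — duplicates encode copy number, which
redundancy estimation needs), and **descriptive** (free text, ignored
by computation). Two flags ride along with the data: a **mask**
(masked contigs are excluded from every summary, metric, selection
and plot) and an integer **highlight** slot 0–8 (0 = none). Colors
are a presentation concern, so the model stores slots, not color
strings; eight slots cover the practical number of simultaneously
distinguishable highlight groups. Missing values are explicit and are
*excluded* from summaries and transforms, never treated as zero —
annotations in this workflow are always partial, and a zero-imputed
GC or coverage would silently bias length-weighted means.

Contig identifiers are compared case-sensitively and exactly; the
incremental `append_columns` path reports (rather than silently
drops) rows whose IDs are unknown, because mismatched ID dialects
between tools are the most common ingestion failure in practice.

## Transforms

Numeric columns can be viewed through square/cube (and their roots),
log/exp, logit/arcsine, or ranks. The logarithm is base 10 and `exp`
is its inverse `10^x`: coverage spans orders of magnitude and base-10
ticks are the readable choice. Out-of-domain inputs (zero coverage
under `log`, proportions outside (0,1) under `logit`) map to missing
and are counted in a report instead of raising — toggling transforms
during exploration must not abort on a handful of degenerate contigs.
Ranks use average ties (deterministic and weight-free); the
sign-preserving cube root keeps negative embedding axes usable.

## Summaries, histograms, range selection

Selection summaries follow the conventions used when reporting bins:
total length is a sum; GC is a length-weighted mean
(`Σwᵢxᵢ/Σwᵢ`); the category of a selection is the majority label,
optionally length-weighted, printed as `"label (NN%)"` with the
percent rounded to the nearest integer. The majority denominator is
the *annotated* part of the selection: the fraction states how
unanimous the annotation is, not how complete it is (that choice is
ambiguous in the field; it is documented prominently here). Ties
break lexicographically so results are reproducible.

Histograms use `n_bins` equal-width bins (default 20) over the
transformed values; bins are half-open `[lo, hi)` with a closed last
bin so the maximum is never dropped. A constant-valued selection gets
a degenerate range widened symmetrically by 0.5 on each side, which
places all mass in the central bin. Range selection is
boundary-inclusive on the transformed scale, matching a drag
selection whose handles sit on data values.

## Evaluation metrics

**Silhouette.** Exact all-pairs Euclidean silhouette over the
unmasked, binned contigs; `s(i) = 0` for singleton-bin members
(Rousseeuw's convention) and for the degenerate `a = b = 0` case.
Features default to user-designated numeric columns (typically the
2D embedding) standardized to zero mean and unit variance, with a
flag to disable: without standardization a raw coverage axis can
dominate a bounded embedding axis by orders of magnitude. Unbinned
contigs receive no score rather than forming a pseudo-bin. For very
large selections an optional seeded subsample (`max_n`) bounds the
O(n²) distance matrix; the default computes exactly.

**Adjusted Rand index.** Computed from the bin-by-bin contingency
table over the contigs binned in *both* plans, with `n_shared`
reported so the restriction is auditable (treating unbinned contigs
as a pseudo-bin is the main alternative; restriction was chosen
because plans under comparison often cover different contig subsets
by design). When `Max = Expected` (both plans trivially agree on all
pairs) the index is defined as 1.

**Completeness/redundancy.** A flat marker catalog, no collocation:
`found` distinct members present, `total` summed member copies,
`comp = 100·found/|G|`, `redund = 100·(total − found)/|G|`.
Redundancy can exceed 100%. Both are monotone non-decreasing as
contigs are added, which the tests exercise; this is a real-time
first-pass check, not a lineage-aware quality model.

**Quality tiers.** `high` iff comp ≥ 90 and cont < 5; `medium` iff
comp ≥ 50, cont < 10, not high; `low` iff comp < 50, cont < 10;
`excluded` iff cont ≥ 10. The four rules partition the plane, so
every (comp, cont) pair maps to exactly one tier.

**Bin overlap.** Length-weighted by default — genome recovery is a
question about base pairs, not contig counts — with an ID-count
variant behind `weighted = FALSE`.

## k-mer embedding

`count_kmers` slides a stride-1 window and skips windows containing
non-ACGT characters, so an N-free sequence of length `L` contributes
exactly `L − k + 1` counts. Canonical pooling (each word merged with
its reverse complement under the lexicographically smaller name) is
on by default: assembly strand is arbitrary, and composition
signatures should not depend on it. Frequencies (rows normalized to
sum 1) rather than raw counts feed the embedding, removing contig
length as a confounder; all-ambiguous contigs yield missing rows and
are flagged.

`embed_contigs` provides PCA (first two components), and t-SNE/UMAP
run on a PCA pre-reduction to `pca_pre_dims = 50` components (capped
at `min(n − 1, m)`), with Barnes-Hut acceleration for t-SNE. Defaults:
`k = 4` (tetranucleotides; 5 and 6 supported), perplexity 30
(auto-lowered for small n), `n_neighbors = 15`, `min_dist = 0.1`,
seed 42. Every stochastic step is seeded and single-threaded so a
rerun with identical inputs reproduces coordinates bit for bit.

## Plans, selections, and undo

A plan is a partial contig→bin map plus an edit history. Every edit
(`create`, `assign`, `unassign`, `merge`, `delete`, `rename`)
appends one reversible record; assigning a contig that already
belongs elsewhere *moves* it in a single atomic record, so undo can
never create double membership. `undo_plan` pops exactly one record;
n undos after n edits restore the initial plan exactly.

Polygon selection uses the even-odd (ray-casting) rule with an
inclusive boundary — a click on a cluster's convex hull should select
the hull points — and accepts either winding order. Attribute search
composes typed predicates conjunctively (numeric comparisons and
boundary-inclusive `between`; categorical equals/contains/regex;
feature-set membership).

Per-bin abundance is the length-weighted mean coverage of members
(a depth-like quantity comparable across bins); a summed
`length × coverage` mass variant is available where a total-yield
reading is wanted.

## Checkpoints, logging, exports

Checkpoints serialize the entire session — table payload with flags,
plans *including their histories*, view settings, log — as JSON with
floats at full precision (`format_version = 1`; newer versions are
refused outright rather than partially loaded). The log is a list of
structured entries (timestamp, operation, parameters); the
`session_*` wrappers append one entry per mutating operation so a log
replay on the initial inputs reproduces the final assignment. Bin
export writes one typed TSV per bin plus the two-column plan file,
with deterministic filename sanitization. Scatter export draws
unmasked contigs in ascending ID order, making repeated exports of
the same session identical.

The contig-table TSV dialect marks column types with header suffixes
(`|n`, `|c`, `|f`, `|d`). This convention is defined by this package:
the four data types needed a file syntax, and explicit suffixes make
round trips independent of inference. Unsuffixed files fall back to
inference (all-numeric → numeric, any comma → feature set, else
categorical).

## The synthetic community generator

`generate_community` emulates just enough structure to exercise every
operation with known truth: per-genome base frequencies drawn from a
Dirichlet (order-0 Markov sequences — sufficient to separate
tetranucleotide clusters without simulating reads or assembly),
lognormal contig lengths (defaults: meanlog 8.0, sdlog 0.45,
floor 500 bp — a few-kbp median typical of short-read metagenome
assemblies), lognormal per-genome depths across samples (meanlog 2.3,
sdlog 0.7, ~10× median) with 10% per-contig noise, a 20-marker
single-copy catalog placed one-per-genome (a duplication flag injects
redundancy), and an optional label-contamination rate. Defaults of 5
genomes × 20–30 contigs keep all-pairs metrics fast while leaving
enough contigs per genome for stable centroids.

What it does **not** emulate: read-level error, chimeric contigs,
strain microdiversity, repeat-driven composition outliers, or
correlated coverage structure. Passing tests therefore demonstrate
correctness of the operators and metrics on separable communities,
not robustness to every pathology of real assemblies.

`perturb_plan` degrades a truth plan (random swaps, splits, merges)
with at least one change whenever intensity is positive, enabling
"curation improves the plan" rehearsals: the acceptance script
corrupts 30% of labels, re-curates by assigning each polygon-selected
nearest-truth-centroid cluster, and verifies that ARI strictly rises
and silhouette does not fall.

## Numerical choices and limitations

Tolerances in tests: silhouette matches a brute-force oracle to
1e-9; ARI matches pair counting exactly (the formula is rational
arithmetic in doubles, exact at these sizes). Histogram edges come
from `seq(lo, hi, length.out = n_bins + 1)`; the last bin is closed.
Polygon boundary detection uses a 1e-12 collinearity band —
embedding coordinates are O(1), so this is far below meaningful
distances. PCA pre-reduction is deterministic up to component sign
(R's `prcomp`); t-SNE/UMAP reproducibility is guaranteed only for
identical inputs, parameters, seed and thread count (fixed to 1).

Known limitations: the silhouette is O(n²) in memory for the exact
path (use `max_n` beyond ~10⁴ contigs); completeness ignores marker
collocation by design; the GFF reader keeps only contig membership
of features (positions are parsed but unused); no compatibility is
promised with checkpoint files of other tools.
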