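Package: magcurate
Title: Curation Toolkit for Metagenome Bins and Contig Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for human-in-the-loop refinement of
    metagenome-assembled genomes (MAGs). Provides a typed per-contig
    property table (numeric, categorical, feature-set and descriptive
    columns) with masking and highlighting, binning-plan editing with
    full undo, selection operators (polygon, histogram range, attribute
    search), value transforms, k-mer frequency embedding (PCA, t-SNE,
    UMAP with PCA pre-reduction), evaluation metrics (silhouette
    coefficient, adjusted Rand index, marker-based completeness and
    redundancy, MAG quality tiers, length-weighted bin comparison),
    converters for common assembler and classifier outputs (SPAdes,
    MegaHit, Kraken, GTDB lineage strings, GFF3, marker maps), JSON
    checkpointing, and a synthetic community generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices,
    generics,
    Biostrings,
    rtracklayer,
    Rtsne,
    uwot
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr
Config/testthat/edition: 3
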