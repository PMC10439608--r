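#' Specify a synthetic metagenomic community
#'
#' The generator emulates the structure a curation session consumes:
#' per-genome base composition (drawn from a Dirichlet, so genomes
#' form separable k-mer clusters), lognormal contig lengths, lognormal
#' per-sample genome depths, single-copy marker placements, and a
#' ground-truth contig-to-genome plan. It does not simulate reads,
#' assembly artifacts or sequencing error.
#'
#' @param n_genomes Number of genomes (default 5).
#' @param contigs_per_genome Two-element range; each genome draws a
#'   uniform contig count from it (default 20..30).
#' @param length_meanlog,length_sdlog Lognormal contig-length
#'   parameters in bp (defaults give a median around 3 kbp).
#' @param min_length Floor on contig length in bp.
#' @param composition_divergence Dirichlet concentration for genome
#'   base frequencies; smaller values give more divergent genome
#'   compositions (default 1, well separated).
#' @param n_samples Number of coverage samples (default 3).
#' @param coverage_meanlog,coverage_sdlog Lognormal per-genome depth
#'   parameters per sample.
#' @param n_markers Size of the single-copy marker catalog (default 20).
#' @param duplicate_markers Fraction of markers per genome placed
#'   twice, to inject redundancy (default 0).
#' @param contamination_rate Fraction of contigs whose truth label is
#'   swapped to another genome (default 0; in \[0, 1)).
#' @param seed Seed making the whole community reproducible.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_genomes = 5, contigs_per_genome = c(20, 30),
                           length_meanlog = 8.0, length_sdlog = 0.45,
                           min_length = 500,
                           composition_divergence = 1,
                           n_samples = 3,
                           coverage_meanlog = 2.3, coverage_sdlog = 0.7,
                           n_markers = 20, duplicate_markers = 0,
                           contamination_rate = 0, seed = 42) {
  if (n_genomes < 1) abort("n_genomes must be >= 1")
  if (contamination_rate < 0 || contamination_rate >= 1) {
    abort("contamination_rate must be in [0, 1)")
  }
  structure(list(n_genomes = n_genomes, contigs_per_genome = contigs_per_genome,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 min_length = min_length,
                 composition_divergence = composition_divergence,
                 n_samples = n_samples, coverage_meanlog = coverage_meanlog,
                 coverage_sdlog = coverage_sdlog, n_markers = n_markers,
                 duplicate_markers = duplicate_markers,
                 contamination_rate = contamination_rate, seed = seed),
            class = "community_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a ground-truth-labeled synthetic community
#'
#' Draws one base-frequency profile per genome (order-0 Markov
#' composition), samples contig sequences and lengths from it, builds
#' a typed contig table with length, GC, per-sample coverage, a
#' genome-taxonomy column and marker-gene feature sets, and returns
#' the ground-truth binning plan. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @return List with `sequences` (named character vector), `table` (a
#'   `contig_table`), `truth` (a `binning_plan` named `"truth"`),
#'   `markers` (the [feature_group()] catalog), and `genomes` (tibble
#'   of genome base frequencies and depths).
#' @export
generate_community <- function(spec) {
  if (spec$min_length < 8) abort("min_length too small to carry tetranucleotides")
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  genome_ids <- sprintf("G%02d", seq_len(spec$n_genomes))

  comp <- t(vapply(genome_ids, function(g)
    rdirichlet1(rep(spec$composition_divergence, 4)), numeric(4)))
  colnames(comp) <- bases

  depths <- matrix(stats::rlnorm(spec$n_genomes * spec$n_samples,
                                 spec$coverage_meanlog, spec$coverage_sdlog),
                   nrow = spec$n_genomes,
                   dimnames = list(genome_ids, sprintf("cov_s%d", seq_len(spec$n_samples))))

  n_contigs <- sample(spec$contigs_per_genome[1]:spec$contigs_per_genome[2],
                      spec$n_genomes, replace = TRUE)
  rows <- list(); seqs <- character(0); truth <- list()
  for (gi in seq_len(spec$n_genomes)) {
    g <- genome_ids[gi]
    cids <- sprintf("%s_c%03d", g, seq_len(n_contigs[gi]))
    lens <- pmax(round(stats::rlnorm(n_contigs[gi], spec$length_meanlog,
                                     spec$length_sdlog)), spec$min_length)
    sq <- vapply(lens, function(L)
      paste(sample(bases, L, replace = TRUE, prob = comp[gi, ]), collapse = ""), "")
    names(sq) <- cids
    seqs <- c(seqs, sq)
    covs <- vapply(seq_len(spec$n_samples), function(s)
      depths[gi, s] * stats::rlnorm(n_contigs[gi], 0, 0.1), numeric(n_contigs[gi]))
    covs <- matrix(covs, nrow = n_contigs[gi])
    row <- tibble(id = cids, length = lens, genome = g)
    for (s in seq_len(spec$n_samples)) row[[colnames(depths)[s]]] <- covs[, s]
    rows[[gi]] <- row
    truth[[gi]] <- tibble(contig = cids, bin = g)
  }
  rows <- bind_rows(rows)
  truth <- bind_rows(truth)

  # single-copy marker placement, one per genome per marker
  markers <- sprintf("M%04d", seq_len(spec$n_markers))
  hit_rows <- lapply(genome_ids, function(g) {
    cids <- rows$id[rows$genome == g]
    placed <- sample(cids, spec$n_markers, replace = TRUE)
    dup_n <- round(spec$duplicate_markers * spec$n_markers)
    if (dup_n > 0) {
      extra <- sample(markers, dup_n)
      placed <- c(placed, sample(cids, dup_n, replace = TRUE))
      mk <- c(markers, extra)
    } else mk <- markers
    tibble(contig = placed, marker = mk)
  })
  hits <- bind_rows(hit_rows)
  feature_cells <- vapply(rows$id, function(cid)
    join_features(hits$marker[hits$contig == cid]), "")

  gc <- vapply(seqs, function(s) {
    f <- count_kmers(s, 1, canonical = FALSE)
    100 * sum(f[c("C", "G")], na.rm = TRUE) / sum(f)
  }, numeric(1))

  tab_rows <- rows
  tab_rows$gc <- unname(gc[rows$id])
  tab_rows$markers <- unname(feature_cells)
  specs <- bind_rows(
    column_spec("length", "numeric"),
    column_spec("gc", "numeric"),
    column_spec("genome", "categorical"),
    bind_rows(lapply(colnames(depths), function(cc) column_spec(cc, "numeric"))),
    column_spec("markers", "feature_set")
  )
  table <- build_contig_table(tab_rows[, c("id", "length", "gc", "genome",
                                           colnames(depths), "markers")], specs)

  if (spec$contamination_rate > 0 && spec$n_genomes > 1) {
    n_swap <- round(spec$contamination_rate * nrow(truth))
    if (n_swap > 0) {
      swap <- sample(nrow(truth), n_swap)
      truth$bin[swap] <- vapply(truth$bin[swap], function(b)
        sample(setdiff(genome_ids, b), 1), "")
    }
  }

  list(sequences = seqs, table = table,
       truth = new_plan("truth", truth),
       markers = feature_group("markers", markers),
       genomes = as_tibble(cbind(tibble(genome = genome_ids),
                                 as_tibble(comp), as_tibble(depths))))
}

#' Degrade a binning plan for curation rehearsals
#'
#' Produces a controllably wrong plan from a ground truth, emulating
#' the imperfect output of automatic binners: `random_swap` reassigns
#' a fraction of contigs to other bins, `split` breaks bins in two,
#' `merge` collapses bin pairs. At least one change is made whenever
#' `intensity > 0`.
#'
#' @param truth A `binning_plan`.
#' @param mode `"random_swap"`, `"split"` or `"merge"`.
#' @param intensity Fraction in \[0, 1\] of contigs (or bins) affected.
#' @param seed Seed for the perturbation draw.
#' @return A new `binning_plan` named `<truth>_<mode>`.
#' @export
perturb_plan <- function(truth, mode = c("random_swap", "split", "merge"),
                         intensity = 0.3, seed = 1) {
  mode <- match.arg(mode)
  if (intensity < 0 || intensity > 1) abort("intensity must be in [0, 1]")
  asg <- truth$assignment
  set.seed(seed)
  if (intensity > 0) {
    if (mode == "random_swap") {
      bins <- unique(asg$bin)
      if (length(bins) > 1) {
        n_swap <- max(1L, round(intensity * nrow(asg)))
        swap <- sample(nrow(asg), n_swap)
        asg$bin[swap] <- vapply(asg$bin[swap], function(b)
          sample(setdiff(bins, b), 1), "")
      }
    } else if (mode == "split") {
      bins <- unique(asg$bin)
      n_split <- max(1L, round(intensity * length(bins)))
      for (b in sample(bins, n_split)) {
        members <- which(asg$bin == b)
        if (length(members) >= 2) {
          half <- sample(members, ceiling(length(members) / 2))
          asg$bin[half] <- paste0(b, "_split")
        }
      }
    } else {
      bins <- unique(asg$bin)
      n_merge <- max(1L, round(intensity * length(bins) / 2))
      for (i in seq_len(n_merge)) {
        bins_now <- unique(asg$bin)
        if (length(bins_now) < 2) break
        pair <- sample(bins_now, 2)
        asg$bin[asg$bin == pair[2]] <- pair[1]
      }
    }
  }
  new_plan(paste0(truth$name, "_", mode), asg)
}
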