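# Canonical form of each k-mer: the lexicographic minimum of the k-mer
# and its reverse complement (strand-insensitive composition).
canonical_names <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

#' Count k-mers in a DNA sequence
#'
#' Sliding window of stride 1; windows containing any non-ACGT
#' character (ambiguity codes, gaps) are skipped. With
#' `canonical = TRUE` each k-mer is pooled with its reverse complement
#' under the lexicographically smaller of the two, so counts do not
#' depend on which strand was assembled.
#'
#' @param seq A DNA string.
#' @param k Word size (>= 1; sizes above 8 are memory-hungry and warn).
#' @param canonical Pool reverse-complement pairs (default TRUE).
#' @return Named integer vector of counts for the observed k-mers,
#'   lexicographically ordered. `k > nchar(seq)` gives an empty vector.
#' @export
#' @examples
#' count_kmers("ATGCA", k = 4)
count_kmers <- function(seq, k, canonical = TRUE) {
  if (k < 1) abort("k must be >= 1")
  if (k > 8) warn(sprintf("k = %d implies %s k-mer columns; expect heavy memory use", k, format(4^k, big.mark = ",")))
  if (k > nchar(seq)) return(stats::setNames(integer(0), character(0)))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
  if (canonical) counts <- tapply(counts, canonical_names(names(counts)), sum)
  counts <- counts[counts > 0]
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[order(names(out))]
}

#' k-mer frequency matrix over a set of contigs
#'
#' Counts k-mers per contig and row-normalizes to frequencies so that
#' composition, not contig length, drives downstream embedding. A
#' contig with zero valid windows (e.g. all ambiguous bases) gets an
#' all-missing row, flagged in the attached report. Columns are the
#' k-mers observed anywhere in the set, lexicographically ordered.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param k Word size (default 4: tetranucleotide frequencies).
#' @param canonical Pool reverse-complement pairs (default TRUE).
#' @return A `kmer_matrix`: list with `freqs` (n x m row-stochastic
#'   matrix, contig IDs as rownames), `k`, `canonical`, and a `report`
#'   listing contigs with no valid windows.
#' @export
kmer_freq_matrix <- function(seqs, k = 4, canonical = TRUE) {
  if (!length(seqs)) abort("no sequences given")
  if (k > 8) warn(sprintf("k = %d implies %s k-mer columns; expect heavy memory use", k, format(4^k, big.mark = ",")))
  sset <- if (inherits(seqs, "DNAStringSet")) seqs else Biostrings::DNAStringSet(seqs)
  if (is.null(names(sset))) abort("sequences must be named by contig ID")
  counts <- Biostrings::oligonucleotideFrequency(sset, width = k)
  if (canonical) {
    canon <- canonical_names(colnames(counts))
    counts <- t(rowsum(t(counts), canon))
  }
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  totals <- rowSums(counts)
  freqs <- counts / ifelse(totals > 0, totals, 1)
  freqs[totals == 0, ] <- NA_real_
  rownames(freqs) <- names(sset)
  structure(list(freqs = freqs, k = k, canonical = canonical,
                 report = list(no_valid_windows = names(sset)[totals == 0])),
            class = "kmer_matrix")
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("<kmer_matrix: %d contigs x %d %s%d-mers>\n", nrow(x$freqs),
              ncol(x$freqs), if (x$canonical) "canonical " else "", x$k))
  invisible(x)
}

#' Embed contigs in 2D from their k-mer frequencies
#'
#' Produces the scatter coordinates for composition-based curation.
#' `pca` returns the first two principal components. `tsne` and `umap`
#' first reduce to `pca_pre_dims` principal components (capped at
#' `min(n - 1, m)`), then run Barnes-Hut t-SNE or UMAP on that reduced
#' space. Every stochastic step is seeded, so a rerun with the same
#' inputs, parameters and seed reproduces the coordinates exactly.
#'
#' @param km A [kmer_freq_matrix()] result (or a plain numeric matrix
#'   with contig rownames).
#' @param method `"pca"`, `"tsne"` or `"umap"`.
#' @param pca_pre_dims Principal components retained before t-SNE/UMAP
#'   (default 50).
#' @param perplexity t-SNE perplexity (default 30; lowered
#'   automatically when the selection is too small for it).
#' @param n_neighbors,min_dist UMAP neighborhood size (default 15) and
#'   minimum embedding distance (default 0.1).
#' @param seed Random seed (default 42).
#' @return A tibble `id`, `x`, `y`, with attributes `method`, `params`
#'   and `seed`; directly appendable to a contig table.
#' @export
embed_contigs <- function(km, method = c("pca", "tsne", "umap"),
                          pca_pre_dims = 50, perplexity = 30,
                          n_neighbors = 15, min_dist = 0.1, seed = 42) {
  method <- match.arg(method)
  X <- if (inherits(km, "kmer_matrix")) km$freqs else km
  bad <- rownames(X)[!apply(is.finite(X), 1, all)]
  if (length(bad)) abort(sprintf("non-finite frequencies for contig '%s'", bad[1]))
  n <- nrow(X)
  if (n < 3) abort("need at least 3 contigs to embed")
  X <- X[, apply(X, 2, function(v) any(v != v[1])), drop = FALSE]
  if (ncol(X) == 0) {  # all contigs compositionally identical
    out <- tibble(id = rownames(X), x = 0, y = 0)
    attr(out, "method") <- method
    return(out)
  }

  pcs <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  coords <- if (method == "pca") {
    p <- pcs$x
    if (ncol(p) < 2) p <- cbind(p, 0)
    p[, 1:2]
  } else {
    ndim <- min(pca_pre_dims, n - 1, ncol(pcs$x))
    Xp <- pcs$x[, seq_len(ndim), drop = FALSE]
    set.seed(seed)
    if (method == "tsne") {
      perp <- min(perplexity, floor((n - 2) / 3))
      Rtsne::Rtsne(Xp, dims = 2, pca = FALSE, perplexity = max(perp, 1),
                   theta = 0.5, check_duplicates = FALSE, num_threads = 1,
                   verbose = FALSE)$Y
    } else {
      uwot::umap(Xp, n_neighbors = min(n_neighbors, n - 1), min_dist = min_dist,
                 n_threads = 1, n_sgd_threads = 1, batch = FALSE)
    }
  }
  out <- tibble(id = rownames(X), x = coords[, 1], y = coords[, 2])
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  attr(out, "params") <- list(pca_pre_dims = pca_pre_dims, perplexity = perplexity,
                              n_neighbors = n_neighbors, min_dist = min_dist)
  out
}
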