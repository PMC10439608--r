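# Normalize a label input (binning_plan, tibble(contig, bin), or named
# character vector) to a named character vector contig -> bin.
as_assignment <- function(labels) {
  if (inherits(labels, "binning_plan")) {
    return(stats::setNames(labels$assignment$bin, labels$assignment$contig))
  }
  if (is.data.frame(labels)) {
    return(stats::setNames(as.character(labels[[2]]), as.character(labels[[1]])))
  }
  if (!is.null(names(labels))) return(stats::setNames(as.character(labels), names(labels)))
  abort("labels must be a binning_plan, a contig/bin data frame, or a named vector")
}

as_coord_matrix <- function(coords) {
  if (is.matrix(coords)) {
    if (is.null(rownames(coords))) abort("coordinate matrix needs contig IDs as rownames")
    return(coords)
  }
  coords <- as_tibble(coords)
  if (!"id" %in% names(coords)) abort("coords must have an 'id' column")
  m <- as.matrix(coords[setdiff(names(coords), c("id", ".mask", ".highlight"))])
  rownames(m) <- coords$id
  storage.mode(m) <- "double"
  m
}

#' Silhouette coefficients of a binning plan
#'
#' Per-contig clustering confidence in a user-chosen numeric feature
#' space (typically the 2D embedding): `s(i) = (b(i) - a(i)) /
#' max(a(i), b(i))` with `a(i)` the mean distance to other members of
#' the contig's own bin and `b(i)` the smallest mean distance to any
#' other bin. Members of singleton bins score 0 by convention;
#' unbinned contigs get no score. Distances are Euclidean over
#' features standardized to zero mean / unit variance (disable with
#' `standardize = FALSE` to use raw axes).
#'
#' @param coords Data frame with an `id` column plus numeric feature
#'   columns, or a numeric matrix with contig IDs as rownames. All
#'   coordinates must be finite.
#' @param labels A `binning_plan`, a two-column contig/bin data frame,
#'   or a named `contig -> bin` vector. Contigs absent from `labels`
#'   or from `coords` are excluded (reported via `n_used`).
#' @param standardize Scale each feature to zero mean / unit variance
#'   before computing distances.
#' @param max_n Subsample at most this many contigs (per `seed`) when
#'   the selection is larger; the default computes the exact all-pairs
#'   silhouette.
#' @param seed Seed for the subsample draw.
#' @return A `silhouette_result` with `per_contig` (tibble `id`, `bin`,
#'   `silhouette`), `per_bin_mean`, `overall_mean`, `n_used`. Has
#'   `tidy()`, `glance()` and `autoplot()` methods.
#' @export
silhouette_scores <- function(coords, labels, standardize = TRUE,
                              max_n = Inf, seed = NULL) {
  X <- as_coord_matrix(coords)
  assign <- as_assignment(labels)
  ids <- intersect(rownames(X), names(assign))
  X <- X[ids, , drop = FALSE]
  bad <- rownames(X)[!apply(is.finite(X), 1, all)]
  if (length(bad)) abort(sprintf("non-finite coordinates for contig '%s'", bad[1]))
  if (length(ids) > max_n) {
    if (!is.null(seed)) set.seed(seed)
    ids <- sort(sample(ids, max_n))
    X <- X[ids, , drop = FALSE]
  }
  g <- assign[ids]
  if (length(unique(g)) < 2L) abort("silhouette requires at least 2 bins")
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0  # constant axis carries no distance
  }
  n <- length(ids)
  d <- as.matrix(stats::dist(X))
  sums <- rowsum(d, g)                      # bin x contig distance sums
  sizes <- as.vector(table(g)[rownames(sums)])
  own <- match(g, rownames(sums))
  a <- sums[cbind(own, seq_len(n))] / pmax(sizes[own] - 1L, 1L)
  means <- sums / sizes
  means[cbind(own, seq_len(n))] <- Inf
  b <- apply(means, 2, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[sizes[own] == 1L] <- 0                  # singleton-bin convention

  per_contig <- tibble(id = ids, bin = unname(g), silhouette = unname(s))
  per_bin <- per_contig |> group_by(.data$bin) |>
    summarise(mean_silhouette = mean(.data$silhouette), n = n(), .groups = "drop")
  structure(list(per_contig = per_contig, per_bin_mean = per_bin,
                 overall_mean = mean(s), n_used = n),
            class = "silhouette_result")
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat(sprintf("<silhouette over %d contigs in %d bins: overall mean %.4f>\n",
              x$n_used, nrow(x$per_bin_mean), x$overall_mean))
  invisible(x)
}

#' @method tidy silhouette_result
#' @export
tidy.silhouette_result <- function(x, ...) x$per_contig

#' @method glance silhouette_result
#' @export
glance.silhouette_result <- function(x, ...) {
  tibble(overall_mean = x$overall_mean, n_used = x$n_used,
         n_bins = nrow(x$per_bin_mean))
}

#' @method autoplot silhouette_result
#' @export
autoplot.silhouette_result <- function(object, ...) {
  d <- object$per_contig |> arrange(.data$bin, desc(.data$silhouette)) |>
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$silhouette,
                                  fill = .data$bin)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = object$overall_mean, linetype = 2) +
    ggplot2::labs(x = NULL, y = "silhouette") +
    ggplot2::theme_minimal()
}

choose2 <- function(n) n * (n - 1) / 2

#' Adjusted Rand index between two binning plans
#'
#' Chance-corrected pair-counting agreement, computed over the
#' intersection of contigs binned in both plans (`n_shared`, reported):
#' `ARI = (Index - Expected) / (Max - Expected)` with
#' `Index = sum_ij C(n_ij, 2)`, `Expected = sum_i C(a_i, 2) *
#' sum_j C(b_j, 2) / C(n, 2)` and `Max = (sum_i C(a_i, 2) +
#' sum_j C(b_j, 2)) / 2` over the bin-by-bin contingency table. Equals
#' 1 exactly when the plans agree on all shared contigs.
#'
#' @param plan_a,plan_b `binning_plan`s, contig/bin data frames, or
#'   named vectors.
#' @return An `ari_result` with `ari`, `n_shared` and the
#'   `contingency` matrix; has `glance()`.
#' @export
adjusted_rand <- function(plan_a, plan_b) {
  a <- as_assignment(plan_a)
  b <- as_assignment(plan_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 2L) abort("plans share fewer than 2 binned contigs")
  tab <- table(a[shared], b[shared])
  n <- length(shared)
  index <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  ari <- if (maximum == expected) {
    1  # both plans induce the same trivial pair structure
  } else {
    (index - expected) / (maximum - expected)
  }
  structure(list(ari = ari, n_shared = n, contingency = unclass(tab)),
            class = "ari_result")
}

#' @export
print.ari_result <- function(x, ...) {
  cat(sprintf("<ARI = %.4f over %d shared contigs>\n", x$ari, x$n_shared))
  invisible(x)
}

#' @method glance ari_result
#' @export
glance.ari_result <- function(x, ...) tibble(ari = x$ari, n_shared = x$n_shared)

#' Marker-based completeness and redundancy of a contig selection
#'
#' A fast first-pass bin quality estimate from a flat marker catalog
#' (no marker collocation model): with `found` the distinct group
#' members present in the selection's feature sets and `total` the
#' summed copy count of member hits, completeness is
#' `100 * |found| / |group|` and redundancy (contamination) is
#' `100 * (total - |found|) / |group|`. Redundancy can exceed 100%.
#' Masked contigs are excluded.
#'
#' @param table A `contig_table`.
#' @param ids Selection (default all unmasked contigs).
#' @param group A [feature_group()] of expected members.
#' @param feature_column Name of the feature-set column holding hits.
#' @return One-row tibble: `completeness`, `redundancy`, `n_found`,
#'   `n_total_hits`, `group_size`.
#' @export
completeness_redundancy <- function(table, ids = NULL, group, feature_column) {
  if (!inherits(group, "feature_group")) abort("group must be a feature_group")
  if (ct_dtype(table, feature_column) != "feature_set") {
    abort(sprintf("column '%s' is not a feature set", feature_column))
  }
  ids <- effective_ids(table, ids)
  hits <- unlist(table[[feature_column]][match(ids, table$id)], use.names = FALSE)
  hits <- hits[hits %in% group$members]
  found <- length(unique(hits))
  total <- length(hits)
  m <- length(group$members)
  tibble(completeness = 100 * found / m,
         redundancy = 100 * (total - found) / m,
         n_found = found, n_total_hits = total, group_size = m)
}

QUALITY_TIERS <- c("high", "medium", "low", "excluded")

#' MAG quality tier from completeness and contamination
#'
#' The community reporting standard: high quality means >= 90%
#' complete and < 5% contaminated; medium quality >= 50% complete and
#' < 10% contaminated (and not high); low quality < 50% complete and
#' < 10% contaminated; bins with >= 10% contamination are excluded
#' from all tiers. Vectorized.
#'
#' @param completeness,contamination Percentages (non-negative).
#' @return Factor with levels `high`, `medium`, `low`, `excluded`.
#' @export
#' @examples
#' classify_quality(c(95, 55, 30, 80), c(3, 8, 5, 12))
classify_quality <- function(completeness, contamination) {
  if (any(completeness < 0 | contamination < 0, na.rm = TRUE)) {
    abort("completeness and contamination must be non-negative")
  }
  tier <- ifelse(contamination >= 10, "excluded",
          ifelse(completeness >= 90 & contamination < 5, "high",
          ifelse(completeness >= 50, "medium", "low")))
  factor(tier, levels = QUALITY_TIERS)
}

as_length_lookup <- function(lengths) {
  if (is.data.frame(lengths)) return(stats::setNames(as.numeric(lengths[[2]]), as.character(lengths[[1]])))
  if (!is.null(names(lengths))) return(stats::setNames(as.numeric(lengths), names(lengths)))
  abort("lengths must be a named vector or an id/length data frame")
}

#' Overlap between two bins
#'
#' Length-weighted by default (the natural scale for genome recovery):
#' `jaccard = shared_length / union_length`, and each containment is
#' the shared length divided by that bin's total length. Set
#' `weighted = FALSE` for the plain contig-count variant.
#'
#' @param bin_a,bin_b Character vectors of contig IDs.
#' @param lengths Named `id -> bp` vector or id/length data frame
#'   (required when `weighted = TRUE`; must cover all members).
#' @param weighted Weight by contig length rather than counting IDs.
#' @return One-row tibble: `jaccard`, `containment_a_in_b`,
#'   `containment_b_in_a`, `shared`.
#' @export
compare_bins <- function(bin_a, bin_b, lengths = NULL, weighted = TRUE) {
  bin_a <- unique(as.character(bin_a)); bin_b <- unique(as.character(bin_b))
  un <- union(bin_a, bin_b)
  if (!length(un)) abort("both bins are empty")
  w <- if (weighted) {
    lut <- as_length_lookup(lengths)
    missing <- setdiff(un, names(lut))
    if (length(missing)) abort(sprintf("no length for contig '%s'", missing[1]))
    lut
  } else stats::setNames(rep(1, length(un)), un)
  shared <- sum(w[intersect(bin_a, bin_b)])
  tibble(jaccard = shared / sum(w[un]),
         containment_a_in_b = shared / sum(w[bin_a]),
         containment_b_in_a = shared / sum(w[bin_b]),
         shared = shared)
}
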