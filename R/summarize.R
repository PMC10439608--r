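numeric_column <- function(table, column) {
  if (ct_dtype(table, column) != "numeric") abort(sprintf("column '%s' is not numeric", column))
  table[[column]]
}

#' Summarize a numeric column over a contig selection
#'
#' The side-panel statistics: total assembly length is the `sum` of
#' contig lengths; GC of a selection is the `weighted_mean` of contig
#' GC weighted by length. Masked contigs and missing values are always
#' excluded; an empty effective selection yields `NA`, not an error.
#'
#' @param table A `contig_table`.
#' @param ids Contig IDs (default: all unmasked).
#' @param column Numeric column to summarize.
#' @param method One of `sum`, `mean`, `weighted_mean`, `min`, `max`,
#'   `median`.
#' @param weight_column Numeric non-negative weight column, required
#'   for `weighted_mean` (weights of all zero are an error).
#' @return A single number, or `NA` when nothing is selected.
#' @export
summarize_numeric <- function(table, ids = NULL, column, method = c("sum", "mean",
                              "weighted_mean", "min", "max", "median"),
                              weight_column = NULL) {
  method <- match.arg(method)
  ids <- effective_ids(table, ids)
  pos <- match(ids, table$id)
  x <- numeric_column(table, column)[pos]
  if (method == "weighted_mean") {
    if (is.null(weight_column)) abort("weighted_mean requires weight_column")
    w <- numeric_column(table, weight_column)[pos]
    if (any(w < 0, na.rm = TRUE)) abort("weights must be non-negative")
    ok <- !is.na(x) & !is.na(w)
    if (!any(ok)) return(NA_real_)
    if (sum(w[ok]) == 0) abort("all weights are zero")
    return(sum(w[ok] * x[ok]) / sum(w[ok]))
  }
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  switch(method, sum = sum(x), mean = mean(x), min = min(x), max = max(x),
         median = stats::median(x))
}

#' Majority category of a contig selection
#'
#' Applies the majority rule over non-missing values, optionally
#' weighted (typically by contig length), and reports the winner with
#' its share as a percentage suffix, e.g. `"Firmicutes (80%)"`. The
#' denominator is the annotated (non-missing) part of the selection.
#' Ties break lexicographically by label.
#'
#' @inheritParams summarize_numeric
#' @param column Categorical column.
#' @param weighted Weight shares by `weight_column` instead of counts.
#' @param weight_column Numeric weight column (e.g. `"length"`).
#' @return One-row tibble with `label`, `fraction`, `weighted` and the
#'   rendered `summary` string, or a zero-row tibble when no contig in
#'   the selection is annotated.
#' @export
summarize_category <- function(table, ids = NULL, column, weighted = FALSE,
                               weight_column = NULL) {
  if (ct_dtype(table, column) != "categorical") abort(sprintf("column '%s' is not categorical", column))
  ids <- effective_ids(table, ids)
  pos <- match(ids, table$id)
  lab <- table[[column]][pos]
  w <- if (weighted) {
    if (is.null(weight_column)) abort("weighted summary requires weight_column")
    numeric_column(table, weight_column)[pos]
  } else rep(1, length(pos))
  ok <- !is.na(lab) & !is.na(w)
  empty <- tibble(label = character(0), fraction = numeric(0),
                  weighted = logical(0), summary = character(0))
  if (!any(ok)) return(empty)
  shares <- tapply(w[ok], lab[ok], sum)
  shares <- shares / sum(shares)
  winner <- sort(names(shares)[shares == max(shares)])[1]  # lexicographic tie-break
  frac <- unname(shares[winner])
  tibble(label = winner, fraction = frac, weighted = weighted,
         summary = sprintf("%s (%d%%)", winner, as.integer(round(100 * frac))))
}

#' Histogram of a (transformed) numeric column
#'
#' Equal-width bins over the range of the transformed values of the
#' selection. All bins are half-open `[lo, hi)` except the last, which
#' is closed so the maximum lands in it. A constant-valued selection is
#' given a degenerate range widened by 0.5 on each side, with every
#' count in the first bin.
#'
#' @inheritParams summarize_numeric
#' @param n_bins Number of bins (default 20).
#' @param transform Transform method applied before binning (see
#'   [transform_values()]).
#' @return A `histogram_result`: list with `edges` (n_bins + 1),
#'   `counts`, `column`, `transform`, `n_used`. Has [generics::tidy()]
#'   and [ggplot2::autoplot()] methods.
#' @export
contig_histogram <- function(table, ids = NULL, column, n_bins = 20, transform = "none") {
  if (n_bins < 1) abort("n_bins must be >= 1")
  ids <- effective_ids(table, ids)
  pos <- match(ids, table$id)
  x <- transform_values(numeric_column(table, column)[pos], transform)
  x <- x[!is.na(x)]
  if (!length(x)) abort(sprintf("no finite values in column '%s' for the selection", column))
  lo <- min(x); hi <- max(x)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(edges = edges, counts = counts, column = column,
                 transform = transform, n_used = length(x)),
            class = "histogram_result")
}

#' @export
print.histogram_result <- function(x, ...) {
  cat(sprintf("<histogram of %s (%s): %d values in %d bins over [%g, %g]>\n",
              x$column, x$transform, x$n_used, length(x$counts),
              x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

#' @method tidy histogram_result
#' @export
tidy.histogram_result <- function(x, ...) {
  n <- length(x$counts)
  tibble(bin = seq_len(n), lower = x$edges[-(n + 1)], upper = x$edges[-1],
         count = x$counts)
}

#' @method autoplot histogram_result
#' @export
autoplot.histogram_result <- function(object, ...) {
  d <- tidy.histogram_result(object)
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                  ymin = 0, ymax = .data$count)) +
    ggplot2::geom_rect(fill = "steelblue", color = "white") +
    ggplot2::labs(x = sprintf("%s (%s)", object$column, object$transform),
                  y = "contigs") +
    ggplot2::theme_minimal()
}

#' Select contigs by value range on a transformed scale
#'
#' The histogram drag-selection: keep contigs whose transformed value
#' falls in `[lo, hi]` (bounds inclusive). Masked contigs and missing
#' (or out-of-domain) values are excluded.
#'
#' @inheritParams contig_histogram
#' @param lo,hi Range bounds on the transformed scale (`lo <= hi`).
#' @return Character vector of selected contig IDs.
#' @export
select_range <- function(table, ids = NULL, column, lo, hi, transform = "none") {
  if (lo > hi) abort("lo must be <= hi")
  ids <- effective_ids(table, ids)
  pos <- match(ids, table$id)
  x <- transform_values(numeric_column(table, column)[pos], transform)
  ids[!is.na(x) & x >= lo & x <= hi]
}
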