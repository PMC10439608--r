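#' Create an empty binning plan
#'
#' A binning plan is a named, partial assignment of contigs to bins
#' (every contig belongs to at most one bin; unbinned contigs are
#' simply absent). Every edit appends a reversible record to the
#' plan's history, so any sequence of edits can be undone step by
#' step.
#'
#' @param name Plan name.
#' @param assignment Optional initial contig/bin data frame or named
#'   `contig -> bin` vector (recorded as the initial state, not as an
#'   edit).
#' @return A `binning_plan`.
#' @export
new_plan <- function(name, assignment = NULL) {
  asg <- if (is.null(assignment)) {
    tibble(contig = character(0), bin = character(0))
  } else {
    v <- as_assignment(assignment)
    if (anyDuplicated(names(v))) abort("a contig appears twice in the assignment")
    tibble(contig = names(v), bin = unname(v))
  }
  if (any(!nzchar(asg$bin))) abort("bin names must be non-empty")
  structure(list(name = as.character(name), bins = sort(unique(asg$bin)),
                 assignment = asg, history = list()),
            class = "binning_plan")
}

#' @export
print.binning_plan <- function(x, ...) {
  cat(sprintf("<binning_plan '%s': %d bins, %d binned contigs, %d edits>\n",
              x$name, length(x$bins), nrow(x$assignment), length(x$history)))
  invisible(x)
}

#' @method tidy binning_plan
#' @export
tidy.binning_plan <- function(x, ...) x$assignment

plan_members <- function(plan, bin) plan$assignment$contig[plan$assignment$bin == bin]

# record: everything needed to revert one edit exactly
push_history <- function(plan, action, args, prev_rows, removed_bins = character(0),
                         added_bins = character(0)) {
  plan$history[[length(plan$history) + 1L]] <- list(
    action = action, args = args, prev_rows = prev_rows,
    removed_bins = removed_bins, added_bins = added_bins,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
  )
  plan
}

rows_for <- function(plan, contigs) {
  hit <- plan$assignment[plan$assignment$contig %in% contigs, , drop = FALSE]
  # contigs currently unbinned are recorded with bin = NA
  miss <- setdiff(contigs, hit$contig)
  bind_rows(hit, tibble(contig = miss, bin = rep(NA_character_, length(miss))))
}

restore_rows <- function(plan, contigs, prev_rows) {
  plan$assignment <- plan$assignment[!plan$assignment$contig %in% contigs, , drop = FALSE]
  keep <- prev_rows[!is.na(prev_rows$bin), , drop = FALSE]
  plan$assignment <- bind_rows(plan$assignment, keep)
  plan
}

#' Edit a binning plan
#'
#' Actions: `create` a bin; `assign` contigs to an existing bin (a
#' contig already in another bin is moved — single membership is
#' invariant, and the move is one atomic history record); `unassign`
#' contigs; `merge` two or more bins into the first of `bins` (or
#' `into`); `delete` a bin and unassign its members; `rename` a bin.
#' Each action appends one reversible history record; see
#' [undo_plan()].
#'
#' @param plan A `binning_plan`.
#' @param action One of `create`, `assign`, `unassign`, `merge`,
#'   `delete`, `rename`.
#' @param bin Target bin (create/assign/delete/rename).
#' @param ids Contig IDs (assign/unassign).
#' @param bins Bins to merge (>= 2).
#' @param into Name of the surviving merged bin (default `bins[1]`).
#' @param new_name New name (rename).
#' @return The edited `binning_plan`.
#' @export
edit_plan <- function(plan, action = c("create", "assign", "unassign", "merge",
                                       "delete", "rename"),
                      bin = NULL, ids = NULL, bins = NULL, into = NULL,
                      new_name = NULL) {
  action <- match.arg(action)
  switch(action,
    create = {
      if (is.null(bin) || !nzchar(bin)) abort("create needs a non-empty bin name")
      if (bin %in% plan$bins) abort(sprintf("bin '%s' already exists", bin))
      plan$bins <- sort(c(plan$bins, bin))
      push_history(plan, "create", list(bin = bin), NULL, added_bins = bin)
    },
    assign = {
      if (is.null(bin) || !bin %in% plan$bins) abort(sprintf("unknown bin '%s'", bin %||% ""))
      ids <- as.character(ids)
      prev <- rows_for(plan, ids)
      plan$assignment <- plan$assignment[!plan$assignment$contig %in% ids, , drop = FALSE]
      plan$assignment <- bind_rows(plan$assignment, tibble(contig = ids, bin = bin))
      push_history(plan, "assign", list(bin = bin, ids = ids), prev)
    },
    unassign = {
      ids <- as.character(ids)
      unknown <- setdiff(ids, plan$assignment$contig)
      if (length(unknown)) abort(sprintf("contig '%s' is not binned", unknown[1]))
      prev <- rows_for(plan, ids)
      plan$assignment <- plan$assignment[!plan$assignment$contig %in% ids, , drop = FALSE]
      push_history(plan, "unassign", list(ids = ids), prev)
    },
    merge = {
      if (length(bins) < 2L) abort("merge needs at least 2 bins")
      missing <- setdiff(bins, plan$bins)
      if (length(missing)) abort(sprintf("unknown bin '%s'", missing[1]))
      into <- into %||% bins[1]
      if (!into %in% bins) abort("'into' must be one of the merged bins")
      gone <- setdiff(bins, into)
      movers <- plan$assignment$contig[plan$assignment$bin %in% gone]
      prev <- rows_for(plan, movers)
      plan$assignment$bin[plan$assignment$bin %in% gone] <- into
      plan$bins <- setdiff(plan$bins, gone)
      push_history(plan, "merge", list(bins = bins, into = into), prev,
                   removed_bins = gone)
    },
    delete = {
      if (is.null(bin) || !bin %in% plan$bins) abort(sprintf("unknown bin '%s'", bin %||% ""))
      members <- plan_members(plan, bin)
      prev <- rows_for(plan, members)
      plan$assignment <- plan$assignment[plan$assignment$bin != bin, , drop = FALSE]
      plan$bins <- setdiff(plan$bins, bin)
      push_history(plan, "delete", list(bin = bin), prev, removed_bins = bin)
    },
    rename = {
      if (is.null(bin) || !bin %in% plan$bins) abort(sprintf("unknown bin '%s'", bin %||% ""))
      if (is.null(new_name) || !nzchar(new_name)) abort("rename needs a non-empty new_name")
      if (new_name %in% plan$bins) abort(sprintf("bin '%s' already exists", new_name))
      plan$assignment$bin[plan$assignment$bin == bin] <- new_name
      plan$bins <- sort(c(setdiff(plan$bins, bin), new_name))
      push_history(plan, "rename", list(bin = bin, new_name = new_name), NULL,
                   removed_bins = bin, added_bins = new_name)
    }
  )
}

#' Undo the most recent plan edit
#'
#' Pops exactly one history record and reverts it; applying `undo_plan`
#' n times after n edits restores the initial plan exactly.
#'
#' @param plan A `binning_plan`.
#' @return The reverted `binning_plan`.
#' @export
undo_plan <- function(plan) {
  if (!length(plan$history)) abort("nothing to undo")
  rec <- plan$history[[length(plan$history)]]
  plan$history <- plan$history[-length(plan$history)]
  if (rec$action == "rename") {
    plan$assignment$bin[plan$assignment$bin == rec$args$new_name] <- rec$args$bin
    plan$bins <- sort(c(setdiff(plan$bins, rec$args$new_name), rec$args$bin))
    return(plan)
  }
  plan$bins <- sort(union(setdiff(plan$bins, rec$added_bins), rec$removed_bins))
  if (!is.null(rec$prev_rows)) {
    plan <- restore_rows(plan, rec$prev_rows$contig, rec$prev_rows)
  }
  plan
}

#' Select contigs inside a polygon
#'
#' The lasso tool on a 2D embedding: membership by the even-odd
#' (ray-casting) rule over the implicitly closed polygon. Points
#' exactly on an edge or vertex are included (selection errs
#' inclusive); either winding order works. Masked contigs are excluded
#' when `coords` is a contig table.
#'
#' @param coords Data frame with `id`, `x`, `y` columns (e.g. an
#'   [embed_contigs()] result joined to a table), or a `contig_table`
#'   whose `x`/`y` columns are named by `xy`.
#' @param polygon Two-column matrix or data frame of >= 3 vertices.
#' @param xy Names of the coordinate columns (default `c("x", "y")`).
#' @return Character vector of contig IDs inside the polygon.
#' @export
select_polygon <- function(coords, polygon, xy = c("x", "y")) {
  polygon <- as.matrix(polygon)[, 1:2, drop = FALSE]
  if (nrow(polygon) < 3L) abort("polygon needs at least 3 vertices")
  if (inherits(coords, "contig_table")) coords <- coords[!coords$.mask, , drop = FALSE]
  coords <- as_tibble(coords)
  px <- as.numeric(coords[[xy[1]]]); py <- as.numeric(coords[[xy[2]]])
  ids <- as.character(coords$id)
  ok <- !is.na(px) & !is.na(py)
  inside <- vapply(which(ok), function(i) point_in_polygon(px[i], py[i], polygon), NA)
  ids[which(ok)[inside]]
}

# Even-odd rule with inclusive boundary: a point on an edge (or vertex)
# counts as inside.
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary test: point collinear with and within the segment's box
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    if (abs(cross) < 1e-12 &&
        x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
        y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
      return(TRUE)
    }
    if ((yi > y) != (yj > y)) {
      xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Search contigs by attribute predicates
#'
#' Conjunction of predicates over a contig table's columns. Numeric
#' columns support `lt`, `le`, `eq`, `ge`, `gt` and `between`
#' (boundary-inclusive); categorical columns `equals`, `contains` and
#' `regex`; feature-set columns `has` (the multiset contains the
#' feature). Masked contigs never match.
#'
#' @param table A `contig_table`.
#' @param ... Predicates built with `pred(column, op, value)`.
#' @return Character vector of matching contig IDs.
#' @export
#' @examples
#' # search_contigs(tab, pred("length", "between", c(2000, 5000)),
#' #                pred("genus", "equals", "Escherichia"))
search_contigs <- function(table, ...) {
  preds <- list(...)
  keep <- !table$.mask
  for (p in preds) {
    dt <- ct_dtype(table, p$column)
    v <- table[[p$column]]
    hit <- switch(dt,
      numeric = {
        if (!p$op %in% c("lt", "le", "eq", "ge", "gt", "between")) {
          abort(sprintf("operator '%s' does not apply to numeric column '%s'", p$op, p$column))
        }
        switch(p$op,
          lt = v < p$value, le = v <= p$value, eq = v == p$value,
          ge = v >= p$value, gt = v > p$value,
          between = v >= p$value[1] & v <= p$value[2])
      },
      categorical = ,
      descriptive = {
        if (!p$op %in% c("equals", "contains", "regex")) {
          abort(sprintf("operator '%s' does not apply to categorical column '%s'", p$op, p$column))
        }
        switch(p$op,
          equals = v == p$value,
          contains = grepl(p$value, v, fixed = TRUE),
          regex = grepl(p$value, v))
      },
      feature_set = {
        if (p$op != "has") abort(sprintf("operator '%s' does not apply to feature-set column '%s'", p$op, p$column))
        vapply(v, function(s) p$value %in% s, NA)
      }
    )
    hit[is.na(hit)] <- FALSE
    keep <- keep & hit
  }
  table$id[keep]
}

#' @rdname search_contigs
#' @param column Column name.
#' @param op Operator (see Details of [search_contigs()]).
#' @param value Comparison value (length 2 for `between`).
#' @export
pred <- function(column, op, value) list(column = column, op = op, value = value)

#' Per-bin summaries of a plan
#'
#' For each bin: contig count, total length, and per-sample abundance,
#' computed as the length-weighted mean coverage of the bin's members
#' (set `abundance = "mass"` for the summed length x coverage
#' variant). Masked contigs are excluded from all totals; empty bins
#' report zero counts and missing abundance.
#'
#' @param plan A `binning_plan`.
#' @param table A `contig_table` with a numeric `length` column.
#' @param coverage_columns Names of numeric per-sample coverage columns.
#' @param abundance `"mean"` (default) or `"mass"`.
#' @return Tibble: `bin`, `n_contigs`, `total_length`, one column per
#'   coverage column.
#' @export
summarize_plan <- function(plan, table, coverage_columns = character(0),
                           abundance = c("mean", "mass")) {
  abundance <- match.arg(abundance)
  if (!"length" %in% ct_specs(table)$name) abort("table lacks a 'length' column")
  act <- active_ids(table)
  rows <- lapply(plan$bins, function(b) {
    ids <- intersect(plan_members(plan, b), act)
    pos <- match(ids, table$id)
    len <- table$length[pos]
    out <- tibble(bin = b, n_contigs = length(ids),
                  total_length = if (length(ids)) sum(len, na.rm = TRUE) else 0)
    for (cc in coverage_columns) {
      cov <- numeric_column(table, cc)[pos]
      ok <- !is.na(cov) & !is.na(len)
      out[[cc]] <- if (!any(ok)) NA_real_
        else if (abundance == "mean") sum(len[ok] * cov[ok]) / sum(len[ok])
        else sum(len[ok] * cov[ok])
    }
    out
  })
  bind_rows(rows)
}

#' Read / write a binning plan as TSV
#'
#' The on-disk shape is two columns, `#contig<TAB>bin`, one row per
#' binned contig (unbinned contigs are omitted). `read_plan` also
#' accepts the per-bin member-list shape (`bin<TAB>member1,member2,...`,
#' detected by comma-containing second columns); export is always
#' two-column.
#'
#' @param path TSV file.
#' @param name Plan name (default: file base name).
#' @return `read_plan`: a `binning_plan`.
#' @export
read_plan <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) abort(sprintf("plan line %d does not have 2 fields", which(nf != 2L)[1]))
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  if (any(grepl(",", b, fixed = TRUE))) {
    # per-bin member lists: first column is the bin
    contig <- unlist(lapply(b, split_features), use.names = FALSE)
    bin <- rep(a, vapply(b, function(s) length(split_features(s)), 0L))
    new_plan(name, tibble(contig = contig, bin = bin))
  } else {
    new_plan(name, tibble(contig = a, bin = b))
  }
}

#' @param plan A `binning_plan`.
#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  asg <- plan$assignment[order(plan$assignment$contig), , drop = FALSE]
  writeLines(c("#contig\tbin", paste(asg$contig, asg$bin, sep = "\t")), path)
  invisible(path)
}
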