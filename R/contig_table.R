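#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

CT_DTYPES <- c("numeric", "categorical", "feature_set", "descriptive")
RESERVED_COLS <- c("id", ".mask", ".highlight")

#' Declare a typed column
#'
#' A column spec names a column and fixes its data type: `numeric`
#' (finite doubles or missing), `categorical` (labels), `feature_set`
#' (multisets of feature identifiers, e.g. KO terms or marker genes;
#' duplicates encode copy number) or `descriptive` (free text, ignored
#' by all computations).
#'
#' @param name Column name (non-empty string; `id`, `.mask` and
#'   `.highlight` are reserved).
#' @param dtype One of `"numeric"`, `"categorical"`, `"feature_set"`,
#'   `"descriptive"`.
#' @return A one-row tibble with columns `name` and `dtype`.
#' @export
#' @examples
#' column_spec("length", "numeric")
column_spec <- function(name, dtype) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    abort("column name must be a non-empty string")
  }
  if (name %in% RESERVED_COLS) {
    abort(sprintf("column name '%s' is reserved", name))
  }
  dtype <- match.arg(dtype, CT_DTYPES)
  tibble(name = name, dtype = dtype)
}

#' Bundle a named set of member features
#'
#' Feature groups (for example a single-copy marker-gene catalog)
#' drive completeness/redundancy estimation: completeness is the share
#' of members found in a contig selection, redundancy the excess copies.
#'
#' @param name Group name.
#' @param members Character vector of distinct feature identifiers
#'   (at least one).
#' @return A `feature_group` object.
#' @export
feature_group <- function(name, members) {
  members <- as.character(members)
  if (length(members) == 0L || anyNA(members)) abort("feature group members must be non-empty")
  if (anyDuplicated(members)) abort("feature group members must be distinct")
  structure(list(name = as.character(name), members = members), class = "feature_group")
}

#' @export
print.feature_group <- function(x, ...) {
  cat(sprintf("<feature_group '%s': %d members>\n", x$name, length(x$members)))
  invisible(x)
}

# Split a comma-joined feature-set cell into a multiset
# (character vector with repeats). Empty/NA cell -> empty set.
split_features <- function(s) {
  if (length(s) != 1L || is.na(s) || !nzchar(trimws(s))) return(character(0))
  out <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

# Canonical comma-join of a feature multiset.
join_features <- function(v) paste(v, collapse = ",")

coerce_column <- function(values, dtype, colname) {
  switch(dtype,
    numeric = {
      out <- suppressWarnings(as.numeric(values))
      bad <- which(!is.na(values) & nzchar(as.character(values)) & is.na(out))
      if (length(bad)) {
        abort(sprintf("column '%s': value '%s' is not numeric", colname, as.character(values)[bad[1]]))
      }
      out[!is.finite(out)] <- NA_real_
      out
    },
    categorical = ,
    descriptive = {
      out <- as.character(values)
      out[!is.na(out) & !nzchar(out)] <- NA_character_
      out
    },
    feature_set = {
      if (is.list(values)) {
        lapply(values, function(v) if (is.null(v) || all(is.na(v))) character(0) else as.character(v))
      } else {
        lapply(as.character(values), split_features)
      }
    }
  )
}

#' Column specs of a contig table
#' @param table A `contig_table`.
#' @return Tibble with `name` and `dtype` per data column.
#' @export
ct_specs <- function(table) attr(table, "col_specs")

ct_dtype <- function(table, column) {
  specs <- ct_specs(table)
  i <- match(column, specs$name)
  if (is.na(i)) abort(sprintf("unknown column '%s'", column))
  specs$dtype[i]
}

new_contig_table <- function(data, specs) {
  structure(data, col_specs = specs, class = c("contig_table", class(tibble())))
}

#' Build a typed contig-property table
#'
#' The table is the central container: one row per contig, typed data
#' columns, plus per-contig `mask` (exclude from plots, summaries and
#' metrics) and `highlight` (integer color slot, 0 = none) flags.
#' Feature-set cells given as comma-separated strings are split into
#' multisets where duplicated identifiers encode copy number.
#'
#' @param rows A data frame with an `id` column of unique contig
#'   identifiers plus one column per spec entry.
#' @param specs Column specs, e.g. `rbind(column_spec("len","numeric"))`.
#' @return A `contig_table` (a tibble with columns `id`, the typed data
#'   columns, `.mask` and `.highlight`).
#' @export
#' @examples
#' build_contig_table(
#'   data.frame(id = c("c1", "c2"), len = c(100, 250)),
#'   column_spec("len", "numeric")
#' )
build_contig_table <- function(rows, specs) {
  rows <- as_tibble(rows)
  if (!"id" %in% names(rows)) abort("rows must have an 'id' column")
  specs <- as_tibble(specs)
  if (anyDuplicated(specs$name)) abort("duplicate column names in specs")
  ids <- as.character(rows$id)
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort(sprintf("duplicate contig ID '%s'", dup[1]))
  if (anyNA(ids) || any(!nzchar(ids))) abort("contig IDs must be non-empty")
  extra <- setdiff(names(rows), c("id", specs$name))
  if (length(extra)) abort(sprintf("column '%s' has no spec", extra[1]))

  data <- tibble(id = ids)
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    vals <- if (nm %in% names(rows)) rows[[nm]] else rep(NA, length(ids))
    data[[nm]] <- coerce_column(vals, specs$dtype[i], nm)
  }
  data$.mask <- rep(FALSE, length(ids))
  data$.highlight <- rep(0L, length(ids))
  new_contig_table(data, specs)
}

#' @export
print.contig_table <- function(x, ...) {
  specs <- ct_specs(x)
  cat(sprintf("<contig_table: %d contigs, %d columns (%d masked, %d highlighted)>\n",
              nrow(x), nrow(specs), sum(x$.mask), sum(x$.highlight > 0L)))
  if (nrow(specs)) {
    cat("  columns:", paste0(specs$name, " [", substr(specs$dtype, 1, 1), "]", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Append columns to an existing contig table
#'
#' Supports the incremental workflow where property tables from
#' different tools are merged onto one assembly: contigs present in
#' `rows` gain values, contigs absent from `rows` get missing values,
#' and rows whose ID is not in the table are skipped (counted in the
#' attached report, never silently dropped).
#'
#' @param table A `contig_table`.
#' @param rows Data frame with an `id` column plus new columns.
#' @param specs Column specs for the new columns.
#' @param overwrite Allow replacing an existing column of the same name.
#' @return The extended `contig_table`; `attr(, "append_report")` lists
#'   `n_matched` and `n_skipped` (with the skipped IDs).
#' @export
append_columns <- function(table, rows, specs, overwrite = FALSE) {
  rows <- as_tibble(rows)
  if (!"id" %in% names(rows)) abort("rows must have an 'id' column")
  specs <- as_tibble(specs)
  old <- ct_specs(table)
  clash <- intersect(specs$name, old$name)
  if (length(clash) && !overwrite) {
    abort(sprintf("column '%s' already exists (set overwrite = TRUE to replace)", clash[1]))
  }
  rid <- as.character(rows$id)
  known <- rid %in% table$id
  skipped <- rid[!known]
  rows <- rows[known, , drop = FALSE]
  pos <- match(as.character(rows$id), table$id)

  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    dt <- specs$dtype[i]
    if (!nm %in% names(rows)) abort(sprintf("rows lack appended column '%s'", nm))
    incoming <- coerce_column(rows[[nm]], dt, nm)
    full <- coerce_column(rep(NA, nrow(table)), dt, nm)
    if (dt == "feature_set") {
      full <- replicate(nrow(table), character(0), simplify = FALSE)
      full[pos] <- incoming
    } else {
      full[pos] <- incoming
    }
    table[[nm]] <- full
  }
  # keep .mask/.highlight as the trailing columns
  keep <- c("id", setdiff(names(table), RESERVED_COLS), ".mask", ".highlight")
  table <- table[, keep]
  new_specs <- bind_rows(old[!old$name %in% specs$name, ], specs)
  out <- new_contig_table(table, new_specs)
  attr(out, "append_report") <- list(
    n_matched = length(pos), n_skipped = length(skipped), skipped_ids = skipped
  )
  out
}

check_known_ids <- function(table, ids) {
  ids <- as.character(ids)
  bad <- setdiff(ids, table$id)
  if (length(bad)) abort(sprintf("unknown contig ID '%s'", bad[1]))
  ids
}

#' Set mask or highlight flags on contigs
#'
#' Masked contigs are excluded from every downstream summary, metric
#' and selection unless a function documents otherwise. Highlights are
#' integer color slots 0-8 (0 = none); actual colors are a
#' presentation-layer concern.
#'
#' @param table A `contig_table`.
#' @param ids Contig IDs to flag (must exist in the table).
#' @param flag `"mask"` or `"highlight"`.
#' @param value Logical for mask; integer in 0..8 for highlight.
#' @return The updated `contig_table`.
#' @export
set_flag <- function(table, ids, flag = c("mask", "highlight"), value = TRUE) {
  flag <- match.arg(flag)
  ids <- check_known_ids(table, ids)
  pos <- match(ids, table$id)
  if (flag == "mask") {
    if (!is.logical(value)) abort("mask value must be logical")
    table$.mask[pos] <- value
  } else {
    value <- as.integer(value)
    if (any(value < 0L | value > 8L)) abort("highlight slot must be in 0..8")
    table$.highlight[pos] <- value
  }
  table
}

#' Focus on a subset of contigs
#'
#' Equivalent to masking the complement: after `focus_contigs` only
#' `ids` remain visible to summaries, metrics and plots.
#'
#' @inheritParams set_flag
#' @return The updated `contig_table`.
#' @export
focus_contigs <- function(table, ids) {
  ids <- check_known_ids(table, ids)
  set_flag(table, setdiff(table$id, ids), "mask", TRUE)
}

#' IDs of unmasked contigs
#' @param table A `contig_table`.
#' @return Character vector of contig IDs with `mask = FALSE`.
#' @export
active_ids <- function(table) table$id[!table$.mask]

# Restrict a requested selection to unmasked contigs; NULL = all.
effective_ids <- function(table, ids = NULL) {
  if (is.null(ids)) return(active_ids(table))
  intersect(check_known_ids(table, ids), active_ids(table))
}
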