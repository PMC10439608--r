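#' Parse an assembly FASTA into per-contig records
#'
#' Extracts sequence length, GC content and (where the header dialect
#' carries it) assembler-reported coverage. GC is computed over
#' unambiguous bases only: `gc = 100 * (G + C) / (A + C + G + T)`; a
#' sequence with no A/C/G/T bases gets a missing GC.
#'
#' @param path FASTA file.
#' @param dialect Header dialect: `"spades"`
#'   (`NODE_<i>_length_<L>_cov_<x>`), `"megahit"`
#'   (`k141_0 flag=1 multi=10.0 len=3000`; `multi` is taken as an
#'   approximate coverage), or `"plain"` (first whitespace token is the
#'   ID; no coverage).
#' @return A tibble with columns `id`, `length`, `gc`, `coverage`
#'   (all-`NA` coverage for the plain dialect).
#' @export
parse_assembly_fasta <- function(path, dialect = c("plain", "spades", "megahit")) {
  dialect <- match.arg(dialect)
  seqs <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(seqs) == 0L)) {
    abort(sprintf("empty sequence for record '%s'", names(seqs)[Biostrings::width(seqs) == 0L][1]))
  }
  headers <- names(seqs)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, 100 * rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt, NA_real_)

  parse_one <- function(h) {
    first <- strsplit(h, "\\s+")[[1]][1]
    if (dialect == "spades") {
      m <- regmatches(first, regexec("^(NODE_\\d+)_length_(\\d+)_cov_([0-9.eE+-]+)$", first))[[1]]
      if (length(m) != 4L) abort(sprintf("malformed SPAdes header: '%s'", h))
      c(id = first, coverage = m[4])
    } else if (dialect == "megahit") {
      multi <- regmatches(h, regexec("\\bmulti=([0-9.eE+-]+)", h))[[1]]
      if (length(multi) != 2L || !grepl("\\blen=\\d+", h)) {
        abort(sprintf("malformed MegaHit header: '%s'", h))
      }
      c(id = first, coverage = multi[2])
    } else {
      c(id = first, coverage = NA_character_)
    }
  }
  parsed <- vapply(headers, parse_one, character(2), USE.NAMES = FALSE)
  tibble(
    id = parsed[1, ],
    length = Biostrings::width(seqs),
    gc = as.numeric(gc),
    coverage = suppressWarnings(as.numeric(parsed[2, ]))
  )
}

GTDB_RANKS <- c(d = "domain", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")

#' Parse taxonomic assignments into contig-table columns
#'
#' @param path Input file. `kraken`: tab-separated lines whose first
#'   three fields are classification flag (`C`/`U`), contig ID and
#'   taxon; unclassified lines yield a missing assignment. `gtdb_lineage`:
#'   a TSV keyed by contig (or bin) ID with a lineage column of
#'   `d__...;p__...;...;s__...` strings, split into seven rank columns;
#'   an empty rank becomes missing.
#' @param format `"kraken"` or `"gtdb_lineage"`.
#' @return A tibble with `id` plus one categorical column (`taxon`) for
#'   kraken, or seven rank columns (`domain` ... `species`) for GTDB
#'   lineages.
#' @export
parse_taxonomy <- function(path, format = c("kraken", "gtdb_lineage")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "kraken") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      abort(sprintf("kraken line %d has %d fields (expected >= 3)", which(nf < 3L)[1], nf[which(nf < 3L)[1]]))
    }
    flag <- vapply(fields, `[`, "", 1L)
    if (!all(flag %in% c("C", "U"))) {
      abort(sprintf("kraken line %d has unknown flag '%s'", which(!flag %in% c("C", "U"))[1],
                    flag[!flag %in% c("C", "U")][1]))
    }
    tibble(
      id = vapply(fields, `[`, "", 2L),
      taxon = ifelse(flag == "U", NA_character_,
                     sub(" \\(taxid \\d+\\)$", "", vapply(fields, `[`, "", 3L)))
    )
  } else {
    # skip a header line if present (GTDB-Tk summaries have one)
    has_header <- grepl("classification|user_genome", lines[1], ignore.case = TRUE) ||
      !grepl("__", lines[1])
    if (has_header && length(lines) > 1L) lines <- lines[-1]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L)) abort(sprintf("lineage line %d has %d fields (expected 2)", which(nf < 2L)[1], nf[which(nf < 2L)[1]]))
    ids <- vapply(fields, `[`, "", 1L)
    lineages <- vapply(fields, `[`, "", 2L)
    rank_rows <- lapply(lineages, function(lin) {
      parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
      out <- stats::setNames(rep(NA_character_, 7L), unname(GTDB_RANKS))
      for (p in parts[nzchar(parts)]) {
        prefix <- sub("__.*$", "", p)
        if (!prefix %in% names(GTDB_RANKS)) abort(sprintf("unknown rank prefix '%s__' in lineage '%s'", prefix, lin))
        val <- sub("^.__", "", p)
        if (nzchar(val)) out[GTDB_RANKS[[prefix]]] <- val
      }
      out
    })
    bind_cols(tibble(id = ids), as_tibble(do.call(rbind, rank_rows)))
  }
}

#' Extract a per-contig feature set from a GFF3 annotation
#'
#' Collects, for each contig (GFF column 1), the multiset of values of
#' one attribute key across its features — e.g. `attribute_key = "KO"`
#' yields each contig's KO content with copy number. Features lacking
#' the key are skipped and counted in the attached report.
#'
#' @param path GFF3 file.
#' @param attribute_key Attribute whose values become feature identifiers.
#' @return A tibble with `id` and a `features` list-column (character
#'   multisets); `attr(, "skip_report")` counts features missing the key.
#' @export
parse_features_gff <- function(path, attribute_key) {
  gff <- rtracklayer::readGFF(path)
  contig <- as.character(gff$seqid)
  if (!attribute_key %in% names(gff)) {
    vals <- rep(NA_character_, length(contig))
  } else {
    vals <- gff[[attribute_key]]
    if (is.list(vals)) vals <- vapply(vals, function(v) if (length(v)) v[[1]] else NA_character_, "")
    vals <- as.character(vals)
  }
  keep <- !is.na(vals)
  n_skipped <- sum(!keep)
  sets <- split(vals[keep], contig[keep])
  out <- tibble(
    id = unique(contig),
    features = lapply(unique(contig), function(cg) unname(sets[[cg]]) %||% character(0))
  )
  attr(out, "skip_report") <- list(n_skipped = n_skipped)
  out
}

#' Read a marker-gene map
#'
#' Consumes a flattened marker map: a two-column TSV of
#' `marker<TAB>contig`, one row per hit (a marker hitting a contig
#' twice appears on two rows). Returns the marker catalog as a
#' [feature_group()] and the per-contig hit multisets.
#'
#' @param path Marker map TSV (optional header line starting with `#`).
#' @param group_name Name for the returned feature group.
#' @return A list with `group` (a `feature_group` of all distinct
#'   markers) and `hits` (tibble: `id`, `features` list-column).
#' @export
parse_checkm_markers <- function(path, group_name = "markers") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort("marker map is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) abort(sprintf("marker map line %d has %d fields (expected 2)", which(nf != 2L)[1], nf[which(nf != 2L)[1]]))
  marker <- vapply(fields, `[`, "", 1L)
  contig <- vapply(fields, `[`, "", 2L)
  sets <- split(marker, contig)
  list(
    group = feature_group(group_name, sort(unique(marker))),
    hits = tibble(id = names(sets), features = lapply(sets, unname))
  )
}

DTYPE_SUFFIX <- c(numeric = "n", categorical = "c", feature_set = "f", descriptive = "d")

infer_dtype <- function(cells) {
  cells <- cells[!is.na(cells) & nzchar(cells)]
  if (!length(cells)) return("categorical")
  if (!anyNA(suppressWarnings(as.numeric(cells)))) return("numeric")
  if (any(grepl(",", cells, fixed = TRUE))) return("feature_set")
  "categorical"
}

#' Read / write a typed contig table as TSV
#'
#' The TSV dialect: UTF-8, tab-delimited, header row, first column the
#' contig ID. Column types may be declared with a header suffix
#' (`|n` numeric, `|c` categorical, `|f` feature set, `|d`
#' descriptive); unsuffixed columns are inferred (all-numeric cells ->
#' numeric; any comma-containing cell -> feature set; else
#' categorical). `write_contig_table` always emits suffixed headers so
#' a round trip never depends on inference. Empty cells are missing;
#' feature sets are comma-joined.
#'
#' @param path TSV file path.
#' @return `read_contig_table`: a `contig_table`.
#' @export
read_contig_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) abort("empty table file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # trailing empty cells are preserved by padding to header width
  width <- length(fields[[1]])
  nf <- lengths(fields)
  if (any(nf > width)) abort(sprintf("ragged row at line %d (%d fields, header has %d)", which(nf > width)[1], max(nf), width))
  fields <- lapply(fields, function(f) c(f, rep("", width - length(f))))
  header <- fields[[1]][-1]
  body <- fields[-1]
  ids <- vapply(body, `[`, "", 1L)

  names_dtypes <- lapply(header, function(h) {
    m <- regmatches(h, regexec("^(.*)\\|([ncfd])$", h))[[1]]
    if (length(m) == 3L) c(m[2], names(DTYPE_SUFFIX)[DTYPE_SUFFIX == m[3]]) else c(h, NA_character_)
  })
  rows <- tibble(id = ids)
  specs <- NULL
  for (j in seq_along(header)) {
    nm <- names_dtypes[[j]][1]
    cells <- vapply(body, `[`, "", j + 1L)
    cells[!nzchar(cells)] <- NA_character_
    dt <- names_dtypes[[j]][2]
    if (is.na(dt)) dt <- infer_dtype(cells)
    rows[[nm]] <- cells
    specs <- bind_rows(specs, column_spec(nm, dt))
  }
  build_contig_table(rows, specs)
}

format_num <- function(x) {
  # repr-shortest decimal formatting so round trips are byte-stable
  ifelse(is.na(x), "", vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE), ""))
}

#' @param table A `contig_table` (data columns only are written; mask
#'   and highlight flags are session state, persisted by checkpoints).
#' @rdname read_contig_table
#' @export
write_contig_table <- function(table, path) {
  specs <- ct_specs(table)
  header <- c("id", paste0(specs$name, "|", DTYPE_SUFFIX[specs$dtype]))
  cols <- lapply(seq_len(nrow(specs)), function(i) {
    v <- table[[specs$name[i]]]
    switch(specs$dtype[i],
      numeric = format_num(v),
      feature_set = vapply(v, join_features, ""),
      { v[is.na(v)] <- ""; v }
    )
  })
  body <- do.call(paste, c(list(table$id), cols, sep = "\t"))
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}

#' Filter contigs on length, coverage and covered breadth
#'
#' The standard assembly pre-filter: keep contigs with
#' `length >= min_len`, `coverage > min_cov` (strict: a contig at
#' exactly the coverage threshold is dropped) and, when
#' `min_breadth > 0`, `breadth >= min_breadth`. The defaults keep
#' contigs of at least 2000 bp with average coverage above 1x over at
#' least 90% of their length. Breadth must be supplied as a column
#' (computing it from alignments is out of scope here).
#'
#' @param records Tibble with `id`, `length`, `coverage` and, if
#'   `min_breadth > 0`, the breadth column.
#' @param min_len Minimum length in bp (inclusive).
#' @param min_cov Coverage threshold (exclusive).
#' @param min_breadth Minimum covered fraction of the contig (inclusive).
#' @param breadth_column Name of the breadth column.
#' @return Character vector of surviving contig IDs.
#' @export
filter_contigs <- function(records, min_len = 2000, min_cov = 1, min_breadth = 0.9,
                           breadth_column = "breadth") {
  records <- as_tibble(records)
  keep <- records$length >= min_len & records$coverage > min_cov
  if (min_breadth > 0) {
    if (!breadth_column %in% names(records)) {
      abort(sprintf("min_breadth > 0 requires a '%s' column", breadth_column))
    }
    keep <- keep & records[[breadth_column]] >= min_breadth
  }
  keep[is.na(keep)] <- FALSE
  as.character(records$id[keep])
}
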