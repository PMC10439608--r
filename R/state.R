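CHECKPOINT_VERSION <- 1L

#' Start a curation session
#'
#' A session bundles the contig table, any number of binning plans,
#' the view settings (active columns, transforms, current selection)
#' and a structured operation log. Sessions are plain values: the
#' `session_*` helpers return an updated session and append a log
#' entry, so replaying the log on the initial inputs reproduces the
#' final state.
#'
#' @param table A `contig_table`.
#' @param plans Named list of `binning_plan`s (or a single plan).
#' @param view List of view settings (free-form scalars/strings).
#' @return A `curation_session`.
#' @export
new_session <- function(table, plans = list(), view = list()) {
  if (inherits(plans, "binning_plan")) plans <- list(plans)
  if (length(plans) && is.null(names(plans))) {
    names(plans) <- vapply(plans, function(p) p$name, "")
  }
  structure(list(table = table, plans = plans, view = view, log = list()),
            class = "curation_session")
}

#' @export
print.curation_session <- function(x, ...) {
  cat(sprintf("<curation_session: %d contigs, %d plans, %d log entries>\n",
              nrow(x$table), length(x$plans), length(x$log)))
  invisible(x)
}

#' Append a structured log entry to a session
#'
#' @param session A `curation_session`.
#' @param op Operation name.
#' @param params Named list of parameters/results worth recording
#'   (filter thresholds, metric values, edit arguments).
#' @return The updated session.
#' @export
log_event <- function(session, op, params = list()) {
  session$log[[length(session$log) + 1L]] <- list(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), op = op, params = params
  )
  session
}

#' Apply a logged plan edit within a session
#'
#' @inheritParams log_event
#' @param plan_name Which plan to edit.
#' @param ... Arguments passed to [edit_plan()].
#' @return The updated session.
#' @export
session_edit_plan <- function(session, plan_name, ...) {
  if (!plan_name %in% names(session$plans)) abort(sprintf("unknown plan '%s'", plan_name))
  session$plans[[plan_name]] <- edit_plan(session$plans[[plan_name]], ...)
  log_event(session, "edit_plan", c(list(plan = plan_name), list(...)))
}

#' Apply a logged mask/highlight change within a session
#'
#' @inheritParams log_event
#' @inheritParams set_flag
#' @return The updated session.
#' @export
session_set_flag <- function(session, ids, flag = "mask", value = TRUE) {
  session$table <- set_flag(session$table, ids, flag, value)
  log_event(session, "set_flag", list(ids = ids, flag = flag, value = value))
}

serialize_table <- function(table) {
  specs <- ct_specs(table)
  cols <- lapply(seq_len(nrow(specs)), function(i) {
    v <- table[[specs$name[i]]]
    if (specs$dtype[i] == "feature_set") vapply(v, join_features, "") else v
  })
  names(cols) <- specs$name
  list(ids = table$id,
       specs = lapply(seq_len(nrow(specs)), function(i) list(name = specs$name[i], dtype = specs$dtype[i])),
       columns = cols, mask = table$.mask, highlight = table$.highlight)
}

deserialize_table <- function(x) {
  specs <- bind_rows(lapply(x$specs, function(s) column_spec(s$name, s$dtype)))
  rows <- tibble(id = as.character(x$ids))
  for (s in x$specs) rows[[s$name]] <- x$columns[[s$name]]
  tab <- build_contig_table(rows, specs)
  tab$.mask <- as.logical(x$mask)
  tab$.highlight <- as.integer(x$highlight)
  tab
}

serialize_plan <- function(plan) {
  list(name = plan$name, bins = plan$bins,
       assignment = list(contig = plan$assignment$contig, bin = plan$assignment$bin),
       history = lapply(plan$history, function(rec) {
         list(action = rec$action, args = rec$args,
              # row-wise records: a missing previous bin is a JSON null
              prev_rows = if (is.null(rec$prev_rows)) NULL else
                lapply(seq_len(nrow(rec$prev_rows)), function(i) {
                  b <- rec$prev_rows$bin[i]
                  list(contig = rec$prev_rows$contig[i],
                       bin = if (is.na(b)) NULL else b)
                }),
              removed_bins = rec$removed_bins, added_bins = rec$added_bins,
              timestamp = rec$timestamp)
       }))
}

deserialize_plan <- function(x) {
  plan <- new_plan(x$name, tibble(contig = as.character(x$assignment$contig %||% character(0)),
                                  bin = as.character(x$assignment$bin %||% character(0))))
  plan$bins <- sort(as.character(unlist(x$bins) %||% character(0)))
  plan$history <- lapply(x$history, function(rec) {
    args <- rec$args
    if (!is.null(args$ids)) args$ids <- as.character(unlist(args$ids))
    if (!is.null(args$bins)) args$bins <- as.character(unlist(args$bins))
    list(action = rec$action, args = args,
         prev_rows = if (is.null(rec$prev_rows)) NULL else
           tibble(contig = vapply(rec$prev_rows, function(r) as.character(r$contig), ""),
                  bin = vapply(rec$prev_rows, function(r) r$bin %||% NA_character_, "")),
         removed_bins = as.character(unlist(rec$removed_bins) %||% character(0)),
         added_bins = as.character(unlist(rec$added_bins) %||% character(0)),
         timestamp = rec$timestamp)
  })
  plan
}

#' Save / load a session checkpoint as JSON
#'
#' A checkpoint captures the whole session — table payload with mask
#' and highlight flags, every plan with its full edit history, view
#' settings and the log — so that loading it resumes the session
#' exactly. Floats are serialized at full precision. Files with an
#' unknown (newer) `format_version` are refused outright rather than
#' partially loaded.
#'
#' @param session A `curation_session`.
#' @param path JSON file path.
#' @return `load_checkpoint`: the restored `curation_session`.
#' @export
save_checkpoint <- function(session, path) {
  payload <- list(
    format_version = CHECKPOINT_VERSION,
    table = serialize_table(session$table),
    plans = lapply(unname(session$plans), serialize_plan),
    view = session$view,
    log = session$log
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @param path JSON file path.
#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  for (key in c("format_version", "table", "plans")) {
    if (is.null(x[[key]])) abort(sprintf("checkpoint is missing required key '%s'", key))
  }
  if (x$format_version > CHECKPOINT_VERSION) {
    abort(sprintf("checkpoint format_version %s is newer than supported version %d",
                  x$format_version, CHECKPOINT_VERSION))
  }
  plans <- lapply(x$plans, deserialize_plan)
  names(plans) <- vapply(plans, function(p) p$name, "")
  structure(list(table = deserialize_table(x$table), plans = plans,
                 view = x$view %||% list(), log = x$log %||% list()),
            class = "curation_session")
}

sanitize_bin_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Export a plan and its per-bin contig data
#'
#' Writes one contig-data TSV per bin (all table columns, typed
#' headers) plus the two-column plan file, with bin names sanitized
#' deterministically for the filesystem.
#'
#' @param plan A non-empty `binning_plan`.
#' @param table A `contig_table`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a tibble mapping `bin` to the written `file`
#'   (plus the plan file as bin `NA`).
#' @export
export_bins <- function(plan, table, out_dir) {
  if (!length(plan$bins)) abort("plan has no bins")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  safe <- sanitize_bin_name(plan$bins)
  dup <- unique(safe[duplicated(safe)])
  if (length(dup)) abort(sprintf("sanitized bin file names collide: %s", paste(dup, collapse = ", ")))
  files <- character(0)
  for (i in seq_along(plan$bins)) {
    ids <- plan_members(plan, plan$bins[i])
    sub <- table[table$id %in% ids, , drop = FALSE]
    sub <- new_contig_table(sub, ct_specs(table))
    f <- file.path(out_dir, paste0(safe[i], ".tsv"))
    write_contig_table(sub, f)
    files <- c(files, f)
  }
  pf <- file.path(out_dir, paste0(sanitize_bin_name(plan$name), ".plan.tsv"))
  write_plan(plan, pf)
  invisible(tibble(bin = c(plan$bins, NA), file = c(files, pf)))
}

apply_aes_transform <- function(table, column, transforms) {
  transform_values(table[[column]], transforms[[column]] %||% "none")
}

#' Scatter plot of contigs under the five aesthetics
#'
#' Builds the standard curation view: x and y (typically an
#' embedding), with optional size, opacity and color mappings, each of
#' which may carry its own transform (e.g. cube-root of length for
#' size, log coverage for opacity). Masked contigs are omitted and
#' contigs are drawn in ascending ID order, so the figure is
#' deterministic.
#'
#' @param table A `contig_table`.
#' @param x,y Numeric column names.
#' @param size,opacity Optional numeric column names.
#' @param color Optional column name (categorical or numeric), or a
#'   `binning_plan` to color by bin.
#' @param transforms Named list `column -> transform method`.
#' @return A ggplot object.
#' @export
plot_contigs <- function(table, x, y, size = NULL, opacity = NULL, color = NULL,
                         transforms = list()) {
  for (col in c(x, y)) {
    if (ct_dtype(table, col) != "numeric") abort(sprintf("column '%s' is not numeric", col))
  }
  d <- table[!table$.mask, , drop = FALSE]
  d <- d[order(d$id), , drop = FALSE]
  plot_data <- tibble(id = d$id,
                      .x = as.numeric(transform_values(d[[x]], transforms[[x]] %||% "none")),
                      .y = as.numeric(transform_values(d[[y]], transforms[[y]] %||% "none")))
  # contigs with missing mapped coordinates cannot be drawn
  drawable <- !is.na(plot_data$.x) & !is.na(plot_data$.y)
  plot_data <- plot_data[drawable, , drop = FALSE]
  d <- d[drawable, , drop = FALSE]
  mapping <- ggplot2::aes(x = .data$.x, y = .data$.y)
  if (!is.null(size)) {
    plot_data$.size <- transform_values(d[[size]], transforms[[size]] %||% "none")
    mapping$size <- quote(.size)
  }
  if (!is.null(opacity)) {
    plot_data$.alpha <- transform_values(d[[opacity]], transforms[[opacity]] %||% "none")
    mapping$alpha <- quote(.alpha)
  }
  if (inherits(color, "binning_plan")) {
    asg <- as_assignment(color)
    plot_data$.color <- unname(asg[d$id])
    mapping$colour <- quote(.color)
  } else if (!is.null(color)) {
    v <- d[[color]]
    plot_data$.color <- if (ct_dtype(table, color) == "numeric") {
      transform_values(v, transforms[[color]] %||% "none")
    } else as.character(v)
    mapping$colour <- quote(.color)
  }
  ggplot2::ggplot(plot_data, mapping) +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = y, colour = if (inherits(color, "binning_plan")) "bin" else color,
                  size = size, alpha = opacity) +
    ggplot2::theme_minimal()
}

#' Export the contig scatter as PNG or SVG
#'
#' @inheritParams plot_contigs
#' @param path Output file; format chosen by extension (`.png` or
#'   `.svg`).
#' @param width,height Figure size in inches.
#' @return Invisibly, `path`.
#' @export
export_scatter <- function(table, x, y, path, size = NULL, opacity = NULL,
                           color = NULL, transforms = list(),
                           width = 7, height = 6) {
  p <- plot_contigs(table, x, y, size = size, opacity = opacity, color = color,
                    transforms = transforms)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in", res = 150,
                   type = "cairo")
  } else {
    abort("path must end in .png or .svg")
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
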