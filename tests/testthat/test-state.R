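make_session <- function() {
  tab <- toy_table()
  tab <- set_flag(tab, "c5", "mask", TRUE)
  tab <- set_flag(tab, "c1", "highlight", 2)
  p1 <- new_plan("auto", tibble::tibble(contig = c("c1", "c2"), bin = c("B1", "B2")))
  p1 <- edit_plan(p1, "assign", bin = "B1", ids = "c3")
  p2 <- new_plan("manual")
  p2 <- edit_plan(p2, "create", bin = "X")
  s <- new_session(tab, list(p1, p2), view = list(x = "gc", y = "length",
                                                  transform_y = "log"))
  log_event(s, "note", list(k = 1))
}

test_that("checkpoints round trip sessions exactly", {
  s <- make_session()
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(s, f)
  back <- load_checkpoint(f)
  expect_equal(back$table, s$table)
  expect_equal(names(back$plans), names(s$plans))
  for (nm in names(s$plans)) {
    expect_equal(back$plans[[nm]]$assignment, s$plans[[nm]]$assignment)
    expect_equal(back$plans[[nm]]$bins, s$plans[[nm]]$bins)
    expect_equal(length(back$plans[[nm]]$history), length(s$plans[[nm]]$history))
  }
  expect_equal(back$view$x, "gc")
  expect_equal(length(back$log), 1)
  # undo still works on a restored plan's history
  undone <- undo_plan(back$plans[["auto"]])
  expect_false("c3" %in% undone$assignment$contig)
})

test_that("checkpoint loading refuses bad files outright", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format_version": 99, "table": {}, "plans": []}', f)
  expect_error(load_checkpoint(f), "format_version")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format_version": 1, "plans": []}', f2)
  expect_error(load_checkpoint(f2), "table")
  f3 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"truncated', f3)
  expect_error(load_checkpoint(f3))
})

test_that("checkpoint round trip is the identity on randomized sessions", {
  set.seed(404)
  for (rep in 1:8) {
    n <- sample(5:15, 1)
    ids <- paste0("c", seq_len(n))
    tab <- build_contig_table(
      data.frame(id = ids, len = round(runif(n, 100, 9999)),
                 cov = runif(n, 0, 50),
                 kos = vapply(ids, function(i)
                   paste(sample(c("K1", "K2", "K3"), sample(0:3, 1), TRUE),
                         collapse = ","), "")),
      rbind(column_spec("len", "numeric"), column_spec("cov", "numeric"),
            column_spec("kos", "feature_set"))
    )
    tab <- set_flag(tab, sample(ids, sample(0:n, 1)), "mask", TRUE)
    p <- new_plan("p", tibble::tibble(contig = sample(ids, 3),
                                      bin = c("A", "A", "B")))
    initial <- p$assignment
    for (i in 1:3) p <- edit_plan(p, "assign", bin = sample(p$bins, 1),
                                  ids = sample(ids, 1))
    s <- new_session(tab, list(p))
    f <- withr::local_tempfile(fileext = ".json")
    save_checkpoint(s, f)
    back <- load_checkpoint(f)
    expect_equal(back$table, s$table)
    expect_equal(back$plans[["p"]]$assignment, s$plans[["p"]]$assignment)
    # full undo of the restored history reaches the initial assignment
    q <- back$plans[["p"]]
    while (length(q$history)) q <- undo_plan(q)
    expect_equal(dplyr::arrange(q$assignment, contig),
                 dplyr::arrange(initial, contig))
  }
})

test_that("session operations append replayable log entries", {
  s <- make_session()
  n0 <- length(s$log)
  s <- session_edit_plan(s, "manual", "assign", bin = "X", ids = "c1")
  s <- session_set_flag(s, "c2", "mask", TRUE)
  expect_equal(length(s$log), n0 + 2)
  expect_equal(s$log[[n0 + 1]]$op, "edit_plan")
  expect_true(s$table$.mask[s$table$id == "c2"])
  # replaying the logged edit on the initial plans reproduces the assignment
  s0 <- make_session()
  entry <- s$log[[n0 + 1]]
  replayed <- edit_plan(s0$plans[[entry$params$plan]],
                        entry$params[[2]], bin = entry$params$bin,
                        ids = entry$params$ids)
  expect_equal(replayed$assignment, s$plans[["manual"]]$assignment)
})

test_that("bin export writes one data TSV per bin plus the plan file", {
  tab <- toy_table()
  p <- new_plan("plan a", tibble::tibble(contig = c("c1", "c2", "c3"),
                                         bin = c("bin/1", "bin/1", "good")))
  d <- withr::local_tempdir()
  files <- export_bins(p, tab, d)
  written <- list.files(d)
  expect_length(written, 3)
  expect_true("bin_1.tsv" %in% written)
  sub <- read_contig_table(file.path(d, "bin_1.tsv"))
  expect_equal(sub$id, c("c1", "c2"))
  expect_equal(ct_specs(sub), ct_specs(tab))
  # exported plan re-imports identically
  back <- read_plan(file.path(d, "plan_a.plan.tsv"))
  expect_equal(dplyr::arrange(back$assignment, contig),
               dplyr::arrange(p$assignment, contig))
  bad <- new_plan("q", tibble::tibble(contig = "c1", bin = "a/b"))
  bad <- edit_plan(bad, "create", bin = "a_b")
  expect_error(export_bins(bad, tab, withr::local_tempdir()), "collide")
})

test_that("scatter export draws unmasked contigs deterministically", {
  tab <- toy_table()
  tab <- set_flag(tab, "c2", "mask", TRUE)
  p <- plot_contigs(tab, x = "length", y = "gc", size = "length",
                    transforms = list(length = "cbrt"))
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 3)               # c2 masked out, c5 has no gc
  expect_false("c2" %in% p$data$id)
  expect_equal(p$data$id, sort(p$data$id))    # ascending ID draw order
  expect_equal(p$data$.size,
               transform_values(tab$length[tab$id %in% c("c1", "c3", "c4")], "cbrt"),
               ignore_attr = TRUE)
  f <- withr::local_tempfile(fileext = ".svg")
  export_scatter(tab, "length", "gc", f, color = "genus")
  expect_true(file.exists(f) && file.size(f) > 0)
  fp <- withr::local_tempfile(fileext = ".png")
  export_scatter(tab, "length", "gc", fp)
  expect_true(file.exists(fp) && file.size(fp) > 0)
  expect_error(export_scatter(tab, "genus", "gc", fp), "not numeric")
})
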