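test_that("plan edits keep single membership and support all actions", {
  p <- new_plan("test")
  p <- edit_plan(p, "create", bin = "B1")
  p <- edit_plan(p, "create", bin = "B2")
  p <- edit_plan(p, "assign", bin = "B1", ids = c("c1", "c2"))
  p <- edit_plan(p, "assign", bin = "B2", ids = "c2")   # moves c2
  expect_equal(sort(magcurate:::plan_members(p, "B1")), "c1")
  expect_equal(sort(magcurate:::plan_members(p, "B2")), "c2")
  expect_equal(anyDuplicated(p$assignment$contig), 0)
  p <- edit_plan(p, "merge", bins = c("B1", "B2"))
  expect_equal(sort(magcurate:::plan_members(p, "B1")), c("c1", "c2"))
  expect_false("B2" %in% p$bins)
  p <- edit_plan(p, "rename", bin = "B1", new_name = "best")
  expect_equal(p$bins, "best")
  expect_error(edit_plan(p, "assign", bin = "nope", ids = "c1"), "nope")
  expect_error(edit_plan(p, "create", bin = "best"), "exists")
  expect_error(edit_plan(p, "rename", bin = "best", new_name = "best"), "exists")
})

test_that("assign/unassign and delete/undo are exact inverses", {
  p0 <- new_plan("t", tibble::tibble(contig = c("c1", "c2"), bin = c("A", "A")))
  p <- edit_plan(p0, "assign", bin = "A", ids = "c3")
  p <- edit_plan(p, "unassign", ids = "c3")
  expect_equal(dplyr::arrange(p$assignment, contig),
               dplyr::arrange(p0$assignment, contig))
  # undo after delete restores the bin with identical membership
  p <- edit_plan(p0, "delete", bin = "A")
  expect_equal(nrow(p$assignment), 0)
  p <- undo_plan(p)
  expect_equal(sort(magcurate:::plan_members(p, "A")), c("c1", "c2"))
  expect_equal(p$bins, "A")
})

test_that("undo^n restores the initial plan after random edit sequences", {
  set.seed(77)
  ids <- paste0("c", 1:40)
  for (rep in 1:10) {
    p0 <- new_plan("r", tibble::tibble(contig = ids[1:20],
                                       bin = sample(c("A", "B", "C"), 20, TRUE)))
    p <- p0
    n_edits <- sample(3:12, 1)
    for (i in seq_len(n_edits)) {
      op <- sample(c("create", "assign", "unassign", "merge", "delete", "rename"), 1)
      p <- tryCatch(switch(op,
        create = edit_plan(p, "create", bin = paste0("new", i)),
        assign = edit_plan(p, "assign", bin = sample(p$bins, 1),
                           ids = sample(ids, sample(1:5, 1))),
        unassign = if (nrow(p$assignment)) {
          edit_plan(p, "unassign", ids = sample(p$assignment$contig, 1))
        } else p,
        merge = if (length(p$bins) >= 2) {
          edit_plan(p, "merge", bins = sample(p$bins, 2))
        } else p,
        delete = edit_plan(p, "delete", bin = sample(p$bins, 1)),
        rename = edit_plan(p, "rename", bin = sample(p$bins, 1),
                           new_name = paste0("ren", i))
      ), error = function(e) p)
      expect_equal(anyDuplicated(p$assignment$contig), 0)  # single membership
    }
    while (length(p$history)) p <- undo_plan(p)
    expect_equal(dplyr::arrange(p$assignment, contig),
                 dplyr::arrange(p0$assignment, contig))
    expect_equal(p$bins, p0$bins)
  }
})

test_that("polygon selection handles the unit square inclusively", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  pts <- tibble::tibble(id = c("in", "out", "edge", "vertex"),
                        x = c(0.5, 1.5, 1.0, 0), y = c(0.5, 0.5, 0.5, 0))
  expect_equal(sort(select_polygon(pts, sq)), c("edge", "in", "vertex"))
  expect_error(select_polygon(pts, sq[1:2, ]), "3 vertices")
  # winding order does not matter
  expect_equal(sort(select_polygon(pts, sq[4:1, ])), c("edge", "in", "vertex"))
})

test_that("polygon selection matches the crossing-number oracle", {
  set.seed(303)
  for (rep in 1:20) {
    poly <- random_polygon(sample(3:9, 1), star = rep %% 2 == 0)
    n <- 200
    pts <- tibble::tibble(id = paste0("p", 1:n),
                          x = runif(n, -1.2, 1.2), y = runif(n, -1.2, 1.2))
    got <- select_polygon(pts, poly)
    want <- pts$id[mapply(function(x, y) oracle_in_polygon(x, y, poly),
                          pts$x, pts$y)]
    expect_equal(sort(got), sort(want))
  }
})

test_that("search matches predicates by dtype with conjunction", {
  tab <- toy_table()
  expect_equal(search_contigs(tab, pred("genus", "equals", "Escherichia")),
               c("c1", "c3"))
  expect_equal(search_contigs(tab, pred("length", "between", c(2000, 5000))),
               c("c3", "c4"))
  expect_equal(search_contigs(tab, pred("feats", "has", "dsrA")), "c4")
  expect_equal(search_contigs(tab, pred("genus", "regex", "^Esch"),
                              pred("length", "ge", 1000)), "c3")
  expect_equal(search_contigs(tab, pred("genus", "contains", "coli")), character(0))
  m <- set_flag(tab, "c1", "mask", TRUE)
  expect_equal(search_contigs(m, pred("genus", "equals", "Escherichia")), "c3")
  expect_error(search_contigs(tab, pred("length", "equals", 100)), "numeric")
  expect_error(search_contigs(tab, pred("genus", "lt", 1)), "categorical")
})

test_that("plan summaries weight abundance by length", {
  tab <- build_contig_table(
    data.frame(id = c("c1", "c2", "c3"), length = c(100, 300, 50),
               cov_s1 = c(10, 20, 99)),
    rbind(column_spec("length", "numeric"), column_spec("cov_s1", "numeric"))
  )
  p <- new_plan("p", tibble::tibble(contig = c("c1", "c2"), bin = c("B", "B")))
  p <- edit_plan(p, "create", bin = "empty")
  s <- summarize_plan(p, tab, "cov_s1")
  b <- s[s$bin == "B", ]
  expect_equal(b$total_length, 400)
  expect_equal(b$cov_s1, (100 * 10 + 300 * 20) / 400)  # 17.5
  e <- s[s$bin == "empty", ]
  expect_equal(e$n_contigs, 0)
  expect_equal(e$total_length, 0)
  expect_true(is.na(e$cov_s1))
  # mass variant and mask semantics
  sm <- summarize_plan(p, tab, "cov_s1", abundance = "mass")
  expect_equal(sm$cov_s1[sm$bin == "B"], 100 * 10 + 300 * 20)
  tm <- set_flag(tab, "c2", "mask", TRUE)
  s2 <- summarize_plan(p, tm, "cov_s1")
  expect_equal(s2$total_length[s2$bin == "B"], 100)
  # binned length never exceeds total unmasked length
  expect_lte(sum(s$total_length), sum(tab$length))
})

test_that("plan TSV round trips in both accepted shapes", {
  p <- new_plan("demo", tibble::tibble(contig = c("c2", "c1", "c3"),
                                       bin = c("B2", "B1", "B1")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_plan(p, f)
  expect_equal(readLines(f)[1], "#contig\tbin")
  back <- read_plan(f, name = "demo")
  expect_equal(dplyr::arrange(back$assignment, contig),
               dplyr::arrange(p$assignment, contig))
  # member-list shape
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("B1\tc1,c3", "B2\tc2"), f2)
  back2 <- read_plan(f2, name = "demo")
  expect_equal(dplyr::arrange(back2$assignment, contig),
               dplyr::arrange(p$assignment, contig))
})
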