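test_that("reading a clonotype table normalizes, merges and validates", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s1.tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count",
               "CASSLF\tV1\tJ1\t3",
               "CASSRF\tV2\tJ1\t1"), p)
  rep <- read_clonotype_table(p)
  expect_s3_class(rep, "tcr_repertoire")
  expect_equal(nrow(rep$clonotypes), 2L)
  expect_equal(sort(rep$clonotypes$frequency), c(0.25, 0.75))
  expect_equal(sum(rep$clonotypes$frequency), 1, tolerance = 1e-9)

  # duplicate rows merge by clonotype key
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count",
               "CASSLF\tV1\tJ1\t2",
               "CASSLF\tV1\tJ1\t2"), p)
  rep <- read_clonotype_table(p)
  expect_equal(nrow(rep$clonotypes), 1L)
  expect_equal(rep$clonotypes$count, 4)
  expect_equal(rep$clonotypes$frequency, 1)

  # non-positive count cites the row
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count",
               "CASSLF\tV1\tJ1\t2", "CASSRF\tV1\tJ1\t2", "CASSTF\tV1\tJ1\t2",
               "CASSGF\tV1\tJ1\t2", "CASSYF\tV1\tJ1\t0"), p)
  expect_error(read_clonotype_table(p), "row 5")

  # missing required column named in the error
  writeLines(c("junction_aa\tv_call", "CASSLF\tV1"), p)
  expect_error(read_clonotype_table(p), "duplicate_count")

  # empty table
  writeLines("junction_aa\tv_call\tj_call\tduplicate_count", p)
  expect_error(read_clonotype_table(p), "empty")
})

test_that("the simple column dialect is accepted", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s2.tsv")
  writeLines(c("cdr3aa\tv\tj\tcount", "CASSLF\tV1\tJ1\t5"), p)
  rep <- read_clonotype_table(p)
  expect_equal(rep$clonotypes$junction_aa, "CASSLF")
  expect_equal(rep$clonotypes$count, 5)
})

test_that("row order does not affect the result", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tsv"); p2 <- file.path(dir, "b.tsv")
  rows <- c("CASSA\tV1\tJ1\t7", "CASSB\tV2\tJ1\t3", "CASSC\tV1\tJ2\t3")
  hdr <- "junction_aa\tv_call\tj_call\tduplicate_count"
  writeLines(c(hdr, rows), p1)
  writeLines(c(hdr, rev(rows)), p2)
  r1 <- read_clonotype_table(p1, sample_id = "s")
  r2 <- read_clonotype_table(p2, sample_id = "s")
  expect_identical(r1$clonotypes, r2$clonotypes)
})

test_that("collapse_by_junction_aa merges V/J variants, conserves counts, idempotent", {
  rep <- tcr_repertoire(data.frame(
    junction_aa = c("CASSLF", "CASSLF", "CASSRF"),
    v_call = c("V1", "V2", "V1"), j_call = "J1",
    count = c(2, 3, 4)))
  col <- collapse_by_junction_aa(rep)
  expect_equal(nrow(col$clonotypes), 2L)
  expect_equal(col$clonotypes$count[col$clonotypes$junction_aa == "CASSLF"], 5)
  expect_equal(total_count(col), total_count(rep))
  expect_identical(collapse_by_junction_aa(col)$clonotypes, col$clonotypes)

  # all-distinct junctions: identity on keys/counts
  rep2 <- make_rep(c("CAAAF", "CCCCF"), c(1, 2))
  col2 <- collapse_by_junction_aa(rep2)
  expect_equal(col2$clonotypes[, c("junction_aa", "count")],
               rep2$clonotypes[, c("junction_aa", "count")])
})

test_that("write/read round-trip preserves keys, counts and annotations", {
  dir <- withr::local_tempdir()
  rep <- tcr_repertoire(data.frame(
    junction_aa = c("CASSLF", "CASSRF", "CASSTF"),
    v_call = c("V1", "V2", NA), j_call = c("J1", NA, "J2"),
    count = c(10, 5, 1)),
    sample_id = "rt", patient = "P9", compartment = "PB",
    subset = "NON_TREG", visit = 3L)
  p <- file.path(dir, "rt.tsv")
  write_clonotype_table(rep, p)
  back <- read_clonotype_table(p, sample_id = "rt", patient = "P9",
                               compartment = "PB", subset = "NON_TREG",
                               visit = 3L)
  expect_equal(back$clonotypes$junction_aa, rep$clonotypes$junction_aa)
  expect_equal(back$clonotypes$count, rep$clonotypes$count)
  expect_equal(back$patient, "P9")
  expect_equal(back$visit, 3L)
  # single clonotype file: header + 1 row
  write_clonotype_table(make_rep("CASSF", 2), file.path(dir, "one.tsv"))
  expect_length(readLines(file.path(dir, "one.tsv")), 2L)
  # missing directory is an I/O error
  expect_error(write_clonotype_table(rep, file.path(dir, "nope", "x.tsv")),
               "directory")
})

test_that("sample sheets round-trip a cohort", {
  dir <- withr::local_tempdir()
  cohort <- list(
    a = make_rep(c("CASSA", "CASSB"), c(3, 1), sample_id = "a",
                 patient = "P1", compartment = "SF_LEFT"),
    b = make_rep(c("CASSB", "CASSC"), c(2, 2), sample_id = "b",
                 patient = "P1", compartment = "SF_RIGHT"))
  manifest <- write_cohort(cohort, dir)
  back <- read_sample_sheet(manifest)
  expect_named(back, c("a", "b"))
  expect_equal(back$a$clonotypes$junction_aa, cohort$a$clonotypes$junction_aa)
  expect_equal(back$b$compartment, "SF_RIGHT")
})
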