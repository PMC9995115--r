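test_that("clonal proportions partition the count mass", {
  expect_equal(clonal_proportion_summary(make_rep(c("CA", "CB"), c(1, 1)))$proportion,
               c(1, 0, 0, 0))
  got <- clonal_proportion_summary(make_rep(c("CA", "CB"), c(100, 1)))
  expect_equal(got$proportion[got$bin == ">=100"], 100 / 101)
  expect_equal(got$proportion[got$bin == "1"], 1 / 101)
  expect_error(clonal_proportion_summary(make_rep("CA", 1), bin_edges = c(1, 10, 5)),
               "increasing")
  # conservation on random inputs
  set.seed(42)
  for (i in 1:20) {
    r <- make_rep(paste0("C", LETTERS[1:8], i), sample(1:200, 8))
    expect_equal(sum(clonal_proportion_summary(r)$proportion), 1)
  }
})

test_that("top-N intersection handles identity, disjoint and partial overlap", {
  a <- make_rep(c("CX", "CY", "CZ"), c(5, 3, 1))
  expect_true(all(top_n_intersection(a, a, n_grid = 1:3)$percent_overlap == 100))
  b <- make_rep(c("CQ", "CR", "CS"), c(9, 2, 1))
  expect_true(all(top_n_intersection(a, b, n_grid = 1:3)$percent_overlap == 0))
  # top-3 sets {x,y,z} vs {x,q,z} -> 2/3
  c1 <- make_rep(c("CX", "CY", "CZ"), c(9, 5, 4))
  c2 <- make_rep(c("CX", "CQ", "CZ"), c(7, 6, 2))
  expect_equal(top_n_intersection(c1, c2, n_grid = 3)$percent_overlap,
               100 * 2 / 3)
  # n above repertoire size dropped with a warning
  expect_warning(got <- top_n_intersection(a, b, n_grid = c(2, 10)),
                 "dropping")
  expect_equal(got$n, 2)
  # identical key sets at n = |A| give 100% regardless of counts
  d1 <- make_rep(c("CA", "CB", "CC"), c(50, 2, 1))
  d2 <- make_rep(c("CA", "CB", "CC"), c(1, 2, 50))
  expect_equal(top_n_intersection(d1, d2, n_grid = 3)$percent_overlap, 100)
})

test_that("Jaccard matrix has unit diagonal, symmetry and exact values", {
  a <- make_rep(c("CA", "CB", "CC"), c(1, 1, 1), sample_id = "a")
  b <- make_rep(c("CB", "CC", "CD"), c(2, 1, 1), sample_id = "b")
  m <- jaccard_matrix(list(a, b))
  expect_equal(m["a", "b"], 0.5)
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_equal(m, t(m))
  # randomized symmetry property
  set.seed(7)
  for (i in 1:25) {
    x <- make_rep(paste0("C", sample(LETTERS, 8)), rep(1, 8), sample_id = "x")
    y <- make_rep(paste0("C", sample(LETTERS, 8)), rep(1, 8), sample_id = "y")
    mm <- jaccard_matrix(list(x, y))
    expect_equal(mm["x", "y"], mm["y", "x"])
    expect_true(all(mm >= 0 & mm <= 1))
  }
})

test_that("sharing classes partition the union", {
  pb <- make_rep(c("CA", "CB"), c(1, 1))
  sfl <- make_rep(c("CA", "CC"), c(1, 1))
  sfr <- make_rep(c("CA", "CB", "CD"), c(1, 1, 1))
  cls <- classify_sharing(list(pb, sfl, sfr))
  expect_equal(cls$n_samples_present[cls$junction_aa == "CA"], 3L)
  expect_equal(cls$n_samples_present[cls$junction_aa == "CC"], 1L)
  expect_equal(nrow(cls), 4L)  # |union|
  expect_equal(sum(table(cls$n_samples_present)), 4L)
})

test_that("paired frequency tables carry exact per-sample frequencies", {
  a <- make_rep(c("CA", "CB"), c(4, 1), sample_id = "a")
  b <- make_rep(c("CB", "CC"), c(1, 1), sample_id = "b")
  pf <- paired_frequency_table(a, b)
  expect_equal(nrow(pf), 3L)
  expect_equal(pf$freqA[pf$junction_aa == "CA"], 0.8)
  expect_equal(pf$freqB[pf$junction_aa == "CA"], 0)
  expect_equal(pf$n_samples_present[pf$junction_aa == "CB"], 2L)
  expect_equal(pf$freqB[pf$junction_aa == "CB"], 0.5)
})

test_that("venn region counts conserve the union", {
  a <- make_rep(c("CA", "CB"), c(2, 1), sample_id = "a")
  b <- make_rep(c("CB", "CC"), c(2, 1), sample_id = "b")
  vc <- suppressMessages(venn_counts(list(a, b), top_n = 2))
  expect_equal(vc[["a"]], 1L)
  expect_equal(vc[["b"]], 1L)
  expect_equal(vc[["a&b"]], 1L)
  # identical tops: only the full intersection region is nonzero
  a2 <- make_rep(c("CA", "CB"), c(5, 2), sample_id = "a2")
  vi <- suppressMessages(venn_counts(list(a, a2), top_n = 2))
  expect_equal(unname(vi), c(0L, 0L, 2L))
  # region counts sum to |union of top sets| on random triples
  set.seed(9)
  for (i in 1:15) {
    reps <- lapply(1:3, function(j)
      make_rep(paste0("C", sample(LETTERS, 10)), sample(1:50, 10),
               sample_id = paste0("s", j)))
    vc <- suppressMessages(venn_counts(reps, top_n = 5))
    un <- length(unique(unlist(lapply(reps, function(r)
      utils::head(r$clonotypes$junction_aa[order(-r$clonotypes$count,
                                                 r$clonotypes$junction_aa)], 5)))))
    expect_equal(sum(vc), un)
  }
})

test_that("overlap statistics are invariant to input row order", {
  perm <- data.frame(junction_aa = c("CB", "CA", "CC"), count = c(3, 9, 1))
  r1 <- tcr_repertoire(perm)
  r2 <- tcr_repertoire(perm[c(3, 1, 2), ])
  expect_identical(r1$clonotypes, r2$clonotypes)
  expect_equal(jaccard_matrix(list(r1, r2))[1, 2], 1)
})
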