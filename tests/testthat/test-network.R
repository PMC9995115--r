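test_that("k-mer sets collapse duplicates and respect bounds", {
  expect_setequal(kmer_set("CASSL", 3), c("CAS", "ASS", "SSL"))
  expect_equal(suppressMessages(kmer_set("AAAA", 3)), "AAA")
  expect_length(suppressMessages(kmer_set("CA", 3)), 0L)
  set.seed(21)
  for (i in 1:30) {
    s <- random_aa_string(sample(3:15, 1))
    expect_lte(length(kmer_set(s, 3)), nchar(s) - 2L)
  }
})

test_that("shared k-mer counts match the brute-force oracle", {
  # identical length-10 strings with all-distinct 3-mers share exactly 8
  s <- "CADEFGHIKL"
  expect_equal(shared_kmer_count(s, s), 8L)
  expect_equal(shared_kmer_count("CASSLSGTGELFF", "CASSLSGTGELFY"), 10L)
  expect_equal(shared_kmer_count("AAAAAA", "CCCCCC"), 0L)
  set.seed(77)
  for (i in 1:200) {
    a <- random_aa_string(sample(3:18, 1))
    b <- random_aa_string(sample(3:18, 1))
    expect_equal(shared_kmer_count(a, b), kmer_oracle(a, b))
  }
})

test_that("edges obey the tau rule and the pigeonhole bound", {
  cfg <- network_config(seed = 1)
  pair <- c("CASSLSGTGELFF", "CASSLSGTGELFY")   # share 10 k-mers
  net <- build_network(pair, c("LEFT", "RIGHT"), cfg)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(length(unique(net$nodes$cluster)), 1L)
  # sequences shorter than tau + k - 1 = 10 are always isolated
  set.seed(5)
  shorts <- vapply(1:30, function(i) random_aa_string(sample(3:9, 1), LETTERS[1:4]),
                   character(1))
  net <- suppressMessages(build_network(shorts, rep("LEFT", 30), cfg))
  expect_equal(nrow(net$edges), 0L)
  # adversarial repeats: "AAAAAAAAA" has 1 distinct 3-mer
  net <- build_network(c("AAAAAAAAA", "AAAAAAAAT"), c("LEFT", "RIGHT"), cfg)
  expect_equal(nrow(net$edges), 0L)
})

test_that("raising tau never adds edges and never merges clusters", {
  set.seed(9)
  seqs <- unique(vapply(1:60, function(i)
    random_aa_string(13, c("A", "C", "D", "E")), character(1)))
  labs <- rep(c("LEFT", "RIGHT"), length.out = length(seqs))
  prev_edges <- Inf; prev_clusters <- 0
  for (tau in c(6, 8, 10)) {
    net <- build_network(seqs, labs, network_config(tau = tau))
    expect_lte(nrow(net$edges), prev_edges)
    expect_gte(length(unique(net$nodes$cluster)), prev_clusters)
    prev_edges <- nrow(net$edges)
    prev_clusters <- length(unique(net$nodes$cluster))
  }
})

test_that("network construction is deterministic with stable cluster ids", {
  set.seed(14)
  seqs <- vapply(1:80, function(i) random_aa_string(12, c("A", "C", "D", "E")),
                 character(1))
  labs <- sample(c("LEFT", "RIGHT"), 80, replace = TRUE)
  n1 <- build_network(seqs, labs)
  n2 <- build_network(rev(seqs), rev(labs))
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$edges, n2$edges)
  # cluster ids ordered by decreasing size
  sizes <- table(n1$nodes$cluster)
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("cluster statistics: purity, connections and SHARED labels", {
  # a fully connected 4-clique from one mutated family
  fam <- c("CASSLSGTGELFF", "CASSLSGTGELFY", "CASSLSGTGELFW", "CASSLSGTGELFH")
  labs <- c("LEFT", "LEFT", "LEFT", "RIGHT")
  net <- build_network(fam, labs)
  st <- cluster_statistics(net, top_c = 1)
  expect_equal(st$n_sequences, 4L)
  expect_equal(st$n_connections, 6L)   # C(4,2)
  expect_equal(st$purity, 0.75)
  # a junction present in both samples is one SHARED node
  net2 <- build_network(c(fam, fam[1]), c(labs, "RIGHT"))
  expect_equal(net2$nodes$label[net2$nodes$junction_aa == fam[1]], "SHARED")
  # singleton cluster has purity 1
  net3 <- build_network(c(fam, "CWWWWWWWWWWWF"), c(labs, "LEFT"))
  st3 <- suppressMessages(cluster_statistics(net3, top_c = 5))
  expect_equal(nrow(st3), 2L)
  expect_equal(st3$purity[2], 1)
  # abundance purity variant degenerates to 1/n without counts
  expect_equal(cluster_statistics(net, top_c = 1, purity = "abundance")$purity,
               0.25)
})

test_that("planted families are recovered as single connected components", {
  recovered <- 0L; total <- 0L
  for (seed in 1:5) {
    g <- generate_cohort(small_antigen_cfg(seed, size = 200L, n_shared = 0L))
    reps <- lapply(g$cohort, collapse_by_junction_aa)
    net <- joint_network(reps[[1]], reps[[2]])
    cl <- setNames(net$nodes$cluster, net$nodes$junction_aa)
    for (fam in g$truth$cluster_families[["P1_TREG"]]) {
      total <- total + 1L
      recovered <- recovered + (length(unique(cl[fam])) == 1L &&
                                  !anyNA(cl[fam]))
    }
  }
  expect_gte(recovered / total, 0.9)
})

test_that("network export writes edge list and GraphML", {
  dir <- withr::local_tempdir()
  net <- build_network(c("CASSLSGTGELFF", "CASSLSGTGELFY"), c("LEFT", "RIGHT"))
  export_network(net, path_graphml = file.path(dir, "n.graphml"),
                 path_edges = file.path(dir, "n.tsv"))
  expect_true(file.exists(file.path(dir, "n.graphml")))
  edges <- read.delim(file.path(dir, "n.tsv"))
  expect_equal(nrow(edges), 1L)
})
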