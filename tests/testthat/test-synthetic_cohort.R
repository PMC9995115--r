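test_that("cohort generation is deterministic and plants its ground truth", {
  cfg <- small_antigen_cfg(42L, size = 150L, n_shared = 20L)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(lapply(g1$cohort, `[[`, "clonotypes"),
                   lapply(g2$cohort, `[[`, "clonotypes"))
  expect_identical(g1$truth$shared_clone_keys, g2$truth$shared_clone_keys)
  # byte-identical emitted tables
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(g1$cohort, d1); write_cohort(g2$cohort, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # planted shared clones present in both compartments
  ks <- g1$truth$shared_clone_keys[["P1_TREG"]]
  expect_length(ks, 20L)
  for (r in g1$cohort)
    expect_true(all(ks %in% r$clonotypes$junction_aa))
  # planted family members present in their assigned compartment
  prov <- g1$truth$provenance
  for (i in seq_len(nrow(prov)))
    expect_true(prov$junction_aa[i] %in%
                  g1$cohort[[prov$sample_id[i]]]$clonotypes$junction_aa)
})

test_that("planted shared clones occupy the configured rank band", {
  cfg <- small_antigen_cfg(7L, size = 200L, n_shared = 25L)
  g <- generate_cohort(cfg)
  ks <- g$truth$shared_clone_keys[["P1_TREG"]]
  for (r in g$cohort) {
    cl <- r$clonotypes[order(-r$clonotypes$count), ]
    expect_true(all(ks %in% cl$junction_aa[1:25]))
  }
})

test_that("clone sizes are heavy-tailed (Zipf sanity bound)", {
  g <- generate_cohort(small_antigen_cfg(3L, size = 300L))
  for (r in g$cohort) {
    counts <- r$clonotypes$count
    expect_gte(max(counts) / median(counts), 10)
    expect_equal(nrow(r$clonotypes), 300L)
  }
})

test_that("random repertoires have exactly size unique junctions, count 1", {
  m <- toy_recomb_model()
  r <- generate_random_repertoire(m, 50, seed = 5)
  expect_equal(nrow(r$clonotypes), 50L)
  expect_false(anyDuplicated(r$clonotypes$junction_aa) > 0)
  expect_true(all(r$clonotypes$count == 1))
  expect_identical(generate_random_repertoire(m, 50, seed = 5)$clonotypes,
                   r$clonotypes)
  r1 <- generate_random_repertoire(m, 1, seed = 9)
  expect_equal(nrow(r1$clonotypes), 1L)
  # exhausted support fails with an explanation
  expect_error(generate_random_repertoire(model_m1(), 2, seed = 1,
                                          max_rounds = 3L),
               "support")
})

test_that("family junctions are too short to plant under an incompatible model", {
  # a model that can only make short junctions cannot seed 13-15 aa families
  short_model <- recomb_model(
    data.frame(name = "V1", seq = "TGTGCA", prob = 1),
    data.frame(name = "J1", seq = "TTCTTT", prob = 1),
    1, 1, rep(1 / 4, 4), uniform_nt)
  cfg <- cohort_config(n_patients = 1, compartments = c("SF_LEFT", "SF_RIGHT"),
                       subsets = "TREG", visits = 1, repertoire_size = 20,
                       reads_per_sample = 200, model = short_model,
                       selection_mode = "ANTIGEN", planted_shared = NULL,
                       planted_clusters = list(n_families = 2, family_size = 4,
                                               s = 1,
                                               compartments = c("SF_LEFT", "SF_RIGHT")),
                       seed = 1)
  expect_error(generate_cohort(cfg), "family|13-15")
})

test_that("NEUTRAL cohorts couple clone frequency to generation probability", {
  m <- toy_recomb_model()
  rhos <- vapply(1:8, function(seed) {
    cfg <- cohort_config(n_patients = 1, compartments = "SF_LEFT",
                         subsets = "TREG", visits = 1,
                         repertoire_size = 250, reads_per_sample = 5000,
                         selection_mode = "NEUTRAL", planted_shared = NULL,
                         planted_clusters = NULL, seed = seed)
    rep <- generate_cohort(cfg)$cohort[[1]]
    pg <- pgen_aa(m, rep$clonotypes$junction_aa)$pgen
    keep <- pg > 0
    spearman_correlation(rep$clonotypes$frequency[keep], pg[keep])$rho
  }, numeric(1))
  expect_gt(mean(rhos), 0)
  expect_gt(mean(rhos > 0), 0.8)
})

test_that("the Treg multiplier yields more planted sharing for Tregs", {
  cfg <- cohort_config(n_patients = 1, compartments = c("SF_LEFT", "SF_RIGHT"),
                       subsets = c("TREG", "NON_TREG"), visits = 1,
                       repertoire_size = 300, reads_per_sample = 6000,
                       selection_mode = "ANTIGEN",
                       planted_shared = list(n_clones = 20,
                                             compartments = c("SF_LEFT", "SF_RIGHT"),
                                             rank_band = c(1L, 20L)),
                       planted_clusters = NULL, treg_multiplier = 2, seed = 4)
  g <- generate_cohort(cfg)
  expect_length(g$truth$shared_clone_keys[["P1_TREG"]], 40L)
  expect_length(g$truth$shared_clone_keys[["P1_NON_TREG"]], 20L)
})

test_that("ground truth serializes to structured text", {
  g <- generate_cohort(small_antigen_cfg(2L, size = 150L))
  p <- file.path(withr::local_tempdir(), "truth.json")
  write_ground_truth(g$truth, p)
  back <- jsonlite::fromJSON(p)
  expect_setequal(unlist(back$shared_clone_keys$P1_TREG),
                  g$truth$shared_clone_keys[["P1_TREG"]])
})
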