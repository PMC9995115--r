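test_that("degenerate model M1 forces its single junction", {
  m1 <- model_m1()
  expect_equal(pgen_nt(m1, "TGTTTT")$pgen, 1)
  expect_equal(pgen_nt(m1, "TGTTTA")$pgen, 0)
  expect_equal(pgen_aa(m1, "CF")$pgen, 1)
  draws <- sample_junctions(m1, 5, seed = 1)
  expect_true(all(draws$nt == "TGTTTT"))
  expect_true(all(draws$aa == "CF"))
  expect_equal(enumerate_pgen_oracle(m1), c(TGTTTT = 1))
})

test_that("single-scenario pgen values are analytically exact (M2, M3)", {
  m2 <- model_m2()
  # one insertion of A: P(len=1) * P(A) = 0.5 * 0.25
  expect_equal(pgen_nt(m2, "TGTATTT")$pgen, 0.125)
  m3 <- model_m3()
  # scenarios (del=0, ins=0) = 0.25 and (del=1, ins="T") = 0.0625
  expect_equal(pgen_nt(m3, "TGTTTT")$pgen, 0.3125)
})

test_that("pgen_nt matches the exhaustive enumeration oracle", {
  for (m in list(model_m2(), model_m3(), model_small(1L), model_small(2L))) {
    oracle <- enumerate_pgen_oracle(m)
    expect_equal(sum(oracle), 1, tolerance = 1e-9)
    got <- pgen_nt(m, names(oracle))$pgen
    expect_true(max(abs(got - unname(oracle))) <= 1e-12)
  }
})

test_that("pgen_aa equals the codon-grouped enumeration oracle", {
  for (m in list(model_m3(), model_small(2L))) {
    oracle <- enumerate_pgen_oracle(m)
    aa <- translate_junction(names(oracle))
    keep <- !is.na(aa) & !grepl("\\*", aa)
    agg <- tapply(oracle[keep], aa[keep], sum)
    got <- pgen_aa(m, names(agg))$pgen
    expect_true(max(abs(got - unname(agg))) <= 1e-12)
    # sum over nt dominated by the aa-level sum
    some_nt <- head(names(oracle)[keep], 3)
    expect_true(all(pgen_aa(m, translate_junction(some_nt))$pgen >=
                      pgen_nt(m, some_nt)$pgen - 1e-15))
  }
})

test_that("oracle refuses oversized models and validates input alphabets", {
  big <- toy_recomb_model()
  expect_error(enumerate_pgen_oracle(big, cap = 1e6), "exceeds cap")
  m <- model_m1()
  expect_error(pgen_nt(m, "TGX"), "A/C/G/T")
  expect_error(pgen_aa(m, "CZ"), "alphabet")
})

test_that("M2 enumeration has the forced 5-sequence support", {
  oracle <- enumerate_pgen_oracle(model_m2())
  expect_length(oracle, 5L)
  expect_true("TGTTTT" %in% names(oracle))
  expect_equal(sum(oracle), 1, tolerance = 1e-12)
})

test_that("sampling is deterministic under a seed and consistent with the oracle", {
  m2 <- model_m2()
  expect_identical(sample_junctions(m2, 50, seed = 7),
                   sample_junctions(m2, 50, seed = 7))
  expect_equal(nrow(sample_junctions(m2, 0, seed = 1)), 0L)
  # empirical frequencies within 3 binomial SE of oracle probabilities
  oracle <- enumerate_pgen_oracle(m2)
  n <- 1e5
  draws <- sample_junctions(m2, n, seed = 11, productive_only = FALSE)
  emp <- table(factor(draws$nt, levels = names(oracle))) / n
  for (s in names(oracle)) {
    p <- oracle[[s]]
    expect_lt(abs(emp[[s]] - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("sampled junctions translate consistently and respect productivity", {
  m <- toy_recomb_model()
  draws <- sample_junctions(m, 400, seed = 3, productive_only = TRUE)
  expect_true(all(translate_junction(draws$nt) == draws$aa))
  expect_true(all(nchar(draws$nt) %% 3 == 0))
  expect_false(any(grepl("\\*", draws$aa)))
})

test_that("a model that cannot produce productive junctions fails with a cap", {
  # single V of 4 nt, no insertions: junction length 7, never in frame
  m <- recomb_model(data.frame(name = "V1", seq = "TGTA", prob = 1),
                    data.frame(name = "J1", seq = "TTT", prob = 1),
                    1, 1, 1, uniform_nt)
  expect_error(sample_junctions(m, 5, seed = 1, productive_only = TRUE,
                                max_rounds = 3L), "productive")
})

test_that("insertion-mass monotonicity: longer insertions cannot raise the 0-ins pgen", {
  m_no_ins <- model_m1()
  m_ins <- model_m2()
  expect_lt(pgen_nt(m_ins, "TGTTTT")$pgen, pgen_nt(m_no_ins, "TGTTTT")$pgen)
})

test_that("model spec files round-trip and are validated", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.json")
  m <- model_small(2L)
  write_recomb_model(m, p)
  back <- read_recomb_model(p)
  expect_equal(back$v_segments$seq, m$v_segments$seq)
  expect_equal(back$ins_len_pmf, m$ins_len_pmf)
  expect_equal(pgen_nt(back, "TGTGCATTCTTT")$pgen,
               pgen_nt(m, "TGTGCATTCTTT")$pgen)
  # invalid pmf rejected
  expect_error(recomb_model(m$v_segments, m$j_segments,
                            c(0.5, 0.6), m$j_del_pmf, m$ins_len_pmf,
                            m$ins_nt_probs), "sum to 1")
  # deletion support beyond segment length rejected
  expect_error(recomb_model(data.frame(name = "V", seq = "TGT", prob = 1),
                            m$j_segments, rep(0.2, 5), m$j_del_pmf,
                            m$ins_len_pmf, m$ins_nt_probs),
               "deletion support")
})

test_that("conditioned pgen rescales by the productive mass", {
  m <- model_m3()
  raw <- pgen_aa(m, "CF")$pgen
  cond <- pgen_aa(m, "CF", conditioned = TRUE, seed = 5)$pgen
  expect_gt(cond, raw)   # conditioning divides by a mass < 1
})
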