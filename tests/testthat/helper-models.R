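# Tiny enumerable recombination models and fixture builders used across the
# suite. M1-M3 are fully enumerable by hand:
#   M1: single V suffix TGT, single J prefix TTT, no deletions/insertions.
#   M2: M1 plus insertion length in {0, 1} (each 1/2), uniform inserted nt.
#   M3: M2 plus V deletions in {0, 1} (each 1/2).

uniform_nt <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

model_m1 <- function() {
  recomb_model(data.frame(name = "V1", seq = "TGT", prob = 1),
               data.frame(name = "J1", seq = "TTT", prob = 1),
               v_del_pmf = 1, j_del_pmf = 1, ins_len_pmf = 1,
               ins_nt_probs = uniform_nt)
}

model_m2 <- function() {
  recomb_model(data.frame(name = "V1", seq = "TGT", prob = 1),
               data.frame(name = "J1", seq = "TTT", prob = 1),
               v_del_pmf = 1, j_del_pmf = 1, ins_len_pmf = c(0.5, 0.5),
               ins_nt_probs = uniform_nt)
}

model_m3 <- function() {
  recomb_model(data.frame(name = "V1", seq = "TGT", prob = 1),
               data.frame(name = "J1", seq = "TTT", prob = 1),
               v_del_pmf = c(0.5, 0.5), j_del_pmf = 1,
               ins_len_pmf = c(0.5, 0.5), ins_nt_probs = uniform_nt)
}

# a richer but still enumerable model: 2 V, 2 J, deletions and insertions
model_small <- function(ins_max = 2L) {
  recomb_model(
    data.frame(name = c("V1", "V2"), seq = c("TGTGCA", "TGCAGT"),
               prob = c(0.6, 0.4)),
    data.frame(name = c("J1", "J2"), seq = c("TTCTTT", "CAGTAC"),
               prob = c(0.7, 0.3)),
    v_del_pmf = c(0.5, 0.3, 0.2), j_del_pmf = c(0.6, 0.4),
    ins_len_pmf = rep(1 / (ins_max + 1), ins_max + 1),
    ins_nt_probs = c(A = 0.1, C = 0.2, G = 0.3, T = 0.4))
}

# quick repertoire from junction/count pairs
make_rep <- function(junctions, counts, ...) {
  tcr_repertoire(data.frame(junction_aa = junctions, count = counts,
                            stringsAsFactors = FALSE), ...)
}

# independent brute-force k-mer intersection oracle (base R substring route)
kmer_oracle <- function(a, b, k = 3L) {
  ka <- unique(substring(a, seq_len(max(nchar(a) - k + 1L, 0L)),
                         seq_len(max(nchar(a) - k + 1L, 0L)) + k - 1L))
  kb <- unique(substring(b, seq_len(max(nchar(b) - k + 1L, 0L)),
                         seq_len(max(nchar(b) - k + 1L, 0L)) + k - 1L))
  length(intersect(ka[nchar(ka) == k], kb[nchar(kb) == k]))
}

random_aa_string <- function(len, alphabet = c("A", "C", "D", "E", "F", "G")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small LEFT/RIGHT ANTIGEN cohort used by several tests
small_antigen_cfg <- function(seed, size = 300L, with_families = TRUE,
                              n_shared = 30L) {
  cohort_config(
    n_patients = 1L, compartments = c("SF_LEFT", "SF_RIGHT"),
    subsets = "TREG", visits = 1L,
    repertoire_size = size, reads_per_sample = 20L * size,
    selection_mode = "ANTIGEN",
    planted_shared = if (n_shared > 0)
      list(n_clones = n_shared, compartments = c("SF_LEFT", "SF_RIGHT"),
           rank_band = c(1L, n_shared)) else NULL,
    planted_clusters = if (with_families)
      list(n_families = 6L, family_size = 8L, s = 1L,
           compartments = c("SF_LEFT", "SF_RIGHT")) else NULL,
    treg_multiplier = 1, seed = seed)
}
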