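# Generative model of V(D)J recombination (V - insertions - J; the D segment
# and both insertion zones are collapsed into one i.i.d. insertion segment).
# Supports seeded sampling of junctions and exact generation probabilities
# (pgen) at nucleotide and amino-acid level.

#' Construct a V(D)J recombination model
#'
#' The model describes junction generation as: choose a V segment (its 3'
#' junction-proximal nucleotide suffix), trim `del_v` nucleotides from its 3'
#' end, insert an i.i.d. nucleotide segment, choose a J segment (5' prefix)
#' trimmed by `del_j` at its 5' end. The junction is the concatenation; its
#' reading frame starts at the first V nucleotide (suffixes are supplied
#' codon-aligned).
#'
#' @param v_segments data.frame with columns `name`, `seq` (3' nucleotide
#'   suffix), `prob` (usage probability).
#' @param j_segments data.frame with columns `name`, `seq` (5' nucleotide
#'   prefix), `prob`.
#' @param v_del_pmf numeric vector of deletion probabilities for 0, 1, ...
#'   nucleotides trimmed from the V suffix.
#' @param j_del_pmf deletion probabilities for the J prefix.
#' @param ins_len_pmf insertion-length probabilities for 0, 1, ... inserted
#'   nucleotides.
#' @param ins_nt_probs named numeric vector of per-position insertion
#'   nucleotide probabilities for `A`, `C`, `G`, `T`.
#' @return An object of class `recomb_model`.
#' @export
#' @examples
#' m <- recomb_model(
#'   v_segments = data.frame(name = "V1", seq = "TGT", prob = 1),
#'   j_segments = data.frame(name = "J1", seq = "TTT", prob = 1),
#'   v_del_pmf = 1, j_del_pmf = 1, ins_len_pmf = 1,
#'   ins_nt_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
#' pgen_nt(m, "TGTTTT")$pgen
recomb_model <- function(v_segments, j_segments, v_del_pmf, j_del_pmf,
                         ins_len_pmf, ins_nt_probs) {
  v_segments <- as.data.frame(v_segments, stringsAsFactors = FALSE)
  j_segments <- as.data.frame(j_segments, stringsAsFactors = FALSE)
  if (!is.null(v_segments$prob)) v_segments$prob <- as.numeric(unlist(v_segments$prob))
  if (!is.null(j_segments$prob)) j_segments$prob <- as.numeric(unlist(j_segments$prob))
  m <- structure(list(
    v_segments = v_segments, j_segments = j_segments,
    v_del_pmf = as.numeric(v_del_pmf), j_del_pmf = as.numeric(j_del_pmf),
    ins_len_pmf = as.numeric(ins_len_pmf),
    ins_nt_probs = ins_nt_probs[c("A", "C", "G", "T")]
  ), class = "recomb_model")
  validate_recomb_model(m)
  m
}

validate_recomb_model <- function(m) {
  stopifnot(inherits(m, "recomb_model"))
  for (seg in list(m$v_segments, m$j_segments)) {
    if (!all(c("name", "seq", "prob") %in% names(seg)))
      stop("segment tables need columns name, seq, prob", call. = FALSE)
    if (!all(grepl("^[ACGT]+$", seg$seq)))
      stop("segment sequences must be over A/C/G/T", call. = FALSE)
  }
  pmfs <- list(v_usage = m$v_segments$prob, j_usage = m$j_segments$prob,
               v_del_pmf = m$v_del_pmf, j_del_pmf = m$j_del_pmf,
               ins_len_pmf = m$ins_len_pmf, ins_nt_probs = m$ins_nt_probs)
  for (nm in names(pmfs)) {
    p <- pmfs[[nm]]
    if (any(is.na(p)) || any(p < 0))
      stop(sprintf("%s must be non-negative", nm), call. = FALSE)
    if (abs(sum(p) - 1) > 1e-12)
      stop(sprintf("%s must sum to 1 (got %.15g)", nm, sum(p)), call. = FALSE)
  }
  if (length(m$v_del_pmf) - 1L > min(nchar(m$v_segments$seq)))
    stop("V deletion support exceeds the shortest V suffix", call. = FALSE)
  if (length(m$j_del_pmf) - 1L > min(nchar(m$j_segments$seq)))
    stop("J deletion support exceeds the shortest J prefix", call. = FALSE)
  invisible(m)
}

#' @export
print.recomb_model <- function(x, ...) {
  cat(sprintf(
    "V(D)J recombination model: %d V suffixes, %d J prefixes, del 0-%d/0-%d, ins 0-%d\n",
    nrow(x$v_segments), nrow(x$j_segments),
    length(x$v_del_pmf) - 1L, length(x$j_del_pmf) - 1L,
    length(x$ins_len_pmf) - 1L))
  invisible(x)
}

#' Read or write a recombination model specification (JSON)
#'
#' The on-disk schema is a JSON object with fields `v_segments`,
#' `j_segments` (arrays of `{name, seq, prob}`), `v_del_pmf`, `j_del_pmf`,
#' `ins_len_pmf` (arrays indexed from 0), and `ins_nt_probs`
#' (`{A, C, G, T}`). The file is validated on load.
#'
#' @param path file path.
#' @return `read_recomb_model()` returns a `recomb_model`;
#'   `write_recomb_model()` returns `path` invisibly.
#' @export
read_recomb_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  spec <- jsonlite::fromJSON(path)
  need <- c("v_segments", "j_segments", "v_del_pmf", "j_del_pmf",
            "ins_len_pmf", "ins_nt_probs")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("model spec missing fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  recomb_model(spec$v_segments, spec$j_segments, spec$v_del_pmf,
               spec$j_del_pmf, spec$ins_len_pmf, unlist(spec$ins_nt_probs))
}

#' @rdname read_recomb_model
#' @param model a `recomb_model`.
#' @export
write_recomb_model <- function(model, path) {
  validate_recomb_model(model)
  spec <- unclass(model)
  spec$ins_nt_probs <- as.list(spec$ins_nt_probs)  # keep A/C/G/T names
  jsonlite::write_json(spec, path, dataframe = "rows",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Default packaged toy recombination model
#'
#' A small model (8 V suffixes, 6 J prefixes, 0-4 deletions, 0-10 i.i.d.
#' insertions, near-uniform usage with mild skew) producing productive
#' junctions of typically 10-15 amino acids. It is deliberately far smaller
#' than a full human TRB model; it exists so that simulations, networks and
#' pgen analyses are reproducible and fast.
#'
#' @return A `recomb_model`.
#' @export
toy_recomb_model <- function() {
  path <- system.file("extdata", "toy_model.json", package = "tcrtrace")
  read_recomb_model(path)
}

# All (segment, deletion) combinations with their joint probabilities.
model_combos <- function(m) {
  vd <- length(m$v_del_pmf) - 1L
  jd <- length(m$j_del_pmf) - 1L
  v <- do.call(rbind, lapply(seq_len(nrow(m$v_segments)), function(i) {
    s <- m$v_segments$seq[i]
    data.frame(part = substring(s, 1L, nchar(s) - (0:vd)),
               prob = m$v_segments$prob[i] * m$v_del_pmf,
               stringsAsFactors = FALSE)
  }))
  j <- do.call(rbind, lapply(seq_len(nrow(m$j_segments)), function(i) {
    s <- m$j_segments$seq[i]
    data.frame(part = substring(s, 1L + (0:jd)),
               prob = m$j_segments$prob[i] * m$j_del_pmf,
               stringsAsFactors = FALSE)
  }))
  list(vparts = v$part, vprobs = v$prob, jparts = j$part, jprobs = j$prob)
}

#' Exact generation probability of a nucleotide junction
#'
#' Sums the probabilities `P(V) P(del_v) P(ins_len) prod P(ins_nt) P(del_j)
#' P(J)` over every recombination scenario whose concatenated junction equals
#' the query.
#'
#' @param model a `recomb_model`.
#' @param nt character vector of nucleotide junctions.
#' @param conditioned if `TRUE`, divide by the model's total productive
#'   probability mass (estimated once by seeded Monte Carlo); the default
#'   reports unconditioned generation probability.
#' @param seed seed for the conditioning estimate (ignored otherwise).
#' @return A data.frame (one row per query) with columns `sequence`, `pgen`,
#'   `level = "NT"`.
#' @export
pgen_nt <- function(model, nt, conditioned = FALSE, seed = 1L) {
  validate_recomb_model(model)
  nt <- toupper(nt)
  if (length(nt) && !all(grepl("^[ACGT]*$", nt)))
    stop("nucleotide sequences must be over A/C/G/T", call. = FALSE)
  cb <- model_combos(model)
  p <- pgen_nt_cpp(nt, cb$vparts, cb$vprobs, cb$jparts, cb$jprobs,
                   model$ins_len_pmf, as.numeric(model$ins_nt_probs))
  if (conditioned) p <- p / productive_mass(model, seed = seed)
  data.frame(sequence = nt, pgen = p, level = "NT", stringsAsFactors = FALSE)
}

#' Exact generation probability of an amino-acid junction
#'
#' Computes the exact sum of [pgen_nt()] over every nucleotide sequence of
#' length `3 * nchar(aa)` translating to the query. For each V/J trimming
#' scenario the nucleotide positions are independent, so the sum factorises
#' over codon positions (summing synonymous codons per position) instead of
#' enumerating codon combinations.
#'
#' @inheritParams pgen_nt
#' @param aa character vector of amino-acid junctions (20-letter alphabet).
#' @return A data.frame with columns `sequence`, `pgen`, `level = "AA"`.
#' @export
pgen_aa <- function(model, aa, conditioned = FALSE, seed = 1L) {
  validate_recomb_model(model)
  aa <- toupper(aa)
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), aa)
  if (length(aa) && any(bad))
    stop("amino-acid sequences must be over the 20-letter alphabet: ",
         paste(head(aa[bad], 3), collapse = ", "), call. = FALSE)
  cb <- model_combos(model)
  cod <- codons_for_aa()
  p <- pgen_aa_cpp(aa, cb$vparts, cb$vprobs, cb$jparts, cb$jprobs,
                   model$ins_len_pmf, as.numeric(model$ins_nt_probs),
                   names(cod), unname(cod))
  if (conditioned) p <- p / productive_mass(model, seed = seed)
  data.frame(sequence = aa, pgen = p, level = "AA", stringsAsFactors = FALSE)
}

# Monte-Carlo estimate of the probability that a recombination event is
# productive (in frame, no stop); cached per model within a session.
productive_mass <- function(model, n = 2e5, seed = 1L) {
  draws <- sample_recombination_events(model, n, seed = seed)
  aa <- translate_junction(draws$nt)
  mean(is_productive_aa(aa))
}

# Raw scenario draws (no productivity filter), vectorised.
sample_recombination_events <- function(model, n, seed) {
  with_seed(seed, {
    vi <- sample.int(nrow(model$v_segments), n, replace = TRUE,
                     prob = model$v_segments$prob)
    ji <- sample.int(nrow(model$j_segments), n, replace = TRUE,
                     prob = model$j_segments$prob)
    dv <- sample.int(length(model$v_del_pmf), n, replace = TRUE,
                     prob = model$v_del_pmf) - 1L
    dj <- sample.int(length(model$j_del_pmf), n, replace = TRUE,
                     prob = model$j_del_pmf) - 1L
    il <- sample.int(length(model$ins_len_pmf), n, replace = TRUE,
                     prob = model$ins_len_pmf) - 1L
    max_ins <- length(model$ins_len_pmf) - 1L
    ins <- character(n)
    if (max_ins > 0L) {
      pool <- matrix(sample(c("A", "C", "G", "T"), n * max_ins, replace = TRUE,
                            prob = model$ins_nt_probs), nrow = n)
      full <- do.call(paste0, as.data.frame(pool, stringsAsFactors = FALSE))
      ins <- substr(full, 1L, il)
    }
    vseq <- model$v_segments$seq[vi]
    vpart <- substr(vseq, 1L, nchar(vseq) - dv)
    jpart <- substring(model$j_segments$seq[ji], 1L + dj)
    data.frame(nt = paste0(vpart, ins, jpart), stringsAsFactors = FALSE)
  })
}

#' Sample junctions from a recombination model
#'
#' Draws independent recombination events and returns their nucleotide and
#' translated amino-acid junctions. With `productive_only = TRUE`,
#' out-of-frame junctions (length not a multiple of 3) and junctions whose
#' translation contains a stop are rejected and redrawn.
#'
#' @inheritParams pgen_nt
#' @param n number of junctions to draw.
#' @param seed integer seed; identical `(model, n, seed)` give identical
#'   output.
#' @param productive_only reject non-productive events.
#' @param max_rounds rejection-sampling round cap before failing.
#' @return A data.frame with columns `nt` and `aa` (`aa` is `NA` for
#'   non-productive junctions when `productive_only = FALSE`).
#' @export
sample_junctions <- function(model, n, seed, productive_only = TRUE,
                             max_rounds = 50L) {
  validate_recomb_model(model)
  stopifnot(n >= 0)
  if (n == 0L) return(data.frame(nt = character(), aa = character(),
                                 stringsAsFactors = FALSE))
  if (!productive_only) {
    ev <- sample_recombination_events(model, n, seed)
    ev$aa <- translate_junction(ev$nt)
    return(ev)
  }
  out_nt <- character(0)
  round <- 0L
  while (length(out_nt) < n) {
    round <- round + 1L
    if (round > max_rounds)
      stop(sprintf("could not draw %d productive junctions in %d rounds",
                   n, max_rounds), call. = FALSE)
    need <- n - length(out_nt)
    ev <- sample_recombination_events(model, max(4L * need, 64L),
                                      seed = stage_seed(seed, paste0("round", round)))
    aa <- translate_junction(ev$nt)
    keep <- is_productive_aa(aa)
    out_nt <- c(out_nt, ev$nt[keep])
  }
  out_nt <- out_nt[seq_len(n)]
  data.frame(nt = out_nt, aa = translate_junction(out_nt),
             stringsAsFactors = FALSE)
}

#' Exhaustive enumeration oracle for generation probabilities
#'
#' Enumerates every recombination scenario of a small model and accumulates
#' probability per nucleotide junction. Used as the independent reference for
#' [pgen_nt()] and [pgen_aa()]; it refuses models whose scenario count
#' exceeds `cap`.
#'
#' @inheritParams pgen_nt
#' @param cap maximum admissible scenario count (default `1e6`).
#' @return Named numeric vector: junction -> total generation probability.
#' @export
enumerate_pgen_oracle <- function(model, cap = 1e6) {
  validate_recomb_model(model)
  nv <- nrow(model$v_segments) * length(model$v_del_pmf)
  nj <- nrow(model$j_segments) * length(model$j_del_pmf)
  ins_counts <- 4^(seq_along(model$ins_len_pmf) - 1L)
  n_scen <- nv * nj * sum(ins_counts)
  if (n_scen > cap)
    stop(sprintf("scenario count %.0f exceeds cap %.0f", n_scen, cap),
         call. = FALSE)
  cb <- model_combos(model)
  acc <- new.env(hash = TRUE, parent = emptyenv())
  nts <- c("A", "C", "G", "T")
  ins_strings <- function(len) {
    if (len == 0L) return(data.frame(s = "", p = 1, stringsAsFactors = FALSE))
    grid <- do.call(expand.grid, c(rep(list(nts), len),
                                   stringsAsFactors = FALSE))
    p <- Reduce(`*`, lapply(grid, function(col) model$ins_nt_probs[col]))
    data.frame(s = do.call(paste0, grid), p = as.numeric(p),
               stringsAsFactors = FALSE)
  }
  for (len in seq_along(model$ins_len_pmf) - 1L) {
    pl <- model$ins_len_pmf[len + 1L]
    if (pl <= 0) next
    insd <- ins_strings(len)
    for (vi in seq_along(cb$vparts)) {
      if (cb$vprobs[vi] <= 0) next
      for (ji in seq_along(cb$jparts)) {
        if (cb$jprobs[ji] <= 0) next
        base <- cb$vprobs[vi] * pl * cb$jprobs[ji]
        seqs <- paste0(cb$vparts[vi], insd$s, cb$jparts[ji])
        ps <- base * insd$p
        for (t in seq_along(seqs)) {
          prev <- acc[[seqs[t]]]
          acc[[seqs[t]]] <- (if (is.null(prev)) 0 else prev) + ps[t]
        }
      }
    }
  }
  out <- unlist(as.list(acc))
  out[order(names(out))]
}
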