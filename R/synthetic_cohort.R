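# Synthetic multi-compartment, multi-visit Treg/non-Treg cohorts with
# controlled ground truth: planted hyper-expanded clones shared across
# compartments/visits, planted sequence-similar ("antigen-driven") clone
# families, and a neutral background drawn from the recombination model with
# power-law (Zipf) clone sizes.
#
# Selection modes:
#   NEUTRAL - clone-size ranks follow the model draw tally, so frequency is
#     positively coupled to generation probability (convergent
#     recombination).
#   ANTIGEN - ranks are assigned independently of clone identity (planted
#     clones occupy a configured top-rank band), so frequency is
#     exchangeable with respect to pgen (convergent selection).

#' Cohort simulation configuration
#'
#' Defaults describe the package's reference synthetic world: 2 patients,
#' three compartments (left/right synovial fluid, blood), 2 visits, both
#' subsets, 2000 clonotypes and 50,000 templates per sample, Zipf exponent
#' 1.5, 40 planted shared hyper-expanded clones occupying top ranks, six
#' planted cross-knee clone families of eight members (one substitution per
#' member), and a Treg sharing multiplier of 2 (Tregs receive twice the
#' planted shared clones of non-Tregs).
#'
#' @param n_patients number of patients.
#' @param compartments compartment labels used per patient.
#' @param subsets cell subsets simulated per patient.
#' @param visits number of visits (>= 1).
#' @param repertoire_size clonotypes per sample.
#' @param reads_per_sample total template count per sample.
#' @param model a `recomb_model` (default: [toy_recomb_model()]).
#' @param alpha Zipf clone-size exponent (> 1).
#' @param selection_mode `"ANTIGEN"` or `"NEUTRAL"`.
#' @param planted_shared list with `n_clones`, `compartments`, `rank_band`
#'   (planted clones appear in all visits); `NULL` for none.
#' @param planted_clusters list with `n_families`, `family_size`, `s`
#'   (substitutions per member), `compartments`; `NULL` for none.
#' @param treg_multiplier factor on planted shared clones for the TREG
#'   subset.
#' @param seed integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2L,
                          compartments = c("SF_LEFT", "SF_RIGHT", "PB"),
                          subsets = c("TREG", "NON_TREG"),
                          visits = 2L,
                          repertoire_size = 2000L,
                          reads_per_sample = 50000L,
                          model = toy_recomb_model(),
                          alpha = 1.5,
                          selection_mode = c("ANTIGEN", "NEUTRAL"),
                          planted_shared = list(
                            n_clones = 40L,
                            compartments = c("SF_LEFT", "SF_RIGHT", "PB"),
                            rank_band = c(1L, 40L)),
                          planted_clusters = list(
                            n_families = 6L, family_size = 8L, s = 1L,
                            compartments = c("SF_LEFT", "SF_RIGHT")),
                          treg_multiplier = 2,
                          seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(alpha > 1, visits >= 1, repertoire_size >= 10,
            reads_per_sample >= repertoire_size)
  if (!is.null(planted_shared)) {
    stopifnot(planted_shared$n_clones >= 0,
              planted_shared$n_clones * max(1, treg_multiplier) <= repertoire_size)
  }
  if (!is.null(planted_clusters)) stopifnot(planted_clusters$s >= 1)
  structure(list(n_patients = as.integer(n_patients),
                 compartments = compartments, subsets = subsets,
                 visits = as.integer(visits),
                 repertoire_size = as.integer(repertoire_size),
                 reads_per_sample = as.integer(reads_per_sample),
                 model = model, alpha = alpha,
                 selection_mode = selection_mode,
                 planted_shared = planted_shared,
                 planted_clusters = planted_clusters,
                 treg_multiplier = treg_multiplier,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Zipf clone counts over ranks 1..S scaled to ~reads total (each >= 1)
zipf_counts <- function(S, alpha, reads) {
  w <- (seq_len(S))^(-alpha)
  cnt <- round(w / sum(w) * reads)
  pmax(cnt, 1)
}

# draw distinct productive junctions plus their draw tallies, tallied over
# enough model draws to cover `n_distinct`
draw_junction_tally <- function(model, n_distinct, seed, factor = 12L,
                                max_rounds = 40L) {
  tallies <- integer(0)
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds)
      stop(sprintf("model support appears smaller than %d distinct junctions",
                   n_distinct), call. = FALSE)
    draws <- sample_junctions(model, factor * n_distinct,
                              seed = stage_seed(seed, paste0("tally", round)),
                              productive_only = TRUE)
    tab <- table(draws$aa)
    new <- tapply(c(tallies, as.integer(tab)),
                  c(names(tallies), names(tab)), sum)
    tallies <- setNames(as.integer(new), names(new))
    if (length(tallies) >= n_distinct) break
  }
  tallies
}

#' Sample a random repertoire of unique junctions
#'
#' Draws productive-only amino-acid junctions from the model, resampling
#' duplicates, until exactly `size` unique junctions are obtained; each gets
#' count 1. Used for size-matched random comparison repertoires.
#'
#' @param model a `recomb_model`.
#' @param size number of unique junctions (>= 1).
#' @param seed integer seed.
#' @param max_rounds sampling round cap before concluding the model support
#'   is too small.
#' @return A `tcr_repertoire` with `size` clonotypes, all counts 1.
#' @export
generate_random_repertoire <- function(model, size, seed, max_rounds = 40L) {
  stopifnot(size >= 1)
  seen <- character(0)
  round <- 0L
  while (length(seen) < size) {
    round <- round + 1L
    if (round > max_rounds)
      stop(sprintf("model support smaller than requested size %d (got %d unique)",
                   size, length(seen)), call. = FALSE)
    draws <- sample_junctions(model, max(2L * (size - length(seen)), 64L),
                              seed = stage_seed(seed, paste0("rr", round)),
                              productive_only = TRUE)
    seen <- unique(c(seen, draws$aa))
  }
  seen <- seen[seq_len(size)]
  tcr_repertoire(data.frame(junction_aa = seen, count = 1,
                            stringsAsFactors = FALSE),
                 sample_id = sprintf("random_s%d", seed))
}

# planted cluster families: seed junction (13-15 aa) mutated at `s`
# positions per member within a short window, verified to satisfy the
# >= tau shared k-mer rule pairwise; regenerated on failure.
make_cluster_families <- function(model, n_families, family_size, s, seed,
                                  k = 3L, tau = 8L, max_tries = 200L) {
  aa_letters <- AA_ALPHABET
  pool <- sample_junctions(model, 400L * n_families + 1000L,
                           seed = stage_seed(seed, "fampool"),
                           productive_only = TRUE)$aa
  pool <- unique(pool[nchar(pool) >= 13L & nchar(pool) <= 15L])
  if (length(pool) < n_families)
    stop("could not draw enough 13-15 aa family seed junctions", call. = FALSE)
  with_seed(stage_seed(seed, "families"), {
    lapply(seq_len(n_families), function(f) {
      base <- pool[f]
      L <- nchar(base)
      if (L < 12L)
        stop(sprintf("family %d: junction too short for the shared k-mer rule", f),
             call. = FALSE)
      for (try in seq_len(max_tries)) {
        # all members mutate the same `s` position(s): pairwise differences
        # then destroy at most 3*s k-mers, keeping >= 8 shared for 13-15 aa
        positions <- sample(3:(L - 2L), s)
        members <- vapply(seq_len(family_size - 1L), function(i) {
          m <- base
          for (pos in positions) {
            old <- substr(m, pos, pos)
            new <- sample(setdiff(aa_letters, old), 1L)
            substr(m, pos, pos) <- new
          }
          m
        }, character(1))
        fam <- unique(c(base, members))
        if (length(fam) < family_size) next
        ok <- TRUE
        for (i in seq_len(length(fam) - 1L)) {
          for (j in (i + 1L):length(fam)) {
            if (shared_kmer_count(fam[i], fam[j], k) < tau) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) return(fam)
      }
      stop(sprintf("family %d: could not satisfy the >= %d shared %d-mer rule",
                   f, tau, k), call. = FALSE)
    })
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' See [cohort_config()] for the simulated world. Background clonotypes are
#' drawn from the recombination model with Zipf clone sizes; planted shared
#' clones are copied into their configured compartments (all visits) at
#' top-rank-band positions; cluster families are split alternately across
#' their configured compartments. Identical seeds give identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return A list with `cohort` (named list of `tcr_repertoire`) and
#'   `truth` (list: `shared_clone_keys`, `cluster_families`, `provenance`
#'   data.frame).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  model <- config$model
  S <- config$repertoire_size
  cohort <- list()
  truth_shared <- list()
  truth_fams <- list()
  prov <- list()
  for (p in seq_len(config$n_patients)) {
    for (sub in config$subsets) {
      ps_seed <- stage_seed(config$seed, sprintf("p%d_%s", p, sub))
      # planted cluster families (split across their compartments)
      fams <- list()
      fam_comp <- list()
      if (!is.null(config$planted_clusters) &&
          config$planted_clusters$n_families > 0) {
        pc <- config$planted_clusters
        fams <- make_cluster_families(model, pc$n_families, pc$family_size,
                                      pc$s, seed = stage_seed(ps_seed, "fam"))
        fam_comp <- lapply(fams, function(f)
          pc$compartments[1L + (seq_along(f) - 1L) %% length(pc$compartments)])
      }
      fam_by_comp <- lapply(setNames(config$compartments, config$compartments),
        function(comp) unique(unlist(lapply(seq_along(fams), function(f)
          fams[[f]][fam_comp[[f]] == comp]))))
      # per-sample candidate pools: the top-S distinct junctions by draw
      # tally (ties broken randomly, seeded), excluding family members
      svs <- expand.grid(comp = config$compartments,
                         v = seq_len(config$visits),
                         stringsAsFactors = FALSE)
      pools <- vector("list", nrow(svs))
      for (i in seq_len(nrow(svs))) {
        sv_seed <- stage_seed(ps_seed, sprintf("%s_v%d", svs$comp[i], svs$v[i]))
        fam_here <- fam_by_comp[[svs$comp[i]]] %||% character(0)
        tal <- draw_junction_tally(model, S + length(fam_here),
                                   seed = stage_seed(sv_seed, "bg"))
        cand <- setdiff(names(tal), unlist(fams))
        o <- with_seed(stage_seed(sv_seed, "pool"),
                       order(-tal[cand], stats::runif(length(cand))))
        pools[[i]] <- cand[o][seq_len(S - length(fam_here))]
      }
      # planted shared clones: in ANTIGEN mode a uniform draw from the
      # intersection of the configured samples' pools, so that planted and
      # chance-shared clones follow the same generation-probability law and
      # frequency stays exchangeable with respect to pgen; in NEUTRAL mode
      # an independent model draw.
      n_sh <- 0L
      shared_keys <- character(0)
      band <- c(1L, 0L)
      sh_comps <- config$planted_shared$compartments %||% character(0)
      if (!is.null(config$planted_shared) && config$planted_shared$n_clones > 0) {
        mult <- if (sub == "TREG") config$treg_multiplier else 1
        n_sh <- as.integer(round(config$planted_shared$n_clones * mult))
        band <- config$planted_shared$rank_band
        band[2] <- max(band[2], band[1] + n_sh - 1L)
        if (config$selection_mode == "ANTIGEN") {
          # intersect the first-visit pools of the configured compartments;
          # persistence across later visits is then forced by injection
          inter <- Reduce(intersect, pools[svs$comp %in% sh_comps & svs$v == 1L])
          if (length(inter) < n_sh)
            stop(sprintf("pool intersection (%d) smaller than planted_shared n = %d",
                         length(inter), n_sh), call. = FALSE)
          shared_keys <- with_seed(stage_seed(ps_seed, "shared"),
                                   sample(inter, n_sh))
        } else {
          shared_keys <- generate_random_repertoire(
            model, n_sh, seed = stage_seed(ps_seed, "shared"))$clonotypes$junction_aa
        }
      }
      key_ps <- sprintf("P%d_%s", p, sub)
      truth_shared[[key_ps]] <- shared_keys
      truth_fams[[key_ps]] <- fams
      for (i in seq_len(nrow(svs))) {
        comp <- svs$comp[i]; v <- svs$v[i]
        sv_seed <- stage_seed(ps_seed, sprintf("%s_v%d", comp, v))
        fam_here <- fam_by_comp[[comp]] %||% character(0)
        sh_here <- if (comp %in% sh_comps) shared_keys else character(0)
        pool <- pools[[i]]
        bg <- setdiff(pool, sh_here)   # keeps tally (abundance) order
        bg <- bg[seq_len(S - length(fam_here) - length(sh_here))]
        counts <- zipf_counts(S, config$alpha, config$reads_per_sample)
        junctions <- character(S)
        with_seed(stage_seed(sv_seed, "assign"), {
          # planted shared clones occupy the configured top-rank band
          sh_ranks <- integer(0)
          if (length(sh_here))
            sh_ranks <- sample(band[1]:band[2], length(sh_here))
          junctions[sh_ranks] <- sh_here
          open <- setdiff(seq_len(S), sh_ranks)
          # family members: random ranks among the remainder
          fam_ranks <- integer(0)
          if (length(fam_here)) {
            fam_ranks <- sample(open, length(fam_here))
            junctions[fam_ranks] <- fam_here
            open <- setdiff(open, fam_ranks)
          }
          # background: tally order (NEUTRAL) or random (ANTIGEN)
          if (config$selection_mode == "ANTIGEN") bg <- sample(bg)
          junctions[open] <- bg
        })
        sid <- sprintf("P%d_%s_%s_V%d", p, comp, sub, v)
        cohort[[sid]] <- tcr_repertoire(
          data.frame(junction_aa = junctions, count = counts,
                     stringsAsFactors = FALSE),
          sample_id = sid, patient = sprintf("P%d", p),
          compartment = comp, subset = sub, visit = v)
        if (length(sh_here) + length(fam_here) > 0) {
          prov[[length(prov) + 1L]] <- data.frame(
            sample_id = sid,
            junction_aa = c(sh_here, fam_here),
            role = c(rep("PLANTED_SHARED", length(sh_here)),
                     rep("PLANTED_FAMILY", length(fam_here))),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- list(shared_clone_keys = truth_shared,
                cluster_families = truth_fams,
                provenance = if (length(prov)) do.call(rbind, prov)
                             else data.frame(sample_id = character(),
                                             junction_aa = character(),
                                             role = character()))
  list(cohort = cohort, truth = truth)
}

#' Write a cohort's ground truth as structured text (JSON)
#'
#' @param truth the `truth` element of [generate_cohort()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
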