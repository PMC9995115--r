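# End-to-end orchestration: spatial (across-joint) analysis, temporal
# (across-visit) analysis, similarity networks vs random repertoires, and
# diversity, from a cohort in memory or a sample sheet on disk. Every
# random stage derives its seed from the global seed and the stage name;
# every output table carries a provenance header (stage, seed, config
# hash), and reruns with the same seed are byte-identical.

as_cohort <- function(x) {
  if (is.character(x) && length(x) == 1L) return(read_sample_sheet(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "tcr_repertoire")))
  x
}

cohort_meta <- function(cohort) {
  data.frame(id = names(cohort),
             patient = vapply(cohort, function(r) r$patient, character(1)),
             compartment = vapply(cohort, function(r) r$compartment, character(1)),
             subset = vapply(cohort, function(r) r$subset, character(1)),
             visit = vapply(cohort, function(r) r$visit, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spatial (across-joint) clone-sharing analysis
#'
#' Per patient and subset, using first-visit samples: clonal proportions per
#' sample, sequential top-N intersection for every compartment pair,
#' sharing classes over the available compartments, left-vs-right paired
#' frequencies, and the frequency-vs-pgen convergence report. Stages that
#' need a missing compartment (e.g. no PB sample) are skipped with a logged
#' reason.
#'
#' @param cohort named list of `tcr_repertoire` objects or a sample-sheet
#'   path.
#' @param out_dir output directory for TSV tables (`NULL`: no files).
#' @param model `recomb_model` for generation probabilities.
#' @param seed global seed.
#' @param visit which visit to analyze (default 1).
#' @return A list of result tables, invisibly when writing files.
#' @export
run_spatial <- function(cohort, out_dir = NULL, model = toy_recomb_model(),
                        seed = 1L, visit = 1L) {
  cohort <- as_cohort(cohort)
  meta <- cohort_meta(cohort)
  meta <- meta[meta$visit == visit, , drop = FALSE]
  hash <- config_hash(list(seed = seed, visit = visit))
  props <- list(); topn <- list(); classes <- list(); paired <- list()
  sub_cohort <- list()
  for (key in unique(paste(meta$patient, meta$subset, sep = "_"))) {
    ids <- meta$id[paste(meta$patient, meta$subset, sep = "_") == key]
    reps <- lapply(cohort[ids], collapse_by_junction_aa)
    comp <- vapply(reps, function(r) r$compartment, character(1))
    for (r in reps)
      props[[r$sample_id]] <- cbind(sample_id = r$sample_id,
                                    clonal_proportion_summary(r))
    if (!all(c("SF_LEFT", "SF_RIGHT") %in% comp)) {
      tcr_log("spatial", "skipping %s: need SF_LEFT and SF_RIGHT", key)
      next
    }
    if (!"PB" %in% comp)
      tcr_log("spatial", "%s: no PB sample; 2-sample analyses only", key)
    L <- reps[[which(comp == "SF_LEFT")[1]]]
    R <- reps[[which(comp == "SF_RIGHT")[1]]]
    pairs <- combn(seq_along(reps), 2L, simplify = FALSE)
    for (pr in pairs) {
      a <- reps[[pr[1]]]; b <- reps[[pr[2]]]
      tn <- suppressWarnings(top_n_intersection(a, b))
      topn[[paste(a$sample_id, b$sample_id)]] <-
        cbind(pair = paste(a$sample_id, b$sample_id, sep = "|"), tn)
    }
    classes[[key]] <- cbind(group = key, classify_sharing(reps))
    paired[[key]] <- cbind(group = key,
                           paired_frequency_table(L, R, context = reps))
    sub_cohort <- c(sub_cohort, cohort[ids])
  }
  conv <- convergence_report(sub_cohort, model)
  out <- list(clonal_proportions = do.call(rbind, props),
              top_n_curves = do.call(rbind, topn),
              sharing_classes = do.call(rbind, classes),
              paired_frequencies = do.call(rbind, paired),
              convergence = conv)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (is.null(out[[nm]])) next
      write_tsv_provenance(out[[nm]], file.path(out_dir, paste0("spatial_", nm, ".tsv")),
                           stage = "spatial", seed = seed, cfg_hash = hash)
    }
  }
  invisible(out)
}

#' Temporal (across-visit) persistence analysis
#'
#' Jaccard overlap matrices over all of a subset's samples, top-100 Venn
#' region counts per patient/compartment across visits, persistence paired
#' frequency tables between consecutive visits, frequency-vs-pgen
#' correlations per visit pair, and a Treg vs non-Treg comparison of
#' across-visit sharing (mean off-diagonal Jaccard). Patients with a single
#' visit are excluded with a log line.
#'
#' @inheritParams run_spatial
#' @return A list of result tables.
#' @export
run_temporal <- function(cohort, out_dir = NULL, model = toy_recomb_model(),
                         seed = 1L) {
  cohort <- as_cohort(cohort)
  meta <- cohort_meta(cohort)
  hash <- config_hash(list(seed = seed))
  jac_long <- list(); venns <- list(); persist <- list()
  subset_sharing <- list()
  for (sub in unique(meta$subset)) {
    ids <- meta$id[meta$subset == sub]
    multi <- names(which(table(meta$patient[meta$subset == sub]) > 1))
    if (!length(multi)) next
    reps <- lapply(cohort[ids], collapse_by_junction_aa)
    jm <- jaccard_matrix(reps)
    jl <- data.frame(subset = sub,
                     sample_a = rep(rownames(jm), ncol(jm)),
                     sample_b = rep(colnames(jm), each = nrow(jm)),
                     jaccard = as.vector(jm), stringsAsFactors = FALSE)
    jac_long[[sub]] <- jl
    # across-visit sharing per patient/compartment
    pm <- meta[meta$subset == sub, ]
    offdiag <- c()
    for (pat in unique(pm$patient)) {
      for (comp in unique(pm$compartment[pm$patient == pat])) {
        vids <- pm$id[pm$patient == pat & pm$compartment == comp]
        if (length(vids) < 2L) {
          tcr_log("temporal", "%s %s %s: single visit, excluded", pat, comp, sub)
          next
        }
        vreps <- reps[vids]
        vc <- venn_counts(vreps, top_n = 100L)
        venns[[paste(sub, pat, comp)]] <-
          data.frame(subset = sub, patient = pat, compartment = comp,
                     region = names(vc), count = as.integer(vc),
                     stringsAsFactors = FALSE)
        for (i in seq_len(length(vids) - 1L)) {
          pf <- paired_frequency_table(vreps[[i]], vreps[[i + 1L]])
          persist[[paste(sub, pat, comp, i)]] <-
            cbind(subset = sub, patient = pat, compartment = comp,
                  visit_pair = paste(i, i + 1L, sep = "-"), pf)
          offdiag <- c(offdiag, jm[vids[i], vids[i + 1L]])
        }
      }
    }
    subset_sharing[[sub]] <- data.frame(subset = sub,
                                        mean_visit_jaccard = mean(offdiag),
                                        n_pairs = length(offdiag),
                                        stringsAsFactors = FALSE)
  }
  conv <- convergence_report(cohort, model)
  out <- list(jaccard = do.call(rbind, jac_long),
              venn_top100 = do.call(rbind, venns),
              persistence = do.call(rbind, persist),
              subset_sharing = do.call(rbind, subset_sharing),
              convergence = conv)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (is.null(out[[nm]])) next
      write_tsv_provenance(out[[nm]], file.path(out_dir, paste0("temporal_", nm, ".tsv")),
                           stage = "temporal", seed = seed, cfg_hash = hash)
    }
  }
  invisible(out)
}

#' Similarity-network analysis vs random repertoires
#'
#' Per patient and subset (first visit): the merged left/right joint
#' network, its top-cluster statistics, and the comparison against
#' `cfg$n_random` size-matched random repertoire pairs. The patient network
#' depends only on the data; only the random comparison consumes the seed.
#'
#' @inheritParams run_spatial
#' @param cfg a [network_config()] (its seed is re-derived from `seed`).
#' @return A list with per-(patient, subset) elements: `network`, `stats`,
#'   `comparison`.
#' @export
run_network <- function(cohort, out_dir = NULL, model = toy_recomb_model(),
                        seed = 1L, cfg = network_config(), visit = 1L) {
  cohort <- as_cohort(cohort)
  meta <- cohort_meta(cohort)
  meta <- meta[meta$visit == visit, , drop = FALSE]
  hash <- config_hash(list(seed = seed, k = cfg$k, tau = cfg$tau,
                           n_random = cfg$n_random))
  out <- list()
  comp_rows <- list()
  stat_rows <- list()
  for (key in unique(paste(meta$patient, meta$subset, sep = "_"))) {
    ids <- meta$id[paste(meta$patient, meta$subset, sep = "_") == key]
    reps <- lapply(cohort[ids], collapse_by_junction_aa)
    comp <- vapply(reps, function(r) r$compartment, character(1))
    if (!all(c("SF_LEFT", "SF_RIGHT") %in% comp)) {
      tcr_log("network", "skipping %s: need SF_LEFT and SF_RIGHT", key)
      next
    }
    L <- reps[[which(comp == "SF_LEFT")[1]]]
    R <- reps[[which(comp == "SF_RIGHT")[1]]]
    cfg_key <- cfg
    cfg_key$seed <- stage_seed(seed, paste0("network_", key))
    net <- joint_network(L, R, cfg = cfg_key)
    st <- cluster_statistics(net, top_c = cfg_key$top_c)
    sizes <- c(length(productive_junctions(L)), length(productive_junctions(R)))
    cmp <- compare_to_random(st, model, sizes, cfg = cfg_key)
    out[[key]] <- list(network = net, stats = st, comparison = cmp)
    stat_rows[[key]] <- cbind(group = key, st)
    rs <- cmp$random_stats
    comp_rows[[key]] <- data.frame(
      group = key, p_value = cmp$p_value, U = cmp$U,
      patient_median_purity = cmp$patient_median,
      random_median_purity = cmp$random_median,
      direction = cmp$direction, n_random = cfg$n_random,
      stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      export_network(net,
                     path_graphml = file.path(out_dir, paste0("network_", key, ".graphml")),
                     path_edges = file.path(out_dir, paste0("network_", key, "_edges.tsv")))
      write_tsv_provenance(cbind(group = key, rs),
                           file.path(out_dir, paste0("network_", key, "_random_stats.tsv")),
                           stage = "network", seed = seed, cfg_hash = hash)
    }
  }
  if (!is.null(out_dir) && length(stat_rows)) {
    write_tsv_provenance(do.call(rbind, stat_rows),
                         file.path(out_dir, "network_cluster_stats.tsv"),
                         stage = "network", seed = seed, cfg_hash = hash)
    write_tsv_provenance(do.call(rbind, comp_rows),
                         file.path(out_dir, "network_comparison.tsv"),
                         stage = "network", seed = seed, cfg_hash = hash)
  }
  out$summary <- do.call(rbind, comp_rows)
  invisible(out)
}

#' Rarefaction/extrapolation diversity analysis
#'
#' Per-sample richness and Shannon curves on a common log-spaced grid, plus
#' a Treg vs non-Treg comparison at the smallest common sample size.
#'
#' @inheritParams run_spatial
#' @param b_reps Monte-Carlo replicates for Shannon interpolation.
#' @return A list with `curves` (long table) and `comparison`.
#' @export
run_diversity <- function(cohort, out_dir = NULL, seed = 1L, b_reps = 100L) {
  cohort <- as_cohort(cohort)
  hash <- config_hash(list(seed = seed, b_reps = b_reps))
  curves <- list()
  for (id in names(cohort)) {
    av <- abundance_vector(cohort[[id]])
    grid <- unique(round(10^seq(1, log10(2 * av$n), length.out = 12)))
    c0 <- rarefy_richness(av, grid)
    c1 <- rarefy_shannon(av, grid, b_reps = b_reps,
                         seed = stage_seed(seed, paste0("shannon_", id)))
    c0$se <- 0
    curves[[id]] <- cbind(sample_id = id, rbind(c0, c1))
  }
  meta <- cohort_meta(cohort)
  tre <- meta$id[meta$subset == "TREG"]
  non <- meta$id[meta$subset == "NON_TREG"]
  comparison <- NULL
  if (length(tre) >= 2L && length(non) >= 2L) {
    cmpr <- compare_group_diversity(lapply(cohort[tre], abundance_vector),
                                    lapply(cohort[non], abundance_vector),
                                    q = 0, seed = stage_seed(seed, "divcmp"))
    comparison <- data.frame(groupA = "TREG", groupB = "NON_TREG", q = 0,
                             at_m = cmpr$at_m, U = cmpr$U,
                             p_value = cmpr$p_value,
                             median_A = cmpr$medians["A"],
                             median_B = cmpr$medians["B"],
                             stringsAsFactors = FALSE)
  }
  out <- list(curves = do.call(rbind, curves), comparison = comparison)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_provenance(out$curves, file.path(out_dir, "diversity_curves.tsv"),
                         stage = "diversity", seed = seed, cfg_hash = hash)
    if (!is.null(out$comparison))
      write_tsv_provenance(out$comparison,
                           file.path(out_dir, "diversity_comparison.tsv"),
                           stage = "diversity", seed = seed, cfg_hash = hash)
  }
  invisible(out)
}

#' Run the full pipeline on a cohort or sample sheet
#'
#' @inheritParams run_spatial
#' @param analyses subset of `c("spatial", "temporal", "network",
#'   "diversity")`.
#' @param network_cfg a [network_config()].
#' @return Named list of stage outputs.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         analyses = c("spatial", "temporal", "network", "diversity"),
                         model = toy_recomb_model(), seed = 1L,
                         network_cfg = network_config()) {
  cohort <- as_cohort(cohort)
  out <- list()
  t0 <- proc.time()[["elapsed"]]
  for (a in analyses) {
    t1 <- proc.time()[["elapsed"]]
    out[[a]] <- switch(a,
      spatial = run_spatial(cohort, out_dir, model = model, seed = seed),
      temporal = run_temporal(cohort, out_dir, model = model, seed = seed),
      network = run_network(cohort, out_dir, model = model, seed = seed,
                            cfg = network_cfg),
      diversity = run_diversity(cohort, out_dir, seed = seed),
      stop("unknown analysis: ", a, call. = FALSE))
    tcr_log("pipeline", "stage=%s n_samples=%d seed=%d elapsed=%.1fs",
            a, length(cohort), seed, proc.time()[["elapsed"]] - t1)
  }
  tcr_log("pipeline", "total elapsed=%.1fs", proc.time()[["elapsed"]] - t0)
  invisible(out)
}
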