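# Sample-size-based rarefaction and extrapolation of Hill numbers q = 0
# (species richness) and q = 1 (exponential Shannon entropy), for comparing
# repertoire diversity between groups.

#' Abundance vector of a repertoire or count vector
#'
#' @param x a `tcr_repertoire` or a vector of positive clonotype counts.
#' @return A list with `counts`, `n` (total), `S_obs`, `f1`, `f2`
#'   (singleton/doubleton counts), of class `abundance_vector`.
#' @export
abundance_vector <- function(x) {
  counts <- if (inherits(x, "tcr_repertoire")) x$clonotypes$count else x
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 1L, all(counts >= 1))
  structure(list(counts = counts, n = sum(counts), S_obs = length(counts),
                 f1 = sum(counts == 1), f2 = sum(counts == 2)),
            class = "abundance_vector")
}

# Chao1 estimate of the number of undetected species
chao1_f0 <- function(av) {
  with(av, if (f2 > 0) (n - 1) / n * f1^2 / (2 * f2)
           else (n - 1) / n * f1 * (f1 - 1) / 2)
}

#' Rarefied and extrapolated species richness (Hill q = 0)
#'
#' Interpolation uses the exact hypergeometric expectation
#' `S(m) = S_obs - sum_i C(n - n_i, m) / C(n, m)` (computed on the
#' log-binomial scale for stability); extrapolation beyond the observed
#' total `n` uses the Chao1-based estimator
#' `S(n + m*) = S_obs + f0 * (1 - (1 - f1 / (n f0 + f1))^m*)`.
#'
#' @param av an `abundance_vector` (or object coercible via
#'   [abundance_vector()]).
#' @param m_grid positive integer sample sizes (may exceed `n`).
#' @return A `diversity_curve` data.frame with columns `q`, `m`, `regime`
#'   (`INT`/`OBS`/`EXT`) and `estimate`.
#' @export
#' @examples
#' rarefy_richness(abundance_vector(c(2, 1)), m_grid = c(1, 2, 3))
rarefy_richness <- function(av, m_grid) {
  if (!inherits(av, "abundance_vector")) av <- abundance_vector(av)
  if (any(m_grid < 1)) stop("m must be >= 1", call. = FALSE)
  m_grid <- as.numeric(m_grid)
  est <- vapply(m_grid, function(m) {
    if (m < av$n) {
      miss <- exp(lchoose(av$n - av$counts, m) - lchoose(av$n, m))
      av$S_obs - sum(miss)
    } else if (m == av$n) {
      av$S_obs
    } else {
      f0 <- chao1_f0(av)
      if (f0 <= 0 || av$f1 == 0) av$S_obs
      else av$S_obs + f0 * (1 - (1 - av$f1 / (av$n * f0 + av$f1))^(m - av$n))
    }
  }, numeric(1))
  regime <- ifelse(m_grid < av$n, "INT", ifelse(m_grid == av$n, "OBS", "EXT"))
  structure(data.frame(q = 0, m = m_grid, regime = regime, estimate = est,
                       stringsAsFactors = FALSE),
            class = c("diversity_curve", "data.frame"))
}

shannon_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Rarefied Shannon diversity (Hill q = 1)
#'
#' Interpolation at subsample size `m < n` is `exp(E[H_m])`, the exponential
#' of the expected Shannon entropy of a size-`m` hypergeometric subsample,
#' estimated by `b_reps` seeded Monte-Carlo subsamples. At `m = n` it equals
#' the plug-in value `exp(H)` exactly. Beyond `n` the asymptotic Chao-Shen
#' style entropy estimate is returned as a constant plateau flagged `EXT`
#' (group comparisons, not extrapolated magnitudes, are the intended use).
#'
#' @inheritParams rarefy_richness
#' @param b_reps Monte-Carlo subsampling replicates (default 200).
#' @param seed integer seed.
#' @return A `diversity_curve` data.frame (`q = 1`) with an extra `se`
#'   column (Monte-Carlo standard error; 0 where exact).
#' @export
rarefy_shannon <- function(av, m_grid, b_reps = 200L, seed = 1L) {
  if (!inherits(av, "abundance_vector")) av <- abundance_vector(av)
  if (b_reps < 1) stop("b_reps must be >= 1", call. = FALSE)
  if (any(m_grid < 1)) stop("m must be >= 1", call. = FALSE)
  reads <- rep.int(seq_along(av$counts), times = av$counts)
  res <- with_seed(seed, lapply(as.numeric(m_grid), function(m) {
    if (m >= av$n) {
      h <- asymptotic_entropy(av)
      if (m == av$n) h <- shannon_entropy(av$counts)
      return(c(est = exp(h), se = 0))
    }
    hs <- vapply(seq_len(b_reps), function(i)
      shannon_entropy(tabulate(sample(reads, m))), numeric(1))
    c(est = exp(mean(hs)), se = exp(mean(hs)) * stats::sd(hs) / sqrt(b_reps))
  }))
  est <- vapply(res, `[[`, numeric(1), "est")
  se <- vapply(res, `[[`, numeric(1), "se")
  regime <- ifelse(m_grid < av$n, "INT", ifelse(m_grid == av$n, "OBS", "EXT"))
  structure(data.frame(q = 1, m = as.numeric(m_grid), regime = regime,
                       estimate = est, se = se, stringsAsFactors = FALSE),
            class = c("diversity_curve", "data.frame"))
}

# Chao-Shen coverage-adjusted entropy (asymptotic plateau for q = 1
# extrapolation)
asymptotic_entropy <- function(av) {
  n <- av$n
  C_hat <- 1 - av$f1 / n
  if (C_hat <= 0) return(shannon_entropy(av$counts))
  p <- C_hat * av$counts / n
  -sum(p * log(p) / (1 - (1 - p)^n))
}

#' @export
plot.diversity_curve <- function(x, ...) {
  int <- x[x$regime != "EXT", ]
  ext <- x[x$regime == "EXT", ]
  plot(int$m, int$estimate, type = "l", xlab = "sample size m",
       ylab = sprintf("Hill number q=%g", x$q[1]),
       xlim = range(x$m), ylim = range(x$estimate), ...)
  if (nrow(ext)) lines(ext$m, ext$estimate, lty = 2)
  invisible(x)
}

#' Compare diversity between two groups at a common sample size
#'
#' Computes each sample's rarefied estimate at a common size `at_m`
#' (default: the smallest observed total across samples) and applies a
#' two-sided Mann-Whitney test between groups.
#'
#' @param groupA,groupB lists of `abundance_vector` (or count vectors /
#'   repertoires).
#' @param q Hill order, 0 or 1.
#' @param at_m common sample size; default `min` of all totals.
#' @param b_reps,seed Monte-Carlo controls for q = 1.
#' @return A list with `U`, `p_value`, `medians` (per group), `at_m`,
#'   `estimates`, and `flag` (`"small-group"` when a group has < 2 samples).
#' @export
compare_group_diversity <- function(groupA, groupB, q = 0, at_m = NULL,
                                    b_reps = 200L, seed = 1L) {
  avsA <- lapply(groupA, function(g)
    if (inherits(g, "abundance_vector")) g else abundance_vector(g))
  avsB <- lapply(groupB, function(g)
    if (inherits(g, "abundance_vector")) g else abundance_vector(g))
  at_m <- at_m %||% min(vapply(c(avsA, avsB), `[[`, numeric(1), "n"))
  est_at <- function(av, i) {
    if (q == 0) rarefy_richness(av, at_m)$estimate
    else rarefy_shannon(av, at_m, b_reps = b_reps,
                        seed = stage_seed(seed, paste0("div", i)))$estimate
  }
  eA <- vapply(seq_along(avsA), function(i) est_at(avsA[[i]], i), numeric(1))
  eB <- vapply(seq_along(avsB), function(i) est_at(avsB[[i]], i + 1000L),
               numeric(1))
  flag <- if (length(eA) < 2L || length(eB) < 2L) "small-group" else "ok"
  mw <- mann_whitney_u(eA, eB)
  list(U = mw$U, p_value = mw$p_value,
       medians = c(A = median(eA), B = median(eB)),
       at_m = at_m, estimates = list(A = eA, B = eB), flag = flag)
}
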