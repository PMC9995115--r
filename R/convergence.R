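# Convergent recombination vs convergent selection: correlate clone
# frequency with generation probability, separately for clones shared
# between two samples and clones private to one. A positive correlation in
# a group indicates frequencies explained by generation probability
# (convergent recombination); absence of correlation among shared
# hyper-expanded clones indicates antigen-driven (convergent) selection.

#' Correlate clone frequency with generation probability per sharing group
#'
#' Rows with `pgen <= 0` are excluded (their number is logged); Spearman's
#' rho is scale-invariant, while the least-squares line (for plotting) is
#' fitted on the configured scale (default log10-log10, pgen on frequency).
#' Groups with fewer than 3 clones are flagged `UNDEFINED` rather than
#' dropped.
#'
#' @param table data.frame with columns `frequency`, `pgen`, and `shared`
#'   (logical: clone present in both samples).
#' @param scale `"LOG10"` (default) or `"LINEAR"` for the regression line.
#' @return data.frame, one row per group (`SHARED`, `NON_SHARED`):
#'   `group`, `n_clones`, `n_pgen_zero`, `rho`, `p_value`, `ci_lo`, `ci_hi`,
#'   `slope`, `intercept`, `flag`.
#' @export
correlate_freq_pgen <- function(table, scale = c("LOG10", "LINEAR")) {
  scale <- match.arg(scale)
  stopifnot(all(c("frequency", "pgen", "shared") %in% names(table)))
  rows <- lapply(c(SHARED = TRUE, NON_SHARED = FALSE), function(is_shared) {
    sub <- table[table$shared == is_shared, , drop = FALSE]
    nz <- sum(sub$pgen <= 0, na.rm = TRUE)
    if (nz > 0)
      tcr_log("convergence", "excluding %d clones with pgen = 0", nz)
    sub <- sub[!is.na(sub$pgen) & sub$pgen > 0, , drop = FALSE]
    n <- nrow(sub)
    if (n < 3L) {
      return(data.frame(n_clones = n, n_pgen_zero = nz, rho = NA_real_,
                        p_value = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, slope = NA_real_,
                        intercept = NA_real_, flag = "UNDEFINED",
                        stringsAsFactors = FALSE))
    }
    sc <- spearman_correlation(sub$frequency, sub$pgen)
    ci <- spearman_ci(sc$rho, sc$n)
    x <- sub$frequency; y <- sub$pgen
    if (scale == "LOG10") { x <- log10(x); y <- log10(y) }
    fit <- coef(lm(y ~ x))
    data.frame(n_clones = n, n_pgen_zero = nz, rho = sc$rho,
               p_value = sc$p_value, ci_lo = ci[1], ci_hi = ci[2],
               slope = unname(fit[2]), intercept = unname(fit[1]),
               flag = if (sc$undefined) "UNDEFINED" else "OK",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(group = names(rows), out)
  rownames(out) <- NULL
  out
}

# frequency/pgen/sharing table for one sample pair, pgen memoised via cache
pair_freq_pgen_table <- function(repA, repB, model,
                                 frequency = c("max", "mean", "A"),
                                 pgen_cache = new.env(parent = emptyenv())) {
  frequency <- match.arg(frequency)
  pf <- paired_frequency_table(repA, repB)
  keep <- is_productive_aa(pf$junction_aa)
  pf <- pf[keep, , drop = FALSE]
  freq <- switch(frequency,
                 max = pmax(pf$freqA, pf$freqB),
                 mean = ifelse(pf$n_samples_present == 2,
                               (pf$freqA + pf$freqB) / 2,
                               pmax(pf$freqA, pf$freqB)),
                 A = ifelse(pf$freqA > 0, pf$freqA, pf$freqB))
  todo <- setdiff(pf$junction_aa, ls(pgen_cache))
  if (length(todo)) {
    pg <- pgen_aa(model, todo)
    for (i in seq_along(todo)) assign(todo[i], pg$pgen[i], envir = pgen_cache)
  }
  pgen <- vapply(pf$junction_aa, get, numeric(1), envir = pgen_cache,
                 USE.NAMES = FALSE)
  data.frame(junction_aa = pf$junction_aa, frequency = freq, pgen = pgen,
             shared = pf$n_samples_present == 2, stringsAsFactors = FALSE)
}

#' Frequency vs generation-probability correlations across a cohort
#'
#' For every within-(patient, subset) pair of samples: classify clones as
#' shared/non-shared between the pair, attach amino-acid generation
#' probabilities, and report Spearman correlations for both groups. For
#' shared clones the frequency used is, by default, the clone's maximum
#' frequency across the pair (configurable). Raw p-values are reported with
#' a Benjamini-Hochberg adjusted column.
#'
#' @param cohort named list of `tcr_repertoire` objects.
#' @param model a `recomb_model` for pgen computation.
#' @param frequency `"max"` (default), `"mean"`, or `"A"` (first sample of
#'   the pair).
#' @param scale regression scale, see [correlate_freq_pgen()].
#' @return data.frame with one row per (pair, group): `patient`, `subset`,
#'   `pair`, `group`, `n_clones`, `rho`, `p_value`, `p_adj`, `ci_lo`,
#'   `ci_hi`, `slope`, `intercept`, `flag`.
#' @export
convergence_report <- function(cohort, model, frequency = "max",
                               scale = "LOG10") {
  collapsed <- lapply(cohort, collapse_by_junction_aa)
  meta <- data.frame(
    id = names(collapsed),
    patient = vapply(collapsed, function(r) r$patient, character(1)),
    subset = vapply(collapsed, function(r) r$subset, character(1)),
    stringsAsFactors = FALSE)
  cache <- new.env(parent = emptyenv())
  rows <- list()
  for (grp in split(meta$id, paste(meta$patient, meta$subset))) {
    if (length(grp) < 2L) next
    for (i in seq_len(length(grp) - 1L)) for (j in (i + 1L):length(grp)) {
      a <- collapsed[[grp[i]]]; b <- collapsed[[grp[j]]]
      tab <- pair_freq_pgen_table(a, b, model, frequency = frequency,
                                  pgen_cache = cache)
      res <- correlate_freq_pgen(tab, scale = scale)
      res$patient <- a$patient
      res$subset <- a$subset
      res$pair <- paste(grp[i], grp[j], sep = "|")
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("no within-(patient, subset) sample pairs", call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adj[ok] <- bh_adjust(out$p_value[ok])
  out[, c("patient", "subset", "pair", "group", "n_clones", "n_pgen_zero",
          "rho", "p_value", "p_adj", "ci_lo", "ci_hi", "slope", "intercept",
          "flag")]
}
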