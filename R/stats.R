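# Rank statistics used across analyses: Spearman's rank-order correlation
# (t approximation, exact permutation at small n) and the Mann-Whitney U
# test (tie-corrected normal approximation; exact conditional permutation
# distribution when one group is small).

# all permutations of 1..n (n <= 8 in practice); deterministic order
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                                sub[, pos:(n - 1L), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman's rank-order correlation
#'
#' Computes rho on average ranks (ties averaged). The p-value uses the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))` by
#' default; for `n <= 8` an exact permutation p-value (all `n!` orderings of
#' one variable) is available.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param method `"t"` (default) or `"exact"` (only for `n <= 8`).
#' @return A list with `rho`, `p_value`, `n`, and `undefined` (`TRUE` when a
#'   vector is constant and rho does not exist).
#' @export
#' @examples
#' spearman_correlation(1:5, c(2, 1, 4, 3, 5))$rho
spearman_correlation <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p_value = NA_real_, n = n,
                          undefined = TRUE))
  rho <- spearman_rho(x, y)
  if (is.na(rho)) return(list(rho = NA_real_, p_value = NA_real_, n = n,
                              undefined = TRUE))
  if (method == "exact") {
    if (n > 8L) stop("exact permutation p only for n <= 8", call. = FALSE)
    perms <- permutations_of(n)
    ry <- rank(y, ties.method = "average")
    rx <- rank(x, ties.method = "average")
    rhos <- apply(perms, 1L, function(idx) {
      if (stats::sd(ry[idx]) == 0) return(NA_real_)
      stats::cor(rx, ry[idx])
    })
    p <- mean(abs(rhos) >= abs(rho) - 1e-12, na.rm = TRUE)
  } else {
    # continuity-corrected t approximation: the permutation distribution of
    # rho lives on a lattice with spacing 12/(n(n^2-1)); shifting |rho| by
    # half a step approximates the inclusive tail P(|rho*| >= |rho|),
    # which the raw t statistic systematically undershoots at small n
    r_adj <- max(abs(rho) - 6 / (n * (n^2 - 1)), 0)
    tt <- r_adj * sqrt((n - 2) / max(1 - r_adj^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = min(p, 1), n = n, undefined = FALSE)
}

# Exact null distribution of the group-A rank sum over all C(N, nA) subsets
# of the pooled (average, possibly tied) ranks, by subset-sum dynamic
# programming. Ranks are doubled so tied average ranks stay on an integer
# grid. Returns P(2*RA = s) indexed by s.
ranksum_distribution <- function(ranks2, nA) {
  N <- length(ranks2)
  maxs <- sum(sort(ranks2, decreasing = TRUE)[seq_len(nA)])
  # f[[j]][s+1] = number of j-subsets with doubled rank sum s
  f <- vector("list", nA + 1L)
  f[[1L]] <- c(1, rep(0, maxs))
  for (j in seq_len(nA)) f[[j + 1L]] <- rep(0, maxs + 1L)
  for (r in ranks2) {
    for (j in rev(seq_len(nA))) {
      shifted <- c(rep(0, r), f[[j]][seq_len(maxs + 1L - r)])
      f[[j + 1L]] <- f[[j + 1L]] + shifted
    }
  }
  f[[nA + 1L]] / choose(N, nA)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums on the pooled sample with average ranks for
#' ties. When `min(nA, nB) <= 8` the two-sided p-value is exact: the full
#' conditional permutation distribution of U given the observed (tied)
#' values is computed by dynamic programming, which is identical to
#' enumerating all `choose(nA+nB, nA)` group assignments. Otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' Two-sided p is the probability of a U at least as far from its null mean
#' as observed.
#'
#' @param a,b numeric vectors (non-empty).
#' @return A list with `U` (for group `a`), `p_value`, `method`
#'   (`"exact"`/`"normal"`), and `all_tied` flag (p forced to 1).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  nA <- length(a); nB <- length(b)
  stopifnot(nA >= 1, nB >= 1)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(U = nA * nB / 2, p_value = 1, method = "degenerate",
                all_tied = TRUE))
  rk <- rank(pooled, ties.method = "average")
  RA <- sum(rk[seq_len(nA)])
  U <- RA - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  if (min(nA, nB) <= 8L) {
    # order-swap so the DP tracks the smaller group
    if (nA <= nB) { ranks2 <- round(2 * rk); k <- nA; R2 <- round(2 * RA) }
    else { ranks2 <- round(2 * rk); k <- nB; R2 <- round(2 * sum(rk[nA + seq_len(nB)])) }
    dist <- ranksum_distribution(ranks2, k)
    s <- seq_along(dist) - 1L
    # U for the tracked group, on the doubled scale
    U2 <- s - k * (k + 1)          # 2*U = 2*R - k(k+1)
    U2obs <- R2 - k * (k + 1)
    d <- abs(U2obs - k * (length(ranks2) - k))  # distance from 2*mu
    p <- sum(dist[abs(U2 - k * (length(ranks2) - k)) >= d - 1e-9])
    method <- "exact"
  } else {
    N <- nA + nB
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- nA * nB / 12 * ((N + 1) - tie_term)
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-max(z, 0))
    method <- "normal"
  }
  list(U = U, p_value = min(p, 1), method = method, all_tied = FALSE)
}

# Fisher-z confidence interval for Spearman's rho (Fieller variance 1.06/(n-3))
spearman_ci <- function(rho, n, level = 0.95) {
  if (is.na(rho) || n <= 3L) return(c(NA_real_, NA_real_))
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- sqrt(1.06 / (n - 3))
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

# Benjamini-Hochberg adjustment (thin wrapper; kept for a stable interface)
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
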