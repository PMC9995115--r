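# Clone-sharing statistics across compartments and visits. All operations
# expect repertoires collapsed to amino-acid junction clonotypes
# (collapse_by_junction_aa); they operate on presence/absence of junctions
# unless stated otherwise.

junction_set <- function(rep) unique(rep$clonotypes$junction_aa)

assert_collapsed <- function(rep) {
  if (anyDuplicated(rep$clonotypes$junction_aa))
    stop("repertoire must be collapsed by junction_aa first", call. = FALSE)
  invisible(rep)
}

#' Clonal proportions by expansion bin
#'
#' For each clone-size bin, the fraction of the repertoire's total template
#' count carried by clonotypes whose count falls in the bin. Default bins:
#' 1, 2-9, 10-99, >= 100.
#'
#' @param rep a `tcr_repertoire`.
#' @param bin_edges increasing lower bin edges (first must be 1).
#' @return data.frame with `bin` labels and `proportion` (sums to 1).
#' @export
clonal_proportion_summary <- function(rep, bin_edges = c(1, 2, 10, 100)) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (is.unsorted(bin_edges, strictly = TRUE) || bin_edges[1] != 1)
    stop("bin_edges must be strictly increasing and start at 1", call. = FALSE)
  cl <- rep$clonotypes
  labels <- c(
    ifelse(bin_edges[-length(bin_edges)] == bin_edges[-1] - 1,
           as.character(bin_edges[-length(bin_edges)]),
           paste0(bin_edges[-length(bin_edges)], "-", bin_edges[-1] - 1)),
    paste0(">=", bin_edges[length(bin_edges)]))
  idx <- findInterval(cl$count, bin_edges)
  mass <- vapply(seq_along(labels),
                 function(b) sum(cl$count[idx == b]), numeric(1))
  data.frame(bin = labels, proportion = mass / sum(cl$count),
             stringsAsFactors = FALSE)
}

# top-n junctions: counts descending, ties broken lexicographically
top_n_junctions <- function(rep, n) {
  cl <- rep$clonotypes
  o <- order(-cl$count, cl$junction_aa, method = "radix")
  cl$junction_aa[o][seq_len(n)]
}

#' Sequential top-N intersection between two repertoires
#'
#' For each n in `n_grid`, the percentage of the top-n clonotypes (ranked
#' by count, ties broken lexicographically) shared between the two samples:
#' `100 * |top_n(A) intersect top_n(B)| / n`. Values of n exceeding either
#' repertoire are dropped with a warning.
#'
#' @param repA,repB collapsed `tcr_repertoire` objects.
#' @param n_grid increasing integer vector (default: log-spaced 1..1000).
#' @return data.frame with columns `n` and `percent_overlap`.
#' @export
top_n_intersection <- function(repA, repB,
                               n_grid = unique(round(10^seq(0, 3, by = 0.1)))) {
  assert_collapsed(repA); assert_collapsed(repB)
  lim <- min(nrow(repA$clonotypes), nrow(repB$clonotypes))
  drop <- n_grid > lim
  if (any(drop)) {
    warning(sprintf("dropping %d n values above min repertoire size %d",
                    sum(drop), lim))
    n_grid <- n_grid[!drop]
  }
  pct <- vapply(n_grid, function(n) {
    100 * length(intersect(top_n_junctions(repA, n), top_n_junctions(repB, n))) / n
  }, numeric(1))
  data.frame(n = n_grid, percent_overlap = pct)
}

#' Jaccard overlap matrix over repertoires
#'
#' `J(A, B) = |A intersect B| / |A union B|` over unique amino-acid junction
#' sets (presence/absence, unweighted).
#'
#' @param reps list of >= 2 collapsed `tcr_repertoire` objects.
#' @return Symmetric matrix with unit diagonal, dimnames = sample ids.
#' @export
jaccard_matrix <- function(reps) {
  stopifnot(length(reps) >= 2L)
  for (r in reps) {
    assert_collapsed(r)
    if (nrow(r$clonotypes) == 0L)
      stop("empty repertoire: ", r$sample_id, call. = FALSE)
  }
  sets <- lapply(reps, junction_set)
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    m[i, j] <- m[j, i] <- inter / (length(sets[[i]]) + length(sets[[j]]) - inter)
  }
  m
}

#' Sharing class of every clonotype across samples
#'
#' Labels each junction in the union with the number of samples containing
#' it (e.g. private = 1, shared in two, shared in all three of PB, SF-left,
#' SF-right).
#'
#' @param reps list of collapsed `tcr_repertoire` objects (2-3 samples from
#'   one patient/subset in the motivating design, but any number works).
#' @return data.frame with `junction_aa` and `n_samples_present`.
#' @export
classify_sharing <- function(reps) {
  for (r in reps) assert_collapsed(r)
  tab <- table(unlist(lapply(reps, junction_set)))
  data.frame(junction_aa = names(tab),
             n_samples_present = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired clone frequencies between two samples
#'
#' Union of junctions with each sample's frequency (0 when absent) and the
#' sharing class over the supplied context samples; the basis for paired
#' frequency scatter plots.
#'
#' @param repA,repB collapsed `tcr_repertoire` objects.
#' @param context optional larger list of repertoires over which the sharing
#'   class is computed (defaults to the pair itself).
#' @return data.frame with `junction_aa`, `freqA`, `freqB`,
#'   `n_samples_present`.
#' @export
paired_frequency_table <- function(repA, repB, context = list(repA, repB)) {
  assert_collapsed(repA); assert_collapsed(repB)
  keys <- sort(union(junction_set(repA), junction_set(repB)))
  fA <- setNames(repA$clonotypes$frequency, repA$clonotypes$junction_aa)
  fB <- setNames(repB$clonotypes$frequency, repB$clonotypes$junction_aa)
  cls <- classify_sharing(context)
  out <- data.frame(junction_aa = keys,
                    freqA = unname(ifelse(keys %in% names(fA), fA[keys], 0)),
                    freqB = unname(ifelse(keys %in% names(fB), fB[keys], 0)),
                    stringsAsFactors = FALSE)
  out$n_samples_present <- cls$n_samples_present[match(keys, cls$junction_aa)]
  out
}

#' Venn region counts over top-N clonotype sets
#'
#' Counts every intersection region of the top-N (default 100) most abundant
#' unique clonotypes of 2-4 repertoires. Region counts sum to the size of
#' the union of the top-N sets. Repertoires smaller than `top_n` contribute
#' all their clonotypes (with a note).
#'
#' @param reps list of 2-4 collapsed `tcr_repertoire` objects.
#' @param top_n clonotypes per sample (default 100).
#' @return Named integer vector; names are `&`-joined sample-id
#'   combinations, e.g. `"s1"`, `"s1&s2"`.
#' @export
venn_counts <- function(reps, top_n = 100L) {
  stopifnot(length(reps) >= 2L, length(reps) <= 4L)
  for (r in reps) assert_collapsed(r)
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  tops <- lapply(reps, function(r) {
    n <- nrow(r$clonotypes)
    if (n < top_n)
      tcr_log("venn", "sample %s has %d < %d clonotypes; using all",
              r$sample_id, n, top_n)
    top_n_junctions(r, min(n, top_n))
  })
  keys <- unique(unlist(tops))
  member <- vapply(tops, function(s) keys %in% s, logical(length(keys)))
  if (length(keys) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(row) paste(ids[row], collapse = "&"))
  regions <- unlist(lapply(seq_along(ids), function(k)
    combn(ids, k, paste, collapse = "&")))
  counts <- table(factor(pattern, levels = regions))
  out <- as.integer(counts)
  names(out) <- regions
  out
}
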