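# Clonotype tables in and out; the clonotype identity conventions used by
# every downstream stage. A clonotype is identified at ingestion by
# (junction_aa, v_call, j_call); all cross-sample comparisons first collapse
# to the amino-acid junction alone.

COMPARTMENTS <- c("SF_LEFT", "SF_RIGHT", "PB")
SUBSETS <- c("TREG", "NON_TREG")

# Accepted column dialects: AIRR Rearrangement names and the short dialect
# produced by common clonotype callers. A custom mapping can be supplied.
DIALECT_AIRR <- c(junction_aa = "junction_aa", v_call = "v_call",
                  j_call = "j_call", count = "duplicate_count")
DIALECT_SIMPLE <- c(junction_aa = "cdr3aa", v_call = "v", j_call = "j",
                    count = "count")

#' Construct a TCR repertoire
#'
#' A repertoire is a labeled collection of clonotypes for one
#' (patient, compartment, subset, visit) sample. Rows with an identical
#' clonotype key `(junction_aa, v_call, j_call)` are merged by summing
#' counts; frequencies are always recomputed from counts.
#'
#' @param clonotypes data.frame with columns `junction_aa`, `count` and
#'   optionally `v_call`, `j_call`.
#' @param sample_id,patient sample identifiers.
#' @param compartment one of `"SF_LEFT"`, `"SF_RIGHT"`, `"PB"`.
#' @param subset one of `"TREG"`, `"NON_TREG"`.
#' @param visit non-negative integer visit index.
#' @return An object of class `tcr_repertoire`.
#' @export
tcr_repertoire <- function(clonotypes, sample_id = "sample",
                           patient = "patient", compartment = "SF_LEFT",
                           subset = "TREG", visit = 0L) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  subset <- match.arg(subset, SUBSETS)
  stopifnot(visit >= 0)
  cl <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  if (!all(c("junction_aa", "count") %in% names(cl)))
    stop("clonotypes need columns junction_aa and count", call. = FALSE)
  if (nrow(cl) == 0L) stop("empty clonotype table", call. = FALSE)
  if (is.null(cl$v_call)) cl$v_call <- NA_character_
  if (is.null(cl$j_call)) cl$j_call <- NA_character_
  bad <- which(is.na(cl$count) | cl$count < 1)
  if (length(bad))
    stop(sprintf("non-positive count in row %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (any(is.na(cl$junction_aa) | !nzchar(cl$junction_aa)))
    stop("empty junction_aa", call. = FALSE)
  key <- paste(cl$junction_aa, cl$v_call, cl$j_call, sep = "\r")
  agg <- rowsum(as.numeric(cl$count), group = key, reorder = FALSE)
  first <- !duplicated(key)
  cl <- cl[first, c("junction_aa", "v_call", "j_call"), drop = FALSE]
  cl$count <- as.numeric(agg[match(key[first], rownames(agg)), 1L])
  # deterministic order: count desc, then junction/v/j lexicographic
  o <- order(-cl$count, cl$junction_aa, cl$v_call, cl$j_call,
             method = "radix", na.last = TRUE)
  cl <- cl[o, , drop = FALSE]
  cl$frequency <- cl$count / sum(cl$count)
  rownames(cl) <- NULL
  structure(list(sample_id = sample_id, patient = patient,
                 compartment = compartment, subset = subset,
                 visit = as.integer(visit), clonotypes = cl),
            class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire %s (patient %s, %s, %s, visit %d): %d clonotypes, %d templates\n",
              x$sample_id, x$patient, x$compartment, x$subset, x$visit,
              nrow(x$clonotypes), round(total_count(x))))
  invisible(x)
}

#' @export
summary.tcr_repertoire <- function(object, ...) {
  cl <- object$clonotypes
  out <- list(sample_id = object$sample_id, n_clonotypes = nrow(cl),
              total_count = total_count(object),
              top_frequency = max(cl$frequency),
              singletons = sum(cl$count == 1))
  class(out) <- "summary.tcr_repertoire"
  out
}

#' @export
print.summary.tcr_repertoire <- function(x, ...) {
  cat(sprintf("%s: %d clonotypes / %d templates; top clone %.4f; %d singletons\n",
              x$sample_id, x$n_clonotypes, round(x$total_count),
              x$top_frequency, x$singletons))
  invisible(x)
}

#' Total template count of a repertoire
#' @param rep a `tcr_repertoire`.
#' @return Numeric scalar.
#' @export
total_count <- function(rep) sum(rep$clonotypes$count)

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype table (UTF-8, header row). Column names
#' follow either the AIRR Rearrangement dialect (`junction_aa`, `v_call`,
#' `j_call`, `duplicate_count`) or a short dialect (`cdr3aa`, `v`, `j`,
#' `count`); a custom header mapping may be supplied. Frequencies are always
#' recomputed from counts, duplicate clonotype keys merged, and the result
#' does not depend on input row order.
#'
#' @param path file path.
#' @param sample_id,patient,compartment,subset,visit sample annotations (see
#'   [tcr_repertoire()]).
#' @param dialect named character vector mapping canonical names
#'   (`junction_aa`, `v_call`, `j_call`, `count`) to file column names, or
#'   `NULL` to auto-detect the two built-in dialects.
#' @return A `tcr_repertoire`.
#' @export
read_clonotype_table <- function(path, sample_id = basename(path),
                                 patient = "patient",
                                 compartment = "SF_LEFT", subset = "TREG",
                                 visit = 0L, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  if (is.null(dialect)) {
    dialect <- if (DIALECT_AIRR[["junction_aa"]] %in% names(tab)) DIALECT_AIRR
               else DIALECT_SIMPLE
  }
  for (canon in c("junction_aa", "count")) {
    if (!dialect[[canon]] %in% names(tab))
      stop(sprintf("missing required column '%s' in %s", dialect[[canon]], path),
           call. = FALSE)
  }
  cl <- data.frame(junction_aa = toupper(tab[[dialect[["junction_aa"]]]]),
                   count = tab[[dialect[["count"]]]],
                   stringsAsFactors = FALSE)
  for (opt in c("v_call", "j_call")) {
    col <- dialect[[opt]]
    cl[[opt]] <- if (!is.null(col) && col %in% names(tab)) as.character(tab[[col]])
                 else NA_character_
  }
  if (nrow(cl) == 0L) stop("empty clonotype table: ", path, call. = FALSE)
  tcr_repertoire(cl, sample_id = sample_id, patient = patient,
                 compartment = compartment, subset = subset, visit = visit)
}

#' Collapse a repertoire to amino-acid junction clonotypes
#'
#' Merges clonotypes sharing the same amino-acid junction (counts summed)
#' and drops V/J calls from the clonotype key. All cross-sample comparisons
#' in the package operate on repertoires collapsed this way, because clone
#' sharing is defined on the amino-acid sequence. Idempotent; total count is
#' conserved.
#'
#' @param rep a `tcr_repertoire`.
#' @return A `tcr_repertoire` keyed by `junction_aa` alone.
#' @export
collapse_by_junction_aa <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes
  agg <- rowsum(cl$count, group = cl$junction_aa)
  out <- data.frame(junction_aa = rownames(agg), count = agg[, 1L],
                    stringsAsFactors = FALSE)
  tcr_repertoire(out, sample_id = rep$sample_id, patient = rep$patient,
                 compartment = rep$compartment, subset = rep$subset,
                 visit = rep$visit)
}

#' Write a clonotype table
#'
#' Writes AIRR-style columns (`junction_aa`, `v_call`, `j_call`,
#' `duplicate_count`); a read of the written file reproduces the clonotype
#' key/count multiset exactly.
#'
#' @param rep a `tcr_repertoire`.
#' @param path output file path (directory must exist).
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  out <- data.frame(junction_aa = rep$clonotypes$junction_aa,
                    v_call = rep$clonotypes$v_call,
                    j_call = rep$clonotypes$j_call,
                    duplicate_count = round(rep$clonotypes$count),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a sample sheet and its clonotype tables
#'
#' The manifest is tab-separated with columns `sample_id`, `patient`,
#' `compartment`, `subset`, `visit`, `path` (paths relative to the manifest's
#' directory or absolute).
#'
#' @param path manifest path.
#' @return A named list of `tcr_repertoire` objects (a cohort).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  sheet <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "patient", "compartment", "subset", "visit", "path")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  base <- dirname(path)
  reps <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$path[i]
    if (!file.exists(p)) p <- file.path(base, sheet$path[i])
    read_clonotype_table(p, sample_id = sheet$sample_id[i],
                         patient = as.character(sheet$patient[i]),
                         compartment = sheet$compartment[i],
                         subset = sheet$subset[i], visit = sheet$visit[i])
  })
  names(reps) <- sheet$sample_id
  reps
}

#' Write a cohort as clonotype tables plus a sample sheet
#'
#' @param cohort named list of `tcr_repertoire` objects.
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(r) {
    fn <- paste0(r$sample_id, ".tsv")
    write_clonotype_table(r, file.path(dir, fn))
    data.frame(sample_id = r$sample_id, patient = r$patient,
               compartment = r$compartment, subset = r$subset,
               visit = r$visit, path = fn, stringsAsFactors = FALSE)
  })
  sheet <- do.call(rbind, rows)
  manifest <- file.path(dir, "samples.tsv")
  write.table(sheet, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# junction strings usable in pgen / network stages: productive, unambiguous
productive_junctions <- function(rep) {
  j <- rep$clonotypes$junction_aa
  j[is_productive_aa(j)]
}
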