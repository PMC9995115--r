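# k-mer based CDR3 similarity networks: two junctions are connected when
# they share at least tau distinct amino-acid k-mers (defaults k = 3,
# tau = 8, independent of sequence length). Clusters are connected
# components; patient networks are benchmarked against generative-model
# random repertoires of matched size.

#' Network configuration
#'
#' @param k k-mer length (default 3).
#' @param tau minimum number of shared distinct k-mers for an edge
#'   (default 8).
#' @param n_random number of random repertoire replicates in comparisons
#'   (default 100).
#' @param top_c number of largest clusters ranked for statistics
#'   (default 5).
#' @param seed integer seed.
#' @param trim_anchors residues to trim from each junction end before
#'   k-merisation (default 0; the conserved C/F anchors are kept).
#' @return A list of class `network_config`.
#' @export
network_config <- function(k = 3L, tau = 8L, n_random = 100L, top_c = 5L,
                           seed = 1L, trim_anchors = 0L) {
  stopifnot(k >= 1, tau >= 1, n_random >= 1, top_c >= 1, trim_anchors >= 0)
  structure(list(k = as.integer(k), tau = as.integer(tau),
                 n_random = as.integer(n_random), top_c = as.integer(top_c),
                 seed = as.integer(seed), trim_anchors = as.integer(trim_anchors)),
            class = "network_config")
}

#' Distinct k-mers of a sequence
#'
#' The set of distinct length-`k` substrings (presence, not multiplicity).
#' Sequences shorter than `k` yield an empty set with a logged note.
#'
#' @param seq amino-acid string.
#' @param k k-mer length.
#' @return Character vector of distinct k-mers.
#' @export
#' @examples
#' kmer_set("CASSL", 3)  # CAS, ASS, SSL
kmer_set <- function(seq, k = 3L) {
  L <- nchar(seq)
  if (L < k) {
    tcr_log("kmer", "sequence of length %d < k = %d: empty k-mer set", L, k)
    return(character(0))
  }
  unique(substring(seq, seq_len(L - k + 1L), k:L))
}

#' Number of distinct k-mers shared by two sequences
#'
#' @param a,b amino-acid strings.
#' @param k k-mer length (default 3).
#' @return Integer count `|kmer_set(a) intersect kmer_set(b)|`.
#' @export
#' @examples
#' shared_kmer_count("CASSLSGTGELFF", "CASSLSGTGELFY")  # 10
shared_kmer_count <- function(a, b, k = 3L) {
  if (nchar(a) < k || nchar(b) < k) return(0L)
  shared_kmer_count_cpp(toupper(a), toupper(b), as.integer(k))
}

#' Build a k-mer similarity network
#'
#' Nodes are unique amino-acid junctions; each carries an origin label set
#' (e.g. LEFT, RIGHT; a junction found in both is labeled SHARED). An edge
#' joins two junctions sharing at least `tau` distinct k-mers. Clusters are
#' connected components with deterministic ids (decreasing size, ties by
#' lexicographically smallest member).
#'
#' @param sequences character vector of junctions (deduplicated internally).
#' @param labels origin label per sequence (same length); duplicated
#'   junctions with different labels become one SHARED node.
#' @param cfg a [network_config()].
#' @return A list of class `tcr_network` with `nodes` (data.frame:
#'   `junction_aa`, `label`, `cluster`), `edges` (data.frame `from`, `to`,
#'   by junction), and `cfg`.
#' @export
build_network <- function(sequences, labels = rep("LEFT", length(sequences)),
                          cfg = network_config()) {
  stopifnot(length(sequences) == length(labels))
  if (length(sequences) == 0L) {
    nodes <- data.frame(junction_aa = character(), label = character(),
                        cluster = integer(), stringsAsFactors = FALSE)
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes, edges = edges, cfg = cfg),
                     class = "tcr_network"))
  }
  sequences <- toupper(sequences)
  if (cfg$trim_anchors > 0L) {
    t <- cfg$trim_anchors
    keep <- nchar(sequences) > 2L * t
    sequences <- sequences[keep]; labels <- labels[keep]
    sequences <- substr(sequences, 1L + t, nchar(sequences) - t)
  }
  lab_by_seq <- vapply(split(labels, sequences), function(l) {
    u <- unique(l)
    if (length(u) > 1L) "SHARED" else u
  }, character(1))
  seqs <- sort(names(lab_by_seq))
  labs <- unname(lab_by_seq[seqs])
  em <- kmer_edges_cpp(seqs, cfg$k, cfg$tau)
  # connected components via union-find-free igraph call
  g <- igraph::graph_from_data_frame(
    data.frame(from = seqs[em[, 1]], to = seqs[em[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = seqs, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[seqs]
  # deterministic cluster ids: size desc, tie by lexicographic min member
  sizes <- table(comp)
  minmem <- vapply(split(seqs, comp), min, character(1))
  o <- order(-as.integer(sizes[names(minmem)]), minmem)
  remap <- setNames(seq_along(o), names(minmem)[o])
  nodes <- data.frame(junction_aa = seqs, label = labs,
                      cluster = unname(remap[as.character(comp)]),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = seqs[em[, 1]], to = seqs[em[, 2]],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, cfg = cfg),
            class = "tcr_network")
}

#' @export
print.tcr_network <- function(x, ...) {
  cat(sprintf("TCR similarity network: %d nodes, %d edges, %d clusters (k=%d, tau=%d)\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$cluster)), x$cfg$k, x$cfg$tau))
  invisible(x)
}

#' Per-cluster statistics
#'
#' Clusters are ranked by node count (decreasing, ties by id); for each of
#' the `top_c` largest the node count, within-cluster edge count, and purity
#' are reported. Purity (default, `purity = "label"`) is the share of the
#' most common origin label among the cluster's nodes, with SHARED counted
#' as its own label. `purity = "abundance"` instead uses the largest clone
#' count share (requires a `count` attribute on nodes; nodes are unique
#' sequences, so without counts this reading degenerates to `1/n`).
#'
#' @param net a `tcr_network`.
#' @param top_c number of clusters (default from the network's config).
#' @param purity `"label"` (default) or `"abundance"`.
#' @param counts optional named vector junction -> clone count for
#'   `purity = "abundance"`.
#' @return data.frame with `cluster`, `n_sequences`, `n_connections`,
#'   `purity`.
#' @export
cluster_statistics <- function(net, top_c = net$cfg$top_c,
                               purity = c("label", "abundance"),
                               counts = NULL) {
  purity <- match.arg(purity)
  ids <- sort(unique(net$nodes$cluster))
  if (length(ids) < top_c)
    tcr_log("network", "only %d clusters available (top_c = %d)",
            length(ids), top_c)
  ids <- ids[seq_len(min(top_c, length(ids)))]
  cl_of <- setNames(net$nodes$cluster, net$nodes$junction_aa)
  edge_cl <- cl_of[net$edges$from]
  rows <- lapply(ids, function(id) {
    members <- net$nodes[net$nodes$cluster == id, ]
    pur <- if (purity == "label") {
      max(table(members$label)) / nrow(members)
    } else if (!is.null(counts)) {
      cc <- counts[members$junction_aa]
      cc[is.na(cc)] <- 1
      max(cc) / sum(cc)
    } else 1 / nrow(members)
    data.frame(cluster = id, n_sequences = nrow(members),
               n_connections = sum(edge_cl == id), purity = pur)
  })
  do.call(rbind, rows)
}

#' Build the merged left/right joint network for one patient
#'
#' Junctions from the two samples are deduplicated; a junction present in
#' both is a single node labeled SHARED.
#'
#' @param repL,repR collapsed `tcr_repertoire` objects (left/right joint).
#' @param cfg a [network_config()].
#' @return A `tcr_network`.
#' @export
joint_network <- function(repL, repR, cfg = network_config()) {
  sl <- productive_junctions(repL)
  sr <- productive_junctions(repR)
  build_network(c(sl, sr), c(rep("LEFT", length(sl)), rep("RIGHT", length(sr))),
                cfg = cfg)
}

#' Compare patient cluster purity against random repertoires
#'
#' Generates `n_random` pairs of size-matched random repertoires from the
#' recombination model (productive-only, deduplicated to unique sequences,
#' matching the patient sample sizes), builds each pair's merged network,
#' and collects top-`top_c` cluster purities and (size, connections)
#' points. Reports a two-sided Mann-Whitney p for patient vs random
#' purities.
#'
#' @param patient_stats `cluster_statistics()` output for the patient
#'   network.
#' @param model a `recomb_model`.
#' @param sizes integer vector of length 2: unique-junction counts of the
#'   left and right samples.
#' @param cfg a [network_config()]; `cfg$seed` scopes all random draws.
#' @return A list with `p_value`, `U`, `patient_median`, `random_median`,
#'   `direction` (`"patient_lower"` / `"patient_higher"` / `"none"`),
#'   `random_stats` (pooled per-replicate cluster stats), and `exact_caveat`
#'   (TRUE when `n_random` is too small for a stable null, i.e. 1).
#' @export
compare_to_random <- function(patient_stats, model, sizes,
                              cfg = network_config()) {
  stopifnot(length(sizes) == 2L)
  rnd <- lapply(seq_len(cfg$n_random), function(r) {
    repL <- generate_random_repertoire(model, sizes[1],
                                       seed = stage_seed(cfg$seed, paste0("randL", r)))
    repR <- generate_random_repertoire(model, sizes[2],
                                       seed = stage_seed(cfg$seed, paste0("randR", r)))
    net <- joint_network(repL, repR, cfg = cfg)
    st <- cluster_statistics(net, top_c = cfg$top_c)
    st$replicate <- r
    st
  })
  random_stats <- do.call(rbind, rnd)
  mw <- mann_whitney_u(patient_stats$purity, random_stats$purity)
  pm <- median(patient_stats$purity)
  rm_ <- median(random_stats$purity)
  list(p_value = mw$p_value, U = mw$U,
       patient_median = pm, random_median = rm_,
       direction = if (pm < rm_) "patient_lower"
                   else if (pm > rm_) "patient_higher" else "none",
       random_stats = random_stats,
       exact_caveat = cfg$n_random < 2L)
}

#' Export a network as GraphML and edge-list TSV
#'
#' @param net a `tcr_network`.
#' @param path_graphml,path_edges output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the written paths.
#' @export
export_network <- function(net, path_graphml = NULL, path_edges = NULL) {
  if (!is.null(path_edges))
    write.table(net$edges, path_edges, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(c(path_graphml, path_edges))
}
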