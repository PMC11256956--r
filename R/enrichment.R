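#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `overlap` members of a gene set when
#' `foreground_size` genes are sampled without replacement from a universe
#' of `universe_size` genes containing `set_size` set members:
#' `P(X >= overlap)`.
#'
#' @param overlap observed overlap between foreground and set.
#' @param set_size genes of the set inside the universe.
#' @param foreground_size foreground (tail) size.
#' @param universe_size total measured genes.
#' @return The upper-tail p-value.
#' @export
hypergeom_p <- function(overlap, set_size, foreground_size, universe_size) {
  if (set_size > universe_size || foreground_size > universe_size)
    stop("set and foreground must fit inside the universe")
  if (overlap > min(set_size, foreground_size) || overlap < 0)
    stop("impossible overlap count")
  stats::phyper(overlap - 1, set_size, universe_size - set_size,
                foreground_size, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as the
#' package's single named entry point for multiple-testing correction.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Adjusted values (step-up rule).
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Expected false discoveries for an ensemble-wide threshold
#'
#' With `n_nodes` probed nodes each tested against `n_sets` gene sets at a
#' per-test threshold `alpha`, the expected number of false discoveries
#' under the global null is `n_nodes * n_sets * alpha`. At the default
#' threshold of 1e-8 a 5000-node ensemble tested against 1444 sets expects
#' fewer than one false call.
#'
#' @param n_nodes pooled bottleneck nodes.
#' @param n_sets gene sets tested per node.
#' @param alpha per-test threshold.
#' @return Expected count of false discoveries.
#' @export
expected_false_discoveries <- function(n_nodes, n_sets, alpha = 1e-8) {
  n_nodes * n_sets * alpha
}

empty_enrichment <- function() {
  data.frame(network = integer(0), node = integer(0), set = character(0),
             category = character(0),
             direction = character(0), test = character(0),
             p = numeric(0), q = numeric(0), effect = numeric(0),
             stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of one node signature
#'
#' Tests two foregrounds against every gene set: the `top_k` genes with the
#' largest `delta_y` (activating tail) and the `top_k` with the smallest
#' (suppressing tail). p-values from [hypergeom_p()] are BH-adjusted within
#' the node (across all set x tail tests) and results with adjusted value
#' below `threshold` are reported. A set passing in both directions is
#' reported once, with the stronger tail. The stringent default threshold
#' (1e-8) keeps the expected number of false discoveries across a full
#' 5000-node ensemble below one.
#'
#' @param sig a `node_signature`.
#' @param coll a [gene_set_collection()], already restricted to the
#'   compendium's universe and size-filtered.
#' @param top_k tail size (genes per direction).
#' @param threshold cutoff on the BH-adjusted value.
#' @return data.frame: network, node, set, category, direction, test, p,
#'   q, effect (overlap count).
#' @export
enrich_node <- function(sig, coll, top_k = 50L, threshold = 1e-8) {
  stopifnot(inherits(sig, "node_signature"),
            inherits(coll, "gene_set_collection"))
  universe <- coll$universe
  if (is.null(universe)) universe <- names(sig$delta_y)
  N <- length(universe)
  if (top_k > N) stop("top_k exceeds the universe size")
  if (length(coll$sets) == 0L) return(empty_enrichment())

  top <- sig$ranked_genes[seq_len(top_k)]
  bottom <- rev(sig$ranked_genes)[seq_len(top_k)]
  sets <- effective_sets(coll)

  rows <- lapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    m <- length(genes)
    if (m == 0L) return(NULL)
    ov_top <- length(intersect(top, genes))
    ov_bot <- length(intersect(bottom, genes))
    data.frame(set = nm, category = unname(coll$category[nm]),
               direction = c("activating", "suppressing"),
               p = c(hypergeom_p(ov_top, m, top_k, N),
                     hypergeom_p(ov_bot, m, top_k, N)),
               effect = c(ov_top, ov_bot), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res <- res[res$q < threshold, , drop = FALSE]
  if (nrow(res) == 0L) return(empty_enrichment())
  ## one call per set: keep the stronger direction
  res <- res[order(res$set, res$p), , drop = FALSE]
  res <- res[!duplicated(res$set), , drop = FALSE]
  data.frame(network = sig$network_index, node = sig$node_index,
             set = res$set, category = res$category,
             direction = res$direction, test = "hypergeometric",
             p = res$p, q = res$q, effect = res$effect,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Enrich every node of an ensemble
#'
#' @param signatures list of `node_signature`s (see [probe_ensemble()]).
#' @param coll a size-filtered, universe-restricted collection.
#' @inheritParams enrich_node
#' @return Row-bound enrichment results for all nodes.
#' @export
enrich_ensemble <- function(signatures, coll, top_k = 50L, threshold = 1e-8) {
  out <- lapply(signatures, enrich_node, coll = coll, top_k = top_k,
                threshold = threshold)
  res <- do.call(rbind, out)
  if (is.null(res)) empty_enrichment() else res
}

gsea_es <- function(ranked_stat, in_set) {
  ## weighted Kolmogorov-Smirnov running sum, weight exponent 1
  nr <- sum(abs(ranked_stat[in_set]))
  n <- length(ranked_stat)
  nh <- sum(in_set)
  if (nh == 0L || nh == n) stop("gene set must be a proper subset of the ranking")
  step <- ifelse(in_set,
                 if (nr > 0) abs(ranked_stat) / nr else 1 / nh,
                 -1 / (n - nh))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Preranked GSEA of one node signature against one gene set
#'
#' Genes are ranked by `delta_y` (descending); the enrichment score is the
#' extremum of the weighted Kolmogorov-Smirnov running sum (weight exponent
#' 1 on `|delta_y|`). The null is generated by gene-label permutation:
#' random sets of the same size drawn from the universe. The p-value is
#' `(1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`.
#'
#' @param sig a `node_signature`.
#' @param gene_set character vector of gene IDs (restricted to the
#'   signature's universe internally).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return List: `es`, `p`, `n_perm`, `set_size`.
#' @export
gsea_preranked <- function(sig, gene_set, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(sig, "node_signature"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  stat <- sig$delta_y[sig$ranked_genes]
  genes <- sig$ranked_genes
  gene_set <- intersect(gene_set, genes)
  if (length(gene_set) == 0L) stop("gene set is empty after universe restriction")
  in_set <- genes %in% gene_set
  es <- gsea_es(stat, in_set)
  set.seed(as.integer(seed))
  m <- length(gene_set); n <- length(genes)
  hits <- replicate(n_perm, {
    perm <- logical(n); perm[sample.int(n, m)] <- TRUE
    abs(gsea_es(stat, perm)) >= abs(es)
  })
  list(es = es, p = (1 + sum(hits)) / (n_perm + 1),
       n_perm = as.integer(n_perm), set_size = m)
}

#' Summarize gene-set recovery across an ensemble
#'
#' A gene set is "recovered" from a node when it passes the node's
#' enrichment threshold. The summary gives the per-set recovery frequency
#' (fraction of all probe nodes), the redundant total (every node x set
#' call counted), the unique count, and the per-network count
#' distribution used for architecture comparisons.
#'
#' @param results enrichment results ([enrich_ensemble()]).
#' @param n_nodes pooled probe nodes in the ensemble.
#' @param n_networks number of networks (for zero-filled per-network
#'   counts).
#' @return A `recovery_summary`: `frequency` (named per set),
#'   `total_recovered`, `unique_recovered`, `per_network_counts`.
#' @export
summarize_recovery <- function(results, n_nodes, n_networks) {
  freq <- if (nrow(results)) table(results$set) / n_nodes else
    table(character(0))
  per_net <- integer(n_networks)
  if (nrow(results)) {
    tab <- table(factor(results$network, levels = seq_len(n_networks)))
    per_net <- as.integer(tab)
  }
  structure(list(frequency = stats::setNames(as.numeric(freq), names(freq)),
                 total_recovered = nrow(results),
                 unique_recovered = length(unique(results$set)),
                 per_network_counts = per_net),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("recovery_summary: %d calls, %d unique sets; per-network median %g\n",
              x$total_recovered, x$unique_recovered,
              stats::median(x$per_network_counts)))
  invisible(x)
}

#' Compare two architectures' per-network enrichment counts
#'
#' Wilcoxon rank-sum test between the per-network counts of two ensembles.
#' Comparisons between architectures of the same depth are two-sided;
#' comparisons across depths are one-sided (is A, the deeper one, greater).
#' The exact distribution is used for small tie-free samples, otherwise
#' the normal approximation with continuity and tie correction.
#'
#' @param counts_a,counts_b per-network enrichment counts.
#' @param sided `"two_sided"` or `"a_greater"`.
#' @return List: `p`, `statistic` (rank-sum W), `sided`.
#' @export
compare_architectures <- function(counts_a, counts_b,
                                  sided = c("two_sided", "a_greater")) {
  sided <- match.arg(sided)
  if (length(counts_a) == 0L || length(counts_b) == 0L)
    stop("both samples must be non-empty")
  alt <- if (sided == "two_sided") "two.sided" else "greater"
  has_ties <- anyDuplicated(c(counts_a, counts_b)) > 0L
  use_exact <- !has_ties && max(length(counts_a), length(counts_b)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(counts_a, counts_b, alternative = alt,
                       exact = use_exact, correct = TRUE))
  p <- wt$p.value
  ## fully tied samples have zero rank variance; no evidence either way
  if (is.na(p)) p <- 1
  list(p = p, statistic = unname(wt$statistic), sided = sided)
}

#' Write enrichment results to TSV
#'
#' @param results enrichment data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
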