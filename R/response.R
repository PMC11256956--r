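#' Bottleneck activations of a compendium under each network
#'
#' Passes every experiment through the encoder of every ensemble member.
#' Each model scales the raw logTPM compendium with its own training
#' split's scaling record before encoding — a model only understands its
#' own input scale.
#'
#' @param ensemble a trained `dae_ensemble`.
#' @param comp an [expression_compendium()] over the same genes the models
#'   were trained on (order is realigned by gene ID).
#' @return List (one per network) of bottleneck x experiment activation
#'   matrices, entries in (0, 1).
#' @export
condition_activations <- function(ensemble, comp) {
  stopifnot(inherits(ensemble, "dae_ensemble"),
            inherits(comp, "expression_compendium"))
  lapply(ensemble$models, function(model) {
    if (!is.null(model$gene_ids)) {
      if (!all(model$gene_ids %in% comp$gene_ids))
        stop("compendium is missing genes the model was trained on")
      V <- comp$values[model$gene_ids, , drop = FALSE]
    } else V <- comp$values
    X <- apply_scaling(t(V), model$scaling)
    Z <- t(encode(model, X))                     # bottleneck x experiments
    colnames(Z) <- comp$experiment_ids
    Z
  })
}

#' Gene-set response phi of one network to one condition
#'
#' `phi = sum_j z_j(x_i) * mean_{g in set} delta_y_j[g]`, summed over all
#' bottleneck nodes `j` of the network: the network's predicted average
#' (scaled-logTPM) change of the gene set's genes in response to
#' experiment `x_i`, under the linear decomposition of node responses.
#'
#' @param z_column activation vector of one experiment (length bottleneck).
#' @param signatures the network's `node_signature` list, node order.
#' @param gene_set character vector of gene IDs.
#' @return The scalar phi.
#' @export
gene_set_response <- function(z_column, signatures, gene_set) {
  if (length(gene_set) == 0L) stop("gene set must be non-empty")
  if (length(z_column) != length(signatures))
    stop("one activation per bottleneck node required")
  means <- vapply(signatures, function(s) {
    d <- s$delta_y[intersect(names(s$delta_y), gene_set)]
    if (length(d) == 0L) stop("gene set has no genes in the model universe")
    mean(d)
  }, 0)
  sum(z_column * means)
}

#' Full response table over an ensemble
#'
#' Computes phi for every (gene set, network, experiment) triple.
#'
#' @param ensemble a trained `dae_ensemble`.
#' @param comp an [expression_compendium()].
#' @param coll a [gene_set_collection()] (restricted to the model universe).
#' @param signatures optional precomputed [probe_ensemble()] output.
#' @param activations optional precomputed [condition_activations()] output.
#' @return A `response_table` data.frame: set, network, experiment, phi.
#' @export
response_table <- function(ensemble, comp, coll, signatures = NULL,
                           activations = NULL) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if (is.null(signatures)) signatures <- probe_ensemble(ensemble)
  if (is.null(activations)) activations <- condition_activations(ensemble, comp)
  sets <- effective_sets(coll)
  sets <- sets[lengths(sets) > 0L]
  nets <- split(signatures,
                vapply(signatures, function(s) s$network_index, 0L))
  rows <- lapply(names(nets), function(i) {
    sigs <- nets[[i]]
    Z <- activations[[as.integer(i)]]           # nodes x experiments
    ## nodes x sets matrix of per-set mean delta_y
    M <- vapply(sets, function(genes)
      vapply(sigs, function(s) mean(s$delta_y[genes]), 0),
      numeric(length(sigs)))
    if (is.null(dim(M))) M <- matrix(M, nrow = length(sigs))
    phi <- crossprod(M, Z)                      # sets x experiments
    data.frame(set = rep(names(sets), times = ncol(Z)),
               network = as.integer(i),
               experiment = rep(colnames(Z), each = length(sets)),
               phi = as.vector(phi), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("response_table", "data.frame")
  out
}

#' RMS of the gene-set response distribution for one experiment
#'
#' Root mean square deviation from zero of all phi values (over gene sets
#' and networks) for one experiment. Zero means no gene set responds; each
#' responding set shifts its phi distribution off zero and raises the RMS,
#' so a lower RMS indicates a more selective (fewer-pathway) explanation
#' of the condition.
#'
#' @param table a [response_table()].
#' @param experiment experiment ID.
#' @return The RMS, a non-negative scalar.
#' @export
response_rms <- function(table, experiment) {
  phi <- table$phi[table$experiment == experiment]
  if (length(phi) == 0L) stop(sprintf("experiment '%s' not in table", experiment))
  sqrt(mean(phi^2))
}

#' Conditions that most activate a gene set's nodes
#'
#' Experiments are ranked by the mean bottleneck activation over all nodes
#' that recover the set in the activating direction.
#'
#' @param results enrichment results ([enrich_ensemble()]).
#' @param activations [condition_activations()] output.
#' @param gene_set_name set name to query.
#' @param top_n how many conditions to return (default 50).
#' @return Character vector of experiment IDs, best first; empty (with a
#'   warning) when no node recovers the set.
#' @export
top_conditions_for_set <- function(results, activations, gene_set_name,
                                   top_n = 50L) {
  hits <- results[results$set == gene_set_name &
                    results$direction == "activating", , drop = FALSE]
  if (nrow(hits) == 0L) {
    warning(sprintf("no node recovers '%s' in the activating direction",
                    gene_set_name))
    return(character(0))
  }
  acts <- mapply(function(net, node) activations[[net]][node, ],
                 hits$network, hits$node, SIMPLIFY = FALSE)
  mean_act <- colMeans(do.call(rbind, acts))
  names(sort(mean_act, decreasing = TRUE))[seq_len(min(top_n, length(mean_act)))]
}

#' Consensus condition across architectures
#'
#' Picks one experiment uniformly at random (seeded) from the intersection
#' of the per-architecture top-condition lists.
#'
#' @param rankings list (>= 2) of ranked experiment ID vectors.
#' @param top_n how many top entries of each ranking to intersect.
#' @param seed integer seed.
#' @return One experiment ID.
#' @export
consensus_condition <- function(rankings, top_n = 50L, seed = 1L) {
  if (length(rankings) < 2L) stop("need at least two rankings")
  tops <- lapply(rankings, function(r) r[seq_len(min(top_n, length(r)))])
  common <- Reduce(intersect, tops)
  if (length(common) == 0L)
    stop("the top condition lists have an empty intersection")
  set.seed(as.integer(seed))
  common[sample.int(length(common), 1L)]
}

#' Co-association counts around an anchor gene set
#'
#' For the nodes that recover `anchor_set` (activating and suppressing
#' anchors counted separately), counts how many of those nodes also
#' recover each other gene set, split by the partner's direction — the
#' four-quadrant co-association structure linking processes through
#' shared nodes.
#'
#' @param results enrichment results ([enrich_ensemble()]).
#' @param anchor_set anchor set name.
#' @return data.frame: anchor_direction, set, direction, n_nodes,
#'   n_anchor_nodes.
#' @export
coassociation_counts <- function(results, anchor_set) {
  out <- list()
  key <- function(df) paste(df$network, df$node)
  for (adir in c("activating", "suppressing")) {
    anchors <- results[results$set == anchor_set &
                         results$direction == adir, , drop = FALSE]
    if (nrow(anchors) == 0L) next
    anchor_nodes <- unique(key(anchors))
    others <- results[key(results) %in% anchor_nodes &
                        results$set != anchor_set, , drop = FALSE]
    if (nrow(others) == 0L) next
    tab <- stats::aggregate(list(n_nodes = key(others)),
                            by = list(set = others$set,
                                      direction = others$direction),
                            FUN = function(k) length(unique(k)))
    tab$anchor_direction <- adir
    tab$n_anchor_nodes <- length(anchor_nodes)
    out[[adir]] <- tab
  }
  if (length(out) == 0L)
    return(data.frame(anchor_direction = character(0), set = character(0),
                      direction = character(0), n_nodes = integer(0),
                      n_anchor_nodes = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("anchor_direction", "set", "direction", "n_nodes", "n_anchor_nodes")]
}
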