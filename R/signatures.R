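#' Probe one bottleneck node through the decoder
#'
#' Computes the node's decoder response `delta_y = decode(e_j) - decode(0)`,
#' where `e_j` sets node `j` to 1 and every other bottleneck node to 0, and
#' the baseline is the all-zero bottleneck. `delta_y` is the per-gene change
#' in predicted (scaled-logTPM) expression attributable to the node — the
#' interpretable unit of the whole method. Genes are ranked by `delta_y`
#' descending, ties broken by gene ID.
#'
#' @param model a trained `dae_model` (untrained models work; gene IDs fall
#'   back to `gene_1 ...` when the model carries none).
#' @param j node index, 1-based, `<=` bottleneck width.
#' @param network_index optional index recorded in the signature (for
#'   ensemble bookkeeping).
#' @return A `node_signature`: `delta_y` (named by gene), `ranked_genes`,
#'   `network_index`, `node_index`.
#' @export
node_response <- function(model, j, network_index = NA_integer_) {
  stopifnot(inherits(model, "dae_model"))
  nb <- model$architecture$bottleneck
  if (j < 1L || j > nb) stop(sprintf("node index %d out of range 1..%d", j, nb))
  e <- numeric(nb); e[j] <- 1
  delta <- decode(model, e) - decode(model, numeric(nb))
  ids <- model$gene_ids
  if (is.null(ids)) ids <- paste0("gene_", seq_len(model$input_dim))
  names(delta) <- ids
  ord <- order(-delta, ids)
  structure(list(network_index = as.integer(network_index),
                 node_index = as.integer(j),
                 delta_y = delta,
                 ranked_genes = ids[ord]),
            class = "node_signature")
}

#' @export
print.node_signature <- function(x, ...) {
  cat(sprintf("node_signature: network %s node %d; top gene %s (delta_y %.4g)\n",
              ifelse(is.na(x$network_index), "?", x$network_index),
              x$node_index, x$ranked_genes[1],
              x$delta_y[x$ranked_genes[1]]))
  invisible(x)
}

#' Probe every bottleneck node of an ensemble
#'
#' @param ensemble a `dae_ensemble`.
#' @return List of `node_signature` objects, networks in order, nodes
#'   within network.
#' @export
probe_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "dae_ensemble"))
  out <- list()
  for (i in seq_along(ensemble$models)) {
    nb <- ensemble$models[[i]]$architecture$bottleneck
    ## probe all nodes with two decoder calls: rows of I vs the zero vector
    base <- decode(ensemble$models[[i]], matrix(0, 1, nb))
    resp <- decode(ensemble$models[[i]], diag(nb))
    ids <- ensemble$models[[i]]$gene_ids
    if (is.null(ids)) ids <- paste0("gene_", seq_len(ncol(resp)))
    for (j in seq_len(nb)) {
      delta <- resp[j, ] - base[1, ]
      names(delta) <- ids
      ord <- order(-delta, ids)
      out[[length(out) + 1L]] <- structure(
        list(network_index = i, node_index = j, delta_y = delta,
             ranked_genes = ids[ord]),
        class = "node_signature")
    }
  }
  out
}

#' Graded activation of one node
#'
#' Evaluates the baseline-subtracted decoder output at intermediate
#' activation levels `z = level * e_j`, tracing how the response builds up
#' from 0 to the full probe at 1.
#'
#' @param model a `dae_model`.
#' @param j node index.
#' @param levels activation levels in [0, 1].
#' @return Matrix levels x genes of baseline-subtracted decoder outputs,
#'   rownames the levels.
#' @export
graded_response <- function(model, j, levels = seq(0, 1, by = 0.25)) {
  stopifnot(inherits(model, "dae_model"))
  nb <- model$architecture$bottleneck
  if (j < 1L || j > nb) stop(sprintf("node index %d out of range 1..%d", j, nb))
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  Z <- matrix(0, length(levels), nb)
  Z[, j] <- levels
  base <- decode(model, matrix(0, 1, nb))
  out <- decode(model, Z) - matrix(base, length(levels), ncol(base),
                                   byrow = TRUE)
  rownames(out) <- as.character(levels)
  if (!is.null(model$gene_ids)) colnames(out) <- model$gene_ids
  out
}

#' Additivity (linearity) of two node responses
#'
#' The decoder is nonlinear, yet node responses combine almost additively
#' in trained networks. This score quantifies the departure: the L1 norm,
#' over genes, between the joint response of activating nodes `j` and `k`
#' together and the sum of their individual responses (all baseline
#' subtracted). Exactly 0 for a linear decoder.
#'
#' @param model a `dae_model`.
#' @param j,k distinct node indices.
#' @return A `linearity_report`: `node_pair`, `l1_score`, `joint`
#'   (response to both nodes), `summed` (sum of single-node responses).
#' @export
linearity_score <- function(model, j, k) {
  stopifnot(inherits(model, "dae_model"))
  if (j == k) stop("j and k must be distinct nodes")
  nb <- model$architecture$bottleneck
  if (max(j, k) > nb || min(j, k) < 1L) stop("node index out of range")
  base <- decode(model, numeric(nb))
  ej <- numeric(nb); ej[j] <- 1
  ek <- numeric(nb); ek[k] <- 1
  joint <- decode(model, ej + ek) - base
  summed <- (decode(model, ej) - base) + (decode(model, ek) - base)
  structure(list(node_pair = c(j = as.integer(j), k = as.integer(k)),
                 l1_score = sum(abs(joint - summed)),
                 joint = joint, summed = summed),
            class = "linearity_report")
}

#' @export
print.linearity_report <- function(x, ...) {
  cat(sprintf("linearity_report: nodes (%d, %d), L1 score %.6g\n",
              x$node_pair["j"], x$node_pair["k"], x$l1_score))
  invisible(x)
}

#' Write node signatures to TSV
#'
#' Long format: network, node, gene, delta_y, rank.
#'
#' @param signatures list of `node_signature` objects.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  rows <- lapply(signatures, function(s) {
    rk <- match(names(s$delta_y), s$ranked_genes)
    data.frame(network = s$network_index, node = s$node_index,
               gene = names(s$delta_y), delta_y = unname(s$delta_y),
               rank = rk)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
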