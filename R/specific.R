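#' Find nodes specific to a condition group
#'
#' A node is specific to the target group when its activation is strictly
#' above `threshold` for every experiment of the target group and strictly
#' below `threshold` for every experiment of the background groups. With
#' the default threshold of 0.5, a node sitting exactly at 0.5 (e.g. a
#' zero-weight network) never qualifies.
#'
#' @param ensemble a trained `dae_ensemble`.
#' @param comp an [expression_compendium()] with condition labels.
#' @param target condition group label the nodes must fire in.
#' @param background labels the nodes must stay silent in; defaults to all
#'   other groups present.
#' @param threshold activation cutoff (strict on both sides).
#' @param activations optional precomputed [condition_activations()].
#' @return data.frame of qualifying nodes: network, node, min_target,
#'   max_background.
#' @export
find_specific_nodes <- function(ensemble, comp, target, background = NULL,
                                threshold = 0.5, activations = NULL) {
  stopifnot(inherits(comp, "expression_compendium"))
  labels <- comp$condition_labels
  if (is.null(background)) background <- setdiff(unique(labels), target)
  if (target %in% background) stop("target group cannot be in the background")
  t_idx <- which(labels == target)
  b_idx <- which(labels %in% background)
  if (length(t_idx) == 0L) stop(sprintf("no experiments in group '%s'", target))
  if (length(b_idx) == 0L) stop("no experiments in the background groups")
  if (is.null(activations)) activations <- condition_activations(ensemble, comp)

  rows <- lapply(seq_along(activations), function(i) {
    Z <- activations[[i]]
    mn_t <- apply(Z[, t_idx, drop = FALSE], 1, min)
    mx_b <- apply(Z[, b_idx, drop = FALSE], 1, max)
    hit <- which(mn_t > threshold & mx_b < threshold)
    if (length(hit) == 0L) return(NULL)
    data.frame(network = i, node = hit, min_target = mn_t[hit],
               max_background = mx_b[hit], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(network = integer(0), node = integer(0),
                      min_target = numeric(0), max_background = numeric(0))
  out
}

#' Derive a de novo gene set from specific nodes
#'
#' Averages the decoder response `delta_y` of the selected nodes per gene
#' and keeps the `top_n` most-activated genes. The suppressed counterpart
#' (most negative mean `delta_y`) is returned alongside, since
#' condition-suppressing nodes are equally informative.
#'
#' @param nodes data.frame with `network` and `node` columns
#'   ([find_specific_nodes()] output).
#' @param signatures [probe_ensemble()] output for the same ensemble.
#' @param top_n genes to keep per direction (default 100).
#' @return A `de_novo_gene_set`: `genes` (named mean delta_y, descending),
#'   `suppressed_genes`, `mean_delta_y` (all genes), `source_nodes`,
#'   `top_n`.
#' @export
derive_de_novo_set <- function(nodes, signatures, top_n = 100L) {
  if (nrow(nodes) == 0L) stop("need at least one source node")
  keys <- vapply(signatures, function(s)
    paste(s$network_index, s$node_index), "")
  idx <- match(paste(nodes$network, nodes$node), keys)
  if (anyNA(idx)) stop("some nodes have no matching signature")
  dys <- vapply(signatures[idx], function(s)
    s$delta_y[order(names(s$delta_y))], signatures[[idx[1]]]$delta_y)
  dys <- matrix(dys, ncol = length(idx))
  rownames(dys) <- sort(names(signatures[[idx[1]]]$delta_y))
  mean_dy <- rowMeans(dys)
  ord <- order(-mean_dy, names(mean_dy))
  top_n <- min(top_n, length(mean_dy))
  structure(list(genes = mean_dy[ord][seq_len(top_n)],
                 suppressed_genes = mean_dy[rev(ord)][seq_len(top_n)],
                 mean_delta_y = mean_dy,
                 source_nodes = nodes[, c("network", "node")],
                 top_n = as.integer(top_n)),
            class = "de_novo_gene_set")
}

#' @export
print.de_novo_gene_set <- function(x, ...) {
  cat(sprintf("de_novo_gene_set: top %d genes from %d nodes; lead gene %s (%.4g)\n",
              x$top_n, nrow(x$source_nodes), names(x$genes)[1], x$genes[1]))
  invisible(x)
}

#' z-scores of genes in named conditions against the whole compendium
#'
#' For each gene: `(mean over the named conditions - compendium mean) /
#' compendium SD`, on unscaled logTPM. Used to check that a de novo gene
#' set is genuinely shifted in the conditions that define it. Zero-variance
#' genes get `NA`.
#'
#' @param comp an [expression_compendium()].
#' @param genes gene IDs to score.
#' @param conditions experiment IDs defining the foreground.
#' @return data.frame: gene, z, cond_mean, comp_mean, comp_sd.
#' @export
zscore_validation <- function(comp, genes, conditions) {
  stopifnot(inherits(comp, "expression_compendium"))
  if (!all(conditions %in% comp$experiment_ids))
    stop("unknown experiment IDs in `conditions`")
  genes <- intersect(genes, comp$gene_ids)
  V <- comp$values[genes, , drop = FALSE]
  comp_mean <- rowMeans(V)
  comp_sd <- apply(V, 1, stats::sd)
  cond_mean <- rowMeans(V[, conditions, drop = FALSE])
  z <- ifelse(comp_sd > 0, (cond_mean - comp_mean) / comp_sd, NA_real_)
  data.frame(gene = genes, z = unname(z), cond_mean = unname(cond_mean),
             comp_mean = unname(comp_mean), comp_sd = unname(comp_sd),
             stringsAsFactors = FALSE)
}

#' Per-gene log-fold change between two condition groups
#'
#' Mean logTPM difference (group A - group B) per gene, optionally
#' stratified by a strain annotation. Genes absent from a stratum are
#' reported as `NA`, never silently zero.
#'
#' @param comp an [expression_compendium()].
#' @param genes gene IDs.
#' @param group_a,group_b condition group labels.
#' @param strain optional named character vector mapping experiment IDs to
#'   strains; when given, one logFC column per strain is returned.
#' @return data.frame with `gene` and one `logFC` column (or one per
#'   strain).
#' @export
group_logfc <- function(comp, genes, group_a, group_b, strain = NULL) {
  stopifnot(inherits(comp, "expression_compendium"))
  labels <- comp$condition_labels
  if (!any(labels == group_a) || !any(labels == group_b))
    stop("both groups must have experiments")
  present <- genes[genes %in% comp$gene_ids]
  fc_for <- function(exp_ids) {
    a <- intersect(exp_ids, comp$experiment_ids[labels == group_a])
    b <- intersect(exp_ids, comp$experiment_ids[labels == group_b])
    if (length(a) == 0L || length(b) == 0L)
      return(stats::setNames(rep(NA_real_, length(genes)), genes))
    fc <- rowMeans(comp$values[present, a, drop = FALSE]) -
      rowMeans(comp$values[present, b, drop = FALSE])
    out <- stats::setNames(rep(NA_real_, length(genes)), genes)
    out[present] <- fc
    out
  }
  if (is.null(strain)) {
    data.frame(gene = genes, logFC = unname(fc_for(comp$experiment_ids)),
               stringsAsFactors = FALSE)
  } else {
    strains <- sort(unique(strain[comp$experiment_ids]))
    cols <- lapply(strains, function(s)
      unname(fc_for(comp$experiment_ids[strain[comp$experiment_ids] == s])))
    names(cols) <- paste0("logFC_", strains)
    cbind(data.frame(gene = genes, stringsAsFactors = FALSE),
          as.data.frame(cols, check.names = FALSE))
  }
}

#' Write a de novo gene set as GMT
#'
#' Emits two lines: the activated set and its suppressed counterpart, so
#' the result can feed straight back into enrichment.
#'
#' @param dns a `de_novo_gene_set`.
#' @param path output GMT path.
#' @param name base set name.
#' @return `path`, invisibly.
#' @export
write_de_novo_gmt <- function(dns, path, name = "de_novo") {
  stopifnot(inherits(dns, "de_novo_gene_set"))
  coll <- gene_set_collection(
    stats::setNames(list(names(dns$genes), names(dns$suppressed_genes)),
                    c(paste0(name, "_activated"),
                      paste0(name, "_suppressed"))),
    category = "custom")
  write_gmt(coll, path)
}
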