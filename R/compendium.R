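#' Expression compendium container
#'
#' A compendium is a genes x experiments matrix of logTPM values together
#' with a condition-group label per experiment. This is the object every
#' downstream stage (training, encoding, validation) consumes.
#'
#' @param values numeric matrix, genes in rows, experiments in columns.
#'   Row and column names are required and must be unique.
#' @param condition_labels character vector naming the condition group of
#'   each experiment; either named by experiment ID or given in column order.
#' @return An object of class `expression_compendium` with elements
#'   `values`, `gene_ids`, `experiment_ids` and `condition_labels`.
#' @export
expression_compendium <- function(values, condition_labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x experiments)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene IDs as rownames and experiment IDs as colnames")
  if (anyDuplicated(rownames(values))) stop("gene IDs must be unique")
  if (anyDuplicated(colnames(values))) stop("experiment IDs must be unique")
  if (any(!is.finite(values))) stop("expression values must be finite (no NAs)")
  if (length(condition_labels) != ncol(values))
    stop("need one condition label per experiment")
  if (is.null(names(condition_labels))) {
    names(condition_labels) <- colnames(values)
  } else {
    if (!setequal(names(condition_labels), colnames(values)))
      stop("condition label names do not match experiment IDs")
    condition_labels <- condition_labels[colnames(values)]
  }
  structure(
    list(values = values,
         gene_ids = rownames(values),
         experiment_ids = colnames(values),
         condition_labels = as.character(stats::setNames(condition_labels,
                                                         colnames(values)))),
    class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("expression_compendium: %d genes x %d experiments, %d condition group(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$condition_labels))))
  invisible(x)
}

#' @export
dim.expression_compendium <- function(x) dim(x$values)

#' Simulation configuration for synthetic compendia
#'
#' Defines the generative model for a logTPM compendium with planted
#' co-regulated gene modules. Each gene has a baseline drawn uniformly from
#' `baseline_mean_range`; each experiment activates between one and three
#' modules; an active module shifts its member genes by `effect_size`
#' (up for activating modules, down for the repressed minority); i.i.d.
#' Gaussian noise of `noise_sd` is added on top. Optionally one module pair
#' is inversely coupled (never co-active) and one module is active in all
#' experiments of exactly one condition group and nowhere else.
#'
#' @param n_genes,n_experiments compendium dimensions.
#' @param n_modules number of planted modules (>= 1).
#' @param module_size_range integer vector `c(min, max)` of genes per module.
#' @param baseline_mean_range logTPM interval the per-gene baselines are
#'   drawn from.
#' @param effect_size logTPM shift applied to a module's genes while active.
#' @param noise_sd standard deviation of the additive Gaussian noise (logTPM).
#' @param n_condition_groups number of condition groups the experiments are
#'   divided into.
#' @param group_specific_module if `TRUE`, the last module is active in every
#'   experiment of the first condition group and in no other experiment.
#' @param inverse_pair if `TRUE`, modules 1 and 2 are anti-coupled: in any
#'   experiment where either would be active, exactly one of the two is.
#' @param overlap_fraction fraction of each module's genes shared with the
#'   previous module (0 = disjoint).
#' @param repressed_fraction fraction of modules whose activation lowers
#'   rather than raises expression.
#' @param seed integer seed making generation deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 300, n_experiments = 200, n_modules = 10,
                       module_size_range = c(10, 20),
                       baseline_mean_range = c(2, 8),
                       effect_size = 1.5, noise_sd = 0.3,
                       n_condition_groups = 4,
                       group_specific_module = TRUE,
                       inverse_pair = TRUE,
                       overlap_fraction = 0,
                       repressed_fraction = 0.1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_experiments = as.integer(n_experiments),
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              baseline_mean_range = as.numeric(baseline_mean_range),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              n_condition_groups = as.integer(n_condition_groups),
              group_specific_module = isTRUE(group_specific_module),
              inverse_pair = isTRUE(inverse_pair),
              overlap_fraction = as.numeric(overlap_fraction),
              repressed_fraction = as.numeric(repressed_fraction),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_modules < 1L) stop("n_modules must be >= 1")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (length(cfg$module_size_range) != 2L ||
      cfg$module_size_range[1] > cfg$module_size_range[2])
    stop("module_size_range must be c(min, max) with min <= max")
  if (cfg$module_size_range[2] > cfg$n_genes)
    stop("module_size_range max exceeds n_genes")
  if (cfg$inverse_pair && cfg$n_modules < 2L)
    stop("inverse_pair requires at least 2 modules")
  if (cfg$n_condition_groups < 1L) stop("need at least one condition group")
  invisible(cfg)
}

#' Generate a synthetic compendium with planted modules
#'
#' Draws a compendium from the generative model described in [sim_config()]
#' and returns it together with the ground truth needed to score recovery:
#' the planted modules as a [gene_set_collection()], the binary
#' module x experiment activity matrix, and the identities of the inverse
#' pair and the group-specific module.
#'
#' @param config a [sim_config()].
#' @return list with elements `compendium` (an `expression_compendium`) and
#'   `truth` (list: `planted_modules`, `module_activity`, `module_sign`,
#'   `inverse_pair_ids`, `group_specific_module_id`).
#' @examples
#' sim <- generate_compendium(sim_config(n_genes = 60, n_experiments = 30,
#'                                       n_modules = 3, seed = 2))
#' dim(sim$compendium)
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  ng <- config$n_genes; ne <- config$n_experiments; nm <- config$n_modules
  gene_ids <- sprintf("g%04d", seq_len(ng))
  exp_ids  <- sprintf("exp%03d", seq_len(ne))

  ## ---- module membership -------------------------------------------------
  sizes <- sample(seq(config$module_size_range[1], config$module_size_range[2]),
                  nm, replace = TRUE)
  n_overlap <- floor(sizes * config$overlap_fraction)
  n_fresh <- sizes - ifelse(seq_len(nm) > 1, n_overlap, 0)
  if (sum(n_fresh) > ng)
    stop("modules do not fit into n_genes; reduce sizes or overlap")
  pool <- sample(gene_ids)            # random gene order, then carve blocks
  modules <- vector("list", nm)
  names(modules) <- sprintf("module%02d", seq_len(nm))
  used <- 0L
  for (m in seq_len(nm)) {
    fresh <- pool[used + seq_len(n_fresh[m])]
    used <- used + n_fresh[m]
    if (m > 1L && n_overlap[m] > 0L) {
      shared <- sample(modules[[m - 1L]], n_overlap[m])
      modules[[m]] <- c(shared, fresh)
    } else {
      modules[[m]] <- fresh
    }
  }

  ## 90/10 activating vs repressed by default; module 1 kept activating so
  ## the inverse pair has a well-defined "up" anchor, and the
  ## group-specific module models an induced program (genes up in its
  ## group), so its sign is fixed positive
  sign_vec <- ifelse(stats::runif(nm) < config$repressed_fraction, -1, 1)
  sign_vec[1] <- 1
  if (config$group_specific_module) sign_vec[nm] <- 1

  ## ---- condition groups and module activity ------------------------------
  groups <- paste0("group", rep_len(seq_len(config$n_condition_groups), ne))
  groups <- sample(groups)            # shuffle assignment
  names(groups) <- exp_ids

  activity <- matrix(0L, nm, ne, dimnames = list(names(modules), exp_ids))
  for (e in seq_len(ne)) {
    k <- sample(1:3, 1)
    activity[sample(nm, min(k, nm)), e] <- 1L
  }

  gs_id <- NULL
  if (config$group_specific_module) {
    gs_id <- names(modules)[nm]
    in_group1 <- groups == "group1"
    activity[nm, ] <- as.integer(in_group1)
  }

  ip_ids <- NULL
  if (config$inverse_pair) {
    ip_ids <- names(modules)[1:2]
    either <- activity[1, ] == 1L | activity[2, ] == 1L
    pick_first <- stats::runif(ne) < 0.5
    activity[1, ] <- as.integer(either & pick_first)
    activity[2, ] <- as.integer(either & !pick_first)
  }

  ## ---- expression values -------------------------------------------------
  mu <- stats::runif(ng, config$baseline_mean_range[1], config$baseline_mean_range[2])
  membership <- matrix(0, ng, nm, dimnames = list(gene_ids, names(modules)))
  for (m in seq_len(nm)) membership[modules[[m]], m] <- 1
  signal <- config$effect_size *
    (membership %*% (sign_vec * activity))          # genes x experiments
  values <- mu + signal + matrix(stats::rnorm(ng * ne, 0, config$noise_sd), ng, ne)
  dimnames(values) <- list(gene_ids, exp_ids)

  comp <- expression_compendium(values, groups)
  coll <- gene_set_collection(
    sets = modules,
    category = stats::setNames(rep("custom", nm), names(modules)),
    universe = gene_ids)
  list(compendium = comp,
       truth = list(planted_modules = coll,
                    module_activity = activity,
                    module_sign = stats::setNames(sign_vec, names(modules)),
                    inverse_pair_ids = ip_ids,
                    group_specific_module_id = gs_id))
}

#' Permute a compendium gene-wise (negative control)
#'
#' Shuffles the values of every gene row independently across experiments.
#' Per-gene value distributions are preserved exactly while gene-gene
#' correlations and any condition specificity are destroyed, giving the
#' negative control used to calibrate gene-set recovery.
#'
#' @param comp an `expression_compendium`.
#' @param seed integer seed; the permutation is deterministic given the seed.
#' @return A permuted `expression_compendium` with unchanged condition labels.
#' @export
permute_compendium <- function(comp, seed = 1L) {
  stopifnot(inherits(comp, "expression_compendium"))
  set.seed(as.integer(seed))
  v <- comp$values
  for (g in seq_len(nrow(v))) v[g, ] <- v[g, sample.int(ncol(v))]
  expression_compendium(v, comp$condition_labels)
}

#' Write / read a compendium as TSV
#'
#' The matrix file has gene IDs in the first column (`gene_id`) and one
#' column per experiment; the companion metadata file maps experiment IDs to
#' condition groups.
#'
#' @param comp an `expression_compendium`.
#' @param path path of the matrix TSV.
#' @param metadata_path path of the metadata TSV (default: `path` with a
#'   `.meta.tsv` suffix).
#' @return `write_compendium` returns `path` invisibly; `read_compendium`
#'   returns an `expression_compendium`.
#' @export
write_compendium <- function(comp, path,
                             metadata_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(comp, "expression_compendium"))
  df <- data.frame(gene_id = comp$gene_ids, comp$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(experiment_id = comp$experiment_ids,
                     condition = comp$condition_labels)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(path, metadata_path = paste0(path, ".meta.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  labels <- stats::setNames(as.character(meta$condition), meta$experiment_id)
  expression_compendium(values, labels)
}
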