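#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: where the compendium comes
#' from (a simulation config or TSV paths), the gene sets, the
#' architectures to train, and the training settings.
#'
#' @param output_dir run directory (created; stage outputs and the
#'   manifest land here).
#' @param sim a [sim_config()] to simulate a compendium, or `NULL` when
#'   reading from files.
#' @param compendium_path,gmt_path input files used when `sim` is `NULL`
#'   (`gmt_path` may also be set alongside `sim` to enrich against an
#'   external collection; by default the planted modules are used).
#' @param architectures character vector of architecture strings, e.g.
#'   `c("100-10", "100-50-10")`.
#' @param train a [train_config()].
#' @param n_models networks per ensemble (`NULL`: derive from
#'   `total_nodes`).
#' @param total_nodes pooled bottleneck nodes per ensemble when `n_models`
#'   is `NULL`.
#' @param top_k,threshold enrichment tail size and q-value cutoff.
#' @param max_set_size gene-set size cap before testing.
#' @param specific optional list(`target`, `background`, `threshold`,
#'   `top_n`) enabling the condition-specific stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, sim = NULL, compendium_path = NULL,
                            gmt_path = NULL,
                            architectures = "100-10",
                            train = train_config(),
                            n_models = NULL, total_nodes = 5000L,
                            top_k = 50L, threshold = 1e-8,
                            max_set_size = 40L, specific = NULL) {
  if (is.null(sim) && is.null(compendium_path))
    stop("either `sim` or `compendium_path` must be given")
  structure(list(output_dir = output_dir, sim = sim,
                 compendium_path = compendium_path, gmt_path = gmt_path,
                 architectures = architectures, train = train,
                 n_models = n_models, total_nodes = as.integer(total_nodes),
                 top_k = as.integer(top_k), threshold = threshold,
                 max_set_size = as.integer(max_set_size),
                 specific = specific),
            class = "pipeline_config")
}

stage_path <- function(dir, ...) file.path(dir, ...)

#' Run the full inference pipeline
#'
#' Executes the stages in order — simulate (or load) the compendium, train
#' one ensemble per architecture, probe every bottleneck node, enrich the
#' signatures against the gene sets, summarize recovery, compute the
#' condition response table, and (optionally) extract condition-specific
#' nodes and their de novo gene set — writing each stage's artifacts as
#' TSV/GMT under the run directory and recording a JSON manifest. The run
#' is deterministic given the seeds in the config.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return A `run_manifest` (invisibly written to `manifest.json`): config
#'   snapshot, per-stage outputs and timings, and in-memory results
#'   (`ensembles`, `results`, `summaries`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  note <- function(name, ...) {
    if (verbose) message(sprintf("[%s] %s", name, sprintf(...)))
  }
  run_stage <- function(name, fun) {
    tic <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stages[[name]] <<- list(seconds = as.numeric(Sys.time() - tic,
                                                 units = "secs"))
    out
  }

  ## ---- data ----------------------------------------------------------
  truth <- NULL
  comp <- run_stage("data", function() {
    if (!is.null(config$sim)) {
      sim <- generate_compendium(config$sim)
      truth <<- sim$truth
      write_compendium(sim$compendium,
                       stage_path(config$output_dir, "compendium.tsv"))
      write_gmt(sim$truth$planted_modules,
                stage_path(config$output_dir, "planted_modules.gmt"))
      sim$compendium
    } else {
      read_compendium(config$compendium_path)
    }
  })
  note("data", "%d genes x %d experiments", nrow(comp$values),
       ncol(comp$values))

  coll <- run_stage("gene_sets", function() {
    raw <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
           else if (!is.null(truth)) truth$planted_modules
           else stop("no gene sets: give `gmt_path` or simulate")
    filter_by_size(restrict_to_universe(raw, comp$gene_ids),
                   config$max_set_size)
  })

  ## ---- per-architecture stages ---------------------------------------
  ensembles <- list(); all_results <- list(); summaries <- list()
  activations <- list()
  for (arch_str in config$architectures) {
    arch <- parse_architecture(arch_str)
    ens <- run_stage(paste0("train:", arch_str), function()
      train_ensemble(arch, comp, config$train,
                     total_nodes = config$total_nodes,
                     n_models = config$n_models, verbose = verbose))
    sigs <- run_stage(paste0("probe:", arch_str), function() {
      s <- probe_ensemble(ens)
      write_signatures(s, stage_path(config$output_dir,
                                     paste0("signatures_", arch_str, ".tsv")))
      s
    })
    res <- run_stage(paste0("enrich:", arch_str), function() {
      r <- enrich_ensemble(sigs, coll, top_k = config$top_k,
                           threshold = config$threshold)
      write_enrichment(r, stage_path(config$output_dir,
                                     paste0("enrichment_", arch_str, ".tsv")))
      r
    })
    summ <- run_stage(paste0("summarize:", arch_str), function()
      summarize_recovery(res, ens$total_bottleneck_nodes,
                         length(ens$models)))
    acts <- run_stage(paste0("respond:", arch_str), function() {
      a <- condition_activations(ens, comp)
      tab <- response_table(ens, comp, coll, signatures = sigs,
                            activations = a)
      utils::write.table(tab, stage_path(config$output_dir,
                                         paste0("response_", arch_str, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      a
    })
    ensembles[[arch_str]] <- ens
    all_results[[arch_str]] <- res
    summaries[[arch_str]] <- summ
    activations[[arch_str]] <- acts
    note(arch_str, "%d calls, %d unique sets", summ$total_recovered,
         summ$unique_recovered)
  }

  ## ---- condition-specific stage (optional) ---------------------------
  specific_out <- NULL
  if (!is.null(config$specific)) {
    sp <- config$specific
    arch_str <- config$architectures[[length(config$architectures)]]
    specific_out <- run_stage("specific", function() {
      nodes <- find_specific_nodes(
        ensembles[[arch_str]], comp, sp$target,
        background = sp$background,
        threshold = if (is.null(sp$threshold)) 0.5 else sp$threshold,
        activations = activations[[arch_str]])
      dns <- NULL
      if (nrow(nodes) > 0L) {
        dns <- derive_de_novo_set(
          nodes, probe_ensemble(ensembles[[arch_str]]),
          top_n = if (is.null(sp$top_n)) 100L else sp$top_n)
        write_de_novo_gmt(dns, stage_path(config$output_dir, "de_novo.gmt"),
                          name = sp$target)
      }
      list(nodes = nodes, de_novo = dns)
    })
  }

  manifest <- structure(
    list(config = config, stages = stages,
         started = format(t0), finished = format(Sys.time()),
         compendium = comp, truth = truth, collection = coll,
         ensembles = ensembles, results = all_results,
         summaries = summaries, activations = activations,
         specific = specific_out),
    class = "run_manifest")
  jsonlite::write_json(
    list(architectures = config$architectures,
         seed = config$train$seed,
         n_genes = nrow(comp$values), n_experiments = ncol(comp$values),
         stages = stages),
    stage_path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %d architecture(s), %d stage(s), output %s\n",
              length(x$ensembles), length(x$stages),
              x$config$output_dir))
  invisible(x)
}

#' Compare two pipeline runs architecture-wise
#'
#' Wilcoxon rank-sum comparison of per-network enrichment counts between
#' two runs (or two architectures of one run): two-sided for equal-depth
#' pairs, one-sided (A greater) across depths, plus the recovery-frequency
#' deltas per gene set.
#'
#' @param manifest_a,manifest_b `run_manifest`s (single-architecture runs,
#'   or give `arch_a`/`arch_b`).
#' @param arch_a,arch_b architecture keys; default the first of each run.
#' @return List: `p`, `sided`, `counts_a`, `counts_b`,
#'   `frequency_delta`.
#' @export
compare_runs <- function(manifest_a, manifest_b, arch_a = NULL,
                         arch_b = NULL) {
  if (is.null(arch_a)) arch_a <- names(manifest_a$summaries)[1]
  if (is.null(arch_b)) arch_b <- names(manifest_b$summaries)[1]
  same_sets <- identical(sort(names(manifest_a$collection$sets)),
                         sort(names(manifest_b$collection$sets)))
  if (!same_sets)
    stop("runs were enriched against different gene-set collections")
  depth_a <- length(parse_architecture(arch_a)$encoder_widths)
  depth_b <- length(parse_architecture(arch_b)$encoder_widths)
  sided <- if (depth_a == depth_b) "two_sided" else "a_greater"
  ca <- manifest_a$summaries[[arch_a]]$per_network_counts
  cb <- manifest_b$summaries[[arch_b]]$per_network_counts
  ## across depths the one-sided test always asks whether the deeper
  ## architecture recovers more
  cmp <- if (depth_a >= depth_b) compare_architectures(ca, cb, sided)
         else compare_architectures(cb, ca, sided)
  fa <- manifest_a$summaries[[arch_a]]$frequency
  fb <- manifest_b$summaries[[arch_b]]$frequency
  sets <- union(names(fa), names(fb))
  delta <- stats::setNames(
    ifelse(sets %in% names(fa), fa[sets], 0) -
      ifelse(sets %in% names(fb), fb[sets], 0), sets)
  list(p = cmp$p, sided = sided, counts_a = ca, counts_b = cb,
       frequency_delta = delta)
}
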