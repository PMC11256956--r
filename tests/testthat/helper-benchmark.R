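## The synthetic benchmark used for planted-module recovery checks:
## 300 genes x 200 experiments, 10 modules, effect 1.5,
## noise 0.3; ensembles of 10 networks with architecture 100-(10).
## Heavy: built once per test run and shared between the acceptance
## blocks that probe recovery, linearity and specificity.

benchmark_seed <- 7L

benchmark_sim <- function() memo("benchmark_sim", function() {
  generate_compendium(sim_config(seed = benchmark_seed))
})

benchmark_collection <- function() {
  sim <- benchmark_sim()
  filter_by_size(restrict_to_universe(sim$truth$planted_modules,
                                      sim$compendium$gene_ids), 40)
}

benchmark_ensemble <- function() memo("benchmark_ensemble", function() {
  train_ensemble(parse_architecture("100-10"),
                 benchmark_sim()$compendium,
                 train_config(seed = benchmark_seed), n_models = 10)
})

benchmark_signatures <- function() memo("benchmark_signatures", function() {
  probe_ensemble(benchmark_ensemble())
})

benchmark_permuted <- function() memo("benchmark_permuted", function() {
  permute_compendium(benchmark_sim()$compendium, seed = benchmark_seed)
})

benchmark_permuted_ensemble <- function()
  memo("benchmark_permuted_ensemble", function() {
    train_ensemble(parse_architecture("100-10"), benchmark_permuted(),
                   train_config(seed = benchmark_seed), n_models = 10)
  })
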