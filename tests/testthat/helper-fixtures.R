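## Shared fixtures. Heavy objects are built lazily and memoised for the
## duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## a model whose weights are all zero (encode -> 0.5, decode -> 0.5)
zero_model <- function(encoder_widths = integer(0), bottleneck = 3L,
                       input_dim = 6L) {
  m <- build_dae(dae_architecture(encoder_widths, bottleneck), input_dim,
                 seed = 1L)
  m$W <- lapply(m$W, function(w) w * 0)
  m
}

## hand-set single-layer model: input_dim genes -> 1 bottleneck node,
## weight vector w, encoder bias be, decoder bias bd
toy_model_1node <- function(w, be = 0, bd = NULL) {
  d <- length(w)
  m <- build_dae(dae_architecture(integer(0), 1L), d, seed = 1L)
  m$W[[1]] <- matrix(w, d, 1)
  m$b_enc[[1]] <- be
  if (!is.null(bd)) m$b_dec[[1]] <- bd
  m
}

## small trained fixture for response/specificity unit tests:
## 80 genes x 60 experiments, 4 modules, group-specific module, 2 networks
mini_sim <- function() memo("mini_sim", function() {
  generate_compendium(sim_config(n_genes = 80, n_experiments = 60,
                                 n_modules = 4, module_size_range = c(8, 12),
                                 n_condition_groups = 3, seed = 11))
})

mini_ensemble <- function() memo("mini_ensemble", function() {
  sim <- mini_sim()
  cfg <- train_config(max_epochs = 400, patience = 40, seed = 11)
  train_ensemble(parse_architecture("30-6"), sim$compendium, cfg,
                 n_models = 2)
})

mini_collection <- function() {
  sim <- mini_sim()
  filter_by_size(restrict_to_universe(sim$truth$planted_modules,
                                      sim$compendium$gene_ids), 40)
}
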