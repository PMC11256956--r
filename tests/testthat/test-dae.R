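test_that("architecture strings parse to the figure notation", {
  a <- parse_architecture("2000-1000-50")
  expect_identical(a$encoder_widths, c(2000L, 1000L))
  expect_identical(a$bottleneck, 50L)
  expect_identical(format(a), "2000-1000-(50)")
  expect_identical(parse_architecture("100-(10)")$bottleneck, 10L)
  expect_identical(parse_architecture("50")$encoder_widths, integer(0))
  expect_error(parse_architecture("abc"), "cannot parse")
})

test_that("initialisation is Glorot-bounded, zero-biased, deterministic", {
  arch <- dae_architecture(c(50), 10)
  m1 <- build_dae(arch, 100, seed = 21)
  m2 <- build_dae(arch, 100, seed = 21)
  expect_identical(m1$W, m2$W)

  ## 100x50 matrix: bound sqrt(6/150)
  expect_lte(max(abs(m1$W[[1]])), sqrt(6 / 150))
  expect_lte(max(abs(m1$W[[2]])), sqrt(6 / 60))
  for (b in c(m1$b_enc, m1$b_dec)) expect_identical(b, numeric(length(b)))
})

test_that("encode and decode match closed-form forward passes", {
  ## zero weights: sigmoid(0) everywhere
  zm <- zero_model(bottleneck = 3, input_dim = 6)
  expect_identical(unname(encode(zm, rep(0.3, 6))), rep(0.5, 3))
  expect_identical(unname(decode(zm, rep(0.9, 3))), rep(0.5, 6))

  ## 2-gene, 1-node toy: w = (1, -1), x = (1, 0) -> sigmoid(1)
  tm <- toy_model_1node(c(1, -1))
  expect_equal(unname(encode(tm, c(1, 0))), stats::plogis(1),
               tolerance = 1e-15)
  ## decoder uses the transposed weights plus its own bias
  tm$b_dec[[1]] <- c(0.2, -0.1)
  z <- 0.7
  expect_equal(unname(decode(tm, z)),
               stats::plogis(c(1, -1) * z + c(0.2, -0.1)), tolerance = 1e-15)

  ## outputs stay strictly inside (0,1); dimension mismatches error
  m <- build_dae(dae_architecture(c(8), 4), 12, seed = 2)
  z <- encode(m, matrix(runif(36), 3, 12))
  expect_true(all(z > 0 & z < 1))
  y <- decode(m, z)
  expect_true(all(y > 0 & y < 1))
  expect_error(encode(m, rep(0.5, 11)), "expected 12")
  expect_error(decode(m, rep(0.5, 3)), "expected 4")
})

test_that("corruption zeroes an exact per-sample count", {
  X <- matrix(runif(10 * 43, min = 0.1), 10, 43)
  expect_identical(corrupt(X, 0), X)
  set.seed(1)
  Xc <- corrupt(X, 0.1)
  expect_identical(rowSums(Xc == 0), rep(4, 10))     # round(0.1 * 43)

  ## positions are uniform: each zeroed at frequency ~ fraction
  set.seed(2)
  counts <- Reduce(`+`, replicate(400, corrupt(X[1, , drop = FALSE],
                                               0.2) == 0,
                                  simplify = FALSE))
  hits <- as.vector(counts) / 400
  expect_true(all(abs(hits - round(0.2 * 43) / 43) < 0.08))
})

test_that("splits have the stated sizes and [0,1] scaling per split", {
  sim <- generate_compendium(sim_config(n_genes = 30, n_experiments = 100,
                                        n_modules = 2,
                                        module_size_range = c(5, 6),
                                        seed = 4))
  cfg <- train_config(seed = 4, scaling = "global")
  sp <- split_and_scale(sim$compendium, cfg)
  expect_identical(c(nrow(sp$train), nrow(sp$val), nrow(sp$test)),
                   c(80L, 10L, 10L))
  for (M in list(sp$train, sp$val, sp$test)) {
    expect_equal(min(M), 0)
    expect_equal(max(M), 1)
  }

  ## per-gene scaling: every non-constant gene column spans [0,1]
  cfgp <- train_config(seed = 4, scaling = "per_gene")
  spp <- split_and_scale(sim$compendium, cfgp)
  expect_equal(unname(apply(spp$train, 2, min)), rep(0, 30))
  expect_equal(unname(apply(spp$train, 2, max)), rep(1, 30))

  ## constant gene row scales to zero, not NaN
  V <- sim$compendium$values; V["g0001", ] <- 5
  compc <- expression_compendium(V, sim$compendium$condition_labels)
  spc <- split_and_scale(compc, cfgp)
  expect_identical(unname(spc$train[, "g0001"]), rep(0, 80))

  tiny <- expression_compendium(
    matrix(runif(12), 3, 4, dimnames = list(paste0("g", 1:3),
                                            paste0("e", 1:4))),
    rep("c", 4))
  expect_error(split_and_scale(tiny, cfg), "non-empty")
})

test_that("backprop gradients match finite differences of the public loss", {
  set.seed(42)
  m <- build_dae(dae_architecture(c(4), 3), 6, seed = 9)
  X <- matrix(runif(30), 5, 6)
  fb <- daeprobe:::dae_forward_backward(m, X, X)
  loss_of <- function(model) mean((decode(model, encode(model, X)) - X)^2)

  eps <- 1e-6
  for (l in seq_along(m$W)) {
    for (idx in sample(length(m$W[[l]]), 5)) {
      up <- m; up$W[[l]][idx] <- up$W[[l]][idx] + eps
      dn <- m; dn$W[[l]][idx] <- dn$W[[l]][idx] - eps
      num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      expect_equal(fb$gW[[l]][idx], num, tolerance = 1e-6)
    }
  }
  for (l in seq_along(m$b_dec)) {
    for (idx in seq_along(m$b_dec[[l]])) {
      up <- m; up$b_dec[[l]][idx] <- up$b_dec[[l]][idx] + eps
      dn <- m; dn$b_dec[[l]][idx] <- dn$b_dec[[l]][idx] - eps
      num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      expect_equal(fb$gbd[[l]][idx], num, tolerance = 1e-6)
    }
  }
})

test_that("training reduces loss, stops on patience, restores best weights", {
  sim <- generate_compendium(sim_config(n_genes = 60, n_experiments = 40,
                                        n_modules = 3, seed = 2))
  cfg <- train_config(max_epochs = 60, patience = 10, seed = 3)
  sp <- split_and_scale(sim$compendium, cfg)
  m0 <- build_dae(parse_architecture("20-5"), 60, seed = 3)
  before <- reconstruction_loss(m0, sp$test)
  m <- train_dae(m0, sp, cfg)
  expect_lt(m$training$test_loss, before)
  expect_identical(m$training$test_loss, reconstruction_loss(m, sp$test))
  expect_lte(m$training$best_epoch, m$training$stopped_epoch)
  ## restored weights reproduce the best validation loss
  expect_equal(reconstruction_loss(m, sp$val),
               min(m$training$val_loss), tolerance = 1e-12)

  ## patience 0: stops at the first epoch that fails to improve
  cfg0 <- train_config(max_epochs = 60, patience = 0, seed = 3)
  mp <- train_dae(build_dae(parse_architecture("20-5"), 60, seed = 3),
                  sp, cfg0)
  expect_identical(mp$training$stopped_epoch,
                   mp$training$best_epoch + 1L)
})

test_that("training on permuted data cannot beat the original", {
  sim <- generate_compendium(sim_config(n_genes = 60, n_experiments = 40,
                                        n_modules = 3, seed = 2))
  cfg <- train_config(max_epochs = 150, patience = 25, seed = 5)
  sp_real <- split_and_scale(sim$compendium, cfg)
  m_real <- train_dae(build_dae(parse_architecture("15-4"), 60, 5),
                      sp_real, cfg)
  perm <- permute_compendium(sim$compendium, seed = 5)
  sp_perm <- split_and_scale(perm, cfg)
  m_perm <- train_dae(build_dae(parse_architecture("15-4"), 60, 5),
                      sp_perm, cfg)
  expect_gte(m_perm$training$test_loss, m_real$training$test_loss)
})

test_that("ensembles keep the pooled node count and distinct member seeds", {
  expect_identical(ensemble_size(5000, 50), 100L)
  expect_identical(ensemble_size(5000, 25), 200L)
  expect_identical(ensemble_size(5000, 5000), 1L)
  expect_error(ensemble_size(10, 50), "at least")

  ens <- mini_ensemble()
  expect_identical(ens$total_bottleneck_nodes,
                   length(ens$models) * ens$architecture$bottleneck)
  seeds <- vapply(ens$models, `[[`, 0L, "seed")
  expect_identical(seeds, ens$base_seed + seq_along(ens$models))
  ## members differ (independent inits and splits)
  expect_false(identical(ens$models[[1]]$W, ens$models[[2]]$W))
})

test_that("model and ensemble archives round-trip bit-exactly", {
  ens <- mini_ensemble()
  m <- ens$models[[1]]
  dir <- withr::local_tempdir()
  save_dae(m, file.path(dir, "m"))
  back <- load_dae(file.path(dir, "m"))
  expect_identical(back$W, m$W)
  expect_identical(back$b_enc, m$b_enc)
  expect_identical(back$b_dec, m$b_dec)
  expect_identical(back$gene_ids, m$gene_ids)
  expect_equal(back$scaling$min, m$scaling$min, tolerance = 0)

  save_ensemble(ens, file.path(dir, "ens"))
  eback <- load_ensemble(file.path(dir, "ens"))
  expect_identical(length(eback$models), length(ens$models))
  expect_identical(eback$models[[2]]$W, ens$models[[2]]$W)
  ## a reloaded model encodes identically
  x <- matrix(runif(2 * m$input_dim), 2)
  expect_identical(encode(back, x), encode(m, x))
})

test_that("the linear identity surrogate inverts exactly", {
  m <- build_dae(dae_architecture(integer(0), 4), 4, seed = 1)
  m$W[[1]] <- diag(4)
  lin <- linear_surrogate(m)
  x <- runif(4)
  expect_identical(decode(lin, encode(lin, x)), x)
})
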