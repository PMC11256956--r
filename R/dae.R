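## Tied-weight denoising autoencoders.
##
## The decoder never owns weight matrices: layer m of the decoder applies
## t(W[[L + 1 - m]]), the transpose of the mirrored encoder matrix, at all
## times. Only the biases of the decoder are free parameters. Gradients for
## each W therefore accumulate from both its encoder and its decoder use.

#' Network architecture
#'
#' Architectures are written in the compact notation `N1-N2-...-(NB)`: the
#' hidden encoder widths followed by the bottleneck width in parentheses.
#' The decoder mirrors the encoder. All layers use sigmoid activations by
#' default; hidden layers (everything except bottleneck and output) can use
#' ReLU instead.
#'
#' @param encoder_widths integer vector of hidden encoder widths, outermost
#'   first; may be empty for a shallow (input -> bottleneck) network.
#' @param bottleneck bottleneck width, >= 1.
#' @param hidden_activation `"sigmoid"` (default) or `"relu"` for the hidden
#'   layers; bottleneck and output are always sigmoid.
#' @return A `dae_architecture` object.
#' @examples
#' dae_architecture(c(100), 10)
#' parse_architecture("2000-1000-50")
#' @export
dae_architecture <- function(encoder_widths = integer(0), bottleneck,
                             hidden_activation = c("sigmoid", "relu")) {
  hidden_activation <- match.arg(hidden_activation)
  encoder_widths <- as.integer(encoder_widths)
  bottleneck <- as.integer(bottleneck)
  if (any(encoder_widths < 1L) || bottleneck < 1L)
    stop("all layer widths must be >= 1")
  structure(list(encoder_widths = encoder_widths,
                 bottleneck = bottleneck,
                 hidden_activation = hidden_activation),
            class = "dae_architecture")
}

#' @rdname dae_architecture
#' @param spec string such as `"2000-1000-50"` or `"2000-1000-(50)"`; the
#'   last element is the bottleneck width.
#' @export
parse_architecture <- function(spec, hidden_activation = c("sigmoid", "relu")) {
  parts <- strsplit(gsub("[()—–]", "-", spec), "-+")[[1]]
  parts <- parts[nzchar(parts)]
  widths <- suppressWarnings(as.integer(parts))
  if (length(widths) == 0L || anyNA(widths))
    stop(sprintf("cannot parse architecture string '%s'", spec))
  dae_architecture(widths[-length(widths)], widths[length(widths)],
                   match.arg(hidden_activation))
}

#' @export
format.dae_architecture <- function(x, ...) {
  paste0(paste(c(x$encoder_widths, sprintf("(%d)", x$bottleneck)),
               collapse = "-"),
         if (x$hidden_activation == "relu") " [ReLU]" else "")
}

#' @export
print.dae_architecture <- function(x, ...) {
  cat("dae_architecture:", format(x), "\n"); invisible(x)
}

## layer widths of the full encoder given the input dimension
encoder_dims <- function(arch, input_dim)
  c(input_dim, arch$encoder_widths, arch$bottleneck)

act_fun <- function(kind) switch(kind,
  sigmoid = stats::plogis,
  relu = function(x) pmax(x, 0),
  linear = identity)

## derivative expressed through the activation value a (sigmoid) or the
## pre-activation sign (relu, where a == s on the active side)
act_grad <- function(kind) switch(kind,
  sigmoid = function(a) a * (1 - a),
  relu = function(a) (a > 0) + 0,
  linear = function(a) 1)

## activation kinds per encoder layer 1..L (L = bottleneck layer)
encoder_acts <- function(arch) {
  k <- length(arch$encoder_widths)
  if (isTRUE(arch$linear)) return(rep("linear", k + 1L))
  c(rep(arch$hidden_activation, k), "sigmoid")
}

## activation kinds per decoder layer 1..L (L = output layer)
decoder_acts <- function(arch) encoder_acts(arch)

#' Linear surrogate of a model (validation hook)
#'
#' Returns a copy of the model with every activation replaced by the
#' identity, keeping weights and biases. In this surrogate node responses
#' are exactly additive (the linearity score is 0 by construction), and a
#' square identity-weight model satisfies `decode(encode(x)) == x`; both
#' serve as closed-form oracles for the probing machinery.
#'
#' @param model a `dae_model`.
#' @return The surrogate `dae_model`.
#' @export
linear_surrogate <- function(model) {
  stopifnot(inherits(model, "dae_model"))
  model$architecture$linear <- TRUE
  model
}

#' Build an untrained DAE
#'
#' Weight matrices are drawn from the Glorot (Xavier) uniform distribution,
#' `U(-b, b)` with `b = sqrt(6 / (fan_in + fan_out))` per matrix; all bias
#' vectors start at zero. The decoder's weight matrices are tied to the
#' encoder's (transposes, in reverse order) and are never materialised.
#'
#' @param arch a [dae_architecture()].
#' @param input_dim number of genes (input/output width).
#' @param seed integer seed; construction is deterministic given the seed.
#' @return A `dae_model` object.
#' @export
build_dae <- function(arch, input_dim, seed = 1L) {
  stopifnot(inherits(arch, "dae_architecture"), input_dim >= 1L)
  set.seed(as.integer(seed))
  dims <- encoder_dims(arch, as.integer(input_dim))
  L <- length(dims) - 1L
  W <- vector("list", L); b_enc <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    bound <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -bound, bound),
                     fan_in, fan_out)
    b_enc[[l]] <- numeric(fan_out)
  }
  dec_widths <- rev(dims)[-1L]              # N_k ... N_1, input_dim
  b_dec <- lapply(dec_widths, numeric)
  structure(list(architecture = arch, input_dim = as.integer(input_dim),
                 W = W, b_enc = b_enc, b_dec = b_dec,
                 seed = as.integer(seed), gene_ids = NULL,
                 scaling = NULL, training = NULL),
            class = "dae_model")
}

#' @export
print.dae_model <- function(x, ...) {
  cat(sprintf("dae_model: %d -> %s%s\n", x$input_dim, format(x$architecture),
              if (is.null(x$training)) " (untrained)"
              else sprintf(" (trained, test loss %.4g)", x$training$test_loss)))
  invisible(x)
}

as_sample_matrix <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != width)
    stop(sprintf("%s: expected %d columns, got %d", what, width, ncol(x)))
  x
}

#' Encode expression vectors to bottleneck activations
#'
#' @param model a `dae_model`.
#' @param x numeric vector of length `input_dim`, or a matrix with samples
#'   in rows, on the [0,1] scaled-logTPM scale of the model's training split.
#' @return Matrix of bottleneck activations (samples x bottleneck), in
#'   (0,1) since the bottleneck is sigmoid; a vector input yields a vector.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "dae_model"))
  vec <- is.null(dim(x))
  A <- as_sample_matrix(x, model$input_dim, "encode")
  acts <- encoder_acts(model$architecture)
  for (l in seq_along(model$W))
    A <- act_fun(acts[l])(sweep(A %*% model$W[[l]], 2, model$b_enc[[l]], "+"))
  if (vec) drop(A) else A
}

#' Decode bottleneck activations to reconstructed expression
#'
#' Applies the transposed encoder matrices in reverse order with the
#' decoder's own biases.
#'
#' @param model a `dae_model`.
#' @param z numeric vector of length `bottleneck`, or a matrix with samples
#'   in rows.
#' @return Reconstructed expression on the [0,1] scale (samples x genes);
#'   a vector input yields a vector.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "dae_model"))
  vec <- is.null(dim(z))
  H <- as_sample_matrix(z, model$architecture$bottleneck, "decode")
  L <- length(model$W)
  acts <- decoder_acts(model$architecture)
  for (m in seq_len(L)) {
    H <- act_fun(acts[m])(
      sweep(H %*% t(model$W[[L + 1L - m]]), 2, model$b_dec[[m]], "+"))
  }
  if (vec) drop(H) else H
}

#' Corrupt a batch by zero-masking
#'
#' For each sample independently, exactly `round(fraction * ncol)` entries
#' chosen uniformly without replacement are set to zero. The mask is drawn
#' from the current RNG state, so it is resampled at every training step.
#'
#' @param batch matrix, samples in rows.
#' @param fraction fraction of entries to zero, in [0, 1).
#' @return The corrupted batch.
#' @export
corrupt <- function(batch, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  k <- round(fraction * ncol(batch))
  if (k == 0L) return(batch)
  for (i in seq_len(nrow(batch)))
    batch[i, sample.int(ncol(batch), k)] <- 0
  batch
}

#' Training configuration
#'
#' @param corruption_fraction fraction of entries zeroed per training step.
#' @param split_fractions train/validation/test fractions, summing to 1.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation improvement before stopping;
#'   the best-validation weights are restored.
#' @param scaling `"per_gene"` (per-gene min-max within each split,
#'   default) or `"global"` (one min-max per split). Per-gene scaling
#'   equalises the dynamic range across genes; without it, deep sigmoid
#'   networks tend to stall in a mean-reconstruction plateau.
#' @param seed base seed for splitting, shuffling and corruption.
#' @return A `train_config` list.
#' @export
train_config <- function(corruption_fraction = 0.1,
                         split_fractions = c(0.8, 0.1, 0.1),
                         learning_rate = 3e-3, batch_size = 32L,
                         max_epochs = 1000L, patience = 60L,
                         scaling = c("per_gene", "global"),
                         seed = 1L) {
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split_fractions must sum to 1")
  if (corruption_fraction < 0 || corruption_fraction >= 1)
    stop("corruption_fraction must be in [0, 1)")
  structure(list(corruption_fraction = corruption_fraction,
                 split_fractions = split_fractions,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 scaling = match.arg(scaling),
                 seed = as.integer(seed)),
            class = "train_config")
}

scale_minmax <- function(X, method) {
  ## X: samples x genes
  if (method == "global") {
    mn <- min(X); mx <- max(X)
    rng <- mx - mn
    list(scaled = if (rng > 0) (X - mn) / rng else X * 0,
         record = list(method = "global", min = mn, max = mx))
  } else {
    ## positional record, in the gene order of the matrix / model
    mn <- unname(apply(X, 2, min)); mx <- unname(apply(X, 2, max))
    rng <- mx - mn
    sc <- sweep(X, 2, mn, "-")
    sc <- sweep(sc, 2, ifelse(rng > 0, rng, 1), "/")
    sc[, rng == 0] <- 0
    list(scaled = sc,
         record = list(method = "per_gene", min = mn, max = mx))
  }
}

#' Apply a stored min-max scaling record
#'
#' Used to put external experiments on the [0,1] scale a model was trained
#' on (each model only understands its own input scale). `inverse = TRUE`
#' maps scaled values (or scaled differences, with `delta = TRUE`) back to
#' logTPM.
#'
#' @param X matrix, samples in rows, genes in columns (in the model's gene
#'   order).
#' @param record a scaling record as stored in `model$scaling`.
#' @param inverse apply the inverse transform.
#' @param delta treat `X` as differences (no offset in the inverse).
#' @return The transformed matrix.
#' @export
apply_scaling <- function(X, record, inverse = FALSE, delta = FALSE) {
  rng <- record$max - record$min
  if (record$method == "global") {
    if (inverse) {
      if (delta) X * rng else X * rng + record$min
    } else {
      if (rng > 0) (X - record$min) / rng else X * 0
    }
  } else {
    r <- ifelse(rng > 0, rng, if (inverse) 0 else 1)
    if (inverse) {
      out <- sweep(X, 2, r, "*")
      if (!delta) out <- sweep(out, 2, record$min, "+")
      out
    } else {
      out <- sweep(sweep(X, 2, record$min, "-"), 2, r, "/")
      out[, rng == 0] <- 0
      out
    }
  }
}

#' Split a compendium and scale each split to [0, 1]
#'
#' Experiments are randomly partitioned into train/validation/test by the
#' configured fractions, then logTPM values are min-max scaled to [0, 1]
#' independently within each split (globally over the split by default,
#' optionally per gene).
#'
#' @param comp an [expression_compendium()].
#' @param cfg a [train_config()]; `cfg$seed` drives the partition.
#' @return List with matrices `train`, `val`, `test` (samples x genes),
#'   split `indices`, per-split `scaling` records, and `gene_ids`.
#' @export
split_and_scale <- function(comp, cfg) {
  stopifnot(inherits(comp, "expression_compendium"),
            inherits(cfg, "train_config"))
  n <- ncol(comp$values)
  n_train <- round(cfg$split_fractions[1] * n)
  n_val <- round(cfg$split_fractions[2] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop(sprintf("%d experiments cannot fill non-empty %s splits", n,
                 paste(cfg$split_fractions, collapse = "/")))
  set.seed(cfg$seed)
  perm <- sample.int(n)
  idx <- list(train = sort(perm[seq_len(n_train)]),
              val = sort(perm[n_train + seq_len(n_val)]),
              test = sort(perm[n_train + n_val + seq_len(n_test)]))
  out <- lapply(idx, function(i) scale_minmax(t(comp$values[, i, drop = FALSE]),
                                              cfg$scaling))
  list(train = out$train$scaled, val = out$val$scaled, test = out$test$scaled,
       indices = idx,
       scaling = list(train = out$train$record, val = out$val$record,
                      test = out$test$record),
       gene_ids = comp$gene_ids)
}

mse <- function(A, B) mean((A - B)^2)

## one forward/backward pass: reconstruct `input`, score against `target`.
## Returns the MSE loss and gradients for W (summing the encoder and the
## transposed-decoder contributions of each tied matrix), b_enc and b_dec.
dae_forward_backward <- function(model, input, target) {
  arch <- model$architecture
  L <- length(model$W)
  enc_f <- lapply(encoder_acts(arch), act_fun)
  dec_f <- lapply(decoder_acts(arch), act_fun)
  enc_g <- lapply(encoder_acts(arch), act_grad)
  dec_g <- lapply(decoder_acts(arch), act_grad)

  A <- vector("list", L + 1L)
  A[[1L]] <- input
  for (l in seq_len(L))
    A[[l + 1L]] <- enc_f[[l]](
      sweep(A[[l]] %*% model$W[[l]], 2, model$b_enc[[l]], "+"))
  H <- vector("list", L + 1L)
  H[[1L]] <- A[[L + 1L]]
  for (m in seq_len(L))
    H[[m + 1L]] <- dec_f[[m]](
      sweep(H[[m]] %*% t(model$W[[L + 1L - m]]), 2, model$b_dec[[m]], "+"))
  out <- H[[L + 1L]]
  loss <- mse(out, target)

  gW <- lapply(model$W, function(w) w * 0)
  gbe <- lapply(model$b_enc, function(b) b * 0)
  gbd <- lapply(model$b_dec, function(b) b * 0)
  dH <- 2 * (out - target) / length(out)
  for (m in rev(seq_len(L))) {
    j <- L + 1L - m
    G <- dH * dec_g[[m]](H[[m + 1L]])
    gW[[j]] <- gW[[j]] + t(G) %*% H[[m]]
    gbd[[m]] <- gbd[[m]] + colSums(G)
    dH <- G %*% model$W[[j]]
  }
  dA <- dH
  for (l in rev(seq_len(L))) {
    G <- dA * enc_g[[l]](A[[l + 1L]])
    gW[[l]] <- gW[[l]] + t(A[[l]]) %*% G
    gbe[[l]] <- gbe[[l]] + colSums(G)
    dA <- G %*% t(model$W[[l]])
  }
  list(loss = loss, gW = gW, gbe = gbe, gbd = gbd)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

#' Train a DAE on scaled splits
#'
#' Minimises the mean squared reconstruction error between
#' `decode(encode(corrupt(x)))` and the clean `x` with the Adam optimiser,
#' shuffling batches every epoch and resampling the corruption mask at
#' every step. Training stops when the validation loss (clean
#' reconstruction) fails to improve for `patience` consecutive epochs; the
#' best-validation weights are restored. The tied-weight constraint is
#' maintained exactly: each encoder matrix receives gradient from both its
#' encoder and its (transposed) decoder application.
#'
#' @param model an untrained (or pre-trained) `dae_model`.
#' @param splits output of [split_and_scale()].
#' @param cfg a [train_config()].
#' @return The trained `dae_model`, with `training` holding the loss
#'   trajectories, stopping epoch and final test loss, `gene_ids` and
#'   `scaling` (the training split's record) attached.
#' @export
train_dae <- function(model, splits, cfg) {
  stopifnot(inherits(model, "dae_model"), inherits(cfg, "train_config"))
  L <- length(model$W)

  X <- splits$train
  n_train <- nrow(X)
  set.seed(cfg$seed)

  params <- c(model$W, model$b_enc, model$b_dec)
  opt <- adam_init(params)
  lr <- cfg$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  best <- list(loss = Inf, W = model$W, b_enc = model$b_enc,
               b_dec = model$b_dec, epoch = 0L)
  wait <- 0L
  train_trace <- numeric(0); val_trace <- numeric(0)

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n_train)
    batch_starts <- seq(1L, n_train, by = cfg$batch_size)
    epoch_loss <- 0; n_seen <- 0L
    for (s in batch_starts) {
      rows <- perm[s:min(s + cfg$batch_size - 1L, n_train)]
      clean <- X[rows, , drop = FALSE]
      nb <- nrow(clean)

      fb <- dae_forward_backward(model, corrupt(clean, cfg$corruption_fraction),
                                 clean)
      if (!is.finite(fb$loss))
        stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate",
                     epoch))
      epoch_loss <- epoch_loss + fb$loss * nb; n_seen <- n_seen + nb

      ## Adam step over the flattened parameter list
      grads <- c(fb$gW, fb$gbe, fb$gbd)
      params <- c(model$W, model$b_enc, model$b_dec)
      opt$t <- opt$t + 1L
      corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
      for (p in seq_along(params)) {
        opt$m[[p]] <- b1 * opt$m[[p]] + (1 - b1) * grads[[p]]
        opt$v[[p]] <- b2 * opt$v[[p]] + (1 - b2) * grads[[p]]^2
        params[[p]] <- params[[p]] -
          lr * (opt$m[[p]] / corr1) / (sqrt(opt$v[[p]] / corr2) + eps)
      }
      model$W <- params[seq_len(L)]
      model$b_enc <- params[L + seq_len(L)]
      model$b_dec <- params[2L * L + seq_len(L)]
    }
    train_trace[epoch] <- epoch_loss / n_seen
    val_loss <- mse(decode(model, encode(model, splits$val)), splits$val)
    val_trace[epoch] <- val_loss

    if (val_loss < best$loss) {
      best <- list(loss = val_loss, W = model$W, b_enc = model$b_enc,
                   b_dec = model$b_dec, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$patience) break
    }
  }

  ## weights are positional; drop dimnames picked up from the data matrix
  model$W <- lapply(best$W, unname)
  model$b_enc <- lapply(best$b_enc, unname)
  model$b_dec <- lapply(best$b_dec, unname)
  test_loss <- mse(decode(model, encode(model, splits$test)), splits$test)
  model$training <- list(train_loss = train_trace, val_loss = val_trace,
                         best_epoch = best$epoch,
                         stopped_epoch = length(train_trace),
                         test_loss = test_loss)
  model$gene_ids <- splits$gene_ids
  model$scaling <- splits$scaling$train
  model
}

#' Reconstruction loss of a model on a scaled matrix
#'
#' @param model a `dae_model`.
#' @param X scaled matrix, samples in rows.
#' @return Mean squared reconstruction error.
#' @export
reconstruction_loss <- function(model, X) {
  X <- as_sample_matrix(X, model$input_dim, "reconstruction_loss")
  mse(decode(model, encode(model, X)), X)
}

#' Networks needed to keep a fixed total of bottleneck nodes
#'
#' When the bottleneck width changes, the ensemble is resized so the pooled
#' number of probe nodes stays constant (e.g. 5000 nodes: 100 networks of
#' 50, or 200 networks of 25).
#'
#' @param total_nodes pooled bottleneck nodes across the ensemble.
#' @param bottleneck nodes per network.
#' @return Number of networks, `round(total_nodes / bottleneck)`.
#' @export
ensemble_size <- function(total_nodes, bottleneck) {
  if (total_nodes < bottleneck)
    stop("total_nodes must be at least the bottleneck width")
  as.integer(round(total_nodes / bottleneck))
}

#' Train an ensemble of DAEs
#'
#' Trains `round(total_nodes / bottleneck)` networks (or `n_models` if
#' given) with member seeds `cfg$seed + 1, cfg$seed + 2, ...`; each member
#' draws its own data split, initialisation, shuffling and corruption
#' stream from its seed.
#'
#' @param arch a [dae_architecture()].
#' @param comp an [expression_compendium()].
#' @param cfg a [train_config()]; `cfg$seed` is the ensemble base seed.
#' @param total_nodes target pooled bottleneck nodes (default 5000).
#' @param n_models explicit member count, overriding `total_nodes`.
#' @param verbose print per-member progress.
#' @return A `dae_ensemble`: list of trained models plus bookkeeping.
#' @export
train_ensemble <- function(arch, comp, cfg, total_nodes = 5000L,
                           n_models = NULL, verbose = FALSE) {
  stopifnot(inherits(arch, "dae_architecture"),
            inherits(comp, "expression_compendium"))
  n <- if (is.null(n_models)) ensemble_size(total_nodes, arch$bottleneck)
       else as.integer(n_models)
  models <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    splits <- split_and_scale(comp, cfg_i)
    model <- build_dae(arch, nrow(comp$values), seed = cfg_i$seed)
    model <- train_dae(model, splits, cfg_i)
    models[[i]] <- model
    if (verbose)
      message(sprintf("  network %d/%d: stopped at epoch %d, test loss %.5f",
                      i, n, model$training$stopped_epoch,
                      model$training$test_loss))
  }
  structure(list(models = models, architecture = arch,
                 total_bottleneck_nodes = n * arch$bottleneck,
                 base_seed = cfg$seed),
            class = "dae_ensemble")
}

#' @export
print.dae_ensemble <- function(x, ...) {
  cat(sprintf("dae_ensemble: %d x %s = %d probe nodes\n",
              length(x$models), format(x$architecture),
              x$total_bottleneck_nodes))
  invisible(x)
}

## ---- serialization --------------------------------------------------------
## A model archive is a directory: model.json (architecture, metadata,
## array shapes) + weights.bin (little-endian doubles in the order W,
## b_enc, b_dec). Binary doubles make the round trip bit-exact.

#' Save / load a DAE model archive
#'
#' @param model a `dae_model`.
#' @param path directory to write (created if needed).
#' @return `save_dae` returns `path` invisibly; `load_dae` the model.
#' @export
save_dae <- function(model, path) {
  stopifnot(inherits(model, "dae_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    architecture = list(encoder_widths = model$architecture$encoder_widths,
                        bottleneck = model$architecture$bottleneck,
                        hidden_activation = model$architecture$hidden_activation),
    input_dim = model$input_dim, seed = model$seed,
    gene_ids = model$gene_ids,
    scaling = if (!is.null(model$scaling))
      list(method = model$scaling$method, n = length(model$scaling$min)),
    training = model$training,
    shapes = list(W = lapply(model$W, dim),
                  b_enc = lapply(model$b_enc, length),
                  b_dec = lapply(model$b_dec, length)))
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  ## all numeric payload goes into the binary file so the round trip is
  ## bit-exact (JSON text representation can drop the last bit)
  con <- file(file.path(path, "weights.bin"), "wb")
  on.exit(close(con))
  payload <- c(model$W, model$b_enc, model$b_dec)
  if (!is.null(model$scaling))
    payload <- c(payload, list(model$scaling$min, model$scaling$max))
  for (w in payload)
    writeBin(as.numeric(w), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_dae
#' @export
load_dae <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  arch <- dae_architecture(meta$architecture$encoder_widths,
                           meta$architecture$bottleneck,
                           meta$architecture$hidden_activation)
  ## array shapes are fully determined by the architecture
  dims <- encoder_dims(arch, as.integer(meta$input_dim))
  L <- length(dims) - 1L
  shapes_W <- lapply(seq_len(L), function(l) c(dims[l], dims[l + 1L]))
  n_W <- vapply(shapes_W, prod, 0)
  n_be <- dims[-1L]
  n_bd <- rev(dims)[-1L]
  n_scal <- if (is.null(meta$scaling)) 0L else 2L * meta$scaling$n
  con <- file(file.path(path, "weights.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric",
                 n = sum(n_W) + sum(n_be) + sum(n_bd) + n_scal,
                 size = 8L, endian = "little")
  pos <- 0L
  take <- function(n) {
    out <- raw[pos + seq_len(n)]; pos <<- pos + as.integer(n); out
  }
  W <- lapply(shapes_W, function(d) matrix(take(prod(d)), d[1], d[2]))
  b_enc <- lapply(n_be, take)
  b_dec <- lapply(n_bd, take)
  scaling <- NULL
  if (!is.null(meta$scaling))
    scaling <- list(method = meta$scaling$method,
                    min = take(meta$scaling$n), max = take(meta$scaling$n))
  training <- meta$training
  if (!is.null(training))
    training[c("best_epoch", "stopped_epoch")] <-
      lapply(training[c("best_epoch", "stopped_epoch")], as.integer)
  structure(list(architecture = arch, input_dim = as.integer(meta$input_dim),
                 W = W, b_enc = b_enc, b_dec = b_dec,
                 seed = as.integer(meta$seed),
                 gene_ids = meta$gene_ids, scaling = scaling,
                 training = training),
            class = "dae_model")
}

#' Save / load an ensemble archive
#'
#' One subdirectory per member (`model_001`, ...) plus an `ensemble.json`
#' manifest.
#'
#' @param ensemble a `dae_ensemble`.
#' @param path directory to write.
#' @return `save_ensemble` returns `path` invisibly; `load_ensemble` the
#'   ensemble.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "dae_ensemble"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$models))
    save_dae(ensemble$models[[i]], file.path(path, sprintf("model_%03d", i)))
  jsonlite::write_json(
    list(n_models = length(ensemble$models),
         base_seed = ensemble$base_seed,
         architecture = list(
           encoder_widths = ensemble$architecture$encoder_widths,
           bottleneck = ensemble$architecture$bottleneck,
           hidden_activation = ensemble$architecture$hidden_activation)),
    file.path(path, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "ensemble.json"),
                              simplifyVector = TRUE)
  arch <- dae_architecture(meta$architecture$encoder_widths,
                           meta$architecture$bottleneck,
                           meta$architecture$hidden_activation)
  models <- lapply(seq_len(meta$n_models), function(i)
    load_dae(file.path(path, sprintf("model_%03d", i))))
  structure(list(models = models, architecture = arch,
                 total_bottleneck_nodes = length(models) * arch$bottleneck,
                 base_seed = as.integer(meta$base_seed)),
            class = "dae_ensemble")
}
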