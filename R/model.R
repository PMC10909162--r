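#' Configuration of the compact transformer encoder
#'
#' The architecture follows the standard BERT recipe (learned position and
#' segment embeddings, post-layer-norm residual blocks, GELU feed-forward,
#' bidirectional multi-head self-attention); only the sizes are exposed.
#' The reference full-scale stack has 12 layers; the desk-scale default used
#' throughout this package is 2 layers of width 64.
#'
#' @param vocab_size number of token embedding rows.
#' @param num_layers number of encoder layers.
#' @param hidden_dim hidden width (must be divisible by `num_heads`).
#' @param num_heads number of attention heads.
#' @param feedforward_dim width of the position-wise feed-forward layer.
#' @param max_position maximum sequence length (learned position rows).
#' @param dropout dropout probability in \[0, 1) applied during training.
#' @param init_std standard deviation of the normal initializer.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(vocab_size, num_layers = 2L, hidden_dim = 64L,
                         num_heads = 4L, feedforward_dim = 256L,
                         max_position = 128L, dropout = 0.0,
                         init_std = 0.02, seed = 1L) {
  dims <- c(vocab_size, num_layers, hidden_dim, num_heads, feedforward_dim,
            max_position)
  if (any(dims < 1)) stop("all model dimensions must be positive")
  if (hidden_dim %% num_heads != 0) {
    stop(sprintf("hidden_dim (%d) must be divisible by num_heads (%d)",
                 hidden_dim, num_heads))
  }
  if (vocab_size < length(SPECIAL_TOKENS)) {
    stop("vocab_size smaller than the number of special tokens")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (init_std <= 0) stop("init_std must be positive")
  structure(list(vocab_size = as.integer(vocab_size),
                 num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 num_heads = as.integer(num_heads),
                 feedforward_dim = as.integer(feedforward_dim),
                 max_position = as.integer(max_position),
                 dropout = dropout, init_std = init_std,
                 seed = as.integer(seed)),
            class = "model_config")
}

rmat <- function(nr, nc, std) matrix(stats::rnorm(nr * nc, sd = std), nr, nc)

#' Initialize a model
#'
#' All weights are drawn from a seeded normal generator with spread
#' `init_std` (layer-norm gains start at 1, biases at 0), so two calls with
#' the same seed produce bit-identical parameters.
#'
#' @param config a `model_config`.
#' @return An object of class `pb_model` with elements `config` and `params`.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  H <- config$hidden_dim
  FF <- config$feedforward_dim
  V <- config$vocab_size
  with_preserved_rng({
    set.seed(config$seed)
    std <- config$init_std
    layers <- lapply(seq_len(config$num_layers), function(l) {
      list(Wq = rmat(H, H, std), bq = numeric(H),
           Wk = rmat(H, H, std), bk = numeric(H),
           Wv = rmat(H, H, std), bv = numeric(H),
           Wo = rmat(H, H, std), bo = numeric(H),
           ln1g = rep(1, H), ln1b = numeric(H),
           W1 = rmat(H, FF, std), b1 = numeric(FF),
           W2 = rmat(FF, H, std), b2 = numeric(H),
           ln2g = rep(1, H), ln2b = numeric(H))
    })
    params <- list(
      tok = rmat(V, H, std),
      pos = rmat(config$max_position, H, std),
      seg = rmat(2, H, std),
      ln_emb_g = rep(1, H), ln_emb_b = numeric(H),
      layers = layers,
      mlm_W = rmat(H, V, std), mlm_b = numeric(V),
      span_W = rmat(H, 2, std), span_b = numeric(2)
    )
    structure(list(config = config, params = params, cls_classes = NULL),
              class = "pb_model")
  })
}

#' @export
print.pb_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pb_model> %d layers, hidden %d, %d heads, vocab %d, max_position %d\n",
    cfg$num_layers, cfg$hidden_dim, cfg$num_heads, cfg$vocab_size,
    cfg$max_position))
  invisible(x)
}

# ---- parameter-tree utilities -------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, tree_map, f = f) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

#' Checksum of a model's parameters
#'
#' Serializes the parameter tree and hashes it; used to assert bit-identical
#' initialization and row preservation.
#'
#' @param x a `pb_model` or any parameter tree.
#' @return a character scalar.
#' @export
param_checksum <- function(x) {
  tree <- if (inherits(x, "pb_model")) x$params else x
  raw <- serialize(tree, connection = NULL, version = 3)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(raw, tmp)
  unname(tools::md5sum(tmp))
}

# ---- embedding resize ----------------------------------------------------

#' Grow the token-embedding table (and tied output head) to a new vocabulary
#'
#' The first `current` rows are preserved bit-identically. New rows are
#' initialized per strategy: `mean_of_subwords` sets each new keyword's row
#' to the mean of the embedding rows of its base-tokenizer sub-word pieces
#' (a warm start consistent with sub-word splits carrying the word's
#' distributed meaning); `random` draws seeded values with spread
#' `init_std`. The masked-token output head gains matching columns under the
#' same strategy.
#'
#' @param model a `pb_model`.
#' @param new_size target vocabulary size (>= current).
#' @param strategy "mean_of_subwords" or "random".
#' @param subword_ids for `mean_of_subwords`: list (one element per new row)
#'   of 0-based base-vocabulary ids of the keyword's sub-word pieces.
#'   [subword_ids_for_keywords()] computes this from a base vocabulary.
#' @param seed seed for the `random` strategy.
#' @return the resized `pb_model`.
#' @export
resize_token_embeddings <- function(model, new_size,
                                    strategy = c("mean_of_subwords", "random"),
                                    subword_ids = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  cur <- model$config$vocab_size
  if (new_size < cur) {
    stop(sprintf("shrinking the embedding table (%d -> %d) is unsupported",
                 cur, new_size))
  }
  if (new_size == cur) return(model)
  n_new <- new_size - cur
  H <- model$config$hidden_dim
  if (strategy == "mean_of_subwords") {
    if (is.null(subword_ids) || length(subword_ids) != n_new) {
      stop("mean_of_subwords needs one sub-word id set per new row")
    }
    new_rows <- t(vapply(subword_ids, function(ids) {
      stopifnot(all(ids >= 0 & ids < cur))
      colMeans(model$params$tok[ids + 1L, , drop = FALSE])
    }, numeric(H)))
    new_cols <- vapply(subword_ids, function(ids) {
      rowMeans(model$params$mlm_W[, ids + 1L, drop = FALSE])
    }, numeric(H))
    new_b <- vapply(subword_ids, function(ids) {
      mean(model$params$mlm_b[ids + 1L])
    }, numeric(1))
  } else {
    new_rows <- with_preserved_rng({
      set.seed(seed)
      rmat(n_new, H, model$config$init_std)
    })
    new_cols <- t(with_preserved_rng({
      set.seed(seed + 1L)
      rmat(n_new, H, model$config$init_std)
    }))
    new_b <- numeric(n_new)
  }
  model$params$tok <- rbind(model$params$tok, new_rows)
  model$params$mlm_W <- cbind(model$params$mlm_W, new_cols)
  model$params$mlm_b <- c(model$params$mlm_b, new_b)
  model$config$vocab_size <- as.integer(new_size)
  stopifnot(nrow(model$params$tok) == new_size)
  model
}

#' Base-tokenizer sub-word ids for new keywords
#'
#' @param base_vocab the base `wp_vocabulary` (before extension).
#' @param keywords character vector of the appended keywords, in id order.
#' @return list of 0-based integer id vectors, one per keyword.
#' @export
subword_ids_for_keywords <- function(base_vocab, keywords) {
  lapply(keywords, function(kw) {
    enc <- tokenize(kw, base_vocab)
    enc$ids
  })
}

# ---- Adam optimizer ------------------------------------------------------

adam_state <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_scale(state$m, 1 / bc1)
  vhat <- tree_scale(state$v, 1 / bc2)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

#' Training-loop hyperparameters
#'
#' @param epochs number of passes over the data.
#' @param batch_size examples per optimizer step.
#' @param lr Adam learning rate.
#' @param seed integer seed controlling shuffling and corruption draws.
#' @param freeze_encoder logical; update only the task head, leaving the
#'   encoder (embeddings and all transformer layers) fixed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 5L, batch_size = 16L, lr = 1e-3,
                         seed = 1L, freeze_encoder = FALSE) {
  stopifnot(epochs >= 0, batch_size >= 1, lr >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed),
                 freeze_encoder = isTRUE(freeze_encoder)),
            class = "train_config")
}

# zero the encoder part of a gradient tree (frozen-encoder mode)
freeze_encoder_grads <- function(grads) {
  for (nm in c("tok", "pos", "seg", "ln_emb_g", "ln_emb_b")) {
    grads[[nm]] <- grads[[nm]] * 0
  }
  grads$layers <- tree_zeros(grads$layers)
  grads$mlm_W <- grads$mlm_W * 0
  grads$mlm_b <- grads$mlm_b * 0
  grads
}

# ---- checkpointing -------------------------------------------------------

#' Save a self-describing model checkpoint
#'
#' Writes a directory holding the model configuration (JSON), the vocabulary
#' file, and the parameter arrays, so a checkpoint can be reloaded without
#' external context.
#'
#' @param model a `pb_model`.
#' @param vocab the `wp_vocabulary` the model was trained with.
#' @param dir output directory (created if needed).
#' @param added optional `wp_added_tokens`.
#' @export
save_checkpoint <- function(model, vocab, dir, added = wp_added_tokens()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(
    list(config = unclass(cfg), added = added$added,
         cls_classes = model$cls_classes),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  write_vocab(vocab, file.path(dir, "vocab.txt"))
  saveRDS(model$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param dir checkpoint directory.
#' @return list with elements `model`, `vocab`, `added`.
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  cfg <- do.call(model_config, meta$config)
  params <- readRDS(file.path(dir, "params.rds"))
  model <- structure(list(config = cfg, params = params,
                          cls_classes = unlist(meta$cls_classes)),
                     class = "pb_model")
  vocab <- load_vocab(file.path(dir, "vocab.txt"))
  list(model = model, vocab = vocab,
       added = wp_added_tokens(unlist(meta$added) %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
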