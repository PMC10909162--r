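test_that("model initialization is seeded and structurally correct", {
  cfg <- model_config(vocab_size = 40, num_layers = 2, hidden_dim = 32,
                      num_heads = 4, feedforward_dim = 64,
                      max_position = 24, seed = 7)
  m1 <- init_model(cfg)
  m2 <- init_model(cfg)
  expect_identical(param_checksum(m1), param_checksum(m2))
  expect_length(m1$params$layers, 2L)
  expect_equal(dim(m1$params$tok), c(40L, 32L))
  m3 <- init_model(model_config(vocab_size = 40, seed = 8,
                                hidden_dim = 32, max_position = 24))
  expect_false(identical(param_checksum(m1), param_checksum(m3)))
})

test_that("invalid model configurations are rejected", {
  expect_error(model_config(vocab_size = 40, hidden_dim = 65, num_heads = 8),
               "divisible")
  expect_error(model_config(vocab_size = 40, num_layers = 0), "positive")
  expect_error(model_config(vocab_size = 2), "special tokens")
  expect_error(model_config(vocab_size = 40, dropout = 1), "dropout")
})

test_that("embedding resize preserves existing rows bit-identically", {
  cfg <- model_config(vocab_size = 30, hidden_dim = 16, num_heads = 4,
                      feedforward_dim = 32, max_position = 16, seed = 2)
  m <- init_model(cfg)
  old_tok <- m$params$tok
  grown <- resize_token_embeddings(m, 33, strategy = "random", seed = 9)
  expect_equal(nrow(grown$params$tok), 33L)
  expect_identical(grown$params$tok[1:30, ], old_tok)
  expect_equal(ncol(grown$params$mlm_W), 33L)
  expect_equal(grown$config$vocab_size, 33L)
  # identity and shrink contracts
  expect_identical(resize_token_embeddings(m, 30), m)
  expect_error(resize_token_embeddings(m, 29), "unsupported")
})

test_that("mean_of_subwords rows equal the mean of the piece rows", {
  cfg <- model_config(vocab_size = 30, hidden_dim = 16, num_heads = 4,
                      feedforward_dim = 32, max_position = 16, seed = 2)
  m <- init_model(cfg)
  subs <- list(c(3L, 7L), c(1L, 4L, 9L))
  grown <- resize_token_embeddings(m, 32, "mean_of_subwords",
                                   subword_ids = subs)
  expect_equal(grown$params$tok[31, ],
               (m$params$tok[4, ] + m$params$tok[8, ]) / 2)
  expect_equal(grown$params$tok[32, ],
               colMeans(m$params$tok[c(2, 5, 10), ]))
})

test_that("softmax is a shift-invariant probability distribution", {
  expect_equal(softmax_probs(rep(3.7, 4)), rep(0.25, 4))
  expect_equal(softmax_probs(c(0, log(2))), c(1 / 3, 2 / 3))
  big <- softmax_probs(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    s <- stats::rnorm(sample(2:12, 1), sd = 5)
    p <- softmax_probs(s)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_equal(p, softmax_probs(s + 123.4), tolerance = 1e-6)
  }
  expect_error(softmax_probs(c(1, NaN)), "finite")
})

test_that("cross entropy matches its closed forms", {
  expect_equal(cross_entropy_loss(c(1, 0, 0), 1), 0)
  expect_equal(cross_entropy_loss(rep(0.25, 4), 3), log(4), tolerance = 1e-9)
  expect_equal(cross_entropy_loss(c(0.2, 0.8), 1), -log(0.2))
  # batch version averages rows
  probs <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(cross_entropy_loss(probs, c(1, 1)),
               mean(c(-log(0.5), -log(0.9))))
  expect_error(cross_entropy_loss(c(0.5, 0.5), 3), "out of range")
  # zero probability is floored, not infinite
  expect_message(l0 <- cross_entropy_loss(c(1, 0), 2), "floored")
  expect_true(is.finite(l0))
  expect_gte(l0, 0)
})

test_that("head outputs have the contracted shapes", {
  v <- toy_vocab()
  m <- small_model(v, max_position = 32)
  enc <- encode_pair("Q", "A B foo bar foo", v, max_len = 16)
  n <- length(enc$ids)
  hidden <- forward_encode(m, enc)
  expect_equal(dim(hidden), c(n, m$config$hidden_dim))
  expect_identical(hidden, forward_encode(m, enc))  # eval determinism
  z <- span_logits(m, enc)
  expect_length(z$S, n)
  expect_length(z$E, n)
  expect_equal(dim(mlm_logits(m, enc)), c(n, vocab_size(v)))
  expect_length(cls_logits(m, enc, 3L), 3L)
  expect_error(cls_logits(m, enc, 1L), "at least 2")
})

test_that("out-of-range ids and overlong encodings are rejected by position", {
  v <- toy_vocab()
  m <- small_model(v, max_position = 8)
  enc <- encode_pair("Q", "A B", v, max_len = 8)
  bad <- enc
  bad$ids[4] <- vocab_size(v)
  expect_error(forward_encode(m, bad), "position 4")
  long <- encode_pair("Q", paste(rep("foo", 30), collapse = " "), v,
                      max_len = 30)
  expect_error(forward_encode(m, long), "max_position")
})

test_that("attention is position-aware and information flows to [CLS]", {
  v <- toy_vocab()
  m <- small_model(v, max_position = 32)
  enc <- encode_pair("Q", "A B foo bar rejection acute", v, max_len = 20)
  out1 <- forward_encode(m, enc)
  # permute two non-special context tokens
  enc2 <- enc
  i <- 4L; j <- 7L
  enc2$ids[c(i, j)] <- enc$ids[c(j, i)]
  out2 <- forward_encode(m, enc2)
  expect_gt(max(abs(out1[i, ] - out2[i, ])), 1e-8)
  # a far-from-[CLS] change reaches the [CLS] classifier (bidirectional flow)
  z1 <- cls_logits(m, enc, 2L)
  z2 <- cls_logits(m, enc2, 2L)
  expect_gt(max(abs(z1 - z2)), 1e-10)
})

test_that("hand-derived encoder gradients match finite differences", {
  cfg <- model_config(vocab_size = 25, num_layers = 2, hidden_dim = 8,
                      num_heads = 2, feedforward_dim = 16,
                      max_position = 10, seed = 3)
  m <- init_model(cfg)
  set.seed(31)
  ids <- sample(0:24, 7)
  segs <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L)
  w <- matrix(stats::rnorm(7 * 8), 7, 8)
  loss_of <- function(model) sum(pathbert:::encoder_fwd(model, ids, segs) * w)
  fw <- pathbert:::encoder_fwd(m, ids, segs, cache = TRUE)
  g <- pathbert:::encoder_bwd(m, fw, w)
  eps <- 1e-6
  probe <- function(get, set, grad, k = 5) {
    vals <- get(m)
    for (i in sample(length(vals), min(k, length(vals)))) {
      mp <- m; vp <- get(mp); vp[i] <- vp[i] + eps; mp <- set(mp, vp)
      mm <- m; vm <- get(mm); vm[i] <- vm[i] - eps; mm <- set(mm, vm)
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(grad[i], num, tolerance = 1e-4)
    }
  }
  probe(function(m) m$params$tok, function(m, v) { m$params$tok <- v; m },
        g$tok)
  probe(function(m) m$params$layers[[1]]$Wq,
        function(m, v) { m$params$layers[[1]]$Wq <- v; m }, g$layers[[1]]$Wq)
  probe(function(m) m$params$layers[[2]]$W2,
        function(m, v) { m$params$layers[[2]]$W2 <- v; m }, g$layers[[2]]$W2)
  probe(function(m) m$params$layers[[1]]$ln1g,
        function(m, v) { m$params$layers[[1]]$ln1g <- v; m },
        g$layers[[1]]$ln1g)
})

test_that("forward and loss stay finite over random seeded trials", {
  v <- toy_vocab()
  m <- small_model(v, max_position = 24)
  set.seed(77)
  for (trial in 1:100) {
    n <- sample(4:20, 1)
    ids <- sample(seq_len(vocab_size(v)) - 1L, n, replace = TRUE)
    enc <- wp_encoding(ids = ids,
                       tokens = v$tokens[ids + 1L],
                       offsets = cbind(seq_len(n) - 1L, seq_len(n)),
                       word_ids = seq_len(n),
                       segment_ids = rep(0L, n),
                       special = rep(FALSE, n))
    out <- forward_encode(m, enc)
    expect_true(all(is.finite(out)))
    p <- softmax_probs(mlm_logits(m, enc)[1, ])
    expect_true(is.finite(cross_entropy_loss(p, sample(vocab_size(v), 1))))
  }
})

test_that("one optimization step decreases the loss on a fixed batch", {
  fx <- ir_fixture(n = 6, seed = 21, max_len = 64)
  m <- small_model(fx$vocab, max_position = 64)
  loss_of <- function(model) {
    tot <- 0
    for (ex in fx$examples) {
      z <- span_logits(model, ex$encoding)
      tgt <- if (is.null(ex$gold_token_span)) c(1L, 1L) else ex$gold_token_span
      tot <- tot + cross_entropy_loss(softmax_probs(z$S), tgt[1]) +
        cross_entropy_loss(softmax_probs(z$E), tgt[2])
    }
    tot / length(fx$examples)
  }
  before <- loss_of(m)
  step <- finetune_ir(m, fx$examples,
                      train_config(epochs = 1, batch_size = 99,
                                   lr = 1e-4, seed = 1))
  expect_lt(loss_of(step$model), before)
})

test_that("checkpoints round-trip model, vocabulary and added tokens", {
  fx <- ir_fixture(n = 4, seed = 9, max_len = 48)
  m <- small_model(fx$vocab, max_position = 48)
  dir <- withr::local_tempdir()
  save_checkpoint(m, fx$vocab, dir, fx$added)
  back <- load_checkpoint(dir)
  expect_identical(param_checksum(back$model), param_checksum(m))
  expect_equal(back$vocab$tokens, fx$vocab$tokens)
  expect_equal(back$added$added, fx$added$added)
  enc <- fx$examples[[1]]$encoding
  expect_identical(forward_encode(back$model, enc), forward_encode(m, enc))
})
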