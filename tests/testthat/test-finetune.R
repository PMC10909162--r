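test_that("gold character spans map onto the covering token span", {
  fx <- ir_fixture(n = 15, seed = 13, max_len = 128,
                   question_id = "rejection_abmr")
  checked <- 0L
  for (ex in fx$examples) {
    if (is.null(ex$gold_token_span)) next
    g <- ex$gold_answers[[1]]
    iv <- c(ex$encoding$offsets[ex$gold_token_span[1], 1],
            ex$encoding$offsets[ex$gold_token_span[2], 2])
    # round trip: the recovered character interval contains the gold text
    expect_lte(iv[1], g$start)
    expect_gte(iv[2], g$end)
    expect_true(grepl(g$text, substr(ex$context, iv[1] + 1, iv[2]),
                      fixed = TRUE))
    checked <- checked + 1L
  }
  expect_gt(checked, 3)
})

test_that("reports without a mention yield the no-answer sentinel", {
  corpus <- small_corpus(40, seed = 19)
  base <- build_fixture_vocab(corpus)
  no_abmr <- Filter(function(r) length(r$gold$rejection_abmr) == 0, corpus)
  expect_gt(length(no_abmr), 0)
  ex <- build_ir_example(no_abmr[[1]], "rejection_abmr", base,
                         max_len = 128)
  expect_length(ex$gold_answers, 0)
  expect_null(ex$gold_token_span)
})

test_that("a gold span truncated away falls back to the sentinel with a warning", {
  fx <- ir_fixture(n = 20, seed = 23, max_len = 128)
  with_gold <- Filter(function(r) length(r$gold$rejection_abmr) > 0,
                      fx$corpus)
  r <- with_gold[[1]]
  # shrink max_len until the answer (which sits in the Comments head only
  # when comments exist; here force truncation by padding the context)
  r$ir_context <- paste(paste(rep("filler words only", 200), collapse = " "),
                        r$ir_context, sep = " ")
  r$gold$rejection_abmr <- lapply(r$gold$rejection_abmr, function(g) {
    shift <- nchar(r$ir_context) - nchar(ir_context(with_gold[[1]]))
    list(start = g$start + shift, end = g$end + shift, text = g$text)
  })
  vocab2 <- build_fixture_vocab(c(fx$corpus, list(r)))
  expect_warning(
    ex <- build_ir_example(r, "rejection_abmr", vocab2, max_len = 64),
    "truncated")
  expect_null(ex$gold_token_span)
})

test_that("decoding follows the end-before-start no-information rule", {
  v <- toy_vocab()
  enc <- encode_pair("Q", "A B foo bar foo bar A B", v, max_len = 16)
  n <- length(enc$ids)
  ctx <- which(enc$segment_ids == 1L & !enc$special)
  peak <- function(pos) { p <- rep(1e-6, n); p[pos] <- 1; p / sum(p) }
  # end argmax strictly before start argmax
  pred <- decode_span(peak(ctx[5]), peak(ctx[2]), enc)
  expect_equal(pred$text, "no information")
  expect_null(pred$char_interval)
  # start = end = k gives the single word at k
  pred1 <- decode_span(peak(ctx[3]), peak(ctx[3]), enc,
                       context = "A B foo bar foo bar A B")
  expect_equal(pred1$start, pred1$end)
  expect_equal(pred1$text, "foo")
  # probability mass on [CLS] decodes as no information
  pred2 <- decode_span(peak(1L), peak(ctx[4]), enc)
  expect_equal(pred2$text, "no information")
})

test_that("decode agrees with an exhaustive argmax oracle on random vectors", {
  v <- toy_vocab()
  enc <- encode_pair("Q", "A B foo bar foo bar", v, max_len = 12)
  n <- length(enc$ids)
  cand <- c(1L, which(enc$segment_ids == 1L & !enc$special))
  set.seed(55)
  for (i in 1:300) {
    s <- softmax_probs(stats::rnorm(n, sd = 3))
    e <- softmax_probs(stats::rnorm(n, sd = 3))
    pred <- decode_span(s, e, enc)
    # oracle: scan every candidate position for the two maxima
    best_s <- cand[1]; best_e <- cand[1]
    for (p in cand) {
      if (s[p] > s[best_s]) best_s <- p
      if (e[p] > e[best_e]) best_e <- p
    }
    expect_equal(pred$start, best_s)
    expect_equal(pred$end, best_e)
    no_info <- best_e < best_s || best_s == 1L || best_e == 1L
    expect_equal(pred$text == "no information", no_info)
    if (!no_info) {
      # never crosses into question or special positions
      expect_true(all(c(pred$start, pred$end) %in% cand[-1]))
    }
  }
})

test_that("decode rejects degenerate inputs", {
  v <- toy_vocab()
  enc <- encode_pair("Q", "A", v, max_len = 8)
  short <- wp_encoding(ids = enc$ids[1:3], tokens = enc$tokens[1:3],
                       offsets = enc$offsets[1:3, ], word_ids = enc$word_ids[1:3],
                       segment_ids = enc$segment_ids[1:3],
                       special = enc$special[1:3])
  p <- rep(1 / 3, 3)
  expect_error(decode_span(p, p, short), "context")
})

test_that("redaction removes trigger sentences and keeps the rest", {
  corpus <- small_corpus(30, seed = 29)
  graded <- Filter(function(r) r$labels$ifta_grade %in%
                     c("mild", "moderate", "severe", "minimal"), corpus)
  r <- graded[[1]]
  ex <- redact_for_classification(r, "ifta")
  expect_false(grepl("interstitial fibrosis", ex$text, ignore.case = TRUE))
  expect_false(grepl("tubular atrophy", ex$text, ignore.case = TRUE))
  expect_equal(ex$label, r$labels$ifta_grade)

  # text without trigger phrases is unchanged
  r2 <- r
  r2$sections$`Microscopic Description` <-
    "The glomeruli are unremarkable. No endotheliitis is identified."
  ex2 <- redact_for_classification(r2, "rejection")
  expect_equal(ex2$text, r2$sections$`Microscopic Description`)

  # a single all-trigger sentence leaves an empty text with a warning
  r3 <- r
  r3$sections$`Microscopic Description` <- "There is acute rejection."
  expect_warning(ex3 <- redact_for_classification(r3, "rejection"),
                 "redacted")
  expect_equal(ex3$text, "")
})

test_that("redacted rejection examples never contain their trigger words", {
  corpus <- small_corpus(25, seed = 31)
  for (r in corpus) {
    ex <- suppressWarnings(redact_for_classification(r, "rejection"))
    for (tr in c("rejection", "ABMR", "TCMR")) {
      expect_false(grepl(tr, ex$text, ignore.case = TRUE))
    }
  }
})

test_that("zero learning rate leaves parameters unchanged", {
  fx <- ir_fixture(n = 5, seed = 37, max_len = 64)
  m <- small_model(fx$vocab, max_position = 64)
  out <- finetune_ir(m, fx$examples,
                     train_config(epochs = 3, lr = 0, seed = 1))
  expect_identical(param_checksum(out$model), param_checksum(m))
  expect_error(finetune_ir(m, list(), train_config()), "no training")
})

test_that("a tiny model memorizes a small span-extraction set", {
  fx <- ir_fixture(n = 8, seed = 41, max_len = 64)
  m <- small_model(fx$vocab, max_position = 64)
  fit <- finetune_ir(m, fx$examples,
                     train_config(epochs = 40, batch_size = 4, lr = 1e-3,
                                  seed = 2))
  expect_lt(tail(fit$trace, 1), fit$trace[1] / 10)
  r <- evaluate_ir(fit$model, fx$examples)
  expect_gte(r$exact_match_rate, 0.8)
})

test_that("frozen-encoder fine-tuning only updates the span head", {
  fx <- ir_fixture(n = 5, seed = 43, max_len = 64)
  m <- small_model(fx$vocab, max_position = 64)
  out <- finetune_ir(m, fx$examples,
                     train_config(epochs = 2, lr = 1e-3, seed = 3,
                                  freeze_encoder = TRUE))
  expect_identical(out$model$params$tok, m$params$tok)
  expect_identical(out$model$params$layers, m$params$layers)
  expect_false(identical(out$model$params$span_W, m$params$span_W))
})

test_that("classification fine-tuning memorizes and yields proper probabilities", {
  corpus <- small_corpus(14, seed = 47,
                         p_abmr = 0.5, p_tcmr = 0.3)
  vocab <- build_fixture_vocab(corpus)
  m <- small_model(vocab, max_position = 96)
  examples <- suppressWarnings(lapply(corpus, redact_for_classification,
                                      task = "rejection"))
  labels <- vapply(examples, `[[`, character(1), "label")
  expect_gt(length(unique(labels)), 1)
  fit <- finetune_cls(m, examples, c("negative", "positive"),
                      train_config(epochs = 30, batch_size = 4, lr = 1e-3,
                                   seed = 5),
                      vocab, max_len = 96)
  rep <- evaluate_cls(fit$model, examples, vocab, max_len = 96,
                      positive_class = "positive")
  expect_gte(rep$accuracy, 0.9)
  p <- predict_cls(fit$model, examples[[1]], vocab, max_len = 96)
  expect_equal(sum(p$probs), 1, tolerance = 1e-6)
  expect_named(p$probs, c("negative", "positive"))
  bad <- examples[[1]]
  bad$label <- "unknown"
  expect_error(finetune_cls(m, list(bad), c("negative", "positive"),
                            train_config(), vocab), "outside")
})
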