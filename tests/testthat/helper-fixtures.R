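# Shared fixtures: a toy vocabulary that reproduces the characteristic
# sub-word splits, a small synthetic corpus, and a fast model config.

toy_vocab <- function(extra = character()) {
  wp_vocabulary(c("[CLS]", "[SEP]", "[MASK]", "[UNK]", "[PAD]",
                  "inter", "##st", "##iti", "##al",
                  "anti", "##body", "body", "-", ".", ",", "?",
                  "mediated", "rejection", "acute", "of", "the",
                  "T", "cell", "No", "evidence", "is", "seen",
                  "What", "kind", "does", "patient", "show",
                  "A", "B", "Q", "foo", "bar", extra))
}

small_corpus <- function(n = 25, seed = 7, ...) {
  generate_corpus(corpus_spec(n_reports = n, seed = seed, ...))
}

dense_spec_args <- function() {
  list(p_abmr = 0.4, p_tcmr = 0.3, p_negative_mention = 0.5,
       keyword_density = 2)
}

small_model <- function(vocab, seed = 5, max_position = 96L, ...) {
  init_model(model_config(vocab_size = vocab_size(vocab),
                          max_position = max_position, seed = seed, ...))
}

# corpus + extended tokenizer + IR examples used by several training tests
ir_fixture <- function(n = 12, seed = 11, max_len = 96L,
                       question_id = "rejection_abmr") {
  corpus <- do.call(generate_corpus,
                    list(do.call(corpus_spec,
                                 c(list(n_reports = n, seed = seed),
                                   dense_spec_args()))))
  base <- build_fixture_vocab(corpus)
  ext <- extend_vocabulary(base, study_keywords())
  examples <- suppressWarnings(
    lapply(corpus, build_ir_example, question_id = question_id,
           vocab = ext$vocab, added = ext$added, max_len = max_len))
  list(corpus = corpus, base = base, vocab = ext$vocab, added = ext$added,
       examples = examples)
}
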