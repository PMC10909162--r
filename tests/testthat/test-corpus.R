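test_that("corpus generation is seeded and byte-identical on rerun", {
  spec <- corpus_spec(n_reports = 30, seed = 61)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_corpus(corpus_spec(n_reports = 30, seed = 62))
  expect_false(identical(serialize(c1, NULL), serialize(c3, NULL)))
})

test_that("every gold interval's substring equals its stored answer text", {
  corpus <- small_corpus(60, seed = 67)
  n_checked <- 0L
  for (r in corpus) {
    for (key in names(r$gold)) {
      for (g in r$gold[[key]]) {
        expect_identical(substr(r$ir_context, g$start + 1L, g$end), g$text)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 50)
})

test_that("graded reports carry the capitalized grade word as IFTA gold", {
  corpus <- small_corpus(80, seed = 71)
  mild <- Filter(function(r) r$labels$ifta_grade == "mild", corpus)
  expect_gt(length(mild), 0)
  for (r in mild) {
    expect_equal(r$gold$ifta[[1]]$text, "Mild")
  }
  uncls <- Filter(function(r) r$labels$ifta_grade == "unclassified", corpus)
  for (r in uncls) expect_length(r$gold$ifta, 0)
})

test_that("a distribution degenerate at unclassified produces no IFTA sentences", {
  probs <- c(severe = 0, moderate = 0, mild = 0, minimal = 0, absent = 0,
             unclassified = 1)
  corpus <- generate_corpus(corpus_spec(20, ifta_probs = probs, seed = 3))
  for (r in corpus) {
    expect_length(r$gold$ifta, 0)
    expect_false(grepl("interstitial fibrosis and tubular atrophy",
                       r$sections$`Microscopic Description`,
                       ignore.case = TRUE))
  }
  bad <- probs
  bad["unclassified"] <- 2
  expect_error(corpus_spec(10, ifta_probs = bad), "distribution")
})

test_that("label frequencies track the study proportions at full size", {
  corpus <- generate_corpus(corpus_spec(n_reports = 3428, seed = 101))
  grades <- vapply(corpus, function(r) r$labels$ifta_grade, character(1))
  counts <- c(severe = 112, moderate = 361, mild = 1120, minimal = 347,
              absent = 1233, unclassified = 256)
  probs <- counts / sum(counts)
  n <- length(corpus)
  for (g in names(probs)) {
    sd <- sqrt(n * probs[[g]] * (1 - probs[[g]]))
    expect_lt(abs(sum(grades == g) - n * probs[[g]]), 3 * sd + 1)
  }
  for (lab in c("abmr", "tcmr")) {
    p <- if (lab == "abmr") 123 / 3428 else 107 / 3428
    k <- sum(vapply(corpus, function(r) r$labels[[lab]], logical(1)))
    sd <- sqrt(n * p * (1 - p))
    expect_lt(abs(k - n * p), 3 * sd + 1)
  }
})

test_that("corpus JSONL writes and reads back losslessly", {
  corpus <- small_corpus(12, seed = 73)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- load_external_reports(path)
  expect_equal(back$skipped, 0L)
  expect_length(back$reports, 12L)
  for (i in seq_along(corpus)) {
    expect_equal(back$reports[[i]]$report_id, corpus[[i]]$report_id)
    expect_equal(back$reports[[i]]$sections, corpus[[i]]$sections)
    expect_equal(back$reports[[i]]$labels, corpus[[i]]$labels)
    expect_equal(back$reports[[i]]$ir_context, corpus[[i]]$ir_context)
    expect_equal(back$reports[[i]]$gold, corpus[[i]]$gold)
  }
})

test_that("malformed JSONL records are skipped and counted", {
  corpus <- small_corpus(3, seed = 79)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  lines <- readLines(path)
  writeLines(c(lines, "{ not json"), path)
  back <- load_external_reports(path)
  expect_length(back$reports, 3L)
  expect_equal(back$skipped, 1L)
  # records whose gold offsets do not match their context are rejected too
  broken <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  broken$gold$ifta <- list(list(start = 0, end = 4, text = "zzzz"))
  writeLines(jsonlite::toJSON(broken, auto_unbox = TRUE), path)
  expect_error(load_external_reports(path), "no parseable")
})

test_that("the fixture vocabulary reproduces the forced sub-word splits", {
  corpus <- small_corpus(15, seed = 83)
  vocab <- build_fixture_vocab(corpus)
  expect_equal(wordpiece_split("interstitial", vocab),
               c("inter", "##st", "##iti", "##al"))
  expect_true(all(SPECIAL_TOKENS %in% vocab$tokens))
  expect_false(any(study_keywords() %in% vocab$tokens))
  # distinct required tokens + specials, recounted independently
  texts <- c(unlist(lapply(corpus, function(r) unlist(r$sections))),
             unname(study_questions()))
  words <- setdiff(unique(unlist(lapply(texts, function(t) {
    basic_pretokenize(t)$word
  }))), study_keywords())
  pieces <- c("inter", "##st", "##iti", "##al", "anti", "##body", "body",
              "fib", "##rosis", "tub", "##ular", "at", "##rophy")
  expect_equal(vocab_size(vocab),
               length(SPECIAL_TOKENS) + length(union(words, pieces)))
  expect_error(build_fixture_vocab(corpus,
                                   required_pieces = c("inter", "tubular")),
               "collides")
})

test_that("padding grows the vocabulary to an exact target size", {
  corpus <- small_corpus(5, seed = 89)
  v <- build_fixture_vocab(corpus, pad_to = 2000)
  expect_equal(vocab_size(v), 2000L)
  expect_error(build_fixture_vocab(corpus, pad_to = 10), "smaller")
})

test_that("keyword occurrences are multi-token under base, atomic under extended", {
  corpus <- small_corpus(20, seed = 97, keyword_density = 2)
  base <- build_fixture_vocab(corpus)
  ext <- extend_vocabulary(base, study_keywords())
  n_found <- 0L
  for (r in corpus[1:10]) {
    txt <- ir_context(r)
    for (kw in study_keywords()) {
      if (!grepl(kw, txt, fixed = TRUE)) next
      n_found <- n_found + 1L
      enc_base <- tokenize(kw, base)
      expect_gt(length(enc_base$ids), 1L)  # split into sub-words
      enc_ext <- tokenize(kw, ext$vocab, ext$added)
      expect_equal(enc_ext$tokens, kw)     # single added token
      # and inside the full report text the added token survives intact
      full <- tokenize(txt, ext$vocab, ext$added)
      expect_true(kw %in% full$tokens)
    }
  }
  expect_gt(n_found, 5)
})

test_that("train/eval split is stratified, exhaustive and seeded", {
  corpus <- small_corpus(100, seed = 103)
  sp <- split_train_eval(corpus, 0.20, seed = 9)
  expect_length(sp$eval, 20L)
  expect_length(sp$train, 80L)
  ids <- function(reports) vapply(reports, `[[`, character(1), "report_id")
  expect_length(intersect(ids(sp$train), ids(sp$eval)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$eval)), ids(corpus))
  sp2 <- split_train_eval(corpus, 0.20, seed = 9)
  expect_identical(ids(sp2$eval), ids(sp$eval))
  sp3 <- split_train_eval(corpus, 0.20, seed = 10)
  expect_false(identical(ids(sp3$eval), ids(sp$eval)))
  expect_error(split_train_eval(corpus, 1.2), "eval_fraction")
  expect_error(split_train_eval(corpus[1:3]), "at least 5")
})

test_that("degenerate strata fall back to a plain random split", {
  corpus <- small_corpus(10, seed = 107)
  for (i in seq_along(corpus)) {
    corpus[[i]]$labels <- list(abmr = FALSE, tcmr = FALSE,
                               ifta_grade = paste0("g", i))
  }
  expect_message(sp <- split_train_eval(corpus, 0.2, seed = 1),
                 "degenerate")
  expect_length(sp$eval, 2L)
})
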