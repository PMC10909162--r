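IFTA_GRADES <- c("severe", "moderate", "mild", "minimal", "absent",
                 "unclassified")

# Label frequencies of the study corpus (class probabilities are the printed
# counts normalized by their own sum).
IFTA_COUNTS <- c(severe = 112, moderate = 361, mild = 1120, minimal = 347,
                 absent = 1233, unclassified = 256)
N_STUDY_REPORTS <- 3428
N_ABMR_POS <- 123
N_TCMR_POS <- 107

#' The two fixed study questions
#' @return named character vector with elements `rejection` and `ifta`.
#' @export
study_questions <- function() {
  c(rejection = "What kind of rejection does the patient show?",
    ifta = "What is the grade of interstitial fibrosis and tubular atrophy?")
}

#' Specification of a synthetic report corpus
#'
#' Defaults reproduce the label frequencies of the study corpus: IFTA grades
#' severe 112 / moderate 361 / mild 1,120 / minimal 347 / absent 1,233 /
#' unclassified 255 out of 3,428 reports, ABMR positives 123/3,428 and TCMR
#' positives 107/3,428 (drawn independently).
#'
#' @param n_reports number of reports to generate.
#' @param ifta_probs named probability vector over the six IFTA grades.
#' @param p_abmr probability a report is ABMR-positive.
#' @param p_tcmr probability a report is TCMR-positive.
#' @param p_negative_mention probability a rejection-negative report still
#'   mentions rejection explicitly ("No evidence of ..."), which is what
#'   makes the no-information case non-trivial.
#' @param keyword_density expected number of additional keyword-bearing
#'   distractor sentences per report.
#' @param comments_prob probability a report without rejection mentions
#'   still has a Comments section.
#' @param seed integer RNG seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_reports,
                        ifta_probs = IFTA_COUNTS / sum(IFTA_COUNTS),
                        p_abmr = N_ABMR_POS / N_STUDY_REPORTS,
                        p_tcmr = N_TCMR_POS / N_STUDY_REPORTS,
                        p_negative_mention = 0.5,
                        keyword_density = 1,
                        comments_prob = 0.4,
                        seed = 1L) {
  stopifnot(n_reports >= 1)
  if (is.null(names(ifta_probs)) ||
      !setequal(names(ifta_probs), IFTA_GRADES)) {
    stop("ifta_probs must be named with the six IFTA grades")
  }
  ifta_probs <- ifta_probs[IFTA_GRADES]
  if (any(ifta_probs < 0) || abs(sum(ifta_probs) - 1) > 1e-8) {
    stop("ifta_probs must be a probability distribution")
  }
  for (p in c(p_abmr, p_tcmr, p_negative_mention, comments_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  structure(list(n_reports = as.integer(n_reports), ifta_probs = ifta_probs,
                 p_abmr = p_abmr, p_tcmr = p_tcmr,
                 p_negative_mention = p_negative_mention,
                 keyword_density = keyword_density,
                 comments_prob = comments_prob, seed = as.integer(seed)),
            class = "corpus_spec")
}

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# A sentence accumulator that records where gold substrings land.
sentence_buffer <- function() {
  env <- new.env(parent = emptyenv())
  env$parts <- character()
  env$len <- 0L
  env$gold <- list()
  env$add <- function(sentence, gold_text = NULL, question = NULL) {
    sep_len <- if (env$len > 0L) 1L else 0L  # joined by single spaces
    base <- env$len + sep_len
    if (!is.null(gold_text)) {
      rel <- regexpr(gold_text, sentence, fixed = TRUE)
      stopifnot(rel > 0)
      env$gold[[length(env$gold) + 1L]] <- list(
        question = question,
        start = base + as.integer(rel) - 1L,
        end = base + as.integer(rel) - 1L + nchar(gold_text),
        text = gold_text)
    }
    env$parts <- c(env$parts, sentence)
    env$len <- base + nchar(sentence)
  }
  env$text <- function() paste(env$parts, collapse = " ")
  env
}

micro_boilerplate <- function() {
  first <- paste("The following findings are based on hematoxylin and eosin",
                 "(H&E), periodic acid-Schiff (PAS), and Masson",
                 "trichrome-stained sections.")
  glom <- sprintf(paste("The specimen submitted for light microscopic",
                        "evaluation consists of cortical tissue with at least",
                        "%d glomeruli."), sample(8:40, 1))
  scler <- sample(c("No segmentally or globally sclerosed glomeruli are seen.",
                    "Two globally sclerosed glomeruli are identified."), 1)
  mes <- sample(c("The glomeruli demonstrate focal mild mesangial widening.",
                  paste("The glomerular capillary walls are of normal",
                        "thickness and contours.")), 1)
  infl <- sprintf(paste("Patchy %s inflammation is noted associated with",
                        "scattered %s tubulitis."),
                  sample(c("mild", "moderate"), 1),
                  sample(c("mild", "moderate"), 1))
  mono <- paste("The inflammation consists predominantly of mononuclear",
                "leukocytes with scattered plasma cells and only rare",
                "eosinophils.")
  c(first, glom, scler, mes, infl, mono)
}

micro_closing <- function() {
  c("The arteries and arterioles show focal mild hyalinosis.",
    "No endotheliitis or peritubular capillaritis is identified.")
}

keyword_fillers <- function() {
  c("There is patchy interstitial edema without significant tubular injury.",
    "Focal tubular epithelial simplification is noted without overt atrophy.",
    "Scattered foci of interstitial inflammation involve the cortex.",
    "C4d staining by antibody immunohistochemistry is negative in peritubular capillaries.",
    "No intimal fibrosis of the arteries is identified.",
    "Rare foci of tubular epithelial injury with luminal debris are seen.")
}

ifta_sentence <- function(grade) {
  pct <- switch(grade, severe = sample(55:80, 1), moderate = sample(30:50, 1),
                mild = sample(10:25, 1), minimal = sample(3:8, 1))
  if (grade == "absent") {
    list(sentence = "Interstitial fibrosis and tubular atrophy are absent.",
         gold = "absent")
  } else {
    word <- cap_first(grade)
    list(sentence = sprintf(
      "%s interstitial fibrosis and tubular atrophy are present (~%d%%).",
      word, pct), gold = word)
  }
}

comment_openers <- function() {
  c(sprintf(paste("The biopsy shows interstitial inflammation (i%d)",
                  "consisting of mostly mononuclear leukocytes."),
            sample(0:2, 1)),
    sprintf(paste("Tubulitis (t%d) is readily identified in the areas with",
                  "infiltrating inflammatory cells."), sample(0:2, 1)))
}

generate_report <- function(spec, report_id) {
  abmr <- stats::runif(1) < spec$p_abmr
  tcmr <- stats::runif(1) < spec$p_tcmr
  ifta <- sample(IFTA_GRADES, 1, prob = spec$ifta_probs)

  micro <- sentence_buffer()
  for (s in micro_boilerplate()) micro$add(s)
  n_fill <- stats::rpois(1, spec$keyword_density)
  if (n_fill > 0) {
    for (s in sample(keyword_fillers(), min(n_fill, 6))) micro$add(s)
  }
  if (ifta != "unclassified") {
    iv <- ifta_sentence(ifta)
    micro$add(iv$sentence, gold_text = iv$gold, question = "ifta")
  }
  for (s in micro_closing()) micro$add(s)

  abmr_mention <- abmr || stats::runif(1) < spec$p_negative_mention
  tcmr_mention <- tcmr || stats::runif(1) < spec$p_negative_mention
  has_comments <- abmr_mention || tcmr_mention ||
    stats::runif(1) < spec$comments_prob
  comments <- NULL
  if (has_comments) {
    cm <- sentence_buffer()
    for (s in sample(comment_openers(), sample(1:2, 1))) cm$add(s)
    if (tcmr_mention) {
      if (tcmr) {
        grade <- sample(c("IA", "IB", "IIA"), 1)
        cm$add(sprintf(paste("These findings support the diagnosis of acute",
                             "T-cell mediated rejection (%s)."), grade),
               gold_text = "acute T-cell mediated rejection",
               question = "rejection_tcmr")
      } else {
        cm$add("No evidence of acute T-cell mediated rejection is identified.",
               gold_text = "No evidence of acute T-cell mediated rejection",
               question = "rejection_tcmr")
      }
    }
    if (abmr_mention) {
      if (abmr) {
        cm$add(paste("There is evidence of acute antibody-mediated rejection",
                     "with peritubular capillaritis."),
               gold_text = "acute antibody-mediated rejection",
               question = "rejection_abmr")
      } else {
        cm$add("No evidence of acute antibody-mediated rejection is seen.",
               gold_text = "No evidence of acute antibody-mediated rejection",
               question = "rejection_abmr")
      }
    }
    comments <- cm
  }

  diagnosis <- paste0(
    "Kidney transplant, needle core biopsy: ",
    if (tcmr) "acute T-cell mediated rejection; "
    else if (abmr) "acute antibody-mediated rejection; "
    else "no acute rejection; ",
    if (ifta == "unclassified") "see microscopic description."
    else sprintf("%s IFTA.", ifta))
  gross <- sprintf(paste("The specimen consists of two cores of tan tissue",
                         "measuring up to %.1f cm, submitted entirely."),
                   stats::runif(1, 0.8, 2.2))

  micro_text <- micro$text()
  shift <- if (has_comments) nchar(comments$text()) + 1L else 0L
  gold <- list(rejection_abmr = list(), rejection_tcmr = list(), ifta = list())
  add_gold <- function(entries, offset) {
    for (g in entries) {
      key <- switch(g$question, ifta = "ifta",
                    rejection_abmr = "rejection_abmr",
                    rejection_tcmr = "rejection_tcmr")
      gold[[key]][[length(gold[[key]]) + 1L]] <<- list(
        start = g$start + offset, end = g$end + offset, text = g$text)
    }
  }
  if (has_comments) add_gold(comments$gold, 0L)
  add_gold(micro$gold, shift)
  ir_context <- if (has_comments) paste(comments$text(), micro_text,
                                        sep = "\n") else micro_text

  sections <- list(Diagnosis = diagnosis,
                   Tissues = "Kidney, transplant, needle core biopsy.",
                   `Gross Description` = gross,
                   `Microscopic Description` = micro_text)
  if (has_comments) sections$Comments <- comments$text()

  structure(list(report_id = report_id, sections = sections,
                 labels = list(abmr = abmr, tcmr = tcmr, ifta_grade = ifta),
                 ir_context = ir_context, gold = gold),
            class = "pb_report")
}

#' Generate a seeded synthetic report corpus
#'
#' Reports are assembled from a template grammar that mimics transplant
#' biopsy microscopy boilerplate (glomeruli counts, tubulitis, hyalinosis),
#' an IFTA severity sentence of the form "Mild interstitial fibrosis and
#' tubular atrophy are present (~10%)." for graded reports, and rejection
#' sentences ("These findings support the diagnosis of acute T-cell mediated
#' rejection", "No evidence of acute antibody-mediated rejection") in the
#' Comments section. Gold answer spans are recorded at generation time as
#' 0-based half-open character intervals into the IR context (Comments,
#' newline, Microscopic Description).
#'
#' @param spec a `corpus_spec`.
#' @return list of `pb_report` objects.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_preserved_rng({
    set.seed(spec$seed)
    lapply(seq_len(spec$n_reports), function(i) {
      generate_report(spec, sprintf("R%05d", i))
    })
  })
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' IR context of a report (Comments first, then Microscopic Description)
#' @param report a `pb_report`.
#' @return a single string.
#' @export
ir_context <- function(report) report$ir_context

#' Build the fixture vocabulary for a corpus
#'
#' Contains every whitespace/punctuation word of the corpus (and of the two
#' study questions) EXCEPT the six study keywords, plus the sub-word pieces
#' required to reproduce the characteristic splits ("inter" "##st" "##iti"
#' "##al"; "anti" "##body"), plus the five reserved tokens. Optionally
#' padded with `[unusedN]` filler tokens to a target size such as 28,996 for
#' size-sensitive work.
#'
#' @param corpus list of `pb_report`s.
#' @param required_pieces extra sub-word pieces to force into the vocabulary.
#' @param exclude words withheld so they are out-of-vocabulary (default: the
#'   six study keywords).
#' @param pad_to optional target size.
#' @return A `wp_vocabulary`.
#' @export
build_fixture_vocab <- function(corpus,
                                required_pieces = c(
                                  "inter", "##st", "##iti", "##al",
                                  "anti", "##body", "body",
                                  "fib", "##rosis", "tub", "##ular",
                                  "at", "##rophy"),
                                exclude = study_keywords(),
                                pad_to = NULL) {
  if (length(corpus) == 0) stop("corpus is empty")
  if (length(intersect(required_pieces, exclude)) > 0) {
    stop("required piece collides with an excluded keyword: ",
         paste(intersect(required_pieces, exclude), collapse = ", "))
  }
  texts <- c(unlist(lapply(corpus, function(r) unlist(r$sections))),
             unname(study_questions()))
  words <- unique(unlist(lapply(texts, function(t) basic_pretokenize(t)$word)))
  words <- sort(setdiff(words, exclude), method = "radix")
  tokens <- c(SPECIAL_TOKENS,
              words,
              setdiff(required_pieces, words))
  if (!is.null(pad_to)) {
    if (pad_to < length(tokens)) {
      stop(sprintf("pad_to (%d) smaller than required token count (%d)",
                   pad_to, length(tokens)))
    }
    tokens <- c(tokens, sprintf("[unused%d]", seq_len(pad_to - length(tokens))))
  }
  wp_vocabulary(tokens)
}

report_stratum <- function(report) {
  paste(report$labels$abmr, report$labels$tcmr, report$labels$ifta_grade,
        sep = "|")
}

#' Stratified train/evaluation split
#'
#' Holds out `eval_fraction` of the reports (default 20%), stratified by the
#' joint (ABMR, TCMR, IFTA grade) label where stratum sizes permit; tiny
#' strata fall back to pooled random allocation (reported via `message()`).
#'
#' @param corpus list of `pb_report`s (at least 5).
#' @param eval_fraction fraction held out, in (0, 1).
#' @param seed integer RNG seed.
#' @return list with elements `train` and `eval` (disjoint, exhaustive).
#' @export
split_train_eval <- function(corpus, eval_fraction = 0.20, seed = 1L) {
  n <- length(corpus)
  if (n < 5) stop("need at least 5 reports to split")
  if (eval_fraction <= 0 || eval_fraction >= 1) {
    stop("eval_fraction must be in (0, 1)")
  }
  with_preserved_rng({
    set.seed(seed)
    strata <- vapply(corpus, report_stratum, character(1))
    target <- round(eval_fraction * n)
    eval_idx <- integer(0)
    degenerate <- all(table(strata) < 2)
    if (degenerate) {
      message("stratification degenerate; falling back to a plain random split")
      eval_idx <- sample.int(n, target)
    } else {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        k <- round(eval_fraction * length(idx))
        if (k > 0) eval_idx <- c(eval_idx, sample(idx, k))
      }
      # adjust to the exact overall target
      if (length(eval_idx) > target) {
        eval_idx <- sample(eval_idx, target)
      } else if (length(eval_idx) < target) {
        pool <- setdiff(seq_len(n), eval_idx)
        eval_idx <- c(eval_idx, sample(pool, target - length(eval_idx)))
      }
    }
    eval_idx <- sort(eval_idx)
    list(train = corpus[setdiff(seq_len(n), eval_idx)],
         eval = corpus[eval_idx])
  })
}

report_to_record <- function(report) {
  gold <- lapply(report$gold, function(entries) {
    lapply(entries, function(g) list(start = g$start, end = g$end,
                                     text = g$text))
  })
  list(report_id = report$report_id, sections = report$sections,
       labels = report$labels, ir_context = report$ir_context, gold = gold)
}

#' Write a corpus as JSONL (one report per line, UTF-8)
#' @param corpus list of `pb_report`s.
#' @param path output path.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(r) {
    jsonlite::toJSON(report_to_record(r), auto_unbox = TRUE, digits = NA)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

default_dialect <- function() {
  list(report_id = "report_id", sections = "sections", labels = "labels",
       ir_context = "ir_context", gold = "gold")
}

record_to_report <- function(rec, dialect) {
  sections <- rec[[dialect$sections]]
  labels <- rec[[dialect$labels]]
  if (is.null(sections) || is.null(labels)) stop("missing required fields")
  ctx <- rec[[dialect$ir_context]]
  if (is.null(ctx)) {
    cm <- sections$Comments
    micro <- sections$`Microscopic Description`
    ctx <- if (!is.null(cm)) paste(cm, micro, sep = "\n") else micro
  }
  gold_in <- rec[[dialect$gold]]
  gold <- list(rejection_abmr = list(), rejection_tcmr = list(), ifta = list())
  for (key in names(gold)) {
    for (g in gold_in[[key]]) {
      if (is.null(g$start) || is.null(g$end) || is.null(g$text)) {
        stop("malformed gold entry")
      }
      if (substr(ctx, g$start + 1L, g$end) != g$text) {
        stop("gold substring mismatch")
      }
      gold[[key]][[length(gold[[key]]) + 1L]] <- list(
        start = as.integer(g$start), end = as.integer(g$end), text = g$text)
    }
  }
  structure(list(report_id = rec[[dialect$report_id]], sections = sections,
                 labels = list(abmr = isTRUE(labels$abmr),
                               tcmr = isTRUE(labels$tcmr),
                               ifta_grade = labels$ifta_grade),
                 ir_context = ctx, gold = gold),
            class = "pb_report")
}

#' Read report records from a JSONL file (best-effort)
#'
#' Parses one JSON record per line into `pb_report` objects through a
#' configurable field mapping; records that fail to parse or validate are
#' skipped and counted.
#'
#' @param path path to a JSONL file.
#' @param dialect named list mapping the five report fields to the file's
#'   field names (defaults to this package's own export format).
#' @return list with elements `reports` and `skipped` (count).
#' @export
load_external_reports <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  reports <- list()
  skipped <- 0L
  for (ln in lines) {
    rep <- tryCatch(
      record_to_report(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                       dialect),
      error = function(e) NULL)
    if (is.null(rep)) skipped <- skipped + 1L else {
      reports[[length(reports) + 1L]] <- rep
    }
  }
  if (length(reports) == 0) {
    stop("no parseable report records in ", path, " (", skipped, " skipped)")
  }
  list(reports = reports, skipped = skipped)
}
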