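check_interval <- function(iv, what = "interval") {
  if (is.null(iv) || length(iv) == 0) return(invisible(NULL))
  if (length(iv) != 2 || anyNA(iv)) stop("malformed ", what)
  if (iv[2] < iv[1]) stop("inverted ", what, ": end < start")
  invisible(iv)
}

#' A predicted/gold span pair
#'
#' Intervals are 0-based half-open character ranges in a common source text.
#' An empty prediction (the "no information" case) is `NULL`; the gold side
#' is a list of intervals (possibly empty, with their answer texts).
#'
#' @param predicted `NULL` or `c(start, end)`.
#' @param gold list of `c(start, end)` intervals.
#' @param gold_texts character vector of the gold answer texts (parallel to
#'   `gold`).
#' @param predicted_text decoded answer text or the literal "no information".
#' @return An object of class `span_pair`.
#' @export
span_pair <- function(predicted = NULL, gold = list(),
                      gold_texts = character(), predicted_text = NULL) {
  check_interval(predicted, "predicted interval")
  lapply(gold, check_interval, what = "gold interval")
  structure(list(predicted = predicted, gold = gold,
                 gold_texts = gold_texts, predicted_text = predicted_text),
            class = "span_pair")
}

interval_intersection <- function(a, b) {
  max(0, min(a[2], b[2]) - max(a[1], b[1]))
}

#' Character-level overlap ratio of a span pair
#'
#' Length of the intersection between the predicted interval and the union
#' of gold intervals, divided by the total gold length, capped at 1.
#' Conventions for the no-information cases: both sides empty scores 1.0,
#' exactly one side empty scores 0.0.
#'
#' @param pair a `span_pair`.
#' @return a real in \[0, 1\].
#' @export
char_overlap_ratio <- function(pair) {
  stopifnot(inherits(pair, "span_pair"))
  pred_empty <- is.null(pair$predicted)
  gold_empty <- length(pair$gold) == 0
  if (pred_empty && gold_empty) return(1.0)
  if (pred_empty || gold_empty) return(0.0)
  gold_len <- sum(vapply(pair$gold, function(g) g[2] - g[1], numeric(1)))
  if (gold_len <= 0) return(0.0)
  ov <- sum(vapply(pair$gold, interval_intersection, numeric(1),
                   a = pair$predicted))
  min(1.0, ov / gold_len)
}

words_hit <- function(iv, word_ranges) {
  if (nrow(word_ranges) == 0) return(integer())
  which(word_ranges$start < iv[2] & word_ranges$end > iv[1])
}

#' Word-level overlap ratio of a span pair
#'
#' Words are the whitespace-delimited units of `source_text`; a word belongs
#' to a span as soon as their character ranges intersect (clipping even one
#' character of a word claims it). Ratio = overlapping words / gold words,
#' with the same empty-side conventions as [char_overlap_ratio()].
#'
#' @param pair a `span_pair`.
#' @param source_text the text both intervals index.
#' @return a real in \[0, 1\].
#' @export
word_overlap_ratio <- function(pair, source_text) {
  stopifnot(inherits(pair, "span_pair"))
  pred_empty <- is.null(pair$predicted)
  gold_empty <- length(pair$gold) == 0
  if (pred_empty && gold_empty) return(1.0)
  if (pred_empty || gold_empty) return(0.0)
  wr <- word_index_of(source_text)
  gold_words <- sort(unique(unlist(lapply(pair$gold, words_hit,
                                          word_ranges = wr))))
  if (length(gold_words) == 0) return(0.0)
  pred_words <- words_hit(pair$predicted, wr)
  min(1.0, length(intersect(pred_words, gold_words)) / length(gold_words))
}

normalize_answer <- function(x) gsub("\\s+", " ", trimws(x))

#' Exact match rate over span pairs
#'
#' A pair matches when the predicted text equals ANY of its gold answer
#' texts after whitespace normalization (gold sets may hold several
#' mentions); a "no information" prediction matches an empty gold set.
#'
#' @param pairs non-empty list of `span_pair`s.
#' @return proportion of matches in \[0, 1\].
#' @export
exact_match_rate <- function(pairs) {
  if (length(pairs) == 0) stop("exact_match_rate needs at least one pair")
  hits <- vapply(pairs, function(p) {
    pred_empty <- is.null(p$predicted) ||
      identical(p$predicted_text, "no information")
    if (length(p$gold_texts) == 0) return(pred_empty)
    if (pred_empty || is.null(p$predicted_text)) return(FALSE)
    normalize_answer(p$predicted_text) %in% normalize_answer(p$gold_texts)
  }, logical(1))
  mean(hits)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics row
#'
#' Accuracy plus either positive-class precision/recall/F1 (binary tasks,
#' `positive_class` given) or class-frequency-weighted precision/recall/F1
#' (`weighted = TRUE`). Zero-denominator cells are reported as 0, so a model
#' that never predicts the positive class scores positive P/R/F1 = 0.
#'
#' @param y_true vector of true labels.
#' @param y_pred vector of predicted labels (same length).
#' @param positive_class the positive label for binary metrics, or `NULL`.
#' @param weighted logical; compute frequency-weighted multi-class metrics.
#' @return one-row data.frame of metrics in \[0, 1\].
#' @export
classification_report <- function(y_true, y_pred, positive_class = NULL,
                                  weighted = is.null(positive_class)) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ")
  }
  if (length(y_true) == 0) stop("empty label vectors")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  out <- data.frame(accuracy = mean(y_true == y_pred))
  prf <- function(cls) {
    tp <- sum(y_true == cls & y_pred == cls)
    p <- safe_div(tp, sum(y_pred == cls))
    r <- safe_div(tp, sum(y_true == cls))
    f <- safe_div(2 * p * r, p + r)
    c(precision = p, recall = r, f1 = f)
  }
  if (!is.null(positive_class)) {
    m <- prf(as.character(positive_class))
    out$positive_precision <- m[["precision"]]
    out$positive_recall <- m[["recall"]]
    out$positive_f1 <- m[["f1"]]
  }
  if (weighted) {
    classes <- sort(unique(y_true))
    w <- vapply(classes, function(cls) mean(y_true == cls), numeric(1))
    m <- vapply(classes, prf, numeric(3))
    out$weighted_precision <- sum(w * m["precision", ])
    out$weighted_recall <- sum(w * m["recall", ])
    out$weighted_f1 <- sum(w * m["f1", ])
  }
  out
}

#' Aggregate span-IR metrics over an evaluation set
#'
#' Per-example overlap ratios are computed first and then averaged (macro
#' averaging; micro pooling of lengths is available via `average = "micro"`).
#'
#' @param pairs list of `span_pair`s.
#' @param source_texts character vector of the texts the pairs index.
#' @param average "macro" (default) or "micro" (pool overlap and gold
#'   lengths across examples before dividing; character level only).
#' @return one-row data.frame: `overlap_ratio_char`, `overlap_ratio_word`,
#'   `exact_match_rate`.
#' @export
ir_report <- function(pairs, source_texts, average = c("macro", "micro")) {
  average <- match.arg(average)
  stopifnot(length(pairs) == length(source_texts), length(pairs) > 0)
  chars <- vapply(pairs, char_overlap_ratio, numeric(1))
  words <- mapply(word_overlap_ratio, pairs, source_texts)
  if (average == "micro") {
    num <- den <- 0
    for (p in pairs) {
      if (length(p$gold) == 0) next
      den <- den + sum(vapply(p$gold, function(g) g[2] - g[1], numeric(1)))
      if (!is.null(p$predicted)) {
        num <- num + sum(vapply(p$gold, interval_intersection, numeric(1),
                                a = p$predicted))
      }
    }
    char_ratio <- safe_div(num, den)
  } else {
    char_ratio <- mean(chars)
  }
  data.frame(overlap_ratio_char = char_ratio,
             overlap_ratio_word = mean(words),
             exact_match_rate = exact_match_rate(pairs))
}
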