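#' Token encoding
#'
#' The parallel-array container produced by [tokenize()], [encode_pair()] and
#' [encode_single()]. All character intervals are 0-based, half-open
#' `[start, end)` into the source string; special tokens carry the empty
#' interval `[0, 0)` and an `NA` word id.
#'
#' @param ids integer vector of 0-based token ids.
#' @param tokens character vector of token strings.
#' @param offsets integer matrix with one `[start, end)` row per token.
#' @param word_ids integer vector; 1-based index of the whitespace-delimited
#'   source word each token came from (`NA` for specials).
#' @param segment_ids integer vector; 0 for question tokens, 1 for context.
#' @param special logical vector marking reserved tokens.
#' @return An object of class `wp_encoding`.
#' @export
wp_encoding <- function(ids, tokens, offsets, word_ids, segment_ids, special) {
  n <- length(ids)
  stopifnot(
    length(tokens) == n,
    nrow(offsets) == n,
    length(word_ids) == n,
    length(segment_ids) == n,
    length(special) == n
  )
  structure(
    list(ids = as.integer(ids), tokens = tokens,
         offsets = matrix(as.integer(offsets), ncol = 2),
         word_ids = as.integer(word_ids),
         segment_ids = as.integer(segment_ids),
         special = as.logical(special)),
    class = "wp_encoding"
  )
}

#' @export
length.wp_encoding <- function(x) length(x$ids)

#' @export
print.wp_encoding <- function(x, ...) {
  cat(sprintf("<wp_encoding> %d tokens: %s\n", length(x$ids),
              paste(utils::head(x$tokens, 12), collapse = " ")))
  invisible(x)
}

#' Whitespace + punctuation pre-tokenization
#'
#' Splits on whitespace, then splits every punctuation or symbol character
#' (including "-") into its own single-character word, so that
#' "antibody-mediated" becomes "antibody", "-", "mediated". Intervals index
#' the original text (0-based, half-open); concatenating the words in order
#' recovers all non-whitespace characters.
#'
#' @param text a single string.
#' @return data.frame with columns `word`, `start`, `end`.
#' @export
basic_pretokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(word = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  pt <- pretokenize_raw(text)
  data.frame(word = pt$word, start = pt$start, end = pt$end,
             stringsAsFactors = FALSE)
}

# list-based variant used on hot paths (no data.frame overhead)
pretokenize_raw <- function(text) {
  m <- gregexpr("(*UCP)\\w+|[^\\w\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(list(word = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  list(word = substring(text, start, start + len - 1L),
       start = start - 1L, end = start + len - 1L)
}

wordpiece_split_spans <- function(word, vocab, max_word_chars = 100L) {
  n <- nchar(word)
  unk <- list(piece = "[UNK]", start = 0L, end = n)
  if (n == 0L) {
    return(list(piece = character(), start = integer(), end = integer()))
  }
  if (n > max_word_chars) return(unk)
  pieces <- character(n)
  starts <- integer(n)
  ends <- integer(n)
  np <- 0L
  from <- 1L
  lookup <- vocab$lookup
  while (from <= n) {
    to <- n
    piece <- NULL
    while (to >= from) {
      cand <- substr(word, from, to)
      if (from > 1L) cand <- paste0("##", cand)
      if (exists(cand, envir = lookup, inherits = FALSE)) {
        piece <- cand
        break
      }
      to <- to - 1L
    }
    if (is.null(piece)) return(unk)
    np <- np + 1L
    pieces[np] <- piece
    starts[np] <- from - 1L
    ends[np] <- to
    from <- to + 1L
  }
  list(piece = pieces[seq_len(np)], start = starts[seq_len(np)],
       end = ends[seq_len(np)])
}

#' Greedy longest-match WordPiece split of a single word
#'
#' Repeatedly takes the longest prefix present in the vocabulary, with the
#' "##" continuation prefix prepended for non-initial pieces; if at any point
#' no prefix matches (or the word exceeds `max_word_chars` characters) the
#' whole word falls back to a single `[UNK]`.
#'
#' @param word a single string with no whitespace.
#' @param vocab a `wp_vocabulary`.
#' @param max_word_chars guard against pathological inputs (default 100).
#' @return character vector of sub-token strings.
#' @export
wordpiece_split <- function(word, vocab, max_word_chars = 100L) {
  stopifnot(is.character(word), length(word) == 1, !grepl("\\s", word))
  wordpiece_split_spans(word, vocab, max_word_chars)$piece
}

find_added_matches <- function(text, added) {
  if (length(added$added) == 0 || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer(),
                      token = character(), stringsAsFactors = FALSE))
  }
  # longest added token first: regex alternation tries alternatives in order,
  # so at each position the longest added token wins
  toks <- added$added[order(-nchar(added$added))]
  esc <- gsub("([][{}()+*^$|\\\\?.#&~%-])", "\\\\\\1", toks)
  m <- gregexpr(paste(esc, collapse = "|"), text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer(),
                      token = character(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = start - 1L, end = start + len - 1L,
             token = substring(text, start, start + len - 1L),
             stringsAsFactors = FALSE)
}

word_index_of <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = start - 1L, end = start + len - 1L)
}

#' Tokenize raw text (context-only, no special tokens)
#'
#' Added tokens are matched greedily against the raw text FIRST (longest
#' added token wins at each position, scanning left to right), so that
#' hyphen-containing added tokens like "T-cell" survive as single units.
#' The remaining stretches are pre-tokenized on whitespace/punctuation and
#' split by greedy WordPiece. Offsets index the input text; word ids link
#' every token back to its whitespace-delimited source word.
#'
#' @param text a single string.
#' @param vocab a `wp_vocabulary` (extended, if `added` is non-empty).
#' @param added a `wp_added_tokens` (default: none).
#' @param segment segment id to assign (default 0).
#' @return A `wp_encoding` without special tokens.
#' @export
tokenize <- function(text, vocab, added = wp_added_tokens(), segment = 0L) {
  stopifnot(inherits(vocab, "wp_vocabulary"), inherits(added, "wp_added_tokens"))
  matches <- find_added_matches(text, added)
  chunks <- list()
  emit_stretch <- function(from, to) {
    # 0-based half-open [from, to) of text
    if (to <= from) return(list())
    seg <- substring(text, from + 1L, to)
    words <- pretokenize_raw(seg)
    out <- vector("list", length(words$word))
    for (i in seq_along(words$word)) {
      sp <- wordpiece_split_spans(words$word[i], vocab)
      out[[i]] <- list(piece = sp$piece,
                       start = from + words$start[i] + sp$start,
                       end = from + words$start[i] + sp$end)
    }
    out
  }
  pos <- 0L
  for (i in seq_len(nrow(matches))) {
    chunks <- c(chunks, emit_stretch(pos, matches$start[i]),
                list(list(piece = matches$token[i],
                          start = matches$start[i],
                          end = matches$end[i])))
    pos <- matches$end[i]
  }
  chunks <- c(chunks, emit_stretch(pos, nchar(text)))
  tokens <- unlist(lapply(chunks, `[[`, "piece"), use.names = FALSE)
  if (is.null(tokens)) tokens <- character(0)
  starts <- as.integer(unlist(lapply(chunks, `[[`, "start"),
                              use.names = FALSE) %||% integer(0))
  ends <- as.integer(unlist(lapply(chunks, `[[`, "end"),
                            use.names = FALSE) %||% integer(0))
  lk <- vocab$lookup
  ids <- vapply(tokens, function(tk) {
    if (exists(tk, envir = lk, inherits = FALSE)) {
      get(tk, envir = lk, inherits = FALSE)
    } else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  if (anyNA(ids)) {
    stop("token(s) missing from vocabulary: ",
         paste(unique(tokens[is.na(ids)]), collapse = ", "))
  }
  wi <- word_index_of(text)
  word_ids <- if (nrow(wi) > 0 && length(starts) > 0) {
    findInterval(starts, wi$start)
  } else {
    integer(length(starts))
  }
  wp_encoding(ids = ids, tokens = tokens,
              offsets = cbind(starts, ends),
              word_ids = word_ids,
              segment_ids = rep(as.integer(segment), length(tokens)),
              special = rep(FALSE, length(tokens)))
}

special_row <- function(vocab, token, segment) {
  list(id = token_id(vocab, token), token = token, segment = segment)
}

#' Encode a question/context pair for span extraction
#'
#' Layout: `[CLS] question [SEP] context [SEP]`, segment ids 0 for the
#' question half and 1 for the context half. When the total exceeds
#' `max_len` the context is truncated from the tail (the fixed questions are
#' short and kept whole). Context-token offsets index the ORIGINAL context
#' string.
#'
#' @param question question string.
#' @param context context string.
#' @param vocab a `wp_vocabulary`.
#' @param added a `wp_added_tokens`.
#' @param max_len maximum total number of tokens (>= question tokens + 3).
#' @return A `wp_encoding` of length at most `max_len`.
#' @export
encode_pair <- function(question, context, vocab, added = wp_added_tokens(),
                        max_len = 128L) {
  q <- tokenize(question, vocab, added, segment = 0L)
  ctx <- tokenize(context, vocab, added, segment = 1L)
  nq <- length(q$ids)
  if (nq + 3L > max_len) {
    stop(sprintf("question (%d tokens) does not fit in max_len %d", nq, max_len))
  }
  keep <- min(length(ctx$ids), max_len - nq - 3L)
  idx <- seq_len(keep)
  cls <- special_row(vocab, "[CLS]", 0L)
  sep <- special_row(vocab, "[SEP]", 0L)
  sep2 <- special_row(vocab, "[SEP]", 1L)
  wp_encoding(
    ids = c(cls$id, q$ids, sep$id, ctx$ids[idx], sep2$id),
    tokens = c("[CLS]", q$tokens, "[SEP]", ctx$tokens[idx], "[SEP]"),
    offsets = rbind(c(0L, 0L), q$offsets, c(0L, 0L),
                    ctx$offsets[idx, , drop = FALSE], c(0L, 0L)),
    word_ids = c(NA_integer_, q$word_ids, NA_integer_, ctx$word_ids[idx],
                 NA_integer_),
    segment_ids = c(0L, q$segment_ids, 0L, rep(1L, keep), 1L),
    special = c(TRUE, rep(FALSE, nq), TRUE, rep(FALSE, keep), TRUE)
  )
}

#' Encode a single text for classification or masked-language modelling
#'
#' Layout: `[CLS] text [SEP]`, all segment ids 0; the text is truncated from
#' the tail to fit `max_len`.
#'
#' @inheritParams encode_pair
#' @param text the input string.
#' @return A `wp_encoding`.
#' @export
encode_single <- function(text, vocab, added = wp_added_tokens(),
                          max_len = 128L) {
  enc <- tokenize(text, vocab, added, segment = 0L)
  keep <- min(length(enc$ids), max_len - 2L)
  idx <- seq_len(keep)
  cls <- special_row(vocab, "[CLS]", 0L)
  sep <- special_row(vocab, "[SEP]", 0L)
  wp_encoding(
    ids = c(cls$id, enc$ids[idx], sep$id),
    tokens = c("[CLS]", enc$tokens[idx], "[SEP]"),
    offsets = rbind(c(0L, 0L), enc$offsets[idx, , drop = FALSE], c(0L, 0L)),
    word_ids = c(NA_integer_, enc$word_ids[idx], NA_integer_),
    segment_ids = rep(0L, keep + 2L),
    special = c(TRUE, rep(FALSE, keep), TRUE)
  )
}

#' Strip the "##" continuation prefix for display
#' @param tokens character vector of token strings.
#' @return tokens with any leading "##" removed.
#' @export
strip_continuation <- function(tokens) sub("^##", "", tokens)
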