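SPECIAL_TOKENS <- c("[CLS]", "[SEP]", "[MASK]", "[UNK]", "[PAD]")

#' Construct a WordPiece vocabulary
#'
#' A vocabulary is an ordered list of token strings; the id of a token is its
#' 0-based position in the list, matching the plain-text vocab file dialect
#' (one token per line, id = line index). The five reserved tokens
#' `[CLS]`, `[SEP]`, `[MASK]`, `[UNK]`, `[PAD]` must be present unless
#' `require_specials = FALSE` (useful for minimal test vocabularies).
#'
#' @param tokens character vector of token strings, in id order.
#' @param cased logical; the tokenizer never lower-cases (cased lineage).
#' @param require_specials logical; insist on all five reserved tokens.
#' @return An object of class `wp_vocabulary`.
#' @export
wp_vocabulary <- function(tokens, cased = TRUE, require_specials = TRUE) {
  stopifnot(is.character(tokens))
  if (anyNA(tokens)) stop("vocabulary tokens must not contain NA")
  dup <- duplicated(tokens)
  if (any(dup)) {
    stop(sprintf("duplicate token %s at line %d",
                 dQuote(tokens[which(dup)[1]]), which(dup)[1]))
  }
  if (require_specials) {
    missing <- setdiff(SPECIAL_TOKENS, tokens)
    if (length(missing) > 0) {
      stop("vocabulary is missing special token(s): ",
           paste(missing, collapse = ", "))
    }
  }
  lookup <- new.env(parent = emptyenv(), size = max(16L, length(tokens)))
  for (i in seq_along(tokens)) assign(tokens[i], i - 1L, envir = lookup)
  specials <- intersect(SPECIAL_TOKENS, tokens)
  structure(
    list(
      tokens = tokens,
      lookup = lookup,
      specials = specials,
      cased = cased,
      continuation_prefix = "##"
    ),
    class = "wp_vocabulary"
  )
}

#' @export
print.wp_vocabulary <- function(x, ...) {
  cat(sprintf("<wp_vocabulary> %d tokens (%d specials, cased=%s)\n",
              length(x$tokens), length(x$specials), x$cased))
  invisible(x)
}

#' Vocabulary size
#' @param vocab a `wp_vocabulary`.
#' @return integer number of entries.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Token id lookup (0-based)
#'
#' @param vocab a `wp_vocabulary`.
#' @param token a single token string.
#' @return 0-based integer id, or `NA_integer_` when absent.
#' @export
token_id <- function(vocab, token) {
  if (nzchar(token) &&
      exists(token, envir = vocab$lookup, inherits = FALSE)) {
    get(token, envir = vocab$lookup, inherits = FALSE)
  } else {
    NA_integer_
  }
}

has_token <- function(vocab, token) {
  nzchar(token) && exists(token, envir = vocab$lookup, inherits = FALSE)
}

#' Read a vocabulary file
#'
#' Plain text, UTF-8, one token per line, id = 0-based line index. A single
#' trailing newline is ignored.
#'
#' @param path path to the vocab file.
#' @param require_specials logical; insist on the five reserved tokens
#'   (relax for minimal test fixtures).
#' @return A `wp_vocabulary`.
#' @export
load_vocab <- function(path, require_specials = TRUE) {
  if (!file.exists(path)) stop("vocab file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("vocab file is empty: ", path)
  wp_vocabulary(lines, require_specials = require_specials)
}

#' Write a vocabulary file
#'
#' Inverse of [load_vocab()]; emits one token per line and no trailing blank
#' line beyond the final newline.
#'
#' @param vocab a `wp_vocabulary`.
#' @param path output path.
#' @export
write_vocab <- function(vocab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vocab$tokens, con, useBytes = TRUE)
  invisible(path)
}

#' Set of raw-text added tokens
#'
#' Added tokens are appended after the base vocabulary (ids `base_size`,
#' `base_size + 1`, ...) and are matched greedily against raw text BEFORE
#' punctuation splitting, so hyphenated keywords like "T-cell" survive as
#' single units.
#'
#' @param added character vector of raw token strings, in id order.
#' @return An object of class `wp_added_tokens`.
#' @export
wp_added_tokens <- function(added = character()) {
  stopifnot(is.character(added))
  if (any(duplicated(added))) stop("duplicate added tokens")
  structure(list(added = added), class = "wp_added_tokens")
}

#' The six study keywords
#'
#' The renal-pathology keywords missing from the base cased BERT vocabulary:
#' "interstitial", "fibrosis", "tubular", "atrophy", "T-cell", "antibody".
#'
#' @return character vector of length 6.
#' @export
study_keywords <- function() {
  c("interstitial", "fibrosis", "tubular", "atrophy", "T-cell", "antibody")
}

#' Extend a vocabulary with raw-text keywords
#'
#' Keywords already present in the base vocabulary are skipped with a
#' warning; genuinely new keywords are appended in order, so a 28,996-entry
#' base grows to 29,002 with the six study keywords.
#'
#' @param vocab base `wp_vocabulary`.
#' @param keywords character vector of keywords (non-empty strings).
#' @return list with elements `vocab` (extended `wp_vocabulary`) and
#'   `added` (`wp_added_tokens` holding the genuinely new keywords).
#' @export
extend_vocabulary <- function(vocab, keywords) {
  stopifnot(inherits(vocab, "wp_vocabulary"), is.character(keywords))
  if (any(!nzchar(keywords))) stop("keywords must be non-empty strings")
  keywords <- keywords[!duplicated(keywords)]
  present <- vapply(keywords, has_token, logical(1), vocab = vocab)
  if (any(present)) {
    warning("keyword(s) already in base vocabulary, skipped: ",
            paste(keywords[present], collapse = ", "))
  }
  new_tokens <- keywords[!present]
  ext <- wp_vocabulary(c(vocab$tokens, new_tokens), cased = vocab$cased,
                       require_specials = length(vocab$specials) == 5L)
  list(vocab = ext, added = wp_added_tokens(new_tokens))
}

#' Read a keywords file (one keyword per line)
#' @param path path to a plain-text file.
#' @return character vector of keywords.
#' @export
load_keywords <- function(path) {
  kw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  kw <- kw[nzchar(kw)]
  if (length(kw) == 0) stop("keywords file contains no keywords: ", path)
  kw
}
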