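#' Masked-language-model corruption configuration
#'
#' Defaults follow the standard BERT recipe the study reuses: 15% of the
#' words are selected; of those, 80% are replaced by `[MASK]`, 10% by a
#' random token, and 10% are left unchanged. Selection is at word
#' granularity by default (`whole_word = TRUE`): all sub-tokens of a
#' selected word are corrupted together.
#'
#' @param select_rate probability a word is selected, in \[0, 1\]
#'   (0 selects nothing and leaves the encoding untouched).
#' @param mask_frac fraction of selected words replaced by `[MASK]`.
#' @param random_frac fraction replaced by a random non-special token.
#' @param keep_frac fraction left unchanged (the three must sum to 1).
#' @param whole_word logical; select at word rather than token granularity.
#' @param seed integer seed used when [mask_tokens()] is asked to seed its
#'   own draws (`local_seed = TRUE`).
#' @return An object of class `masking_config`.
#' @export
masking_config <- function(select_rate = 0.15, mask_frac = 0.80,
                           random_frac = 0.10, keep_frac = 0.10,
                           whole_word = TRUE, seed = 1L) {
  if (select_rate < 0 || select_rate > 1) {
    stop("select_rate must lie in [0, 1]")
  }
  if (abs(mask_frac + random_frac + keep_frac - 1) > 1e-8) {
    stop("mask_frac + random_frac + keep_frac must equal 1")
  }
  if (min(mask_frac, random_frac, keep_frac) < 0) {
    stop("corruption fractions must be non-negative")
  }
  structure(list(select_rate = select_rate, mask_frac = mask_frac,
                 random_frac = random_frac, keep_frac = keep_frac,
                 whole_word = isTRUE(whole_word), seed = as.integer(seed)),
            class = "masking_config")
}

#' Corrupt an encoding for masked-language-model training
#'
#' Special-token positions are never selected. With `whole_word = TRUE` the
#' Bernoulli selection and the 80/10/10 corruption category are drawn once
#' per word and applied to all of its sub-tokens; random replacements draw
#' uniformly from the non-special vocabulary ids (one draw per token).
#' Draws come from the current RNG stream unless `local_seed = TRUE`, in
#' which case `cfg$seed` is used (leaving the caller's stream untouched).
#'
#' @param encoding a `wp_encoding` with at least one non-special token.
#' @param cfg a `masking_config`.
#' @param vocab the `wp_vocabulary` (provides `[MASK]` and the non-special
#'   id pool).
#' @param local_seed logical; seed the draws from `cfg$seed`.
#' @return An object of class `masked_batch` with elements `corrupted_ids`,
#'   `labels` (original id where selected, `NA` elsewhere) and
#'   `selection_mask`.
#' @export
mask_tokens <- function(encoding, cfg, vocab, local_seed = FALSE) {
  stopifnot(inherits(encoding, "wp_encoding"),
            inherits(cfg, "masking_config"),
            inherits(vocab, "wp_vocabulary"))
  cand <- which(!encoding$special)
  if (length(cand) == 0) stop("encoding has no non-special tokens")
  special_ids <- vapply(vocab$specials, token_id, integer(1), vocab = vocab)
  pool <- setdiff(seq_len(vocab_size(vocab)) - 1L, special_ids)
  if (cfg$random_frac > 0 && length(pool) < 2) {
    stop("vocabulary too small for random replacement (need >= 2 non-special tokens)")
  }
  mask_id <- token_id(vocab, "[MASK]")
  run <- function() {
    n <- length(encoding$ids)
    # group candidate positions into units (words or single tokens)
    unit_of <- if (cfg$whole_word) {
      key <- ifelse(is.na(encoding$word_ids[cand]), -cand,
                    encoding$word_ids[cand])
      match(key, unique(key))
    } else {
      seq_along(cand)
    }
    n_units <- max(unit_of)
    sel_unit <- stats::runif(n_units) < cfg$select_rate
    u <- stats::runif(n_units)
    cat_unit <- ifelse(u < cfg$mask_frac, "mask",
                       ifelse(u < cfg$mask_frac + cfg$random_frac,
                              "random", "keep"))
    selected <- cand[sel_unit[unit_of]]
    categories <- cat_unit[unit_of][sel_unit[unit_of]]
    corrupted <- encoding$ids
    corrupted[selected[categories == "mask"]] <- mask_id
    rnd <- selected[categories == "random"]
    if (length(rnd) > 0) {
      corrupted[rnd] <- sample(pool, length(rnd), replace = TRUE)
    }
    labels <- rep(NA_integer_, n)
    labels[selected] <- encoding$ids[selected]
    mask <- rep(FALSE, n)
    mask[selected] <- TRUE
    structure(list(corrupted_ids = corrupted, labels = labels,
                   selection_mask = mask),
              class = "masked_batch")
  }
  if (local_seed) with_preserved_rng({ set.seed(cfg$seed); run() }) else run()
}

#' Chunk report texts into masked-language-model training encodings
#'
#' Concatenates each report's sections, tokenizes once, and wraps
#' consecutive windows of at most `max_len - 2` tokens in `[CLS]`/`[SEP]`.
#'
#' @param reports list of `pb_report`s.
#' @param vocab a `wp_vocabulary`.
#' @param added a `wp_added_tokens`.
#' @param max_len window length including the two specials.
#' @return list of `wp_encoding`s.
#' @export
prepare_mlm_encodings <- function(reports, vocab, added = wp_added_tokens(),
                                  max_len = 128L) {
  out <- list()
  cls_id <- token_id(vocab, "[CLS]")
  sep_id <- token_id(vocab, "[SEP]")
  for (rep in reports) {
    text <- paste(unlist(rep$sections), collapse = "\n")
    enc <- tokenize(text, vocab, added)
    n <- length(enc$ids)
    if (n == 0) next
    starts <- seq(1L, n, by = max_len - 2L)
    for (s in starts) {
      idx <- s:min(n, s + max_len - 3L)
      out[[length(out) + 1L]] <- wp_encoding(
        ids = c(cls_id, enc$ids[idx], sep_id),
        tokens = c("[CLS]", enc$tokens[idx], "[SEP]"),
        offsets = rbind(c(0L, 0L), enc$offsets[idx, , drop = FALSE],
                        c(0L, 0L)),
        word_ids = c(NA_integer_, enc$word_ids[idx], NA_integer_),
        segment_ids = rep(0L, length(idx) + 2L),
        special = c(TRUE, rep(FALSE, length(idx)), TRUE))
    }
  }
  out
}

# forward + masked-token loss/grads for one encoding; accumulates into env
mlm_example_pass <- function(model, enc, batch, acc) {
  sel <- which(batch$selection_mask)
  if (length(sel) == 0) return(invisible(NULL))
  fw <- encoder_fwd(model, batch$corrupted_ids, enc$segment_ids,
                    cache = TRUE, train = TRUE)
  hsel <- fw$out[sel, , drop = FALSE]
  logits <- add_bias(hsel %*% model$params$mlm_W, model$params$mlm_b)
  logp <- log_softmax_rows(logits)
  lab <- batch$labels[sel] + 1L
  acc$loss <- acc$loss + sum(-logp[cbind(seq_along(sel), lab)])
  acc$count <- acc$count + length(sel)
  dlogits <- exp(logp)
  dlogits[cbind(seq_along(sel), lab)] <-
    dlogits[cbind(seq_along(sel), lab)] - 1
  acc$g$mlm_W <- acc$g$mlm_W + crossprod(hsel, dlogits)
  acc$g$mlm_b <- acc$g$mlm_b + colSums(dlogits)
  d_out <- matrix(0, length(batch$corrupted_ids), model$config$hidden_dim)
  d_out[sel, ] <- dlogits %*% t(model$params$mlm_W)
  enc_g <- encoder_bwd(model, fw, d_out)
  for (nm in names(enc_g)) acc$g[[nm]] <- tree_add(acc$g[[nm]], enc_g[[nm]])
  invisible(NULL)
}

#' Masked-language-model pre-training loop
#'
#' Iterates epochs over shuffled batches; the loss is cross-entropy over the
#' corrupted (labelled) positions only, and every parameter of the encoder
#' and masked-token head updates via Adam. Fully reproducible given the
#' seeds in `train_cfg`.
#'
#' @param model a `pb_model`.
#' @param corpus non-empty list of `wp_encoding`s
#'   (see [prepare_mlm_encodings()]).
#' @param mask_cfg a `masking_config`.
#' @param train_cfg a `train_config`.
#' @param vocab the `wp_vocabulary`.
#' @return list with the trained `model` and `trace` (per-epoch mean loss).
#' @export
pretrain_mlm <- function(model, corpus, mask_cfg, train_cfg, vocab) {
  if (length(corpus) == 0) stop("empty corpus")
  stopifnot(inherits(train_cfg, "train_config"))
  trace <- numeric(0)
  if (train_cfg$epochs == 0) return(list(model = model, trace = trace))
  with_preserved_rng({
    set.seed(train_cfg$seed)
    state <- adam_state(model$params)
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(corpus))
      ep_loss <- 0
      ep_count <- 0L
      for (bi in split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))) {
        acc <- new.env(parent = emptyenv())
        acc$g <- tree_zeros(model$params)
        acc$loss <- 0
        acc$count <- 0L
        for (i in bi) {
          batch <- mask_tokens(corpus[[i]], mask_cfg, vocab)
          mlm_example_pass(model, corpus[[i]], batch, acc)
        }
        if (acc$count == 0L) next
        grads <- tree_scale(acc$g, 1 / acc$count)
        if (train_cfg$freeze_encoder) grads <- freeze_encoder_grads(grads)
        step <- adam_step(model$params, grads, state, train_cfg$lr)
        model$params <- step$params
        state <- step$state
        ep_loss <- ep_loss + acc$loss
        ep_count <- ep_count + acc$count
      }
      trace <- c(trace, ep_loss / max(1L, ep_count))
    }
    list(model = model, trace = trace)
  })
}
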