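IR_QUESTION_IDS <- c("rejection", "rejection_abmr", "rejection_tcmr", "ifta")

question_for <- function(question_id) {
  if (question_id == "ifta") study_questions()[["ifta"]]
  else study_questions()[["rejection"]]
}

gold_entries_for <- function(report, question_id) {
  switch(question_id,
         rejection = c(report$gold$rejection_abmr, report$gold$rejection_tcmr),
         rejection_abmr = report$gold$rejection_abmr,
         rejection_tcmr = report$gold$rejection_tcmr,
         ifta = report$gold$ifta,
         stop("unknown question_id: ", question_id))
}

#' Build a span-extraction training example from a report
#'
#' The context is the report's Comments (when present) followed by its
#' Microscopic Description; the question is one of the two fixed study
#' questions. Gold character spans are mapped to token spans through the
#' encoding offsets: a token belongs to the span when its character interval
#' intersects it. An example whose gold span was truncated away gets the
#' no-answer sentinel and a warning.
#'
#' @param report a `pb_report`.
#' @param question_id one of "rejection", "rejection_abmr",
#'   "rejection_tcmr", "ifta" (the rejection variants share the rejection
#'   question but score against that subtask's gold spans).
#' @param vocab a `wp_vocabulary`.
#' @param added a `wp_added_tokens`.
#' @param max_len maximum encoding length.
#' @return An object of class `ir_example` with the encoding, the gold
#'   character answers, and `gold_token_span` (1-based start/end encoding
#'   positions, or `NULL` for no answer).
#' @export
build_ir_example <- function(report, question_id, vocab,
                             added = wp_added_tokens(), max_len = 128L) {
  if (!question_id %in% IR_QUESTION_IDS) {
    stop("unknown question_id: ", question_id)
  }
  context <- ir_context(report)
  if (is.null(context)) stop("report lacks a Microscopic Description")
  enc <- encode_pair(question_for(question_id), context, vocab, added,
                     max_len = max_len)
  gold <- gold_entries_for(report, question_id)
  span <- NULL
  if (length(gold) > 0) {
    g <- gold[[1]]  # training target: the first tagged mention
    ctx_pos <- which(enc$segment_ids == 1L & !enc$special)
    hit <- ctx_pos[enc$offsets[ctx_pos, 1] < g$end &
                     enc$offsets[ctx_pos, 2] > g$start]
    if (length(hit) == 0) {
      warning(sprintf("gold span of report %s truncated away; using the no-answer sentinel",
                      report$report_id))
    } else {
      span <- c(min(hit), max(hit))
    }
  }
  structure(list(report_id = report$report_id, question_id = question_id,
                 question = question_for(question_id), context = context,
                 gold_answers = gold, encoding = enc,
                 gold_token_span = span),
            class = "ir_example")
}

#' Decode a span prediction from start/end probabilities
#'
#' Start and end are independent argmaxes over the context positions plus
#' the `[CLS]` position (the no-answer sentinel that no-answer training
#' supervises); the prediction is the literal "no information" when either
#' argmax lands on `[CLS]` or when the end argmax falls before the start
#' argmax.
#'
#' @param s_probs probability vector over encoding positions (start).
#' @param e_probs probability vector over encoding positions (end).
#' @param encoding the `wp_encoding` the vectors index.
#' @param context optional context string used to recover the answer text.
#' @return An object of class `span_prediction` with fields `start`, `end`
#'   (1-based encoding positions), `text` and `char_interval` (0-based
#'   half-open, `NULL` for no information).
#' @export
decode_span <- function(s_probs, e_probs, encoding, context = NULL) {
  n <- length(encoding$ids)
  stopifnot(length(s_probs) == n, length(e_probs) == n)
  ctx_pos <- which(encoding$segment_ids == 1L & !encoding$special)
  if (length(ctx_pos) == 0) stop("encoding has no context positions")
  cand <- c(1L, ctx_pos)  # [CLS] is the decodable no-answer sentinel
  start <- cand[which.max(s_probs[cand])]
  end <- cand[which.max(e_probs[cand])]
  if (end < start || start == 1L || end == 1L) {
    return(structure(list(start = start, end = end, text = "no information",
                          char_interval = NULL),
                     class = "span_prediction"))
  }
  iv <- c(encoding$offsets[start, 1], encoding$offsets[end, 2])
  text <- if (!is.null(context)) {
    substr(context, iv[1] + 1L, iv[2])
  } else {
    paste(strip_continuation(encoding$tokens[start:end]), collapse = " ")
  }
  structure(list(start = start, end = end, text = text, char_interval = iv),
            class = "span_prediction")
}

#' Predict an answer span for one example
#'
#' @param model a `pb_model`.
#' @param example an `ir_example`.
#' @return a `span_prediction`.
#' @export
predict_span <- function(model, example) {
  z <- span_logits(model, example$encoding)
  decode_span(softmax_probs(z$S), softmax_probs(z$E), example$encoding,
              context = example$context)
}

ir_targets <- function(example) {
  if (is.null(example$gold_token_span)) c(1L, 1L) else example$gold_token_span
}

span_example_pass <- function(model, example, acc) {
  enc <- example$encoding
  fw <- encoder_fwd(model, enc$ids, enc$segment_ids, cache = TRUE,
                    train = TRUE)
  z <- add_bias(fw$out %*% model$params$span_W, model$params$span_b)
  tgt <- ir_targets(example)
  dz <- matrix(0, nrow(z), 2)
  for (j in 1:2) {
    lp <- z[, j] - max(z[, j])
    lp <- lp - log(sum(exp(lp)))
    acc$loss <- acc$loss + (-lp[tgt[j]])
    p <- exp(lp)
    p[tgt[j]] <- p[tgt[j]] - 1
    dz[, j] <- p
  }
  acc$count <- acc$count + 1L
  acc$g$span_W <- acc$g$span_W + crossprod(fw$out, dz)
  acc$g$span_b <- acc$g$span_b + colSums(dz)
  enc_g <- encoder_bwd(model, fw, dz %*% t(model$params$span_W))
  for (nm in names(enc_g)) acc$g[[nm]] <- tree_add(acc$g[[nm]], enc_g[[nm]])
  invisible(NULL)
}

run_training <- function(model, examples, train_cfg, pass, freeze_keep) {
  trace <- numeric(0)
  if (train_cfg$epochs == 0 || train_cfg$lr == 0) {
    return(list(model = model, trace = trace))
  }
  with_preserved_rng({
    set.seed(train_cfg$seed)
    state <- adam_state(model$params)
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(examples))
      ep_loss <- 0
      ep_count <- 0L
      for (bi in split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))) {
        acc <- new.env(parent = emptyenv())
        acc$g <- tree_zeros(model$params)
        acc$loss <- 0
        acc$count <- 0L
        for (i in bi) pass(model, examples[[i]], acc)
        if (acc$count == 0L) next
        grads <- tree_scale(acc$g, 1 / acc$count)
        if (train_cfg$freeze_encoder) {
          grads <- freeze_encoder_grads(grads)
          kept <- grads[freeze_keep]
          grads <- tree_zeros(grads)
          grads[freeze_keep] <- kept
        }
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

#' Fine-tune the span-extraction head (and, by default, the whole encoder)
#'
#' The loss per example is the sum of the start and end cross-entropies
#' (softmax over all encoding positions), averaged over the batch. By
#' default every model parameter updates; `train_cfg$freeze_encoder = TRUE`
#' trains only the span head on fixed encoder outputs. No-answer examples
#' supervise both start and end onto the `[CLS]` position.
#'
#' @param model a `pb_model`.
#' @param examples non-empty list of `ir_example`s.
#' @param train_cfg a `train_config`.
#' @return list with the fine-tuned `model` and `trace` (per-epoch mean loss).
#' @export
finetune_ir <- function(model, examples, train_cfg) {
  if (length(examples) == 0) stop("no training examples")
  run_training(model, examples, train_cfg, span_example_pass,
               freeze_keep = c("span_W", "span_b"))
}

#' Evaluate span predictions against gold answers
#'
#' @param model a `pb_model`.
#' @param examples list of `ir_example`s.
#' @param average passed to [ir_report()].
#' @return one-row data.frame of IR metrics.
#' @export
evaluate_ir <- function(model, examples, average = "macro") {
  pairs <- lapply(examples, function(ex) {
    pred <- predict_span(model, ex)
    span_pair(
      predicted = pred$char_interval,
      gold = lapply(ex$gold_answers, function(g) c(g$start, g$end)),
      gold_texts = vapply(ex$gold_answers, `[[`, character(1), "text"),
      predicted_text = pred$text)
  })
  ir_report(pairs, vapply(examples, `[[`, character(1), "context"),
            average = average)
}

REJECTION_TRIGGERS <- c("rejection", "ABMR", "TCMR")
IFTA_TRIGGERS <- c("severe", "moderate", "mild", "minimal", "absent",
                   "interstitial fibrosis", "tubular atrophy")

#' Redact task-revealing sentences for the classification task
#'
#' Splits the Microscopic Description into sentences (on ". " and newline
#' boundaries — crude but deterministic, adequate for templated text) and
#' deletes every sentence containing a task trigger phrase, so the
#' classifier cannot read the answer off the input. The label comes from the
#' report metadata: rejection (binary; `rejection_mode` chooses any/ABMR/
#' TCMR positivity) or the six-class IFTA grade.
#'
#' @param report a `pb_report`.
#' @param task "rejection" or "ifta".
#' @param rejection_mode "any" (default), "abmr" or "tcmr".
#' @return An object of class `cls_example` with `text`, `label`,
#'   `report_id`.
#' @export
redact_for_classification <- function(report, task = c("rejection", "ifta"),
                                      rejection_mode = c("any", "abmr", "tcmr")) {
  task <- match.arg(task)
  rejection_mode <- match.arg(rejection_mode)
  micro <- report$sections$`Microscopic Description`
  if (is.null(micro)) stop("report lacks a Microscopic Description")
  triggers <- if (task == "rejection") REJECTION_TRIGGERS else IFTA_TRIGGERS
  sentences <- strsplit(micro, "(?<=\\.) |\n", perl = TRUE)[[1]]
  hit <- vapply(sentences, function(s) {
    any(vapply(triggers, function(tr) {
      grepl(tr, s, ignore.case = TRUE, fixed = FALSE)
    }, logical(1)))
  }, logical(1))
  kept <- sentences[!hit]
  if (length(kept) == 0) {
    warning(sprintf("all sentences of report %s were redacted for task %s",
                    report$report_id, task))
  }
  label <- if (task == "rejection") {
    pos <- switch(rejection_mode,
                  any = report$labels$abmr || report$labels$tcmr,
                  abmr = report$labels$abmr,
                  tcmr = report$labels$tcmr)
    if (pos) "positive" else "negative"
  } else {
    report$labels$ifta_grade
  }
  structure(list(report_id = report$report_id,
                 text = paste(kept, collapse = " "), label = label),
            class = "cls_example")
}

cls_example_pass_factory <- function(classes) {
  force(classes)
  function(model, example, acc) {
    enc <- example$encoding
    fw <- encoder_fwd(model, enc$ids, enc$segment_ids, cache = TRUE,
                      train = TRUE)
    h1 <- fw$out[1, , drop = FALSE]
    z <- drop(h1 %*% model$params$cls_W) + model$params$cls_b
    lp <- z - max(z)
    lp <- lp - log(sum(exp(lp)))
    tgt <- match(example$label, classes)
    acc$loss <- acc$loss + (-lp[tgt])
    acc$count <- acc$count + 1L
    p <- exp(lp)
    p[tgt] <- p[tgt] - 1
    acc$g$cls_W <- acc$g$cls_W + crossprod(h1, matrix(p, nrow = 1))
    acc$g$cls_b <- acc$g$cls_b + p
    d_out <- matrix(0, length(enc$ids), model$config$hidden_dim)
    d_out[1, ] <- model$params$cls_W %*% p
    enc_g <- encoder_bwd(model, fw, d_out)
    for (nm in names(enc_g)) acc$g[[nm]] <- tree_add(acc$g[[nm]], enc_g[[nm]])
    invisible(NULL)
  }
}

attach_cls_encoding <- function(example, vocab, added, max_len) {
  example$encoding <- encode_single(example$text, vocab, added, max_len)
  example
}

#' Fine-tune the `[CLS]` classification head (and the encoder)
#'
#' Cross-entropy on the `[CLS]` logits; all parameters update unless
#' `train_cfg$freeze_encoder`. Examples are encoded as `[CLS] text [SEP]`.
#'
#' @param model a `pb_model`.
#' @param examples non-empty list of `cls_example`s.
#' @param classes character vector fixing the class-index order; all labels
#'   must appear in it.
#' @param train_cfg a `train_config`.
#' @param vocab a `wp_vocabulary`.
#' @param added a `wp_added_tokens`.
#' @param max_len maximum encoding length.
#' @return list with the fine-tuned `model`, `trace`, and `classes`.
#' @export
finetune_cls <- function(model, examples, classes, train_cfg, vocab,
                         added = wp_added_tokens(), max_len = 128L) {
  if (length(examples) == 0) stop("no training examples")
  if (length(classes) < 2) stop("need at least 2 classes")
  labels <- vapply(examples, `[[`, character(1), "label")
  if (any(!labels %in% classes)) {
    stop("label(s) outside the class set: ",
         paste(setdiff(labels, classes), collapse = ", "))
  }
  model <- ensure_cls_head(model, length(classes))
  model$cls_classes <- classes
  examples <- lapply(examples, attach_cls_encoding, vocab = vocab,
                     added = added, max_len = max_len)
  out <- run_training(model, examples, train_cfg,
                      cls_example_pass_factory(classes),
                      freeze_keep = c("cls_W", "cls_b"))
  out$classes <- classes
  out
}

#' Predict a class for a redacted example
#'
#' @param model a fine-tuned `pb_model` (with a classifier head).
#' @param example a `cls_example`.
#' @param vocab,added,max_len tokenizer context (must match training).
#' @return list with `class` (label string) and `probs` (named probability
#'   vector summing to 1).
#' @export
predict_cls <- function(model, example, vocab, added = wp_added_tokens(),
                        max_len = 128L) {
  if (is.null(model$params$cls_W) || is.null(model$cls_classes)) {
    stop("model has no fitted classification head")
  }
  enc <- encode_single(example$text, vocab, added, max_len)
  z <- cls_logits(model, enc, ncol(model$params$cls_W))
  probs <- softmax_probs(z)
  names(probs) <- model$cls_classes
  list(class = model$cls_classes[which.max(probs)], probs = probs)
}

#' Evaluate a fitted classifier on examples
#'
#' @inheritParams predict_cls
#' @param examples list of `cls_example`s.
#' @param positive_class,weighted passed to [classification_report()].
#' @return one-row data.frame of classification metrics.
#' @export
evaluate_cls <- function(model, examples, vocab, added = wp_added_tokens(),
                         max_len = 128L, positive_class = NULL,
                         weighted = is.null(positive_class)) {
  y_true <- vapply(examples, `[[`, character(1), "label")
  y_pred <- vapply(examples, function(ex) {
    predict_cls(model, ex, vocab, added, max_len)$class
  }, character(1))
  classification_report(y_true, y_pred, positive_class = positive_class,
                        weighted = weighted)
}
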