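ABLATION_ARMS <- c("base_vocab", "extended_vocab", "no_pretrain",
                   "frozen_encoder")
ABLATION_TASKS <- c("rejection_ir_abmr", "rejection_ir_tcmr", "ifta_ir",
                    "rejection_cls", "ifta_cls")

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 7907) %% 2147483629)
}

#' Configuration of the vocabulary-extension ablation
#'
#' The ablation compares pipelines that differ only in vocabulary handling:
#' `base_vocab` (keywords split into sub-words), `extended_vocab` (the six
#' keywords appended as whole tokens, embedding rows warm-started from
#' their sub-word means), `no_pretrain` (skip the masked-language-model
#' stage) and `frozen_encoder` (task head only, encoder fixed). Within a
#' seed every arm sees the identical corpus and train/eval split.
#'
#' The default corpus is keyword-dense: rejection statuses are balanced far
#' above the study prevalence so that every report carries rejection
#' phrasing for the span task to retrieve. Training defaults are
#' deliberately scarce (one pre-training epoch, two fine-tuning epochs):
#' the small-corpus regime under study keeps both arms off ceiling, where
#' the vocabulary effect is visible as faster learning rather than washed
#' out by saturation on templated text.
#'
#' @param n_reports corpus size per seed.
#' @param arms subset of the four arm names.
#' @param seeds integer vector of replicate seeds.
#' @param tasks subset of the five task names.
#' @param corpus_args extra arguments for [corpus_spec()].
#' @param model_args extra arguments for [model_config()].
#' @param mask_cfg a `masking_config`.
#' @param pretrain_epochs,finetune_epochs,batch_size,lr training sizes.
#' @param max_len encoding length for all tasks.
#' @param eval_fraction held-out fraction.
#' @return An object of class `ablation_config`.
#' @export
ablation_config <- function(n_reports = 500L,
                            arms = c("base_vocab", "extended_vocab"),
                            seeds = 1:5,
                            tasks = "rejection_ir_abmr",
                            corpus_args = list(p_abmr = 0.35, p_tcmr = 0.25,
                                               p_negative_mention = 0.45,
                                               keyword_density = 2),
                            model_args = list(),
                            mask_cfg = masking_config(),
                            pretrain_epochs = 1L, finetune_epochs = 2L,
                            batch_size = 16L, lr = 1e-3,
                            max_len = 96L, eval_fraction = 0.20) {
  stopifnot(all(arms %in% ABLATION_ARMS), length(arms) >= 1,
            all(tasks %in% ABLATION_TASKS), length(tasks) >= 1,
            length(seeds) >= 1)
  structure(list(n_reports = as.integer(n_reports), arms = arms,
                 seeds = as.integer(seeds), tasks = tasks,
                 corpus_args = corpus_args, model_args = model_args,
                 mask_cfg = mask_cfg,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 max_len = as.integer(max_len),
                 eval_fraction = eval_fraction),
            class = "ablation_config")
}

arm_uses_extended <- function(arm) arm == "extended_vocab"
arm_pretrains <- function(arm) arm != "no_pretrain"

run_ir_task <- function(model, examples, cfg, seed, freeze) {
  tc <- train_config(epochs = cfg$finetune_epochs,
                     batch_size = cfg$batch_size, lr = cfg$lr,
                     seed = derive_seed(seed, 31L),
                     freeze_encoder = freeze)
  fit <- finetune_ir(model, examples$train, tc)
  evaluate_ir(fit$model, examples$eval)
}

run_cls_task <- function(task, model, examples, vocab, added, cfg, seed,
                         freeze) {
  is_rej <- task == "rejection_cls"
  classes <- if (is_rej) c("negative", "positive") else IFTA_GRADES
  tc <- train_config(epochs = cfg$finetune_epochs,
                     batch_size = cfg$batch_size, lr = cfg$lr,
                     seed = derive_seed(seed, 37L),
                     freeze_encoder = freeze)
  fit <- finetune_cls(model, examples$train, classes, tc, vocab, added,
                      max_len = cfg$max_len)
  evaluate_cls(fit$model, examples$eval, vocab, added,
               max_len = cfg$max_len,
               positive_class = if (is_rej) "positive" else NULL)
}

#' Run the vocabulary-extension ablation
#'
#' For each seed: generate a corpus, split it once, build the base fixture
#' vocabulary and its six-keyword extension, pre-train one model per
#' vocabulary variant, then fine-tune and evaluate every (arm, task) cell on
#' the shared held-out reports. Arms within a seed share the corpus, split
#' and initial parameters, so they differ only in vocabulary handling (or in
#' skipping pre-training / freezing the encoder).
#'
#' @param cfg an `ablation_config`.
#' @param verbose print per-cell progress.
#' @return An object of class `ablation_result`: `results` (one row per
#'   arm/task/seed), `medians` (per arm/task medians across seeds), `config`.
#' @export
run_ablation <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "ablation_config"))
  rows <- list()
  for (seed in cfg$seeds) {
    spec <- do.call(corpus_spec, c(list(n_reports = cfg$n_reports,
                                        seed = derive_seed(seed, 1L)),
                                   cfg$corpus_args))
    corpus <- generate_corpus(spec)
    split <- split_train_eval(corpus, cfg$eval_fraction,
                              seed = derive_seed(seed, 2L))
    base_vocab <- build_fixture_vocab(corpus)
    ext <- extend_vocabulary(base_vocab, study_keywords())
    model_seed <- derive_seed(seed, 3L)
    base_cfg <- do.call(model_config,
                        c(list(vocab_size = vocab_size(base_vocab),
                               max_position = cfg$max_len,
                               seed = model_seed),
                          cfg$model_args))
    base_init <- init_model(base_cfg)
    ext_init <- resize_token_embeddings(
      base_init, vocab_size(ext$vocab), "mean_of_subwords",
      subword_ids = subword_ids_for_keywords(base_vocab, ext$added$added))

    pretrained <- list()
    get_model <- function(arm) {
      variant <- if (arm_uses_extended(arm)) "ext" else "base"
      init <- if (variant == "ext") ext_init else base_init
      vocab <- if (variant == "ext") ext$vocab else base_vocab
      added <- if (variant == "ext") ext$added else wp_added_tokens()
      if (!arm_pretrains(arm)) {
        return(list(model = init, vocab = vocab, added = added))
      }
      if (is.null(pretrained[[variant]])) {
        encs <- prepare_mlm_encodings(split$train, vocab, added,
                                      max_len = cfg$max_len)
        tc <- train_config(epochs = cfg$pretrain_epochs,
                           batch_size = cfg$batch_size, lr = cfg$lr,
                           seed = derive_seed(seed, 11L))
        pretrained[[variant]] <<- pretrain_mlm(init, encs, cfg$mask_cfg,
                                               tc, vocab)$model
      }
      list(model = pretrained[[variant]], vocab = vocab, added = added)
    }

    ex_cache <- list()
    get_examples <- function(variant, task, vocab, added) {
      key <- paste(variant, task)
      if (is.null(ex_cache[[key]])) {
        ex_cache[[key]] <<- if (grepl("_ir", task)) {
          qid <- switch(task,
                        rejection_ir_abmr = "rejection_abmr",
                        rejection_ir_tcmr = "rejection_tcmr",
                        ifta_ir = "ifta")
          mk <- function(reports) {
            suppressWarnings(lapply(reports, build_ir_example,
                                    question_id = qid, vocab = vocab,
                                    added = added, max_len = cfg$max_len))
          }
          list(train = mk(split$train), eval = mk(split$eval))
        } else {
          redact <- function(reports) {
            suppressWarnings(lapply(
              reports, redact_for_classification,
              task = if (task == "rejection_cls") "rejection" else "ifta"))
          }
          list(train = redact(split$train), eval = redact(split$eval))
        }
      }
      ex_cache[[key]]
    }

    for (arm in cfg$arms) {
      mv <- get_model(arm)
      freeze <- arm == "frozen_encoder"
      variant <- if (arm_uses_extended(arm)) "ext" else "base"
      for (task in cfg$tasks) {
        if (verbose) {
          message(sprintf("seed %d | arm %s | task %s", seed, arm, task))
        }
        examples <- get_examples(variant, task, mv$vocab, mv$added)
        row <- if (grepl("_ir", task)) {
          run_ir_task(mv$model, examples, cfg, seed, freeze)
        } else {
          run_cls_task(task, mv$model, examples, mv$vocab, mv$added, cfg,
                       seed, freeze)
        }
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(arm = arm, task = task, seed = seed), row)
      }
    }
  }
  results <- do.call(rbind, lapply(rows, function(r) {
    # align columns across IR and CLS rows
    all_cols <- c("arm", "task", "seed", "overlap_ratio_char",
                  "overlap_ratio_word", "exact_match_rate", "accuracy",
                  "positive_precision", "positive_recall", "positive_f1",
                  "weighted_precision", "weighted_recall", "weighted_f1")
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA_real_
    r[all_cols]
  }))
  metric_cols <- setdiff(names(results), c("arm", "task", "seed"))
  medians <- do.call(rbind, lapply(
    split(results, list(results$arm, results$task), drop = TRUE),
    function(d) {
      out <- data.frame(arm = d$arm[1], task = d$task[1])
      for (col in metric_cols) {
        out[[col]] <- stats::median(d[[col]])
      }
      out
    }))
  rownames(medians) <- NULL
  structure(list(results = results, medians = medians, config = cfg),
            class = "ablation_result")
}

PAPER_HEADERS <- c(
  accuracy = "Overall Acc", positive_precision = "Positive precision",
  positive_recall = "Positive recall", positive_f1 = "Positive F1-score",
  weighted_precision = "Weighted precision",
  weighted_recall = "Weighted recall", weighted_f1 = "Weighted F1-score",
  overlap_ratio_char = "Overlap Ratio char",
  overlap_ratio_word = "Overlap Ratio word",
  exact_match_rate = "Exact match rate")

#' Write per-task ablation tables and a run log
#'
#' One TSV per task (rows = arms, median metrics across seeds, columns named
#' after the conventional report headers) plus `run_log.json` capturing
#' every configuration value and the full per-seed results.
#'
#' @param result an `ablation_result`.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
report_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "ablation_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (task in unique(result$medians$task)) {
    d <- result$medians[result$medians$task == task, , drop = FALSE]
    d <- d[order(match(d$arm, ABLATION_ARMS)), , drop = FALSE]
    keep <- c("arm", names(PAPER_HEADERS)[names(PAPER_HEADERS) %in%
                                            names(d)[!vapply(d, anyNA, logical(1))]])
    out <- d[, keep, drop = FALSE]
    names(out) <- c("Model", unname(PAPER_HEADERS[keep[-1]]))
    path <- file.path(out_dir, paste0(task, ".tsv"))
    utils::write.table(format(out, digits = 4, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path)
  }
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(
    list(config = unclass(result$config),
         results = result$results, medians = result$medians),
    log_path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    force = TRUE)
  files <- c(files, log_path)
  invisible(files)
}
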