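---
title: "Vocabulary extension and span-extraction IR on renal pathology reports: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocabulary extension and span-extraction IR on renal pathology reports: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbert)
```

## The problem

Kidney-transplant biopsy reports are unstructured text with a conventional
section layout (Diagnosis, Tissues, Gross Description, Microscopic
Description, sometimes Comments). Two clinically central questions are
"What kind of rejection does the patient show?" (antibody-mediated, ABMR,
or T-cell-mediated, TCMR) and "What is the grade of interstitial fibrosis
and tubular atrophy?" (IFTA, graded severe / moderate / mild / minimal /
absent). Extractive question answering — predicting a start and an end
position in the report rather than generating text — is a natural fit,
but BERT-family models inherit a fixed WordPiece vocabulary in which the
domain keywords `interstitial`, `fibrosis`, `tubular`, `atrophy`, `T-cell`
and `antibody` do not occur: they are fragmented into sub-words
(`inter ##st ##iti ##al`), which dilutes exactly the tokens that mark the
answers. `pathbert` implements, at desk scale, the full pipeline needed to
study this effect: a cased WordPiece tokenizer with raw-text added-token
extension, a compact transformer encoder with masked-language-model (MLM),
span and `[CLS]` heads, whole-word MLM pre-training, span fine-tuning with a
"no information" decode rule, overlap-based evaluation metrics, a synthetic
report generator with gold answer spans, and an ablation driver that
compares base against extended vocabularies under otherwise identical
conditions.

The package deliberately does not attempt to reproduce full-scale
clinical results: those require pretrained clinical BERT weights, a private
corpus of ~3,400 real reports and GPU fine-tuning. What is reproducible on
one CPU in minutes is (a) every printed procedural constant and worked
example of the method and (b) the *direction* of the central claim —
extending the vocabulary helps keyword-bearing span retrieval on a small
corpus.

## Tokenization

`tokenize()` runs three stages:

1. **Added-token matching on raw text.** The added keywords are matched
   greedily (longest token wins at each position, scanning left to right)
   against the *raw* string, before any punctuation splitting. Only this
   ordering lets a hyphenated keyword like `T-cell` survive as one token
   while `antibody-mediated` still splits into `antibody`, `-`,
   `mediated`. Matching is substring-based (as in the reference slow
   tokenizers), so `peritubular` legitimately re-splits around the
   embedded `tubular`.
2. **Pre-tokenization.** Whitespace splitting, then every punctuation or
   symbol character becomes its own single-character word. Offsets are
   0-based half-open intervals into the source text.
3. **Greedy WordPiece.** Longest-prefix-first against the vocabulary, with
   `##` marking non-initial pieces; a word with no matching prefix (or
   longer than 100 characters, a guard against pathological input) becomes
   a single `[UNK]`.

Casing is preserved throughout — the 28,996-entry reference vocabulary is
the *cased* lineage, and the synthetic corpus distinguishes sentence-initial
`Mild` from `mild`. `encode_pair()` lays out
`[CLS] question [SEP] context [SEP]` with segment ids 0/1 and truncates the
context tail when the total exceeds `max_len`; the fixed questions are short
and always kept whole. This plain head-truncation (rather than sliding
windows) is the simplest contract consistent with the tasks here, where
answers in the synthetic data sit in the Comments block at the head of the
context; `build_ir_example()` warns and falls back to the no-answer
sentinel when a gold span is truncated away.

One detail is under-determined by the sources: the printed base split of
"antibody" is `anti`, `body` without the continuation marker, while the
"interstitial" split is printed with `##` markers. Standard WordPiece
yields `anti ##body`; the package emits the standard form, and
`strip_continuation()` recovers the display form.

## The encoder

`init_model()` builds a standard post-layer-norm transformer encoder:
learned token, position and segment embeddings; per layer, multi-head
scaled-dot-product self-attention and a GELU feed-forward block, each with
a residual connection and layer norm. The full-scale reference stack is 12
layers; the desk-scale default is **2 layers, 64 hidden units, 4 heads,
256 feed-forward units, 128 positions** — large enough to learn the
synthetic tasks, small enough for CPU minutes. GELU is evaluated through
the usual sigmoid approximation `x * sigmoid(1.702 x)`; the same function
is used in forward and backward passes, so the approximation does not bias
gradients. Dropout (default 0 at this scale) is applied to the embedding
output and each sub-layer output when enabled.

Three linear heads sit on the contextual vectors: per-position vocabulary
scores for MLM, one shared linear map producing the start/end score vectors
S and E for span extraction, and a classifier reading only the `[CLS]`
position. Probabilities come from a shift-invariant softmax
(`p_i = exp(s_i) / sum_j exp(s_j)`, maximum subtracted first) and training
minimizes cross-entropy `-log p[truth]`, with probabilities floored at
1e-12 (logged) so a degenerate prediction cannot produce an infinite loss
while real bugs remain visible.

The backward pass is hand-derived for this fixed architecture and verified
against central finite differences in the test suite; the optimizer is
Adam (default learning rate 1e-3, batch 16 — unreported in the source
study, so chosen for the tiny-model scale and exposed in
`train_config()`). All training loops are seeded end to end: corpus
generation, splitting, parameter initialization, masking draws, batch
shuffling and dropout come from explicitly derived RNG streams, and
re-running any function with the same inputs reproduces its outputs
bit for bit.

## Vocabulary extension

`extend_vocabulary()` appends the six keywords to the 28,996-entry base
(ids 28,996…29,001, giving 29,002), and
`resize_token_embeddings()` grows the embedding table without touching the
first 28,996 rows. The study's description does not say how the six new
rows were initialized; the package defaults to `mean_of_subwords` — each
keyword's row starts at the mean of its base-tokenizer sub-word rows, a
warm start consistent with the motivation that sub-word splits lose the
word's meaning — with seeded `random` initialization available. The MLM
output head gains matching columns under the same strategy.

## Pre-training

`mask_tokens()` implements the standard corruption recipe: 15% of the
*words* are selected (whole-word granularity by default, because the
procedure is defined over words; token-level masking is available via
`whole_word = FALSE`); of the selected words 80% are replaced by `[MASK]`,
10% by a random non-special token and 10% kept. Special-token positions
are never selected. Next-sentence prediction is omitted entirely — it has
been found unimportant for this family of models and the source procedure
drops it. Pre-training epochs, learning rate and batch size for the
original models are unreported; the defaults here make no claim to match
them and are logged with every run.

## Fine-tuning and decoding

Span fine-tuning minimizes the sum of start and end cross-entropies with
softmax over all encoding positions; all parameters update by default
(`freeze_encoder = TRUE` trains the head only, the comparison arm that
full fine-tuning is expected to beat). The sources give the decode rule
but not the training encoding of "no information"; the package supervises
both start and end onto the `[CLS]` position, which makes the sentinel
decodable. Decoding takes *independent* argmaxes of the start and end
probabilities — not the best valid joint pair, because the
end-before-start rule only exists under independent decoding — over the
context positions plus `[CLS]`; `end < start` or either argmax on `[CLS]`
yields the literal `"no information"`.

For classification, sentences containing task trigger phrases (for
rejection: "rejection", "ABMR", "TCMR"; for IFTA: the grade words and
"interstitial fibrosis" / "tubular atrophy") are deleted from the
Microscopic Description before encoding, so the label cannot be read off
the input. Sentence splitting is on ". " and newlines — crude, but
deterministic and adequate for templated text.

## Metrics

For span answers, `char_overlap_ratio()` and `word_overlap_ratio()` divide
the overlap between predicted and expected answers by the expected length
at character and word level; a word counts as claimed as soon as one of
its characters is covered. The reference description is ambiguous between
per-example (macro) and pooled (micro) averaging: the package computes
per-example ratios and averages them (micro pooling available via
`average = "micro"`), caps each ratio at 1 (an engulfing prediction cannot
beat a perfect one), and scores the no-information cases as 1 when both
sides are empty and 0 when exactly one is — all three conventions are
choices of this package, as the sources are silent. `exact_match_rate()`
normalizes whitespace and accepts a match against *any* of an example's
tagged gold mentions. `classification_report()` reports accuracy plus
positive-class or frequency-weighted precision/recall/F1, with
zero-denominator cells reported as 0 (a model that never predicts the
positive class scores 0.000, matching the convention of the reference
tables).

## The synthetic corpus

`generate_corpus()` assembles reports from a template grammar mimicking
transplant-biopsy microscopy boilerplate: glomeruli counts, tubulitis and
hyalinosis phrasing, an IFTA sentence
(`"Mild interstitial fibrosis and tubular atrophy are present (~15%)."`)
whose capitalized grade word is the gold IFTA answer, and rejection
sentences in the Comments
(`"These findings support the diagnosis of acute T-cell mediated rejection (IA)."`,
`"No evidence of acute antibody-mediated rejection is seen."`) whose
tagged phrases are the gold rejection answers. Gold spans are recorded at
generation time as character intervals into the IR context (Comments,
newline, Microscopic Description — Comments first, following the layout
of the worked example in the source material). Default label frequencies
are the study's: IFTA severe 112 / moderate 361 / mild 1,120 / minimal 347
/ absent 1,233 / unclassified 256 (normalized by their own sum, which is
3,429 as printed), ABMR 123/3,428, TCMR 107/3,428. Negative reports can
still mention rejection explicitly ("No evidence of …"), and reports
without any mention make the no-information case non-trivial; distractor
inflammation sentences carry the keywords into non-answer positions.

What the generator does *not* emulate: real clinical lexical diversity,
dictation noise, Banff scoring consistency, or inter-report correlation.
Passing tests on this corpus therefore demonstrate that the machinery is
correct and that the vocabulary effect has the claimed direction under
controlled conditions — not that any particular accuracy would transfer
to real reports.

## The ablation and its regime

`run_ablation()` compares, per seed, arms that share the corpus, the
80/20 stratified split and the initial parameters, and differ only in
vocabulary handling (or in skipping pre-training / freezing the encoder).
The extended arm's model is the base arm's initialization with six
warm-started embedding rows appended — exactly the resize-then-pretrain
pipeline.

The default study conditions are 500 reports, the 2×64 encoder, one MLM
pre-training epoch and two span fine-tuning epochs, with the
keyword-dense corpus (ABMR 0.35, TCMR 0.25, explicit negative mentions
0.45, keyword density 2) the directional comparison calls for. The scarce
fine-tuning regime is deliberate: it mirrors the small-corpus setting
under study, and it keeps both arms off ceiling — with enough epochs both
vocabularies eventually saturate the templated task and the comparison
becomes uninformative. Under scarce fine-tuning the extended arm's
advantage (shorter, distinctive answer tokens) shows up as faster
learning. Medians across five seeds are compared, which tolerates one
unlucky optimization run. The frozen-encoder arm shares the base
pre-trained model and trains only the span head, reproducing the
full-fine-tuning-beats-frozen comparison.

With these sizes the three-arm, five-seed ablation completes in roughly
ten minutes on one CPU core; `report_tables()` writes one TSV per task
plus a JSON run log containing every configuration value and per-seed
result, sufficient to reproduce any cell bit for bit.

## Numerical choices and degenerate inputs

* Layer-norm epsilon 1e-12; softmax always max-shifted.
* Cross-entropy probability floor 1e-12, logged when hit.
* Argmax ties break to the first (lowest) position, deterministically.
* Words longer than 100 characters tokenize to `[UNK]`.
* An empty redacted text encodes as bare `[CLS] [SEP]`.
* `select_rate` 0 and 1 are accepted (identity and saturation corruption).
* Stratified splitting falls back to pooled random allocation (with a
  message) when every stratum is a singleton, and adjusts to the exact
  overall held-out count.

## Known limitations

* The encoder is a from-scratch desk-scale stand-in trained on synthetic
  text; absolute metric values have no clinical meaning.
* Truncation drops context tails; documents longer than `max_position`
  lose answers placed there (warned at example construction).
* The reader for external report files is best-effort and validated only
  against this package's own JSONL dialect; field mappings for other
  deposits must be configured and verified by the user.
* Only the two fixed study questions are modelled; new questions require
  choosing new keywords, which is the method's own stated limitation.
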