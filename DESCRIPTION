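Package: pathbert
Title: WordPiece Vocabulary Extension and Span-Extraction Information
    Retrieval for Renal Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for studying how extending a WordPiece
    tokenizer's vocabulary with domain keywords affects extractive
    information retrieval from kidney-transplant pathology reports.
    Provides a cased WordPiece tokenizer with added-token extension, a
    compact transformer encoder with masked-language-model, span-extraction
    and [CLS]-classification heads trained by backpropagation, whole-word
    masked-language-model pre-training (15% selection, 80/10/10
    corruption), span decoding with a "no information" rule,
    character/word-level span-overlap and exact-match evaluation metrics, a
    seeded generator of synthetic renal-pathology reports with gold answer
    spans, and an ablation driver comparing base against extended
    vocabularies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
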