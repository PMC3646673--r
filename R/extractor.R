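# The hybrid extractor: featurization of documents, CRF training data
# construction, the one-call corpus-level fit (CRF + training dictionary)
# and the end-to-end tagging pipeline.

# Sentence-level view of one section: token data frame (section-level
# offsets) per sentence.
section_sentences <- function(text) {
  sents <- sentence_split(text)
  lapply(seq_len(nrow(sents)), function(k) {
    s <- sents$char_start[k]; e <- sents$char_end[k]
    toks <- tokenize(substr(text, s + 1L, e))
    toks$char_start <- toks$char_start + s
    toks$char_end <- toks$char_end + s
    toks
  })
}

#' Build CRF training sequences from documents and gold annotations
#'
#' Sections are split into sentences (the CRF sequence unit), tokenized,
#' featurized, and gold spans are converted to BIO labels per sentence.
#' Annotation offsets must refer to the documents as given (apply
#' [filter_sections()] before annotating, or pass unfiltered documents
#' whose indices the gold uses).
#'
#' @param docs List of `label_document`s.
#' @param gold Annotation data frame.
#' @param lexicon A `sem_lexicon`.
#' @param config A [feature_config()].
#' @param pos_tagger POS provider, defaults to [pos_tag()].
#' @return List with `x` (list of feature-vector sequences) and `y`
#'   (aligned list of BIO label vectors).
#' @export
build_training_data <- function(docs, gold, lexicon,
                                config = feature_config(),
                                pos_tagger = pos_tag) {
  x <- list(); y <- list()
  for (doc in docs) {
    dg <- gold[gold$doc_id == doc$doc_id, , drop = FALSE]
    for (si in seq_len(nrow(doc$sections)) - 1L) {
      text <- doc$sections$text[si + 1L]
      sg <- dg[dg$section_index == si, , drop = FALSE]
      for (toks in section_sentences(text)) {
        if (nrow(toks) == 0) next
        lo <- min(toks$char_start); hi <- max(toks$char_end)
        spans <- sg[sg$char_start >= lo & sg$char_end <= hi, , drop = FALSE]
        x[[length(x) + 1L]] <- sentence_features(toks, lexicon, config,
                                                 pos_tagger)
        y[[length(y) + 1L]] <- encode_bio(toks, spans)
      }
    }
  }
  list(x = x, y = y)
}

#' Fit the hybrid medical-condition extractor
#'
#' The one-call corpus-level fit: trains the linear-chain CRF on the
#' training documents' gold annotations and builds the longest-exact-match
#' term dictionary from the same training gold.  The returned object tags
#' new documents via [predict.mc_extractor()] (CRF tagging followed by
#' dictionary post-processing).
#'
#' @param docs Training `label_document`s (already section-filtered if the
#'   gold refers to filtered indices).
#' @param gold Training-fold annotation data frame (never from the
#'   documents to be tagged).
#' @param lexicon A `sem_lexicon` used for semantic features.
#' @param feature_cfg A [feature_config()].
#' @param crf_cfg A [crf_config()].
#' @param pos_tagger POS provider, defaults to [pos_tag()].
#' @return Object of class `mc_extractor`: list with `model` (`mc_crf`),
#'   `dictionary` (`term_dictionary`), `lexicon`, `feature_cfg`,
#'   `pos_tagger`.
#' @export
mc_extractor <- function(docs, gold, lexicon,
                         feature_cfg = feature_config(),
                         crf_cfg = crf_config(),
                         pos_tagger = pos_tag) {
  td <- build_training_data(docs, gold, lexicon, feature_cfg, pos_tagger)
  model <- crf_train(td$x, td$y, crf_cfg)
  dict <- build_term_dictionary(gold, provenance = sprintf(
    "%d training documents, %d annotations", length(docs), nrow(gold)))
  structure(list(model = model, dictionary = dict, lexicon = lexicon,
                 feature_cfg = feature_cfg, pos_tagger = pos_tagger),
            class = "mc_extractor")
}

#' @export
print.mc_extractor <- function(x, ...) {
  cat("<mc_extractor> hybrid CRF + dictionary extractor\n")
  print(x$model)
  print(x$dictionary)
  cat("semantic features:", x$feature_cfg$semantic, "\n")
  invisible(x)
}

#' Run the extraction pipeline on one document
#'
#' Section filtering, sentence splitting, tokenization, featurization,
#' Viterbi tagging, BIO decoding, dictionary post-processing and triple
#' assembly.  Deterministic given its inputs.
#'
#' @param doc A `label_document`.
#' @param model A fitted `mc_crf` (ignored for the rule-based baselines).
#' @param dict A `term_dictionary` (post-processing and `"dict"` baseline).
#' @param lexicon A `sem_lexicon`.
#' @param feature_cfg A [feature_config()].
#' @param whitelist Section whitelist; `NULL` skips filtering (for
#'   documents already filtered).
#' @param postprocess Apply dictionary post-processing to CRF output.
#' @param baseline `NULL` for the hybrid system, `"tui"` for the TUI-filter
#'   baseline, `"dict"` for the dictionary-only baseline.
#' @param tuis Qualifying TUI codes for the `"tui"` baseline.
#' @param pos_tagger POS provider, defaults to [pos_tag()].
#' @return List with `spans` (annotation data frame; offsets local to the
#'   filtered document's sections) and `triples` (data frame).
#' @export
run_pipeline <- function(doc, model = NULL, dict = NULL, lexicon,
                         feature_cfg = feature_config(),
                         whitelist = section_whitelist(),
                         postprocess = TRUE, baseline = NULL,
                         tuis = default_tui_set(), pos_tagger = pos_tag) {
  fdoc <- if (is.null(whitelist)) doc else filter_sections(doc, whitelist)
  all_spans <- span_annotations()
  for (si in seq_len(nrow(fdoc$sections)) - 1L) {
    text <- fdoc$sections$text[si + 1L]
    for (toks in section_sentences(text)) {
      if (nrow(toks) == 0) next
      spans <- if (identical(baseline, "tui")) {
        sem <- semantic_lookup(toks, lexicon)
        baseline_tui_extract(toks, sem, tuis, text = text,
                             doc_id = fdoc$doc_id, section_index = si)
      } else if (identical(baseline, "dict")) {
        dictionary_match(toks, dict, text = text, doc_id = fdoc$doc_id,
                         section_index = si)
      } else {
        feats <- sentence_features(toks, lexicon, feature_cfg, pos_tagger)
        labels <- predict(model, feats)
        crf_spans <- decode_bio(toks, labels, text = text,
                                doc_id = fdoc$doc_id, section_index = si)
        if (postprocess && !is.null(dict)) {
          dict_spans <- dictionary_match(toks, dict, text = text,
                                         doc_id = fdoc$doc_id,
                                         section_index = si)
          postprocess_merge(crf_spans, dict_spans)
        } else {
          crf_spans
        }
      }
      all_spans <- rbind(all_spans, spans)
    }
  }
  rownames(all_spans) <- NULL
  list(spans = all_spans, triples = assemble_triples(fdoc, all_spans))
}

#' Tag documents with a fitted extractor
#'
#' @param object A fitted [mc_extractor()].
#' @param docs A `label_document` or list of them.
#' @param whitelist Section whitelist; `NULL` skips filtering.
#' @param postprocess Apply dictionary post-processing (default `TRUE`).
#' @param ... Unused.
#' @return For one document, the [run_pipeline()] result; for a list, a
#'   list with pooled `spans` and `triples`.
#' @export
predict.mc_extractor <- function(object, docs, whitelist = NULL,
                                 postprocess = TRUE, ...) {
  one <- function(d) {
    run_pipeline(d, model = object$model, dict = object$dictionary,
                 lexicon = object$lexicon,
                 feature_cfg = object$feature_cfg, whitelist = whitelist,
                 postprocess = postprocess, pos_tagger = object$pos_tagger)
  }
  if (inherits(docs, "label_document")) return(one(docs))
  res <- lapply(docs, one)
  spans <- do.call(rbind, lapply(res, `[[`, "spans"))
  triples <- do.call(rbind, lapply(res, `[[`, "triples"))
  rownames(spans) <- rownames(triples) <- NULL
  list(spans = spans, triples = triples)
}

#' Gold BIO label sequences for a document set
#'
#' Sentence-aligned gold labels (collapsed-union encoding), shaped exactly
#' like the prediction side, for token-level evaluation.
#'
#' @param docs List of `label_document`s.
#' @param gold Annotation data frame.
#' @return Named list (by doc_id) of lists of label vectors.
#' @export
gold_bio_by_doc <- function(docs, gold) {
  out <- list()
  for (doc in docs) {
    dg <- gold[gold$doc_id == doc$doc_id, , drop = FALSE]
    seqs <- list()
    for (si in seq_len(nrow(doc$sections)) - 1L) {
      text <- doc$sections$text[si + 1L]
      sg <- dg[dg$section_index == si, , drop = FALSE]
      for (toks in section_sentences(text)) {
        if (nrow(toks) == 0) next
        lo <- min(toks$char_start); hi <- max(toks$char_end)
        spans <- sg[sg$char_start >= lo & sg$char_end <= hi, , drop = FALSE]
        seqs[[length(seqs) + 1L]] <- encode_bio(toks, spans)
      }
    }
    out[[doc$doc_id]] <- seqs
  }
  out
}

#' Predicted BIO label sequences for a document set
#'
#' Converts predicted spans back to sentence-aligned BIO labels, shaped
#' like [gold_bio_by_doc()], for token-level evaluation.
#'
#' @param docs List of `label_document`s (the same, already-filtered
#'   documents the spans refer to).
#' @param spans Predicted annotation data frame.
#' @return Named list (by doc_id) of lists of label vectors.
#' @export
pred_bio_by_doc <- function(docs, spans) {
  gold_bio_by_doc(docs, spans)
}
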