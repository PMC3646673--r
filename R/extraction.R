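# Rule-based extraction components of the hybrid pipeline: the TUI-filter
# baseline, the training-set term dictionary with longest-exact-match
# lookup (maximum coverage rule), the CRF/dictionary merge, and assembly of
# drug-condition-section triples.

#' Default set of medical-condition semantic types (TUIs)
#'
#' The eleven UMLS semantic types treated as medical conditions by the
#' TUI-filter baseline: congenital abnormality (T019), acquired abnormality
#' (T020), injury or poisoning (T037), pathologic function (T046), disease
#' or syndrome (T047), mental or behavioral dysfunction (T048), cell or
#' molecular dysfunction (T049), experimental model of disease (T050),
#' sign or symptom (T184), anatomical abnormality (T190), neoplastic
#' process (T191).  The noisy T033 (finding) type is deliberately excluded.
#'
#' @return Character vector of TUI codes.
#' @export
default_tui_set <- function() {
  c("T019", "T020", "T037", "T046", "T047", "T048", "T049", "T050",
    "T184", "T190", "T191")
}

#' TUI-filter baseline extraction
#'
#' Maximal runs of consecutive tokens whose semantic type is in the
#' qualifying TUI set become medical-condition spans.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param sem Data frame from [semantic_lookup()] aligned to `tokens`.
#' @param tuis Character vector of qualifying TUI codes.
#' @param text,doc_id,section_index Passed through to the resulting
#'   annotations (see [decode_bio()]).
#' @return Annotation data frame.
#' @export
baseline_tui_extract <- function(tokens, sem, tuis = default_tui_set(),
                                 text = NULL, doc_id = "",
                                 section_index = 0L) {
  stopifnot(nrow(tokens) == nrow(sem))
  qual <- sem$tui %in% tuis
  labels <- rep("O", nrow(tokens))
  run_start <- c(TRUE, !qual[-length(qual)])
  labels[qual & run_start] <- "MC_B"
  labels[qual & !run_start] <- "MC_I"
  decode_bio(tokens, labels, text = text, doc_id = doc_id,
             section_index = section_index)
}

#' Build a term dictionary from training-fold gold surfaces
#'
#' Terms are tokenized, lowercased gold surfaces; duplicates collapse.
#' The dictionary must be built from training folds only — never from the
#' fold it will be applied to.
#'
#' @param train_gold Annotation data frame from the training folds.
#' @param provenance Free-text identifier of the corpus/folds the
#'   dictionary was built from.
#' @return Object of class `term_dictionary`.
#' @export
build_term_dictionary <- function(train_gold, provenance = "") {
  surfaces <- unique(train_gold$surface)
  terms <- unique(vapply(surfaces, normalize_term, character(1),
                         USE.NAMES = FALSE))
  terms <- terms[nzchar(terms)]
  lens <- vapply(strsplit(terms, " ", fixed = TRUE), length, integer(1))
  structure(list(terms = terms,
                 lookup = setNames(rep(TRUE, length(terms)), terms),
                 max_len = if (length(terms)) max(lens) else 0L,
                 provenance = provenance),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary>", length(x$terms), "terms, max length",
      x$max_len, "tokens")
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Longest-exact-match dictionary tagging (maximum coverage rule)
#'
#' Greedy leftmost-longest, case-insensitive token-sequence matching: the
#' sentence is scanned left to right, at each position the longest
#' dictionary term matching the token sequence is labelled, and scanning
#' resumes after the match — so when "nausea", "vomiting" and "nausea and
#' vomiting" are all in the dictionary, only the single long span is
#' produced.  Output spans never overlap.
#'
#' @param tokens Token data frame from [tokenize()] for one sentence.
#' @param dict A [build_term_dictionary()] result.
#' @param text,doc_id,section_index Passed to the resulting annotations.
#' @return Annotation data frame.
#' @export
dictionary_match <- function(tokens, dict, text = NULL, doc_id = "",
                             section_index = 0L) {
  n <- nrow(tokens)
  labels <- rep("O", n)
  if (n > 0 && dict$max_len > 0L) {
    low <- tolower(tokens$text)
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (len in seq(min(dict$max_len, n - i + 1L), 1L)) {
        key <- paste(low[i:(i + len - 1L)], collapse = " ")
        if (!is.na(dict$lookup[key])) { hit <- len; break }
      }
      if (hit > 0L) {
        labels[i] <- "MC_B"
        if (hit > 1L) labels[(i + 1L):(i + hit - 1L)] <- "MC_I"
        i <- i + hit
      } else {
        i <- i + 1L
      }
    }
  }
  decode_bio(tokens, labels, text = text, doc_id = doc_id,
             section_index = section_index)
}

spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Merge CRF spans with dictionary spans
#'
#' Dictionary-based post-processing of the CRF output: a CRF span strictly
#' contained in a dictionary span is replaced by that dictionary span
#' (boundary correction); a dictionary span overlapping no CRF span is
#' added (recall repair); on partial, non-containment overlap the CRF span
#' wins and the dictionary span is dropped.  A replacing dictionary span
#' that would collide with another retained CRF span is abandoned and its
#' contained CRF spans restored, so the result is always non-overlapping.
#'
#' @param crf_spans,dict_spans Annotation data frames for the same section,
#'   each internally non-overlapping.
#' @return Annotation data frame, sorted, non-overlapping.
#' @export
postprocess_merge <- function(crf_spans, dict_spans) {
  if (is.null(dict_spans) || nrow(dict_spans) == 0) {
    out <- crf_spans
  } else if (is.null(crf_spans) || nrow(crf_spans) == 0) {
    out <- dict_spans
  } else {
    nc <- nrow(crf_spans); nd <- nrow(dict_spans)
    # container[c] = index of a dict span strictly containing crf span c
    container <- rep(NA_integer_, nc)
    for (c in seq_len(nc)) {
      cs <- crf_spans$char_start[c]; ce <- crf_spans$char_end[c]
      cand <- which(dict_spans$char_start <= cs & dict_spans$char_end >= ce &
                      (dict_spans$char_end - dict_spans$char_start) > (ce - cs))
      if (length(cand)) container[c] <- cand[1]
    }
    kept <- crf_spans[is.na(container), , drop = FALSE]
    add <- dict_spans[0, , drop = FALSE]
    for (d in unique(container[!is.na(container)])) {
      ds <- dict_spans$char_start[d]; de <- dict_spans$char_end[d]
      collide <- nrow(kept) > 0 &&
        any(spans_overlap(ds, de, kept$char_start, kept$char_end))
      if (collide) {
        kept <- rbind(kept, crf_spans[which(container == d), , drop = FALSE])
      } else {
        add <- rbind(add, dict_spans[d, , drop = FALSE])
      }
    }
    for (d in seq_len(nd)) {
      touches_crf <- any(spans_overlap(dict_spans$char_start[d],
                                       dict_spans$char_end[d],
                                       crf_spans$char_start,
                                       crf_spans$char_end))
      if (!touches_crf) add <- rbind(add, dict_spans[d, , drop = FALSE])
    }
    out <- rbind(kept, add)
  }
  out <- out[order(out$section_index, out$char_start, out$char_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble drug-condition-section triples
#'
#' One triple per distinct (lowercased condition surface, section header)
#' pair per document, in order of first occurrence; the drug name comes
#' from the document.
#'
#' @param doc A `label_document` (section headers should already be the
#'   canonical ones, i.e. after [filter_sections()]).
#' @param spans Annotation data frame referencing `doc`'s sections.
#' @return Data frame with columns `drug_name`, `condition`,
#'   `section_header`.
#' @export
assemble_triples <- function(doc, spans) {
  if (nrow(spans) > 0 &&
      any(spans$section_index < 0 | spans$section_index >= nrow(doc$sections))) {
    stop("data error: span references a section missing from document ",
         doc$doc_id)
  }
  spans <- spans[order(spans$section_index, spans$char_start), , drop = FALSE]
  header <- doc$sections$header[spans$section_index + 1L]
  key <- paste(tolower(spans$surface), header, sep = "\r")
  keep <- !duplicated(key)
  data.frame(drug_name = rep(doc$drug_name, sum(keep)),
             condition = spans$surface[keep],
             section_header = header[keep],
             stringsAsFactors = FALSE)
}

#' Write extracted triples
#'
#' @param triples Data frame from [assemble_triples()].
#' @param path Output path; `.json` writes JSON, anything else TSV
#'   (`drug_name  condition  section_header`, header row).
#' @export
write_triples <- function(triples, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(triples, path, auto_unbox = TRUE)
  } else {
    write.table(triples, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
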