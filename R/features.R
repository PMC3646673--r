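# Tokenization, sentence splitting, a deterministic heuristic POS tagger,
# semantic-lexicon lookup and the per-token feature strings that feed the
# CRF.  Offsets are 0-based half-open over the section text.

#' Tokenize text into word/punctuation tokens with offsets
#'
#' Splits on whitespace, then separates punctuation from alphanumeric
#' material: every punctuation character becomes its own token, except that
#' hyphens and apostrophes between alphanumerics are kept inside the word
#' (`anti-itch` stays one token).
#'
#' @param text A length-1 character string.
#' @return Data frame with columns `text`, `char_start`, `char_end`
#'   (0-based, half-open).
#' @examples
#' tokenize("stinging, burning")
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(text = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE))
  }
  pat <- "[[:alnum:]]+(?:[-'][[:alnum:]]+)*|[^[:alnum:][:space:]]"
  g <- gregexpr(pat, text, perl = TRUE)
  m <- g[[1]]
  if (m[1] == -1) {
    return(data.frame(text = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(text = regmatches(text, g)[[1]],
             char_start = starts, char_end = starts + lens,
             stringsAsFactors = FALSE)
}

# Abbreviations whose trailing period never ends a sentence.
sentence_abbrev <- c("e.g", "i.e", "etc", "vs", "cf", "dr", "mr", "mrs",
                     "ms", "st", "no", "fig", "approx")

#' Split text into sentence spans
#'
#' A sentence boundary is a run of sentence-final punctuation (`.`, `!`,
#' `?`) followed by whitespace and an upper-case letter or digit, unless
#' the word before the punctuation is a guarded abbreviation (e.g., i.e.,
#' etc., vs., Dr., Fig.).  Returned spans are trimmed to their
#' non-whitespace extent, are non-overlapping and ordered, and jointly
#' cover all non-whitespace characters.
#'
#' @param text A length-1 character string.
#' @return Data frame with columns `char_start`, `char_end` (0-based,
#'   half-open), one row per sentence.
#' @export
sentence_split <- function(text) {
  empty <- data.frame(char_start = integer(0), char_end = integer(0))
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  n <- nchar(text)
  m <- gregexpr("[.!?]+(?=[[:space:]]+[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1) {
    for (k in seq_along(m)) {
      pend <- as.integer(m[k]) + attr(m, "match.length")[k] - 1L # 1-based
      before <- substr(text, 1, as.integer(m[k]) - 1L)
      word <- regmatches(before, regexpr("[[:alnum:].]+$", before))
      guarded <- length(word) == 1 &&
        tolower(sub("\\.+$", "", word)) %in% sentence_abbrev
      if (!guarded) cuts <- c(cuts, pend) # sentence ends after punct run
    }
  }
  bounds <- c(0L, cuts, n) # 1-based end positions -> 0-based starts
  out <- empty
  for (k in seq_len(length(bounds) - 1L)) {
    s <- bounds[k]; e <- bounds[k + 1L]
    seg <- substr(text, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^[[:space:]]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[[:space:]]+$", "", seg))
    s2 <- s + lead; e2 <- e - trail
    if (e2 > s2) out <- rbind(out, data.frame(char_start = s2, char_end = e2))
  }
  rownames(out) <- NULL
  out
}

pos_closed_class <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", each = "DT", every = "DT", some = "DT", any = "DT",
  no = "DT",
  of = "IN", "in" = "IN", on = "IN", at = "IN", by = "IN", with = "IN",
  from = "IN", to = "TO", "for" = "IN", as = "IN", into = "IN",
  over = "IN", under = "IN", within = "IN", without = "IN", during = "IN",
  after = "IN", before = "IN",
  and = "CC", or = "CC", but = "CC", nor = "CC",
  it = "PRP", they = "PRP", them = "PRP", you = "PRP", he = "PRP",
  she = "PRP", its = "PRP$", their = "PRP$", your = "PRP$", his = "PRP$",
  her = "PRP$",
  may = "MD", can = "MD", must = "MD", should = "MD", could = "MD",
  will = "MD", would = "MD", might = "MD", shall = "MD",
  is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB",
  been = "VBN", being = "VBG", has = "VBZ", have = "VBP", had = "VBD",
  do = "VBP", does = "VBZ", did = "VBD",
  not = "RB", very = "RB", also = "RB", only = "RB",
  "if" = "IN", when = "WRB", where = "WRB", which = "WDT", who = "WP"
)

#' Deterministic heuristic part-of-speech tagger
#'
#' A shipped POS provider implementing the provider contract (one tag per
#' token, deterministic): a closed-class lexicon, then suffix rules
#' (-ing/-ed/-ly/-ous/-al/-ive/-ic/plural -s), digits as `CD`, punctuation
#' tagged as itself, capitalized words as `NNP`, fallback `NN`.  Any
#' function with the same signature can be substituted where a `pos_tagger`
#' argument is accepted.
#'
#' @param tokens Character vector of token texts (one sentence).
#' @return Character vector of POS tags, same length.
#' @export
pos_tag <- function(tokens) {
  vapply(tokens, function(tok) {
    low <- tolower(tok)
    if (!is.na(hit <- pos_closed_class[low]) && low %in% names(pos_closed_class)) {
      return(unname(pos_closed_class[low]))
    }
    if (grepl("^[0-9]+([.,][0-9]+)*$", tok)) return("CD")
    if (grepl("^[^[:alnum:]]+$", tok)) return(tok)
    if (grepl("ing$", low) && nchar(low) > 4) return("VBG")
    if (grepl("ed$", low) && nchar(low) > 3) return("VBD")
    if (grepl("ly$", low) && nchar(low) > 3) return("RB")
    if (grepl("(ous|ive|ic|al)$", low) && nchar(low) > 4) return("JJ")
    if (grepl("^[A-Z]", tok)) return("NNP")
    if (grepl("s$", low) && nchar(low) > 3 && !grepl("(ss|us|is)$", low)) {
      return("NNS")
    }
    "NN"
  }, character(1), USE.NAMES = FALSE)
}

normalize_term <- function(term) {
  toks <- tokenize(term)$text
  paste(tolower(toks), collapse = " ")
}

#' Build a semantic lexicon mapping terms to CUI/TUI codes
#'
#' Emulates the term-to-concept output of a clinical NLP dictionary lookup:
#' each (possibly multiword) term maps to a UMLS-style concept identifier
#' (CUI, `C0000000`-like) and semantic type identifier (TUI, `T000`-like).
#' Terms are normalized to lowercased token sequences; lookup is
#' case-insensitive.
#'
#' @param term Character vector of terms (may be multiword).
#' @param cui,tui Character vectors, same length as `term`.
#' @return Object of class `sem_lexicon`.
#' @export
sem_lexicon <- function(term = character(0), cui = character(0),
                        tui = character(0)) {
  stopifnot(length(term) == length(cui), length(term) == length(tui))
  norm <- vapply(term, normalize_term, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(norm))) stop("empty terms are not allowed in a lexicon")
  keep <- !duplicated(norm)
  entries <- data.frame(term = norm[keep], cui = cui[keep], tui = tui[keep],
                        stringsAsFactors = FALSE)
  lens <- vapply(strsplit(entries$term, " ", fixed = TRUE), length, integer(1))
  structure(list(entries = entries,
                 lookup = setNames(seq_len(nrow(entries)), entries$term),
                 max_term_len = if (nrow(entries)) max(lens) else 0L),
            class = "sem_lexicon")
}

#' @export
print.sem_lexicon <- function(x, ...) {
  cat("<sem_lexicon>", nrow(x$entries), "entries, max term length",
      x$max_term_len, "tokens\n")
  invisible(x)
}

#' Read/write a semantic lexicon as TSV
#'
#' Format: UTF-8, header row, columns `term`, `cui`, `tui`; terms may be
#' multiword (space-separated).
#'
#' @param path File path.
#' @return `read_sem_lexicon`: a `sem_lexicon`.
#' @export
read_sem_lexicon <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(tab), c("term", "cui", "tui"))) {
    stop("lexicon file must have header: term\tcui\ttui")
  }
  sem_lexicon(tab$term, tab$cui, tab$tui)
}

#' @param lexicon A `sem_lexicon` to write.
#' @rdname read_sem_lexicon
#' @export
write_sem_lexicon <- function(lexicon, path) {
  write.table(lexicon$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Greedy leftmost-longest semantic lookup over a token sequence
#'
#' Scans the sentence left to right; at each position takes the longest
#' lexicon term (up to the lexicon's maximum term length) matching the
#' lowercased token sequence, projects that term's CUI/TUI onto every
#' constituent token, and resumes after the match.  Uncovered tokens get
#' `NONE`.
#'
#' @param tokens Token data frame from [tokenize()] (or a character vector
#'   of token texts) for one sentence.
#' @param lexicon A `sem_lexicon`.
#' @return Data frame with columns `cui`, `tui`, one row per token.
#' @export
semantic_lookup <- function(tokens, lexicon) {
  texts <- if (is.data.frame(tokens)) tokens$text else tokens
  n <- length(texts)
  cui <- rep("NONE", n); tui <- rep("NONE", n)
  if (n == 0 || lexicon$max_term_len == 0L) {
    return(data.frame(cui = cui, tui = tui, stringsAsFactors = FALSE))
  }
  low <- tolower(texts)
  i <- 1L
  while (i <= n) {
    hit_len <- 0L; hit_idx <- NA_integer_
    for (len in seq(min(lexicon$max_term_len, n - i + 1L), 1L)) {
      key <- paste(low[i:(i + len - 1L)], collapse = " ")
      idx <- lexicon$lookup[key]
      if (!is.na(idx)) { hit_len <- len; hit_idx <- idx; break }
    }
    if (hit_len > 0L) {
      rng <- i:(i + hit_len - 1L)
      cui[rng] <- lexicon$entries$cui[hit_idx]
      tui[rng] <- lexicon$entries$tui[hit_idx]
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  data.frame(cui = cui, tui = tui, stringsAsFactors = FALSE)
}

#' Feature configuration for the CRF feature extractor
#'
#' Controls the semantic feature group, mirroring the system ablations:
#' `"none"` (token + linguistic features only), `"tui"` (add the semantic
#' type of the current token — the best-performing configuration, used as
#' the default), `"cui"` (add the concept identifier instead), `"both"`.
#'
#' @param semantic One of `"none"`, `"tui"`, `"cui"`, `"both"`.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(semantic = c("tui", "none", "cui", "both")) {
  semantic <- match.arg(semantic)
  structure(list(semantic = semantic), class = "feature_config")
}

PAD <- "<PAD>"

char_class <- function(tok) {
  has_d <- grepl("[0-9]", tok); has_a <- grepl("[[:alpha:]]", tok)
  if (has_d && has_a) "mixed" else if (has_d) "digit"
  else if (has_a) "alpha" else "other"
}

caps_class <- function(tok) {
  if (!grepl("[[:alpha:]]", tok)) return("none")
  letters_only <- gsub("[^[:alpha:]]", "", tok)
  if (letters_only == toupper(letters_only)) "all"
  else if (grepl("[A-Z]", letters_only)) "mixed"
  else "none"
}

#' Extract the feature strings for one token position
#'
#' Emits the fixed feature schema for token `i` of a sentence: the token's
#' original, lowercased and stemmed forms; the previous/next two tokens;
#' the two token bigrams; POS tags and initial-capital flags over the
#' 5-token window; character-class and all-caps flags; two-character prefix
#' and suffix; token length; and (configuration-dependent) the CUI/TUI of
#' the current token.  Out-of-bounds context positions emit the `<PAD>`
#' sentinel, so the feature count per token is constant for a given
#' configuration.
#'
#' @param tokens Character vector of sentence token texts.
#' @param i Position (1-based) within the sentence.
#' @param pos Character vector of POS tags aligned to `tokens`.
#' @param sem Data frame from [semantic_lookup()] aligned to `tokens`.
#' @param config A [feature_config()].
#' @return Character vector of `name=value` feature strings.
#' @export
extract_features <- function(tokens, i, pos, sem,
                             config = feature_config()) {
  n <- length(tokens)
  if (i < 1 || i > n) stop("range error: token index ", i, " not in [1, ", n, "]")
  stopifnot(length(pos) == n, nrow(sem) == n)
  ctx <- function(x, j) if (j >= 1 && j <= n) x[j] else PAD
  tok <- tokens[i]
  f <- c(
    paste0("w0=", tok),
    paste0("w0.lower=", tolower(tok)),
    paste0("w0.stem=", stem(tok)),
    paste0("w-2=", ctx(tokens, i - 2L)),
    paste0("w-1=", ctx(tokens, i - 1L)),
    paste0("w+1=", ctx(tokens, i + 1L)),
    paste0("w+2=", ctx(tokens, i + 2L)),
    paste0("big-1=", ctx(tokens, i - 1L), "|", tok),
    paste0("big0=", tok, "|", ctx(tokens, i + 1L)),
    paste0("pos-2=", ctx(pos, i - 2L)),
    paste0("pos-1=", ctx(pos, i - 1L)),
    paste0("pos0=", pos[i]),
    paste0("pos+1=", ctx(pos, i + 1L)),
    paste0("pos+2=", ctx(pos, i + 2L)),
    paste0("cap-2=", if (i - 2L >= 1) grepl("^[A-Z]", tokens[i - 2L]) else PAD),
    paste0("cap-1=", if (i - 1L >= 1) grepl("^[A-Z]", tokens[i - 1L]) else PAD),
    paste0("cap0=", grepl("^[A-Z]", tok)),
    paste0("cap+1=", if (i + 1L <= n) grepl("^[A-Z]", tokens[i + 1L]) else PAD),
    paste0("cap+2=", if (i + 2L <= n) grepl("^[A-Z]", tokens[i + 2L]) else PAD),
    paste0("charclass0=", char_class(tok)),
    paste0("allcaps0=", caps_class(tok)),
    paste0("prefix2=", substr(tok, 1, 2)),
    paste0("suffix2=", substr(tok, max(1, nchar(tok) - 1), nchar(tok))),
    paste0("len0=", nchar(tok))
  )
  if (config$semantic %in% c("cui", "both")) {
    f <- c(f, paste0("cui0=", sem$cui[i]))
  }
  if (config$semantic %in% c("tui", "both")) {
    f <- c(f, paste0("tui0=", sem$tui[i]))
  }
  f
}

#' Feature vectors for every token of a sentence
#'
#' @param tokens Character vector of sentence token texts (or a token data
#'   frame from [tokenize()]).
#' @param lexicon A `sem_lexicon` (used for the semantic features).
#' @param config A [feature_config()].
#' @param pos_tagger POS provider function; defaults to [pos_tag()].
#' @return List of character vectors, one per token.
#' @export
sentence_features <- function(tokens, lexicon, config = feature_config(),
                              pos_tagger = pos_tag) {
  texts <- if (is.data.frame(tokens)) tokens$text else tokens
  if (length(texts) == 0) return(list())
  pos <- pos_tagger(texts)
  if (length(pos) != length(texts)) {
    stop("POS provider returned ", length(pos), " tags for ",
         length(texts), " tokens")
  }
  sem <- semantic_lookup(texts, lexicon)
  lapply(seq_along(texts), function(i) {
    extract_features(texts, i, pos, sem, config)
  })
}

#' Write a debugging feature dump
#'
#' One token per line with its tab-separated `name=value` features (and the
#' label, if given, in the first column); a blank line between sentences —
#' the de-facto CRF training text format.
#'
#' @param sequences List of sentences, each a list of feature vectors.
#' @param path Output path.
#' @param labels Optional list of label vectors aligned to `sequences`.
#' @export
write_feature_dump <- function(sequences, path, labels = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in seq_along(sequences)) {
    for (t in seq_along(sequences[[s]])) {
      line <- paste(sequences[[s]][[t]], collapse = "\t")
      if (!is.null(labels)) line <- paste(labels[[s]][t], line, sep = "\t")
      writeLines(line, con)
    }
    writeLines("", con)
  }
  invisible(path)
}
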