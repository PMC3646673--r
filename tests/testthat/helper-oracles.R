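# Independent brute-force oracles and small fixture builders shared across
# tests.  Oracles deliberately use a different strategy than the
# implementation they check (full enumeration, position-by-position
# tallies).

# Brute-force leftmost-longest matcher: enumerate ALL (start, length)
# dictionary matches, then repeatedly select the match with the smallest
# start (ties: longest), discarding overlapping candidates.
brute_leftmost_longest <- function(low_tokens, term_set, max_len) {
  n <- length(low_tokens)
  cand <- list()
  for (i in seq_len(n)) {
    for (len in seq_len(min(max_len, n - i + 1L))) {
      key <- paste(low_tokens[i:(i + len - 1L)], collapse = " ")
      if (key %in% term_set) {
        cand[[length(cand) + 1L]] <- c(i, len)
      }
    }
  }
  picked <- list()
  while (length(cand) > 0) {
    starts <- vapply(cand, `[`, numeric(1), 1)
    lens <- vapply(cand, `[`, numeric(1), 2)
    ord <- order(starts, -lens)
    sel <- cand[[ord[1]]]
    picked[[length(picked) + 1L]] <- sel
    lo <- sel[1]; hi <- sel[1] + sel[2] - 1L
    cand <- Filter(function(c) c[1] > hi, cand)
  }
  picked
}

# Brute-force semantic-lookup oracle built on the same selection rule.
brute_semantic_lookup <- function(low_tokens, lexicon) {
  n <- length(low_tokens)
  cui <- rep("NONE", n); tui <- rep("NONE", n)
  hits <- brute_leftmost_longest(low_tokens, lexicon$entries$term,
                                 lexicon$max_term_len)
  for (h in hits) {
    key <- paste(low_tokens[h[1]:(h[1] + h[2] - 1L)], collapse = " ")
    row <- match(key, lexicon$entries$term)
    rng <- h[1]:(h[1] + h[2] - 1L)
    cui[rng] <- lexicon$entries$cui[row]
    tui[rng] <- lexicon$entries$tui[row]
  }
  data.frame(cui = cui, tui = tui, stringsAsFactors = FALSE)
}

# Random mc_crf over a fixed small feature vocabulary.
random_model <- function(feats = paste0("f=", letters[1:6])) {
  W <- matrix(runif(length(feats) * 3, -2, 2), ncol = 3,
              dimnames = list(feats, c("MC_B", "MC_I", "O")))
  Tr <- matrix(runif(9, -2, 2), 3, 3,
               dimnames = list(c("MC_B", "MC_I", "O"),
                               c("MC_B", "MC_I", "O")))
  structure(list(features = feats, state = W, transitions = Tr,
                 config = crf_config(), loglik = NA_real_,
                 convergence = 0L, version = "mc_crf/1"),
            class = "mc_crf")
}

random_feature_sequence <- function(n, feats = paste0("f=", letters[1:6])) {
  lapply(seq_len(n), function(i) sample(feats, sample(1:3, 1)))
}

# Random non-overlapping, non-adjacent token-aligned spans over a token
# data frame.
random_token_spans <- function(tokens, max_spans = 3) {
  n <- nrow(tokens)
  if (n == 0) return(span_annotations())
  out <- span_annotations()
  i <- 1L
  while (i <= n && nrow(out) < max_spans) {
    if (runif(1) < 0.3) {
      len <- min(sample(1:3, 1), n - i + 1L)
      out <- rbind(out, span_annotations(
        doc_id = "d", section_index = 0L,
        char_start = tokens$char_start[i],
        char_end = tokens$char_end[i + len - 1L],
        category = "MC",
        surface = paste(tokens$text[i:(i + len - 1L)], collapse = " ")))
      i <- i + len + 1L # skip one token: never adjacent
    } else {
      i <- i + 1L
    }
  }
  out
}

# Random span set in a given coordinate range (possibly overlapping).
random_spans <- function(n_spans, doc_id = "d", width = 100L) {
  if (n_spans == 0) return(span_annotations())
  s <- sort(sample.int(width - 5L, n_spans, replace = TRUE))
  e <- s + sample.int(5L, n_spans, replace = TRUE)
  span_annotations(doc_id = rep(doc_id, n_spans),
                   section_index = 0L, char_start = s, char_end = e,
                   category = "MC",
                   surface = strrep("x", e - s))
}

# A small filler sentence whose tokens never collide with lexicon terms.
filler_words <- c("alpha", "bravo", "delta", "echo", "foxtrot", "golf",
                  "hotel", "india", "juliet", "kilo")

# Tiny cached synthetic corpus for structural tests (fast).
small_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(synth_config(
        n_docs = 8L, conditions_per_section = 3, n_condition_terms = 30L,
        seed = 11L))
    }
    cache
  }
})
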