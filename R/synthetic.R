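# Seeded synthetic-corpus generator: SPL XML drug labels with standoff gold
# annotations, a condition lexicon and a semantic lexicon, emulating the
# statistical structure of an annotated drug-label corpus (OTC labels carry
# only Warnings and Indications sections; Rx labels draw from all eight;
# roughly one third of test-fold mention surfaces never occur in training).
# Filler prose comes from a fixed non-medical vocabulary, so negatives
# never collide with condition terms and baseline behaviour is analytically
# predictable.  Mentions are never adjacent to each other.

synth_filler <- c(
  "the", "a", "of", "apply", "product", "if", "area", "surface", "use",
  "do", "not", "contact", "consult", "doctor", "keep", "away", "children",
  "store", "room", "temperature", "wash", "hands", "before", "after",
  "this", "with", "water", "small", "amount", "twice", "daily", "as",
  "directed", "physician", "results", "vary", "individual", "response",
  "clean", "dry", "gently", "each", "day", "reduce", "exposure", "avoid",
  "direct", "sun", "light", "when", "using", "other", "topical", "follow",
  "instructions", "carefully", "to", "on", "for", "in")

synth_modifiers <- c("generalized", "transient", "severe", "mild",
                     "persistent", "recurrent")

synth_cond_adjectives <- c("acute", "chronic", "focal", "diffuse")

synth_syllables <- list(
  pre = c("derma", "cardi", "neuro", "hepat", "nephr", "gastr", "arthr",
          "myo", "oste", "pulmo", "angi", "lympho", "entero", "kerato"),
  mid = c("", "to", "ra", "li", "no", "sta", "ve"),
  suf = c("itis", "osis", "algia", "emia", "pathy", "oma", "rrhea",
          "penia", "plasia", "spasm"))

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the standard study conditions used throughout the
#' package's end-to-end tests: 40 documents across the three drug
#' categories, about five condition mentions per section, a 120-term
#' condition vocabulary with roughly a third multiword terms, 30% of
#' test-fold mention surfaces unseen in training, full semantic-lexicon
#' coverage, and occasional out-of-span modifiers ("generalized rash")
#' exercising the left-boundary error mode.
#'
#' @param n_docs Number of documents.
#' @param category_mix Proportions over OTC / Rx_Top200 / Rx_Other
#'   (must sum to 1).
#' @param conditions_per_section Mean mention count per section (Poisson).
#' @param n_condition_terms Size of the condition lexicon.
#' @param multiword_fraction Fraction of multiword condition terms.
#' @param unseen_term_rate Fraction of test-fold mentions whose surface
#'   never occurs in a training fold.
#' @param coverage Fraction of condition terms with a semantic-lexicon
#'   entry.
#' @param modifier_probability Probability that a modifier token directly
#'   precedes a mention (outside the gold span).
#' @param n_folds Fold count; documents are assigned round-robin and fold 0
#'   is the designated test fold.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 40L,
                         category_mix = c(OTC = 0.3, Rx_Top200 = 0.4,
                                          Rx_Other = 0.3),
                         conditions_per_section = 5,
                         n_condition_terms = 120L,
                         multiword_fraction = 0.35,
                         unseen_term_rate = 0.3,
                         coverage = 1.0,
                         modifier_probability = 0.15,
                         n_folds = 4L,
                         seed = 1L) {
  if (abs(sum(category_mix) - 1) > 1e-8 || any(category_mix < 0)) {
    stop("configuration error: category_mix must be non-negative and sum to 1")
  }
  if (!setequal(names(category_mix), c("OTC", "Rx_Top200", "Rx_Other"))) {
    stop("configuration error: category_mix needs OTC, Rx_Top200, Rx_Other")
  }
  for (r in c(multiword_fraction, unseen_term_rate, coverage,
              modifier_probability)) {
    if (r < 0 || r > 1) stop("configuration error: rates must be in [0, 1]")
  }
  if (n_docs < n_folds) {
    stop("configuration error: n_docs must be >= n_folds")
  }
  structure(list(n_docs = as.integer(n_docs), category_mix = category_mix,
                 conditions_per_section = conditions_per_section,
                 n_condition_terms = as.integer(n_condition_terms),
                 multiword_fraction = multiword_fraction,
                 unseen_term_rate = unseen_term_rate,
                 coverage = coverage,
                 modifier_probability = modifier_probability,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a condition-term lexicon
#'
#' Deterministic pseudo-medical vocabulary: single-token terms built from
#' syllables, plus multiword terms — adjective-noun pairs/triples whose
#' head noun is itself a term, and coordinated "X and Y" terms whose
#' constituents are also terms (to exercise the maximum coverage rule).
#'
#' @param n Number of unique terms (>= 1).
#' @param multiword_fraction Fraction of multiword terms.
#' @param seed Integer seed.
#' @return Character vector of `n` unique terms.
#' @export
generate_condition_lexicon <- function(n, multiword_fraction = 0.35,
                                       seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  n_multi <- round(n * multiword_fraction)
  n_single <- n - n_multi
  if (n_multi > 0 && n_single < 2) {
    stop("configuration error: multiword terms need at least 2 single-token terms")
  }
  with_seed(seed, {
    singles <- character(0)
    while (length(singles) < n_single) {
      w <- paste0(sample(synth_syllables$pre, 1),
                  sample(synth_syllables$mid, 1),
                  sample(synth_syllables$suf, 1))
      if (!w %in% singles && !w %in% synth_filler) singles <- c(singles, w)
    }
    multis <- character(0)
    while (length(multis) < n_multi) {
      kind <- sample(c("adj2", "adj3", "coord"), 1,
                     prob = c(0.5, 0.2, 0.3))
      t <- switch(kind,
        adj2 = paste(sample(synth_cond_adjectives, 1), sample(singles, 1)),
        adj3 = paste(paste(sample(synth_cond_adjectives, 2), collapse = " "),
                     sample(singles, 1)),
        coord = paste(sample(singles, 2), collapse = " and "))
      if (!t %in% multis) multis <- c(multis, t)
    }
    c(singles, multis)
  })
}

#' Default TUI assignment distribution for generated condition terms
#'
#' A mix of the eleven qualifying medical-condition semantic types (total
#' probability 0.55) with the noisy `T033` (finding, 0.25) and the
#' non-condition `T170` (intellectual product, 0.20), emulating the
#' imperfect semantic typing of a real terminology lookup — the reason a
#' pure TUI-filter baseline misses mentions.
#'
#' @return Named numeric probability vector over TUI codes.
#' @export
default_tui_distribution <- function() {
  c(T047 = 0.15, T184 = 0.15, T046 = 0.06, T048 = 0.05, T037 = 0.04,
    T191 = 0.03, T190 = 0.02, T019 = 0.02, T020 = 0.01, T049 = 0.01,
    T050 = 0.01, T033 = 0.25, T170 = 0.20)
}

#' Generate a semantic lexicon over condition terms
#'
#' Assigns a CUI and a TUI (drawn from `tui_distribution`) to a
#' `coverage` fraction of the condition terms.  Decoy (non-condition)
#' terms receive non-qualifying TUIs (`T033`/`T170`), except for
#' `decoy_qualifying` of them which receive qualifying TUIs — emulating
#' ambiguous vocabulary entries that give a TUI-filter baseline false
#' positives.
#'
#' @param terms Character vector of condition terms.
#' @param coverage Fraction of terms receiving an entry.
#' @param tui_distribution Named probability vector over TUI codes.
#' @param seed Integer seed.
#' @param decoy_terms Non-condition terms to include as decoys.
#' @param decoy_qualifying How many decoys get qualifying TUIs.
#' @return A [sem_lexicon()].
#' @export
generate_semantic_lexicon <- function(terms, coverage = 1.0,
                                      tui_distribution = default_tui_distribution(),
                                      seed = 1L,
                                      decoy_terms = character(0),
                                      decoy_qualifying = 0L) {
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  with_seed(seed, {
    n_cov <- round(coverage * length(terms))
    covered <- if (n_cov > 0) sample(terms, n_cov) else character(0)
    tuis <- if (n_cov > 0) {
      sample(names(tui_distribution), n_cov, replace = TRUE,
             prob = tui_distribution)
    } else character(0)
    all_terms <- covered
    all_tuis <- tuis
    if (length(decoy_terms) > 0) {
      decoy_qualifying <- min(decoy_qualifying, length(decoy_terms))
      qual_idx <- if (decoy_qualifying > 0) {
        sample(seq_along(decoy_terms), decoy_qualifying)
      } else integer(0)
      d_tuis <- sample(c("T033", "T170"), length(decoy_terms),
                       replace = TRUE)
      if (length(qual_idx)) {
        d_tuis[qual_idx] <- sample(default_tui_set(), length(qual_idx),
                                   replace = TRUE)
      }
      all_terms <- c(all_terms, decoy_terms)
      all_tuis <- c(all_tuis, d_tuis)
    }
    cuis <- sprintf("C%07d", seq_along(all_terms))
    sem_lexicon(all_terms, cuis, all_tuis)
  })
}

# One generated sentence: returns list(words, mention_range or NULL).
synth_sentence <- function(mention_tokens = NULL, modifier = FALSE) {
  pre <- sample(synth_filler, sample(2:6, 1), replace = TRUE)
  pre[1] <- paste0(toupper(substr(pre[1], 1, 1)), substring(pre[1], 2))
  post <- sample(synth_filler, sample(1:4, 1), replace = TRUE)
  if (is.null(mention_tokens)) {
    return(list(words = c(pre, post), mention = NULL))
  }
  if (modifier) pre <- c(pre, sample(synth_modifiers, 1))
  a <- length(pre) + 1L
  b <- a + length(mention_tokens) - 1L
  list(words = c(pre, mention_tokens, post), mention = c(a, b))
}

synth_section_codes <- function(category) {
  wl <- section_whitelist()
  if (category == "OTC") {
    return(c("34071-1", "34067-9")) # Warnings; Indications & Usage
  }
  codes <- names(wl)
  sample(codes, sample(4:8, 1))
}

#' Generate a synthetic annotated SPL corpus
#'
#' Produces SPL XML label documents, gold standoff annotations, a
#' condition lexicon and a semantic lexicon, deterministically from the
#' config seed.  Documents are assigned round-robin to `n_folds` folds;
#' fold 0 is the designated test fold, and a mention in a test-fold
#' document draws (with probability `unseen_term_rate`) a surface from a
#' reserved term pool that never occurs in training folds, otherwise a
#' surface realized in the training folds.  Mentions are embedded in
#' filler prose and never adjacent to one another; with probability
#' `modifier_probability` a modifier token directly precedes a mention and
#' is excluded from the gold span.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory: writes one SPL XML file per
#'   document, `gold.tsv` (standoff), `condition_lexicon.txt`,
#'   `semantic_lexicon.tsv` and `manifest.json`.
#' @return Object of class `synth_corpus`: list with `documents` (named
#'   list of `label_document`s), `gold` (annotation data frame),
#'   `condition_lexicon`, `semantic_lexicon`, `manifest`.
#' @export
generate_corpus <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  terms <- generate_condition_lexicon(config$n_condition_terms,
                                      config$multiword_fraction,
                                      seed = config$seed + 101L)
  semlex <- generate_semantic_lexicon(
    terms, coverage = config$coverage, seed = config$seed + 202L,
    decoy_terms = synth_filler, decoy_qualifying = 3L)

  res <- with_seed(config$seed, {
    n <- config$n_docs
    # term pools: reserve ~35% for test-only surfaces
    n_test_pool <- max(1L, round(0.35 * length(terms)))
    test_pool <- sample(terms, n_test_pool)
    train_pool <- setdiff(terms, test_pool)
    if (length(train_pool) == 0) stop("configuration error: no training terms left")

    cats <- sample(rep(names(config$category_mix),
                       times = round(config$category_mix * n) + 1)[1:n])
    folds <- (seq_len(n) - 1L) %% config$n_folds
    doc_ids <- sprintf("doc%03d", seq_len(n))
    drug_names <- paste0("Drug", toupper(letters[(seq_len(n) - 1L) %% 26 + 1]),
                         seq_len(n))
    ndcs <- sprintf("%05d-%03d-%02d", sample(10000:99999, n, replace = TRUE),
                    sample(100:999, n, replace = TRUE),
                    sample(10:99, n, replace = TRUE))

    gen_doc <- function(i, mention_sampler) {
      codes <- synth_section_codes(cats[i])
      wl <- section_whitelist()
      sec_texts <- character(0); sec_codes <- character(0)
      gold_rows <- list()
      for (si in seq_along(codes) - 1L) {
        n_m <- rpois(1, config$conditions_per_section)
        n_f <- rpois(1, 1) + 1L
        kinds <- c(rep(TRUE, n_m), rep(FALSE, n_f))
        kinds <- kinds[sample.int(length(kinds))]
        pos <- 0L
        parts <- character(0)
        for (is_mention in kinds) {
          if (is_mention) {
            term <- mention_sampler()
            mt <- strsplit(term, " ", fixed = TRUE)[[1]]
            sen <- synth_sentence(mt, modifier = runif(1) < config$modifier_probability)
          } else {
            sen <- synth_sentence()
          }
          stext <- paste0(paste(sen$words, collapse = " "), ".")
          if (!is.null(sen$mention)) {
            a <- sen$mention[1]; b <- sen$mention[2]
            lens <- nchar(sen$words)
            cs <- pos + if (a > 1) sum(lens[1:(a - 1)]) + (a - 1L) else 0L
            ce <- pos + sum(lens[1:b]) + (b - 1L)
            gold_rows[[length(gold_rows) + 1L]] <- data.frame(
              doc_id = doc_ids[i], section_index = si,
              char_start = cs, char_end = ce,
              category = sample(c("DD", "SS"), 1),
              surface = paste(sen$words[a:b], collapse = " "),
              stringsAsFactors = FALSE)
          }
          parts <- c(parts, stext)
          pos <- pos + nchar(stext) + 1L # joining space
        }
        sec_texts <- c(sec_texts, paste(parts, collapse = " "))
        sec_codes <- c(sec_codes, codes[si + 1L])
      }
      sections <- data.frame(loinc_code = sec_codes,
                             header = unname(wl[sec_codes]),
                             text = sec_texts, stringsAsFactors = FALSE)
      doc <- new_label_document(doc_ids[i], drug_names[i], ndcs[i],
                                cats[i], sections)
      list(doc = doc, gold = if (length(gold_rows)) {
        do.call(rbind, gold_rows)
      } else span_annotations())
    }

    documents <- vector("list", n)
    gold_list <- vector("list", n)
    train_surfaces <- character(0)
    train_sampler <- function() sample(train_pool, 1)
    for (i in which(folds != 0L)) {
      out <- gen_doc(i, train_sampler)
      documents[[i]] <- out$doc
      gold_list[[i]] <- out$gold
      train_surfaces <- union(train_surfaces, tolower(out$gold$surface))
    }
    if (length(train_surfaces) == 0) {
      stop("configuration error: training folds realized no mentions")
    }
    test_sampler <- function() {
      if (runif(1) < config$unseen_term_rate) sample(test_pool, 1)
      else sample(train_surfaces, 1)
    }
    for (i in which(folds == 0L)) {
      out <- gen_doc(i, test_sampler)
      documents[[i]] <- out$doc
      gold_list[[i]] <- out$gold
    }
    gold <- do.call(rbind, gold_list)
    rownames(gold) <- NULL
    names(documents) <- doc_ids
    list(documents = documents, gold = gold, folds = folds,
         doc_ids = doc_ids, categories = cats,
         train_surfaces = train_surfaces)
  })

  validate_annotations(res$gold, res$documents)
  test_docs <- res$doc_ids[res$folds == 0L]
  test_gold <- res$gold[res$gold$doc_id %in% test_docs, , drop = FALSE]
  seen <- tolower(test_gold$surface) %in% res$train_surfaces
  per_doc <- table(factor(res$gold$doc_id, levels = res$doc_ids))
  manifest <- list(
    config = unclass(config), seed = config$seed,
    folds = setNames(as.list(res$folds), res$doc_ids),
    categories = setNames(as.list(res$categories), res$doc_ids),
    mention_counts = setNames(as.list(as.integer(per_doc)), res$doc_ids),
    n_test_mentions = nrow(test_gold),
    realized_seen_fraction = if (nrow(test_gold)) mean(seen) else NA_real_)

  corpus <- structure(list(documents = res$documents, gold = res$gold,
                           condition_lexicon = terms,
                           semantic_lexicon = semlex,
                           manifest = manifest),
                      class = "synth_corpus")
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}

#' @export
print.synth_corpus <- function(x, ...) {
  m <- x$manifest
  cat("<synth_corpus>", length(x$documents), "documents,",
      nrow(x$gold), "gold mentions,",
      length(x$condition_lexicon), "condition terms\n")
  cat(sprintf("test fold: %d mentions, realized seen-surface fraction %.3f\n",
              m$n_test_mentions, m$realized_seen_fraction))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' @param corpus A `synth_corpus`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (doc in corpus$documents) {
    writeLines(serialize_spl(doc), file.path(dir, paste0(doc$doc_id, ".xml")),
               useBytes = TRUE)
  }
  write_standoff(corpus$gold, file.path(dir, "gold.tsv"))
  writeLines(corpus$condition_lexicon,
             file.path(dir, "condition_lexicon.txt"), useBytes = TRUE)
  write_sem_lexicon(corpus$semantic_lexicon,
                    file.path(dir, "semantic_lexicon.tsv"))
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Worked micro-example fixtures
#'
#' Ready-made (text, gold, dictionary) fixtures for the three canonical
#' micro-examples used throughout the tests:
#' \describe{
#'   \item{urea}{A two-section excerpt of the Urea 40 Gel/Lotion label
#'     (synthetic condensation of the indications sentence so that
#'     "hyperkeratotic lesion" is contiguous) with gold spans for
#'     "hyperkeratotic lesion", "stinging" and "burning", and the three
#'     expected triples.}
#'   \item{nausea}{"Side effects may include nausea and vomiting." with
#'     the dictionary \{"nausea", "vomiting", "nausea and vomiting"\} —
#'     maximum coverage must label the single long span.}
#'   \item{muscle}{"muscle tenderness or weakness" with two overlapping
#'     gold spans sharing the start token "muscle" — the token-level MC_B
#'     count is 1 while the span-level left-match gold count is 2.}
#' }
#'
#' @return Named list of fixtures.
#' @export
worked_example_fixtures <- function() {
  ind_text <- paste("For debridement and promotion of normal healing of a",
                    "hyperkeratotic lesion such as dry, rough skin,",
                    "dermatitis, psoriasis, xerosis, ichthyosis, eczema,",
                    "keratosis, keratoderma, corns and calluses.")
  adv_text <- paste("Transient stinging, burning, itching or irritation may",
                    "occur and normally disappear on discontinuing the",
                    "medication.")
  xml <- paste0(
    '<label id="urea-40" category="Rx_Other">',
    '<drug name="Urea" ndc="42192-101-10"/>',
    '<section code="34067-9" title="INDICATIONS AND USAGE">', ind_text,
    '</section>',
    '<section code="34084-4" title="ADVERSE REACTIONS">', adv_text,
    '</section></label>')
  doc <- parse_spl(xml)
  fdoc <- filter_sections(doc)
  span_at <- function(section_index, pattern) {
    text <- fdoc$sections$text[section_index + 1L]
    m <- regexpr(pattern, text, fixed = TRUE)
    span_annotations(doc_id = fdoc$doc_id, section_index = section_index,
                     char_start = as.integer(m) - 1L,
                     char_end = as.integer(m) + attr(m, "match.length") - 1L,
                     category = "MC", surface = pattern)
  }
  urea_gold <- rbind(span_at(0L, "hyperkeratotic lesion"),
                     span_at(1L, "stinging"),
                     span_at(1L, "burning"))
  urea <- list(xml = xml, doc = doc, filtered = fdoc, gold = urea_gold,
               triples = data.frame(
                 drug_name = "Urea",
                 condition = c("hyperkeratotic lesion", "stinging", "burning"),
                 section_header = c("INDICATION", "ADVERSE REACTION",
                                    "ADVERSE REACTION"),
                 stringsAsFactors = FALSE))

  nausea_text <- "Side effects may include nausea and vomiting."
  m <- regexpr("nausea and vomiting", nausea_text, fixed = TRUE)
  nausea <- list(
    text = nausea_text,
    dict = build_term_dictionary(data.frame(
      surface = c("nausea", "vomiting", "nausea and vomiting"),
      stringsAsFactors = FALSE), provenance = "worked example"),
    gold = span_annotations(doc_id = "nausea", section_index = 0L,
                            char_start = as.integer(m) - 1L,
                            char_end = as.integer(m) + attr(m, "match.length") - 1L,
                            category = "SS", surface = "nausea and vomiting"))

  muscle_text <- "Patients reported muscle tenderness or weakness today."
  m1 <- regexpr("muscle tenderness or weakness", muscle_text, fixed = TRUE)
  m2 <- regexpr("muscle tenderness", muscle_text, fixed = TRUE)
  muscle <- list(
    text = muscle_text,
    gold = span_annotations(
      doc_id = c("muscle", "muscle"), section_index = 0L,
      char_start = c(as.integer(m2) - 1L, as.integer(m1) - 1L),
      char_end = c(as.integer(m2) + attr(m2, "match.length") - 1L,
                   as.integer(m1) + attr(m1, "match.length") - 1L),
      category = c("SS", "SS"),
      surface = c("muscle tenderness", "muscle tenderness or weakness")))

  list(urea = urea, nausea = nausea, muscle = muscle)
}
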