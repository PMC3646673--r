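test_that("condition lexicon honours size, multiword fraction and coordination", {
  terms <- generate_condition_lexicon(10, multiword_fraction = 0.5, seed = 7)
  expect_length(terms, 10)
  expect_length(unique(terms), 10)
  n_words <- lengths(strsplit(terms, " ", fixed = TRUE))
  expect_equal(sum(n_words > 1), 5)

  singles <- generate_condition_lexicon(8, multiword_fraction = 0, seed = 2)
  expect_true(all(lengths(strsplit(singles, " ")) == 1))

  # coordinated terms imply their constituents are terms too
  big <- generate_condition_lexicon(80, multiword_fraction = 0.4, seed = 5)
  coords <- grep(" and ", big, value = TRUE)
  expect_gt(length(coords), 0)
  for (co in coords) {
    parts <- strsplit(co, " and ", fixed = TRUE)[[1]]
    expect_true(all(parts %in% big))
  }
})

test_that("semantic lexicon coverage bounds and decoy typing hold", {
  terms <- generate_condition_lexicon(20, 0.3, seed = 3)
  full <- generate_semantic_lexicon(terms, coverage = 1, seed = 1)
  norm <- vapply(terms, mclabel:::normalize_term, character(1))
  expect_true(all(norm %in% full$entries$term))

  none <- generate_semantic_lexicon(terms, coverage = 0, seed = 1)
  expect_equal(nrow(none$entries), 0)

  # decoys without qualifying slots are invisible to the TUI baseline
  lx <- generate_semantic_lexicon(terms, coverage = 0, seed = 4,
                                  decoy_terms = c("apply", "water"),
                                  decoy_qualifying = 0)
  expect_true(all(lx$entries$tui %in% c("T033", "T170")))
  toks <- tokenize("apply with water")
  sem <- semantic_lookup(toks, lx)
  expect_equal(nrow(baseline_tui_extract(toks, sem, text = "apply with water")), 0)
})

test_that("corpus generation is deterministic given the seed", {
  cfg <- synth_config(n_docs = 6L, conditions_per_section = 2,
                      n_condition_terms = 24L, seed = 21L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(lapply(c1$documents, serialize_spl),
                   lapply(c2$documents, serialize_spl))
  expect_identical(c1$gold, c2$gold)
  expect_identical(c1$manifest, c2$manifest)
})

test_that("generated gold validates and the manifest counts agree", {
  corp <- small_corpus()
  expect_silent(validate_annotations(corp$gold, corp$documents))
  counts <- table(factor(corp$gold$doc_id, levels = names(corp$documents)))
  expect_equal(unlist(corp$manifest$mention_counts),
               setNames(as.integer(counts), names(corp$documents)))
  # OTC documents have exactly the Warning and Indications sections
  for (doc in corp$documents) {
    if (doc$category == "OTC") {
      expect_setequal(doc$sections$loinc_code, c("34071-1", "34067-9"))
    }
  }
})

test_that("the realized unseen-surface rate tracks the configured rate", {
  corp <- generate_corpus(synth_config(seed = 7)) # defaults: 40 docs, 0.3
  m <- corp$manifest
  expect_gte(m$n_test_mentions, 200)
  expect_lt(abs((1 - m$realized_seen_fraction) - 0.3), 0.05)
})

test_that("modifier_probability = 1 puts a modifier before every mention, outside it", {
  modifiers <- c("generalized", "transient", "severe", "mild",
                 "persistent", "recurrent")
  corp <- generate_corpus(synth_config(
    n_docs = 4L, conditions_per_section = 3, n_condition_terms = 20L,
    modifier_probability = 1, seed = 9L))
  expect_gt(nrow(corp$gold), 0)
  for (i in seq_len(nrow(corp$gold))) {
    g <- corp$gold[i, ]
    text <- corp$documents[[g$doc_id]]$sections$text[g$section_index + 1L]
    toks <- tokenize(text)
    first <- which(toks$char_start == g$char_start)
    expect_gt(first, 1)
    expect_true(toks$text[first - 1L] %in% modifiers)
    expect_false(grepl(paste(modifiers, collapse = "|"), g$surface))
  }
})

test_that("with no unseen terms the dictionary baseline reaches recall 1", {
  corp <- generate_corpus(synth_config(
    n_docs = 8L, conditions_per_section = 3, n_condition_terms = 30L,
    unseen_term_rate = 0, seed = 31L))
  folds <- unlist(corp$manifest$folds)
  test_ids <- names(folds)[folds == 0]
  train_gold <- corp$gold[!corp$gold$doc_id %in% test_ids, ]
  test_gold <- corp$gold[corp$gold$doc_id %in% test_ids, ]
  dict <- build_term_dictionary(train_gold)
  pred <- do.call(rbind, lapply(corp$documents[test_ids], function(d)
    run_pipeline(d, dict = dict, lexicon = corp$semantic_lexicon,
                 baseline = "dict")$spans))
  ev <- span_level_eval(test_gold, pred, "exact")
  expect_equal(ev$recall, 1)
})

test_that("an impossible configuration is rejected", {
  expect_error(synth_config(category_mix = c(OTC = 0.5, Rx_Top200 = 0.2,
                                             Rx_Other = 0.2)),
               "configuration error")
  expect_error(synth_config(unseen_term_rate = 1.2), "configuration error")
  expect_error(synth_config(n_docs = 2, n_folds = 4), "configuration error")
  expect_error(generate_condition_lexicon(2, multiword_fraction = 0.5),
               "configuration error")
})

test_that("worked-example fixtures carry the canonical texts and structures", {
  fx <- worked_example_fixtures()
  expect_match(document_text(fx$urea$doc),
               "Transient stinging, burning, itching or irritation may occur",
               fixed = TRUE)
  expect_setequal(fx$nausea$dict$terms,
                  c("nausea", "vomiting", "nausea and vomiting"))
  expect_equal(nrow(fx$muscle$gold), 2)
  expect_equal(fx$muscle$gold$char_start[1], fx$muscle$gold$char_start[2])
  expect_lt(fx$muscle$gold$char_end[1], fx$muscle$gold$char_end[2])
})

test_that("write_corpus emits parseable XML, valid standoff and lexicon files", {
  corp <- small_corpus()
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  xmls <- list.files(dir, pattern = "\\.xml$", full.names = TRUE)
  expect_length(xmls, length(corp$documents))
  doc1 <- parse_spl(xmls[1])
  expect_s3_class(doc1, "label_document")
  ann <- read_standoff(file.path(dir, "gold.tsv"), docs = corp$documents)
  expect_equal(nrow(ann), nrow(corp$gold))
  lex <- read_sem_lexicon(file.path(dir, "semantic_lexicon.tsv"))
  expect_equal(nrow(lex$entries), nrow(corp$semantic_lexicon$entries))
})
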