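test_that("TUI baseline groups maximal qualifying runs and excludes T033", {
  text <- "alpha cellulitis sepsis bravo"
  toks <- tokenize(text)
  sem <- data.frame(cui = c("NONE", "C1", "C2", "NONE"),
                    tui = c("NONE", "T047", "T047", "NONE"))
  spans <- baseline_tui_extract(toks, sem, text = text)
  expect_equal(nrow(spans), 1)
  expect_equal(spans$surface, "cellulitis sepsis")

  sem_none <- data.frame(cui = rep("NONE", 4), tui = rep("NONE", 4))
  expect_equal(nrow(baseline_tui_extract(toks, sem_none, text = text)), 0)

  sem_t033 <- data.frame(cui = c("NONE", "C1", "NONE", "NONE"),
                         tui = c("NONE", "T033", "NONE", "NONE"))
  expect_equal(nrow(baseline_tui_extract(toks, sem_t033, text = text)), 0)
})

test_that("term dictionaries are built from normalized unique surfaces", {
  gold <- data.frame(surface = c("rash", "generalized rash", "Rash"))
  dict <- build_term_dictionary(gold)
  expect_setequal(dict$terms, c("rash", "generalized rash"))
  expect_equal(dict$max_len, 2L)

  empty <- build_term_dictionary(data.frame(surface = character(0)))
  expect_equal(length(empty$terms), 0)
  expect_equal(empty$max_len, 0L)
})

test_that("maximum coverage labels only the longest matching span", {
  fx <- worked_example_fixtures()$nausea
  toks <- tokenize(fx$text)
  spans <- dictionary_match(toks, fx$dict, text = fx$text)
  expect_equal(spans$surface, "nausea and vomiting")
  expect_equal(nrow(spans), 1)

  none <- dictionary_match(toks, build_term_dictionary(
    data.frame(surface = character(0))), text = fx$text)
  expect_equal(nrow(none), 0)
})

test_that("greedy dictionary matching equals the brute-force oracle", {
  set.seed(31)
  terms <- c("alpha", "bravo", "alpha bravo", "echo kilo", "kilo",
             "delta echo kilo", "golf")
  dict <- build_term_dictionary(data.frame(surface = terms))
  for (r in 1:200) {
    toks_txt <- sample(filler_words, sample(1:10, 1), replace = TRUE)
    text <- paste(toks_txt, collapse = " ")
    toks <- tokenize(text)
    got <- dictionary_match(toks, dict, text = text)
    want <- brute_leftmost_longest(tolower(toks$text), dict$terms,
                                   dict$max_len)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      i <- want[[k]][1]; len <- want[[k]][2]
      expect_equal(got$char_start[k], toks$char_start[i])
      expect_equal(got$char_end[k], toks$char_end[i + len - 1L])
    }
    # matched surfaces are dictionary terms; output never overlaps
    expect_true(all(tolower(got$surface) %in% dict$terms))
    if (nrow(got) > 1) {
      expect_true(all(got$char_start[-1] >= head(got$char_end, -1)))
    }
  }
})

test_that("post-processing replaces contained CRF spans and adds missed terms", {
  mk <- function(starts, ends) span_annotations(
    doc_id = rep("d", length(starts)), section_index = 0L,
    char_start = starts, char_end = ends, category = "MC",
    surface = strrep("x", ends - starts))

  # CRF found "rash" inside the dictionary's "generalized rash"
  crf <- mk(12, 16)
  dict <- mk(0, 16)
  out <- postprocess_merge(crf, dict)
  expect_equal(out$char_start, 0L)
  expect_equal(out$char_end, 16L)

  # disjoint dictionary span ("photosensitivity") is added
  out <- postprocess_merge(mk(0, 4), mk(10, 26))
  expect_equal(out$char_start, c(0L, 10L))

  # empty dictionary output leaves CRF spans untouched
  crf <- mk(c(0, 10), c(4, 15))
  expect_equal(postprocess_merge(crf, span_annotations()), crf)

  # partial (non-containment) overlap: CRF wins, dictionary span dropped
  out <- postprocess_merge(mk(5, 12), mk(8, 20))
  expect_equal(out$char_start, 5L)
  expect_equal(out$char_end, 12L)
})

test_that("merged output never loses covered characters (monotone coverage)", {
  set.seed(59)
  covered <- function(sp) {
    if (nrow(sp) == 0) return(integer(0))
    sort(unique(unlist(mapply(seq, sp$char_start, sp$char_end - 1L,
                              SIMPLIFY = FALSE))))
  }
  nonoverlapping <- function(n) {
    sp <- random_spans(n)
    keep <- rep(TRUE, nrow(sp))
    if (nrow(sp) > 1) for (i in 2:nrow(sp)) {
      prev <- max(sp$char_end[seq_len(i - 1)][keep[seq_len(i - 1)]])
      if (sp$char_start[i] < prev) keep[i] <- FALSE
    }
    sp[keep, , drop = FALSE]
  }
  for (r in 1:100) {
    crf <- nonoverlapping(sample(0:4, 1))
    dic <- nonoverlapping(sample(0:4, 1))
    out <- postprocess_merge(crf, dic)
    expect_true(all(covered(crf) %in% covered(out)))
    # result is sorted and non-overlapping
    if (nrow(out) > 1) {
      expect_true(all(out$char_start[-1] >= head(out$char_end, -1)))
    }
  }
})

test_that("triples are assembled per unique condition and section header", {
  fx <- worked_example_fixtures()$urea
  got <- assemble_triples(fx$filtered, fx$gold)
  expect_equal(got, fx$triples)

  expect_equal(nrow(assemble_triples(fx$filtered, span_annotations())), 0)

  twice <- rbind(fx$gold, fx$gold[2, ])
  expect_equal(assemble_triples(fx$filtered, twice), fx$triples)

  bad <- fx$gold
  bad$section_index[1] <- 5L
  expect_error(assemble_triples(fx$filtered, bad), "data error")
})

test_that("the pipeline surfaces every gold condition when the dictionary is complete", {
  corp <- small_corpus()
  folds <- unlist(corp$manifest$folds)
  test_ids <- names(folds)[folds == 0]
  dict <- build_term_dictionary(corp$gold) # complete: includes test surfaces
  for (id in test_ids) {
    res <- run_pipeline(corp$documents[[id]], dict = dict,
                        lexicon = corp$semantic_lexicon, baseline = "dict")
    gold_d <- corp$gold[corp$gold$doc_id == id, ]
    expect_true(all(tolower(gold_d$surface) %in% tolower(res$triples$condition)))
  }
})

test_that("a label with no whitelisted sections yields an empty result", {
  doc <- parse_spl(paste0('<label id="x"><drug name="X"/>',
                          '<section code="12345-6" title="T">alpha bravo.</section>',
                          '</label>'))
  res <- run_pipeline(doc, dict = build_term_dictionary(
    data.frame(surface = "alpha")), lexicon = sem_lexicon(),
    baseline = "dict")
  expect_equal(nrow(res$spans), 0)
  expect_equal(nrow(res$triples), 0)
})
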