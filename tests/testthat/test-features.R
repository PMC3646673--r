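test_that("sentence_split finds boundaries and honors abbreviation guards", {
  s <- sentence_split("Transient stinging may occur. Discontinue use.")
  expect_equal(nrow(s), 2)
  expect_equal(s$char_start, c(0L, 30L))

  expect_equal(nrow(sentence_split("")), 0)
  expect_equal(nrow(sentence_split("e.g. Rash may appear")), 1)
  expect_equal(nrow(sentence_split("See Fig. 2 for details")), 1)

  # sentences cover all non-whitespace characters
  text <- "First one. Second one! Third? 4th sentence."
  s <- sentence_split(text)
  expect_equal(nrow(s), 4)
  covered <- unlist(lapply(seq_len(nrow(s)), function(i) {
    (s$char_start[i] + 1):s$char_end[i]
  }))
  chars <- strsplit(text, "")[[1]]
  nonws <- which(!grepl("[[:space:]]", chars))
  expect_true(all(nonws %in% covered))
})

test_that("tokenize separates punctuation, keeps hyphens, records offsets", {
  expect_equal(tokenize("stinging, burning")$text,
               c("stinging", ",", "burning"))
  expect_equal(nrow(tokenize("")), 0)
  expect_equal(tokenize("SPF 34")$text, c("SPF", "34"))
  expect_equal(tokenize("anti-itch cream")$text, c("anti-itch", "cream"))

  # every token equals its text slice (offset invariant)
  set.seed(5)
  for (text in c("Take 2 tablets (max. 6/day); see insert.",
                 "Rx only -- store at 25 C",
                 paste(sample(filler_words, 8, TRUE), collapse = " "))) {
    toks <- tokenize(text)
    expect_equal(substring(text, toks$char_start + 1L, toks$char_end),
                 toks$text)
  }
})

test_that("Porter stemmer reproduces hand-traced stems", {
  pairs <- c(
    caresses = "caress", ponies = "poni", caress = "caress", cats = "cat",
    feed = "feed", agreed = "agre", plastered = "plaster",
    motoring = "motor", hopping = "hop", falling = "fall", filing = "file",
    sized = "size", happy = "happi", sky = "sky",
    lesions = "lesion", burning = "burn", rash = "rash",
    stinging = "sting", itching = "itch",
    electrical = "electr", hopeful = "hope", goodness = "good",
    rate = "rate", controll = "control", roll = "roll")
  expect_equal(stem(names(pairs)), unname(pairs))
  # non-alphabetic and short tokens pass through lowercased
  expect_equal(stem(c("SPF", "34", "B-12", "of")),
               c("spf", "34", "b-12", "of"))
})

test_that("heuristic POS tagger is deterministic and total", {
  toks <- c("Transient", "stinging", ",", "burning", "may", "occur",
            "in", "34", "patients", ".")
  tags <- pos_tag(toks)
  expect_length(tags, length(toks))
  expect_equal(tags[toks == "may"], "MD")
  expect_equal(tags[toks == "34"], "CD")
  expect_equal(tags[toks == "in"], "IN")
  expect_equal(tags[toks == ","], ",")
  expect_identical(pos_tag(toks), tags)
})

test_that("semantic_lookup links terms and projects codes over constituents", {
  lex <- sem_lexicon("cellulitis", "C0007642", "T047")
  got <- semantic_lookup(tokenize("cellulitis"), lex)
  expect_equal(got$cui, "C0007642")
  expect_equal(got$tui, "T047")

  empty <- sem_lexicon()
  got <- semantic_lookup(tokenize("nausea and vomiting"), empty)
  expect_equal(got$tui, rep("NONE", 3))

  lex2 <- sem_lexicon(c("nausea", "nausea and vomiting"),
                      c("C1", "C2"), c("T184", "T184"))
  got <- semantic_lookup(tokenize("nausea and vomiting"), lex2)
  expect_equal(got$cui, rep("C2", 3)) # leftmost-longest 3-gram wins
})

test_that("semantic_lookup agrees with the brute-force enumeration oracle", {
  set.seed(77)
  vocab <- c(filler_words, "derma", "itis", "algia")
  terms <- c("derma", "itis algia", "alpha derma itis", "bravo", "echo kilo")
  lex <- sem_lexicon(terms, sprintf("C%07d", seq_along(terms)),
                     sample(c("T047", "T184", "T033"), length(terms), TRUE))
  for (r in 1:200) {
    toks <- sample(vocab, sample(1:10, 1), replace = TRUE)
    expect_equal(semantic_lookup(toks, lex),
                 brute_semantic_lookup(tolower(toks), lex))
  }
})

test_that("extract_features emits the fixed schema with PAD sentinels", {
  toks <- c("Transient", "stinging")
  pos <- pos_tag(toks)
  sem <- data.frame(cui = c("NONE", "C1"), tui = c("NONE", "T184"))
  f <- extract_features(toks, 2L, pos, sem, feature_config("tui"))
  expect_true(all(c("w0=stinging", "w-1=Transient", "w-2=<PAD>",
                    "cap-1=TRUE", "len0=8", "prefix2=st", "suffix2=ng",
                    "w0.stem=sting", "big-1=Transient|stinging",
                    "tui0=T184") %in% f))
  expect_false(any(grepl("^cui0=", f)))

  f_cui <- extract_features(toks, 2L, pos, sem, feature_config("cui"))
  expect_true("cui0=C1" %in% f_cui)
  expect_false(any(grepl("^tui0=", f_cui)))

  num <- extract_features("34", 1L, "CD",
                          data.frame(cui = "NONE", tui = "NONE"),
                          feature_config("none"))
  expect_true("charclass0=digit" %in% num)

  expect_error(extract_features(toks, 3L, pos, sem), "range error")
})

test_that("feature count is constant and ablation disables the semantic group", {
  lex <- sem_lexicon(c("alpha", "bravo echo"), c("C1", "C2"),
                     c("T047", "T184"))
  set.seed(21)
  for (r in 1:10) {
    toks <- sample(c(filler_words, "Alpha", "34"), sample(2:8, 1), TRUE)
    for (cfg in list(feature_config("none"), feature_config("tui"),
                     feature_config("cui"), feature_config("both"))) {
      fs <- sentence_features(toks, lex, cfg)
      expect_length(unique(lengths(fs)), 1)
    }
    # with the semantic group disabled, the lexicon cannot matter
    f_none <- sentence_features(toks, lex, feature_config("none"))
    f_none2 <- sentence_features(toks, sem_lexicon(), feature_config("none"))
    expect_identical(f_none, f_none2)
  }
})

test_that("a POS provider with wrong output length is rejected", {
  bad_tagger <- function(tokens) rep("NN", length(tokens) + 1L)
  expect_error(
    sentence_features(c("a", "b"), sem_lexicon(), pos_tagger = bad_tagger),
    "POS provider")
})
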