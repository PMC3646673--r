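test_that("prf and f_measure follow the harmonic-mean identities", {
  expect_equal(round_metric(f_measure(0.933, 0.771)), 0.844)
  expect_equal(round_metric(f_measure(0.900, 0.812)), 0.854)
  z <- prf(0, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f), c(0, 0, 0))
  p <- prf(8, 2, 4)
  expect_equal(p$precision, 0.8)
  expect_equal(p$recall, 8 / 12)
  expect_equal(p$f, f_measure(0.8, 8 / 12))
  expect_error(prf(-1, 0, 0), "domain error")
})

test_that("token-level evaluation tallies per label with micro overall", {
  gold <- list(c("O", "MC_B", "MC_I", "O"), c("MC_B", "O"))
  expect_equal(token_level_eval(gold, gold)$overall$f, 1)

  pred <- list(c("O", "MC_B", "O", "O"), c("MC_B", "MC_I"))
  ev <- token_level_eval(gold, pred)
  expect_equal(ev$per_label$MC_B$tp, 2)
  expect_equal(ev$per_label$MC_I$fn, 1)
  expect_equal(ev$per_label$MC_I$fp, 1)
  expect_equal(ev$overall$tp, ev$per_label$MC_B$tp + ev$per_label$MC_I$tp)

  expect_error(token_level_eval(gold, list(c("O"))), "data error")
})

test_that("overlapping entities sharing a start token count one MC_B", {
  fx <- worked_example_fixtures()$muscle
  toks <- tokenize(fx$text)
  gold_labels <- encode_bio(toks, fx$gold)
  ev <- token_level_eval(list(gold_labels), list(gold_labels))
  expect_equal(ev$per_label$MC_B$tp, 1)
})

test_that("token counts equal a brute-force position-by-position tally", {
  set.seed(87)
  labs <- c("MC_B", "MC_I", "O")
  for (r in 1:50) {
    shape <- sample(1:6, sample(1:4, 1), replace = TRUE)
    gold <- lapply(shape, function(n) sample(labs, n, TRUE))
    pred <- lapply(shape, function(n) sample(labs, n, TRUE))
    ev <- token_level_eval(gold, pred)
    g <- unlist(gold); p <- unlist(pred)
    for (L in c("MC_B", "MC_I")) {
      tp <- 0; fp <- 0; fn <- 0
      for (i in seq_along(g)) {
        if (p[i] == L && g[i] == L) tp <- tp + 1
        if (p[i] == L && g[i] != L) fp <- fp + 1
        if (g[i] == L && p[i] != L) fn <- fn + 1
      }
      expect_equal(ev$per_label[[L]]$tp, tp)
      expect_equal(ev$per_label[[L]]$fp, fp)
      expect_equal(ev$per_label[[L]]$fn, fn)
    }
  }
})

test_that("boundary criteria behave as specified for a truncated prediction", {
  # gold "generalized rash", prediction only "rash"
  gold <- span_annotations("d", 0L, 0L, 16L, "MC", "generalized rash")
  pred <- span_annotations("d", 0L, 12L, 16L, "MC", "rash")
  for (cr in c("partial", "right")) {
    ev <- span_level_eval(gold, pred, cr)
    expect_equal(ev$matched_pred, 1)
    expect_equal(ev$matched_gold, 1)
  }
  for (cr in c("exact", "left")) {
    ev <- span_level_eval(gold, pred, cr)
    expect_equal(ev$matched_pred, 0)
    expect_equal(ev$matched_gold, 0)
  }
})

test_that("perfect predictions score 1 under all criteria", {
  set.seed(6)
  gold <- random_spans(5)
  for (cr in c("exact", "left", "right", "partial")) {
    ev <- span_level_eval(gold, gold, cr)
    expect_equal(c(ev$precision, ev$recall, ev$f), c(1, 1, 1))
  }
})

test_that("one prediction can satisfy two overlapping gold mentions on the left", {
  fx <- worked_example_fixtures()$muscle
  pred <- fx$gold[1, ] # "muscle tenderness" only
  ev <- span_level_eval(fx$gold, pred, "left")
  expect_equal(ev$matched_gold, 2) # left match counted twice
  expect_equal(ev$recall, 1)
  ev_tok <- span_level_eval(fx$gold, pred, "exact")
  expect_equal(ev_tok$matched_gold, 1)
})

test_that("matched counts are monotone from exact to partial", {
  set.seed(14)
  for (r in 1:50) {
    gold <- random_spans(sample(1:6, 1))
    pred <- random_spans(sample(1:6, 1))
    ev <- lapply(setNames(nm = c("exact", "left", "right", "partial")),
                 function(cr) span_level_eval(gold, pred, cr))
    expect_lte(ev$exact$matched_pred, ev$left$matched_pred)
    expect_lte(ev$left$matched_pred, ev$partial$matched_pred)
    expect_lte(ev$exact$matched_pred, ev$right$matched_pred)
    expect_lte(ev$right$matched_pred, ev$partial$matched_pred)
    expect_lte(ev$exact$matched_gold, ev$left$matched_gold)
    expect_lte(ev$left$matched_gold, ev$partial$matched_gold)
    expect_lte(ev$exact$matched_gold, ev$right$matched_gold)
    expect_lte(ev$right$matched_gold, ev$partial$matched_gold)
    for (e in ev) {
      expect_true(e$precision >= 0 && e$precision <= 1)
      expect_true(e$recall >= 0 && e$recall <= 1)
      if (e$precision > 0 && e$recall > 0) {
        expect_lte(e$f, max(e$precision, e$recall) + 1e-12)
        expect_gte(e$f, min(e$precision, e$recall) - 1e-12)
      }
    }
  }
})

test_that("bonferroni_threshold divides alpha by the comparison count", {
  expect_equal(round_metric(bonferroni_threshold(0.05, 7)), 0.007)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(1.5, 2), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("crossval_report macro-averages P/R/F and keeps folds", {
  f1 <- prf(8, 2, 2)  # F = 0.8
  f2 <- prf(9, 1, 1)  # F = 0.9
  agg <- crossval_report(list(f1, f2))
  expect_equal(agg$f, mean(c(f1$f, f2$f)))
  expect_length(attr(agg, "folds"), 2)

  single <- crossval_report(list(f1))
  expect_equal(single$f, f1$f)

  set.seed(33)
  reports <- lapply(1:4, function(i) {
    gold <- random_spans(5); pred <- random_spans(5)
    span_eval_all(gold, pred)
  })
  agg <- crossval_report(reports)
  for (cr in c("exact", "left", "right", "partial")) {
    expect_equal(agg[[cr]]$precision,
                 mean(vapply(reports, function(r) r[[cr]]$precision,
                             numeric(1))))
    expect_equal(agg[[cr]]$f,
                 mean(vapply(reports, function(r) r[[cr]]$f, numeric(1))))
  }
  expect_error(crossval_report(list()), "at least one")
})

test_that("identical systems give randomization p exactly 1", {
  set.seed(2)
  gold <- do.call(rbind, lapply(sprintf("d%d", 1:6), function(d)
    random_spans(3, doc_id = d)))
  counts <- span_counts_by_doc(gold, gold, "exact")
  res <- ar_test(counts, counts, "f", reps = 199, seed = 4)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed_diff, 0)
})

test_that("sampled randomization p approximates exhaustive enumeration", {
  set.seed(44)
  docs <- sprintf("d%02d", 1:10)
  gold <- do.call(rbind, lapply(docs, function(d) random_spans(4, doc_id = d)))
  pred_a <- do.call(rbind, lapply(docs, function(d) {
    sp <- gold[gold$doc_id == d, ]
    sp[seq_len(min(3, nrow(sp))), ] # good system: keeps most gold spans
  }))
  pred_b <- do.call(rbind, lapply(docs, function(d) random_spans(4, doc_id = d)))
  ca <- span_counts_by_doc(gold, pred_a, "exact")
  cb <- span_counts_by_doc(gold, pred_b, "exact")
  exact <- ar_test(ca, cb, "f", exhaustive = TRUE)
  sampled <- ar_test(ca, cb, "f", reps = 9999, seed = 17)
  expect_lt(abs(sampled$p_value - exact$p_value), 0.02)
  expect_error(ar_test(ca, cb[1:5, ], "f"), "data error")
})
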