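# Token-level and span-level scoring, the approximate-randomization
# significance test, Bonferroni correction and cross-validation
# aggregation.
#
# Span-level matching is criterion satisfaction against ANY gold span (no
# one-to-one assignment): precision counts matched predictions, recall
# counts matched gold spans independently, which is what makes a single
# prediction starting at a shared token able to satisfy two overlapping
# gold mentions under the left criterion.

match_criteria <- c("exact", "left", "right", "partial")

#' Precision / recall / F from raw counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`, each 0 when its
#' denominator is 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Object of class `prf`: list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f`.
#' @export
prf <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("domain error: counts must be non-negative")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f = f_measure(p, r)),
            class = "prf")
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Reals in `[0, 1]`.
#' @return `2PR/(P+R)`, or 0 when `P + R = 0`.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' @export
print.prf <- function(x, digits = 3, ...) {
  cat(sprintf("P = %.*f  R = %.*f  F = %.*f  (tp %g, fp %g, fn %g)\n",
              digits, x$precision, digits, x$recall, digits, x$f,
              x$tp, x$fp, x$fn))
  invisible(x)
}

#' Token-level evaluation of BIO label sequences
#'
#' Position-by-position tallies for the two in-mention labels: for label L,
#' `tp` = positions where gold = pred = L, `fp` = pred L but gold not L,
#' `fn` = gold L but pred not L.  `Overall` is the micro-average over MC_B
#' and MC_I (O is excluded).  Gold labels should come from the collapsed
#' union encoding ([encode_bio()]), so a token starting two overlapping
#' mentions contributes a single MC_B.
#'
#' @param gold,pred Lists of BIO label vectors with identical shapes.
#' @return Object of class `token_eval`: list with `per_label` (MC_B,
#'   MC_I `prf`s) and `overall` (`prf`).
#' @export
token_level_eval <- function(gold, pred) {
  if (length(gold) != length(pred) ||
      !all(lengths(gold) == lengths(pred))) {
    stop("data error: gold and pred label shapes differ")
  }
  g <- unlist(gold, use.names = FALSE)
  p <- unlist(pred, use.names = FALSE)
  per <- lapply(c(MC_B = "MC_B", MC_I = "MC_I"), function(L) {
    prf(tp = sum(g == L & p == L),
        fp = sum(p == L & g != L),
        fn = sum(g == L & p != L))
  })
  overall <- prf(tp = per$MC_B$tp + per$MC_I$tp,
                 fp = per$MC_B$fp + per$MC_I$fp,
                 fn = per$MC_B$fn + per$MC_I$fn)
  structure(list(per_label = per, overall = overall), class = "token_eval")
}

#' @export
print.token_eval <- function(x, ...) {
  cat("token-level evaluation\n")
  cat("  MC_B   : "); print(x$per_label$MC_B)
  cat("  MC_I   : "); print(x$per_label$MC_I)
  cat("  Overall: "); print(x$overall)
  invisible(x)
}

span_satisfies <- function(ps, pe, gs, ge, criterion) {
  switch(criterion,
         exact = ps == gs & pe == ge,
         left = ps == gs,
         right = pe == ge,
         partial = ps < ge & gs < pe,
         stop("unknown criterion: ", criterion))
}

span_group_key <- function(spans) {
  paste(spans$doc_id, spans$section_index, sep = "\r")
}

#' Per-document span counts for randomization testing
#'
#' Matched/total prediction and gold counts per document under a span
#' criterion — the per-document statistics pooled by [ar_test()].
#'
#' @param gold,pred Annotation data frames.
#' @param criterion Span matching criterion.
#' @return Numeric matrix (documents x `matched_pred`, `n_pred`,
#'   `matched_gold`, `n_gold`) with document ids as rownames.
#' @export
span_counts_by_doc <- function(gold, pred, criterion) {
  docs <- sort(unique(c(gold$doc_id, pred$doc_id)))
  out <- matrix(0, nrow = length(docs), ncol = 4,
                dimnames = list(docs, c("matched_pred", "n_pred",
                                        "matched_gold", "n_gold")))
  for (d in docs) {
    gd <- gold[gold$doc_id == d, , drop = FALSE]
    pd <- pred[pred$doc_id == d, , drop = FALSE]
    mp <- 0L; mg <- if (nrow(gd)) logical(nrow(gd)) else logical(0)
    for (i in seq_len(nrow(pd))) {
      same <- gd$section_index == pd$section_index[i]
      hit <- same & span_satisfies(pd$char_start[i], pd$char_end[i],
                                   gd$char_start, gd$char_end, criterion)
      if (any(hit)) mp <- mp + 1L
      mg <- mg | hit
    }
    out[d, ] <- c(mp, nrow(pd), sum(mg), nrow(gd))
  }
  out
}

#' Span-level evaluation under a matching criterion
#'
#' A predicted span is matched if some gold span in the same document
#' section satisfies the criterion (`exact`: both boundaries equal;
#' `left`/`right`: that boundary equal; `partial`: the intervals
#' intersect).  Precision = matched predictions / predictions; recall is
#' counted on the gold side independently (gold spans satisfied by at
#' least one prediction / gold spans); F is their harmonic mean.
#'
#' @param gold,pred Annotation data frames (`doc_id`, `section_index`,
#'   `char_start`, `char_end`); gold may contain overlapping spans.
#' @param criterion One of `"exact"`, `"left"`, `"right"`, `"partial"`.
#' @return A `prf` with extra fields `matched_pred`, `n_pred`,
#'   `matched_gold`, `n_gold` and `criterion`.
#' @export
span_level_eval <- function(gold, pred,
                            criterion = c("exact", "left", "right",
                                          "partial")) {
  criterion <- match.arg(criterion)
  counts <- span_counts_by_doc(gold, pred, criterion)
  tot <- colSums(counts)
  res <- prf(tp = tot[["matched_pred"]],
             fp = tot[["n_pred"]] - tot[["matched_pred"]],
             fn = tot[["n_gold"]] - tot[["matched_gold"]])
  # recall must use the independently counted gold side
  res$recall <- if (tot[["n_gold"]] > 0) {
    tot[["matched_gold"]] / tot[["n_gold"]]
  } else 0
  res$f <- f_measure(res$precision, res$recall)
  res$matched_pred <- tot[["matched_pred"]]
  res$n_pred <- tot[["n_pred"]]
  res$matched_gold <- tot[["matched_gold"]]
  res$n_gold <- tot[["n_gold"]]
  res$criterion <- criterion
  res
}

#' Span-level evaluation under all four criteria
#'
#' @inheritParams span_level_eval
#' @return Named list of `prf`s (`exact`, `left`, `right`, `partial`),
#'   class `span_eval`.
#' @export
span_eval_all <- function(gold, pred) {
  structure(lapply(setNames(match_criteria, match_criteria),
                   function(cr) span_level_eval(gold, pred, cr)),
            class = "span_eval")
}

#' @export
print.span_eval <- function(x, ...) {
  cat("span-level evaluation\n")
  for (cr in names(x)) {
    cat(sprintf("  %-7s: ", cr)); print(x[[cr]])
  }
  invisible(x)
}

metric_from_counts <- function(sums, measure) {
  if (all(c("matched_pred", "n_pred", "matched_gold", "n_gold") %in%
          colnames(sums))) {
    p <- ifelse(sums[, "n_pred"] > 0,
                sums[, "matched_pred"] / sums[, "n_pred"], 0)
    r <- ifelse(sums[, "n_gold"] > 0,
                sums[, "matched_gold"] / sums[, "n_gold"], 0)
  } else if (all(c("tp", "fp", "fn") %in% colnames(sums))) {
    p <- ifelse(sums[, "tp"] + sums[, "fp"] > 0,
                sums[, "tp"] / (sums[, "tp"] + sums[, "fp"]), 0)
    r <- ifelse(sums[, "tp"] + sums[, "fn"] > 0,
                sums[, "tp"] / (sums[, "tp"] + sums[, "fn"]), 0)
  } else {
    stop("unrecognized count columns: ", paste(colnames(sums), collapse = ", "))
  }
  switch(measure, precision = p, recall = r, f = f_measure(p, r))
}

#' Per-document micro token counts (MC_B and MC_I pooled)
#'
#' @param gold_by_doc,pred_by_doc Named lists (by doc_id) of lists of BIO
#'   label vectors, e.g. from [gold_bio_by_doc()] / [pred_bio_by_doc()].
#' @return Numeric matrix (documents x `tp`, `fp`, `fn`).
#' @export
token_counts_by_doc <- function(gold_by_doc, pred_by_doc) {
  docs <- names(gold_by_doc)
  out <- matrix(0, nrow = length(docs), ncol = 3,
                dimnames = list(docs, c("tp", "fp", "fn")))
  for (d in docs) {
    ev <- token_level_eval(gold_by_doc[[d]], pred_by_doc[[d]])$overall
    out[d, ] <- c(ev$tp, ev$fp, ev$fn)
  }
  out
}

#' Approximate-randomization test between two systems
#'
#' Two-sided paired significance test on a metric difference, free of
#' distributional assumptions.  The stratification unit is the document:
#' each repetition independently swaps the two systems' outputs per
#' document with probability 1/2 and recomputes the pooled metric
#' difference; the p-value is `(count(diff >= observed) + 1)/(R + 1)`.
#' With `exhaustive = TRUE`, all `2^n` swap patterns are enumerated instead
#' and the p-value is the exact tail fraction (used as the small-corpus
#' oracle).
#'
#' @param counts_a,counts_b Per-document count matrices with identical
#'   rownames (document ids): either span counts
#'   (`matched_pred`/`n_pred`/`matched_gold`/`n_gold`, from
#'   [span_counts_by_doc()]) or token counts (`tp`/`fp`/`fn`).
#' @param measure `"precision"`, `"recall"` or `"f"`.
#' @param reps Number of randomization repetitions (default 9999).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param exhaustive Enumerate all swap patterns (requires few documents).
#' @return Object of class `ar_result`: list with `p_value`,
#'   `observed_diff`, `reps`, `seed`, `measure`.
#' @export
ar_test <- function(counts_a, counts_b, measure = c("f", "precision", "recall"),
                    reps = 9999L, seed = 1L, exhaustive = FALSE) {
  measure <- match.arg(measure)
  if (!identical(rownames(counts_a), rownames(counts_b))) {
    stop("data error: systems cover different document sets")
  }
  if (reps < 1) stop("reps must be >= 1")
  n <- nrow(counts_a)
  obs <- abs(metric_from_counts(rbind(colSums(counts_a)), measure) -
               metric_from_counts(rbind(colSums(counts_b)), measure))
  diff_for <- function(Z) {
    # Z: patterns x docs matrix of 0/1 (1 = swap this document)
    sums_a <- Z %*% counts_b + (1 - Z) %*% counts_a
    sums_b <- Z %*% counts_a + (1 - Z) %*% counts_b
    abs(metric_from_counts(sums_a, measure) -
          metric_from_counts(sums_b, measure))
  }
  if (exhaustive) {
    if (n > 20) stop("exhaustive enumeration limited to 20 documents")
    Z <- as.matrix(expand.grid(replicate(n, 0:1, simplify = FALSE),
                               KEEP.OUT.ATTRS = FALSE))
    colnames(Z) <- NULL
    diffs <- diff_for(Z)
    p <- mean(diffs >= obs - 1e-12)
    reps <- nrow(Z)
  } else {
    Z <- with_seed(seed, matrix(rbinom(reps * n, 1, 0.5), nrow = reps))
    diffs <- diff_for(Z)
    p <- (sum(diffs >= obs - 1e-12) + 1) / (reps + 1)
  }
  structure(list(p_value = p, observed_diff = unname(obs),
                 reps = as.integer(reps), seed = as.integer(seed),
                 measure = measure, exhaustive = exhaustive),
            class = "ar_result")
}

#' @export
print.ar_result <- function(x, ...) {
  cat(sprintf("approximate randomization (%s%s): observed diff = %.4f, p = %.4g (R = %d)\n",
              x$measure, if (x$exhaustive) ", exhaustive" else "",
              x$observed_diff, x$p_value, x$reps))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in `(0, 1)`.
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 7) # 0.00714..., i.e. 0.007 at 3 decimals
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

avg_prf_fields <- function(xs) {
  out <- xs[[1]]
  for (f in c("precision", "recall", "f")) {
    out[[f]] <- mean(vapply(xs, function(x) x[[f]], numeric(1)))
  }
  for (f in c("tp", "fp", "fn")) {
    if (!is.null(out[[f]])) {
      out[[f]] <- mean(vapply(xs, function(x) x[[f]], numeric(1)))
    }
  }
  out
}

#' Aggregate per-fold evaluation reports
#'
#' Arithmetic (macro) mean over folds of every precision, recall and F
#' field; the per-fold reports are retained in `$folds`.  Note the
#' fold-averaged F is stored as-is: it is not, in general, the harmonic
#' mean of the averaged P and R.
#'
#' @param fold_reports List of reports of identical shape: `prf`s,
#'   `span_eval`s or `token_eval`s.
#' @return Report of the same shape with averaged fields, plus `$folds`.
#' @export
crossval_report <- function(fold_reports) {
  if (length(fold_reports) == 0) stop("need at least one fold report")
  r1 <- fold_reports[[1]]
  shapes <- vapply(fold_reports, function(r) class(r)[1], character(1))
  if (length(unique(shapes)) != 1) stop("data error: fold report shapes differ")
  if (inherits(r1, "prf")) {
    out <- avg_prf_fields(fold_reports)
  } else if (inherits(r1, "span_eval")) {
    out <- structure(lapply(setNames(names(r1), names(r1)), function(cr) {
      avg_prf_fields(lapply(fold_reports, `[[`, cr))
    }), class = "span_eval")
  } else if (inherits(r1, "token_eval")) {
    out <- structure(list(
      per_label = lapply(setNames(c("MC_B", "MC_I"), c("MC_B", "MC_I")),
                         function(L) avg_prf_fields(
                           lapply(fold_reports, function(r) r$per_label[[L]]))),
      overall = avg_prf_fields(lapply(fold_reports, `[[`, "overall"))),
      class = "token_eval")
  } else {
    stop("data error: unsupported report type ", class(r1)[1])
  }
  attr(out, "folds") <- fold_reports
  out
}

#' Round metric values for reporting
#'
#' Three decimals, round-half-even (base R rounding).
#'
#' @param x Numeric.
#' @return Rounded numeric.
#' @export
round_metric <- function(x) round(x, 3)
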