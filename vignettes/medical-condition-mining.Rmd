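---
title: "Mining medical conditions from drug labels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining medical conditions from drug labels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mclabel)
```

## The task

FDA drug labels bury a wealth of safety knowledge in narrative prose: which
conditions a drug treats, when it must not be given, and which adverse
reactions it can cause. `mclabel` extracts *medical-condition mentions* —
diseases/disorders (DD) and signs/symptoms (SS), collapsed to a single MC
class for tagging — from the eight LOINC-coded label sections that carry
that content, and emits `[drug name]-[condition]-[section header]` triples
suitable for a drug-safety trigger database.

The pipeline is hybrid: a supervised sequence labeller provides
generalization to unseen surface forms, and a dictionary of training-set
gold surfaces repairs its two characteristic failure modes (boundary
truncation and missed known terms).

## The sequence model

Tagging is a first-order linear-chain conditional random field over BIO
labels $\{MC\_B, MC\_I, O\}$. For a sentence $x$ with $T$ tokens and label
path $y$,

$$ p(y \mid x) \propto \exp\Big( \sum_{t=1}^{T} \mathbf{w}^\top
   \mathbf{f}(x, t, y_t) + \sum_{t=2}^{T} v_{y_{t-1}, y_t} \Big), $$

with state weights $\mathbf{w}$ over sparse `name=value` feature strings
and a $3 \times 3$ transition matrix $v$. Training maximizes the
conditional log-likelihood penalized by $\frac{\lambda}{2}\lVert\theta\rVert^2$,
with exact gradients from forward–backward, optimized by L-BFGS from a
zero initialization (hence deterministic). Decoding is Viterbi with ties
broken toward the fixed label order $MC\_B < MC\_I < O$; a brute-force
$3^n$ path enumerator with the same tie-break ships as an independent test
oracle and the two are checked for agreement on a thousand random models
per test run.

Defaults: `l2_penalty = 1.0`, `max_iterations = 100`. These are ordinary
values for a sparse, indicator-featured chain CRF of this size; the
training objective is convex, so the choice affects shrinkage, not the
optimum's identity. The sequence unit is the *sentence*: sections can run
to thousands of tokens, sentence units are standard practice for NER, and
no cross-sentence label dependencies exist in this annotation scheme.

### Features

Per token: original, lowercased and Porter-stemmed forms; the previous and
next two tokens; the two adjacent token bigrams; POS tags and
initial-capital flags over the 5-token window; a digit/alpha/mixed
character-class flag; an all-caps flag; 2-character prefix and suffix;
token length; and, configurably, the CUI and/or TUI code of the current
token from a semantic lexicon. Out-of-window context positions emit an
explicit `<PAD>` sentinel so every token yields a fixed-width feature set.
`feature_config()` exposes the ablations: `"none"` (token + linguistic
only), `"tui"`, `"cui"`, `"both"`; `"tui"` is the default, being the
best-performing configuration of this family of systems.

The stemmer is the classic Porter (1980) algorithm, implemented in the
package (no stemming dependency exists in the target environment) and
verified against an independently written reference during development.
The POS provider is a shipped deterministic heuristic (closed-class
lexicon, then suffix rules, fallback `NN`); any tagger with the same
one-tag-per-token contract can be substituted via the `pos_tagger`
argument. This removes the heavyweight clinical-NLP dependency while
keeping the POS feature contract intact — with the caveat that heuristic
tags are noisier than a trained tagger's, which matters little here
because the token and semantic features carry most of the signal.

Multiword lexicon terms are projected onto each constituent token
(semantic lookup is greedy leftmost-longest over token n-grams,
case-insensitive), since term-to-concept linkage is naturally a span-level
statement applied to every token it covers.

## Dictionary post-processing and the maximum coverage rule

`build_term_dictionary()` collects the tokenized, lowercased gold surfaces
of the *training folds only*. At tagging time, `dictionary_match()`
performs greedy leftmost-longest matching: when several dictionary terms
match overlapping text ("nausea", "vomiting", "nausea and vomiting"),
only the longest span is labelled. This greedy reading of the maximum
coverage rule — rather than a global weighted-interval optimization —
satisfies the rule's span-local definition and its canonical coordination
example, and is linear-time.

`postprocess_merge()` combines CRF and dictionary output: a CRF span
strictly contained in a dictionary span is replaced by it (boundary
repair, e.g. CRF's "rash" inside "generalized rash"); a dictionary span
disjoint from all CRF spans is added (recall repair); on partial,
non-containment overlap the CRF span wins, because post-processing is
meant to add and repair, not to override the classifier wholesale. If a
replacing dictionary span would collide with another retained CRF span,
the replacement is abandoned — the merge output is always sorted and
non-overlapping, and never covers fewer characters than the CRF output.

## Annotation model

Spans are continuous, 0-based, half-open character intervals in section
text, token-aligned; section indices are 0-based. Overlapping gold spans
are accepted (two mentions may share a start token), discontinuous
mentions are not representable — a stated limitation of the BIO encoding,
affecting roughly five percent of real mentions. Encoding collapses
overlaps to a token-level union: a token beginning at least one span is
`MC_B` exactly once; that is what makes the token-level count of a shared
start token 1 while the span-level left-match gold count is 2. At decode
time an orphan `MC_I` (raw CRF output may emit one) leniently opens a new
span — the recall-maximizing repair, chosen because the convention is
otherwise arbitrary.

## Evaluation

Span-level matching is criterion satisfaction against *any* gold span in
the same section: exact (both boundaries), left, right (one boundary),
partial (intersection). Precision counts matched predictions over
predictions; recall counts, independently, gold spans satisfied by at
least one prediction — the two sides are not forced into a one-to-one
assignment, which is required for the shared-start-token counting above.
Token-level P/R/F is computed per BIO label with a micro-averaged Overall
over `MC_B` and `MC_I` (O excluded); micro is the natural reading of an
"overall" row lying between the per-label rows. Cross-validation reports
are macro averages over folds, and the fold-averaged F is stored as its
own field — it is not the harmonic mean of the averaged P and R, and the
report does not pretend otherwise.

Significance testing uses approximate randomization stratified by
document: each repetition swaps the two systems' per-document outputs with
probability one half and recomputes the pooled metric difference; the
two-sided p-value is $(c + 1)/(R + 1)$ with add-one smoothing, default
$R = 9999$. For identical systems the p-value is exactly 1. An exhaustive
$2^n$ enumeration mode serves as the small-corpus oracle, and a
same-error-process null simulation checks the rejection rate at
$\alpha = 0.05$ against binomial tolerance (the add-one smoothing makes
the test slightly conservative). Multiple comparisons use Bonferroni,
$\alpha/m$, e.g. $0.05/7 \approx 0.007$ for a seven-test family.
Reported metrics are rounded to three decimals, round-half-even.

## The synthetic corpus generator

Real annotated drug-label corpora are not redistributable, so
`generate_corpus()` produces a structurally faithful stand-in,
deterministic given one seed:

* **Sections**: OTC documents carry only the Warnings and Indications
  sections; Rx documents draw 4–8 of the eight whitelisted sections.
* **Vocabulary**: condition terms are pseudo-medical syllable compounds
  ("ostenoalgia"), with a configurable multiword fraction including
  adjective compounds and coordinated "X and Y" terms whose constituents
  are themselves terms — exercising the maximum coverage rule. Filler
  prose comes from a fixed non-medical vocabulary disjoint from the
  condition vocabulary, so negatives never collide with condition terms
  and baseline recall/precision are analytically predictable.
* **Mention placement**: at most one mention per sentence, never adjacent
  to another mention; with configurable probability a modifier
  ("generalized", "transient") directly precedes a mention and is excluded
  from the gold span, reproducing the left-boundary error mode.
* **Train/test surface overlap**: documents are assigned round-robin to
  folds with fold 0 held out; a test-fold mention draws, with probability
  `unseen_term_rate` (default 0.3, mirroring the roughly one-third unique
  surfaces of real corpora), a surface from a reserved pool that never
  occurs in training folds, and otherwise a surface realized in training.
  The dictionary baseline's exact-match recall therefore *equals* the
  realized seen-surface fraction by construction — a sharp acceptance
  property rather than a loose bound.
* **Semantic lexicon**: a configurable coverage fraction of condition
  terms receives CUI/TUI entries, with TUIs drawn from a distribution
  mixing the eleven qualifying condition types (0.55 total) with the
  noisy `T033` and non-condition `T170`; a small number of filler words
  (default 3) receive qualifying TUIs as ambiguous decoys. Both
  imperfections are deliberate: with a clean, complete lexicon the
  TUI-filter baseline would be perfect and the characteristic ordering
  *hybrid > dictionary baseline > TUI baseline* — the qualitative
  finding this family of systems exhibits on real data — could not be
  studied. The default rates were chosen once, as plausible
  terminology-noise levels, before any system comparison was run.

What passing tests on this corpus do **not** show: robustness to real
clinical prose (abbreviation-dense, typo-ridden, list-heavy), to realistic
term-frequency distributions, or to discontinuous mentions. The generator
demonstrates mechanism correctness and relative system behaviour, not
absolute real-world scores.

## Study problem sizes

The standard study corpus used by the acceptance tests and
`scripts/acceptance.R` is 40 documents (~900 mentions, ~10k training
tokens), 4 folds with fold 0 held out, semantic coverage 1.0 and unseen
rate 0.3; the CRF trains in about a minute at this size. Oracle-agreement
suites run a thousand random cases each; the randomization-test null
calibration uses 200 trials of 10 documents at $R = 499$. These sizes were
chosen to make every property measurable with comfortable statistical
margins while keeping a full test run interactive.

## Numerical and degenerate-input choices

* Offsets are counted over Unicode code points, 0-based, half-open.
* Whitespace runs collapse to single spaces during XML text extraction, so
  offsets are invariant to pretty-printing.
* P, R and F are defined as 0 when their denominators are 0.
* Empty documents, empty sections, empty dictionaries, empty label
  sequences and header-only standoff files are all valid inputs with empty
  outputs; errors are reserved for structural violations (missing drug
  name, spans crossing token boundaries, surface/offset mismatches,
  negative counts).
* Viterbi ties (measure-zero under trained weights, but reachable with
  all-zero weights) resolve to the lexicographically first optimal path
  under $MC\_B < MC\_I < O$, in both the decoder and the brute-force
  oracle.
* Model files are JSON with a format-version field and full-precision
  weights; save/load round-trips preserve predictions exactly.

## Known limitations

Discontinuous mentions ("muscle ... weakness") are out of scope by
design. The heuristic POS tagger is weaker than a trained one. The CRF
trainer is a dense-gradient L-BFGS implementation suited to the tens of
thousands of parameters arising at study scale, not an online trainer for
million-feature industrial corpora. Triple assembly deduplicates per
(condition, section) within a document; mention-level frequencies are
available from the span output instead.
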