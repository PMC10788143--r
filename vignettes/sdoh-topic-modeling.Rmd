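---
title: "Discovering social-determinant themes in clinical social work notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering social-determinant themes in clinical social work notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdohtopics)
```

## The problem

Clinical social work notes are among the richest free-text sources of
social determinants of health (SDoH): housing, family support, abuse
history, financial strain, risk of self-harm. Almost none of that
information reaches structured fields. `sdohtopics` implements an
unsupervised pipeline that surfaces these themes from a notes corpus and
quantifies how they vary across note types and disease groups:

1. **Note selection and cleaning.** Notes are flagged as social work
   notes when the substring "social" (case-insensitive) appears in the
   encounter type, department name, specialty, or provider type. Notes
   under 30 characters are dropped (strict inequality, measured on the
   raw text), then exact duplicate texts are removed keeping the first
   occurrence. Length runs before deduplication; both counts are
   reported so the order is auditable.
2. **Tokenization.** Text is lowercased; every non-alphabetic character
   is a separator; stopwords from a packaged static English list are
   removed. No vocabulary pruning by document frequency is applied.
3. **Topic inference.** Latent Dirichlet allocation fitted by batch
   mean-field variational Bayes (details below).
4. **Choosing the number of topics K.** A grid of candidate K is scored
   by topic coherence C (sliding-window NPMI with one-set segmentation
   and cosine confirmation) and by topic similarity S (mean pairwise
   Jaccard of top-10 word sets). Candidates are ranked by descending C
   (rank i) and ascending S (rank j); the K minimizing i + j wins, ties
   going to the smaller K.
5. **Automatic labeling.** Each fitted topic, rendered as its top-10
   words, is compared with a packaged dictionary of 11 SDoH labels by
   intersection over union; the argmax label is assigned only when at
   least 2 words overlap, ties broken lexicographically.
6. **Stratified analysis.** Replicate fits per stratum (note types, or
   ICD-10 disease chapters resolved from encounter codes) are pooled
   into label-proportion matrices, and a one-vs-rest chi-squared
   word-frequency comparison contrasts strata at the token level.

## The model and estimator

LDA assumes each document mixes a few topics: per document,
$\theta_d \sim \mathrm{Dir}(\alpha)$; per topic,
$\phi_k \sim \mathrm{Dir}(\eta)$; each token draws a topic
$z \sim \theta_d$ and a word $w \sim \phi_z$. `lda_vb()` maximizes the
evidence lower bound over the standard factorized variational family
with batch coordinate ascent: per-document Dirichlet parameters
$\gamma_d$ are iterated to convergence against fixed topic parameters
$\lambda_k$, which are then updated from the pooled sufficient
statistics. The bound is checked to be non-decreasing (a monotonicity
test runs in the suite). Batch updates share their fixed points with the
online stochastic variant used on very large corpora, but are fully
deterministic for a fixed seed, which desk-scale reproducibility needs.

Numerical and design choices:

* **Priors** default to symmetric $\alpha = \eta = 1/K$, the common
  library default; both are arguments.
* **Convergence**: relative ELBO change below `tol = 1e-4`, at most
  `max_iter = 200` outer iterations.
* **Initialization**: topic-word variational parameters start at
  i.i.d. Gamma(100, 100) values — small perturbations around uniform.
  Spiky Dirichlet($\eta$) starts were rejected because with
  $\eta = 1/K$ most coordinates underflow to zero in double precision
  and the digamma updates stall.
* **Restarts**: the variational objective is non-convex and a single
  start can settle on merged or split topics. `lda_vb()` therefore runs
  `n_starts = 3` independently seeded initializations (derived
  deterministically from `seed`) and returns the fit with the highest
  final ELBO. Restart selection by the bound, not by any downstream
  score, keeps the estimator honest.
* **Degenerate cases**: K = 1 reduces to the eta-smoothed corpus word
  distribution; exact weight ties in `top_words()` break
  lexicographically.

## Coherence, similarity, and picking K

Coherence uses boolean sliding windows: every window of
`window = 110` consecutive tokens (step 1; shorter documents form a
single window) is a virtual document; $P(w)$ and $P(w_i, w_j)$ are
window fractions. For top words $w_1 \ldots w_N$, each word's context
vector holds its NPMI against all N words (one-set segmentation), and
the score is the mean cosine between each vector and the sum vector.
The 110-token window is the convention of this coherence variant;
NPMI uses $\varepsilon = 10^{-12}$ inside the logarithms, a pair with
zero joint count scores $-1$, and a word with itself $+1$. Rank ties in
the K rule use competition ranking (ties share the best rank). Where a
convention was genuinely open — tie handling, and whether ranks are
assigned within one scan after averaging C and S over replicates or
mixed across replicate scans — this package fixes the former choice in
each case and tests it.

## The synthetic corpus generator

Access-restricted clinical text cannot ship with a package, so every
stage is exercised on corpora drawn from the generative model the
inference assumes, with planted structure:

* One planted topic per dictionary label concentrates 90% of its mass
  uniformly on that label's keywords, the rest Zipf-weighted over a
  deterministic ~500-word background vocabulary (Zipf weighting gives
  realistic frequency skew for the coherence windows).
* Each of the 14 categories (4 note types; 10 ICD-10 chapters
  represented by one 3-character code each) receives exactly
  `n_docs_per_category` documents — note-type documents carry no
  diagnosis code and chapter documents carry the minor type "Letter",
  so per-stratum counts stay exact and auditable. Note types beyond
  the 4 analyzed ones exist in real repositories; "Letter" plays that
  role here.
* Defaults: `alpha_true = 0.1` (notes dominated by one or two themes),
  Poisson document lengths with mean 60 tokens truncated below at 8
  (so a base document can never fall under the 30-character filter —
  short notes exist only as labeled contaminants), and a 6-fold
  Dirichlet boost of the "Group session" topic in Group Notes and of
  the telephone/online topic in Telephone encounters, mirroring the
  strongest category signatures of real social work notes.
* Contaminants are injected at 2% each per base document: sub-30-
  character notes, exact duplicates of existing notes, and notes whose
  metadata contain no "social". Ground truth records every injection so
  filter bookkeeping can be checked exactly.

What the generator does *not* emulate: grammar, negation, section
structure, spelling variation, or the long-tailed vocabulary of real
clinical text. Passing tests therefore demonstrate correctness of the
algorithms under the model's own assumptions, not performance on real
notes.

## Study conditions used by the test and acceptance runs

Problem sizes were chosen so a full run fits comfortably on a laptop
core: the 14-category bookkeeping run uses 200 documents per category
with K = 20 and 5 replicate fits (1400 topic clusters); topic-recovery
experiments use 5 planted topics with disjoint 20-word,
geometrically-weighted supports (decay 0.85, so top-10 rankings are
unambiguous), 1000 documents of mean length 100, fitted across 5 seeds;
the K grid for those corpora is 2–10 with a single replicate per
candidate, repeated over 5 seeded corpora. The full-corpus convention
of scanning K from 10 to 50 remains the default grid documented in
`run_config()` for real repositories.

## Worked example

```{r example, eval = FALSE}
library(sdohtopics)

cfg <- run_config(
  mode = "synthetic", k_override = 20, n_runs = 5, seed = 1,
  generator = corpus_config(n_docs_per_category = 200, seed = 1)
)
report <- run_pipeline(cfg)
report
#> Pipeline report
#>   notes loaded:       2968
#>   social work notes:  2912
#>   dropped short:      56
#>   dropped duplicate:  56
#>   analyzed:           2800
#>   strata fitted:      14
#>   topic clusters:     1400
#>   labeled clusters:   1396 (99.7%)

round(report$proportions["Group Note", "Group session"], 3)
#> [1] 0.23
```

## Interface choices

The pipeline is exposed as ordinary R functions around one fitted-model
class (`lda_vb`), rather than as a shell tool with subcommands: the
intended users are informaticians working in R, every stage is a
function they can call and inspect, and `run_pipeline()` plus
`scripts/acceptance.R` cover batch execution. Artifacts are plain text
(JSONL notes, MatrixMarket matrices, TSV cluster/proportion tables,
JSON reports).

## Known limitations

* The labeler only knows the 11 packaged labels; topics outside the
  dictionary (and topics whose top words overlap a label by fewer than
  2 words) stay unlabeled rather than being forced.
* Chapter strata rely on encounter-level ICD-10 codes; ICD-9 is not
  supported.
* Negation is not handled: a note discussing *absence* of suicidal
  ideation still contributes to the risk-of-death topic.
* The embedding-based dictionary expansion replaces interactive manual
  review with explicit allow/deny lists; expanded dictionaries should
  be reviewed before use on real data.
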