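---
title: "Predictability and word viewing times: models, transforms, and the GAM ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictability and word viewing times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexpred)
```

## The problem

When people read sentences, how long their eyes rest on a word depends not
only on the word itself (its length and frequency) but on how *predictable*
it is from its context. The classical way to quantify predictability is the
cloze completion probability (CCP): the proportion of participants in a
norming study who complete a truncated sentence with that word. Probabilistic
language models offer an algorithmic alternative — they state *how* a
prediction arises from prior linguistic experience. `lexpred` implements the
comparison of CCP against three such models as predictors of word viewing
times:

* an **interpolated Kneser–Ney smoothed trigram model**, capturing syntactic
  and short-range semantic structure through counts:
  $p(w_n \mid w_{n-2}, w_{n-1})$;
* a **latent Dirichlet allocation (LDA) topic model**, capturing long-range
  semantic structure through word–document co-occurrence, queried
  incrementally over the sentence prefix:
  $p(w_i \mid d) = \sum_{z} p(w_i \mid z)\, p(z \mid d)$, where the "document"
  $d$ is the sentence history up to *and including* $w_i$;
* a **simple recurrent (Elman) network**, trained to predict the next word
  from its hidden state, with the hidden layer copied to a context layer
  after every word.

Because the original eye-movement corpora and the hundred-million-token
subtitle training corpora are external data, the package ships a fully
synthetic study: generators with *planted, known structure* stand in for the
corpora, so every downstream stage can be tested quantitatively.

## Predictor construction

Cloze proportions are logit-transformed,

$$\mathrm{CCP} = 0.5\,\ln\frac{ccp}{1-ccp},$$

after replacing 0 and 1 by $1/(2K)$ and $1-1/(2K)$, where $K$ is the number
of complete cloze protocols ($K = 83$ in the reference norms, the package
default; `logit_ccp()` clamps rather than replaces only exact 0/1, which is
identical on exact inputs and numerically safer). The logarithm is natural;
any other base is an affine rescaling and irrelevant to rank-based or
GAM-based analysis. Language-model probabilities are $\log_{10}$-transformed
(`transform_lm()`).

`assemble_predictors()` aligns each predictor in three roles — present, last
(lag 1) and next (lead 1) word within the sentence — and flags exclusions:
the first and last word of every sentence (their last-/next-word
predictability is undefined) and words absent from the training vocabulary
(OOV). OOV words are invalid as targets for all four predictability sources
but still serve as context for their neighbours. On any input the target
count satisfies `total − 2·sentences − OOV(non-boundary)` exactly.

## Viewing-time measures

`compute_viewing_times()` derives, per participant × trial × word:

* **first pass** — the maximal run of consecutive fixations on a word
  starting at its first fixation, before any fixation on another word;
* **SFD** (single-fixation duration) — defined only when the first pass has
  exactly one fixation, in which case SFD = GD;
* **GD** (gaze duration) — the sum of first-pass durations;
* **TVT** (total viewing time) — the sum of all durations on the word in the
  trial, so TVT = GD + revisit durations exactly;
* **relative landing position** — first-fixation landing letter / word
  length, in (0, 1].

The cutoff policy applies a 70 ms floor to *individual fixations before
aggregation* (sub-70 ms fixations are dropped, not merged into neighbours —
merging conventions vary between laboratories and are out of scope) and
measure-level ceilings as inclusive exclusions: SFD ≥ 800 ms, GD ≥ 1200 ms,
TVT ≥ 1600 ms are removed from the respective measure's analysis set. A
value of exactly 800 ms is excluded; 799.9 ms is retained. Whether the floor
applies before or after aggregation is not fixed by convention;
before-aggregation is implemented and documented here. Skipped words yield
no record.

## The GAM comparison ladder

Fixation-event-level measures are analysed with generalized additive models:
gamma family with logarithmic link (viewing-time distributions are
right-skewed and positive; gamma response models are the standard choice in
eye-movement control modelling), penalized thin-plate regression-spline
smooths with basis dimension `k = 10`, and smoothing parameters selected by
GCV. The baseline model contains seven covariate smooths: relative landing
position plus the length and frequency class of the present, last and next
word. Frequency classes are Leipzig-style: the most frequent word is
$2^{class}$ times more frequent than the word in question, rounded to the
nearest integer (the $2^{class}$ definition leaves rounding open;
nearest-integer is symmetric) and clipped at 0.

`run_ladder()` then adds, per predictability source, the present-word term,
the last-word term and the next-word term in sequence, comparing each model
with its predecessor via `compare_gams()`: GCV, the change in adjusted
$R^2$ in percentage points, the deviance difference, the difference in
total effective degrees of freedom, and a $\chi^2$ test at $\alpha = 0.05$
(no multiple-testing correction, matching the analysis design the package
reproduces). The reported deviance difference is
`deviance(reduced) − deviance(extended)`, so positive values favour the
extended model; effective-df differences can be fractional or negative
because smoothing selection re-estimates every term's complexity in the
larger model.

### Why the test is not the raw deviance drop

The natural $\chi^2$ test — scaled deviance difference on the effective-df
difference — is anti-conservative when smoothness is selected from the data:
the added term's wiggliness is tuned on the same data the test then uses, a
point made repeatedly in the smoothing literature. In our null simulations
(gamma response, one real covariate, one pure-noise covariate) that
construction, and several variants of it (reference-df accounting,
shrinkage bases, ML-refit likelihood ratios), rejected clearly above the
nominal 5% level. `compare_gams()` therefore takes its p-value from the
smoothing-selection-corrected term statistics that mgcv computes for each
smooth (reference-df-scaled F; squared t for terms entered linearly),
aggregated over the terms the extended model adds. The package's test suite
verifies by simulation (200 null replicates) that this test's rejection
rate lies within [2%, 8%] at $\alpha = 0.05$, and that its power for a
planted log-link slope of −0.05 at n = 5000 events exceeds 95%. The
deviance and df differences remain in every ladder table as descriptive
statistics.

Two further numerical choices: covariates with fewer than 5 distinct values
(coarse frequency classes on small fixtures) enter as linear parametric
terms, since no spline basis is identifiable there; and each smooth's basis
is capped at one less than the number of distinct covariate values.

## The synthetic data generators

`generate_corpus()` emulates a topic-structured training corpus: the
vocabulary is split into disjoint per-topic blocks with Zipf-shaped
($p \propto 1/\mathrm{rank}$) within-topic unigram distributions; each
sentence draws a topic and then words from a
`markov_strength : (1 − markov_strength)` blend of a deterministic
within-topic successor chain and the topic unigram. Pseudo-word labels carry
varying lengths (2–9 letters) so the length covariate behaves like text.
The planted topic labels, vocabularies and successor map are exposed as
attributes, which is what makes topic-recovery and transition-learning tests
quantitative rather than impressionistic.

`generate_cloze_norms()` draws, per word, the number of protocols completed
with the target from the completion multinomial's target-vs-other margin,
i.e. Binomial($K$, target probability); downstream analysis only ever uses
the target's proportion. `generate_fixations()` draws every fixation
duration from a gamma distribution with fixed shape (default 25, giving a
realistic ~20% coefficient of variation) and mean
$\exp(\beta_0 + \sum_j \beta_j x_j)$ on the planted predictor columns —
deliberately the same family/link the GAM stage assumes, so
parameter-recovery tests are well-posed. Refixations and regressions are
independent Bernoulli events per word (the minimal process that makes SFD,
GD and TVT distinct); regressions are planted only on non-final words,
because a revisit appended immediately after the final word's first pass
would merge into it. Landing letters are uniform over the word's letters
(landing position is used only as a covariate).

What the generators do *not* emulate — word skipping, saccade-targeting and
oculomotor error, participant- and item-level random variation, and the
deep correlational structure of natural language — bounds what passing
tests show: they validate the *machinery* (model estimation, measure
extraction, exclusion arithmetic, test calibration), not claims about real
reading behaviour.

## Model implementation notes

**Kneser–Ney.** Interpolated (not backoff-only) smoothing with one discount
per order, $D_k = n_1/(n_1 + 2n_2)$ from that order's count-of-counts (raw
counts at the top order, continuation counts below); degenerate tables — no
singletons or no doubletons, where the formula leaves $[0,1)$ — fall back
to $D = 0.5$, and discounts are clipped to $[0, 0.999]$. Sentences are
padded with two begin tokens and one end token; the end token is a
first-class event, which is what makes $\sum_w p(w \mid h) = 1$ exact for
every history (verified to $10^{-8}$, and against an independently written
direct-recursion oracle to $10^{-10}$). Unknown *target* words raise an
error (they are excluded upstream); unknown history tokens simply back off.

**LDA.** Collapsed Gibbs sampling (Rcpp) over token-topic assignments;
$\hat\phi_{zw} = (n_{zw}+\beta)/(n_z+V\beta)$. Defaults
$N = 200, \alpha = 0.25, \beta = 0.001$ mirror common large-corpus practice;
fixtures use 2–10 topics. Inference on a new prefix document resamples with
the topic-word statistics frozen, averaging 5 theta samples taken every 2
sweeps after 50 burn-in sweeps (the reference implementation's schedule is
not recoverable; these defaults were chosen for stability and are
configurable). The prefix document *includes the current word*, exactly as
the incremental retrieval probability is defined; the mild circularity this
induces is intentional and documented, not corrected. All samplers use R's
RNG, so `set.seed()`-style reproducibility holds end to end.

**Elman RNN.** One-hot input, sigmoid hidden layer
$h_t = \sigma(W_{in}x_t + W_{rec}h_{t-1})$, exact full softmax output over
the vocabulary plus the end token (a hierarchical softmax is an
approximation device for web-scale vocabularies; desk-scale vocabularies
make exact normalization both feasible and testable). Training is per-token
cross-entropy gradient descent with copy-back recurrence only (gradients do
not flow through the copied context). The retrieval temperature
$\tau = 0.6$ divides the output logits at scoring time
($p_i \propto e^{z_i/\tau}$); $\tau = 1$ recovers the training softmax.
Output weights start at zero — the untrained model is exactly uniform — and
the hidden state resets to 0.5 (mid-sigmoid) at each sentence start. A
sigmoid output layer cannot yield normalized probabilities, so the softmax
output is adopted as the only reading consistent with probability
semantics.

## Problem sizes

The shipped tests and the acceptance script use: 500-sentence planted
corpora for topic recovery; 20–40-sentence corpora for the n-gram oracle
checks; 200 null replicates at n = 500 events for test calibration; 100
replicates at n = 5000 events for power and slope recovery; and an
end-to-end pipeline of 400 training sentences, 40 stimulus sentences and 12
simulated participants. These sizes were chosen as the smallest at which
the quantities of interest are stable.

## Worked example

```{r, eval = FALSE}
library(lexpred)

res <- run_pipeline(pipeline_config(seed = 5))
res$manifest
res$ladders[["gd:ngram"]]
round(res$correlations[c("ccp", "ngram", "topic", "rnn"),
                       c("mean_sfd", "mean_gd", "mean_tvt")], 2)

# smooth curves for plotting, all other covariates at their means
fit <- attr(res$ladders[["gd:ngram"]], "fits")[["+ present"]]
export_smooths(fit, "ngram")
autoplot(fit, terms = "ngram")
```

## Known limitations

* The GAM stage fits no participant or item random effects; the analysis is
  a fixed-effects event-level design by construction.
* The ladder's χ² decisions are uncorrected for multiple comparisons, by
  design fidelity.
* The topic model's incremental probability is circular in the current word
  (see above) — a property of the quantity being reproduced, not a bug.
* Synthetic cloze norms share no human response variability: their ccp is a
  binomial draw around a planted probability.
* The n-gram serialization stores top-order counts only; models with
  manually overridden lower-order tables cannot be represented (none are
  produced by the package).
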