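---
title: "Semantic scales for cued autobiographical memories: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic scales for cued autobiographical memories: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscale)
```

`memscale` quantifies the semantic content of verbally narrated
autobiographical memories and tests whether that content depends on the
sensory modality of the retrieval cue. This vignette is the package's own
account of the model, the tunable parameters and why their defaults are what
they are, the numerical decisions taken where the procedure left choices
open, what the synthetic-data generator does and does not emulate, and the
method's known limitations.

## The semantic space

The space is a classical LSA construction from 5-gram counts. Within each
5-gram, every *ordered* pair of positions (i, j), i ≠ j, contributes
`5 - |i - j|` times the record's count to the cell indexed by the row word at
i and the context word at j, so adjacency carries weight 4 and the widest
span weight 1. Three decisions here were genuinely open and are fixed as
follows:

* **Pairing rule.** All twenty ordered position pairs contribute, rather
  than designating one "target" slot. Symmetric accumulation is the standard
  LSA-style reading, uses each of the four printed weights, and makes the
  total cell mass of a record an exact, testable quantity (the unit tests
  check it against a brute-force pair enumerator).
* **Logarithm base.** Cells become `log(x + 1)` in natural log. The base
  rescales all cells by one constant, which cancels in cosines at full rank;
  `log1p` keeps empty cells at exactly zero.
* **Projection.** Word vectors are rows of *U S* (left singular vectors
  scaled by singular values) truncated to *k* dimensions, then unit
  normalized. *U S* preserves the row geometry of the normalized matrix —
  at full rank, projection cosines equal raw-row cosines to numerical
  precision, which the tests assert at 1e-6. Rows whose k-projection is
  numerically zero are dropped and reported, never normalized.

Dimensionality is selected by the synonym test: for each candidate *k* on
the doubling grid, each synonym pair's cosine is ranked within `n_random`
seeded random in-space word pairs (sampled with replacement, self-pairs
excluded), strictly-greater counting with ties worth one half — the unbiased
mid-rank. The score is the median percentile across pairs, low is good, and
ties between candidate dimensionalities resolve to the smaller *k* (the
cheaper space). Random-pair scores sit at chance (~50) by construction,
which the calibration tests verify; the tie rule and mid-rank are what make
the score exactly 50 in fully degenerate spaces.

## From narratives to scales

Tokenization lowercases, splits on whitespace and emits punctuation marks as
separate tokens so they can carry the `interpunction` word class. The study
data this design targets were transcribed speech; whether such transcripts
retain punctuation is corpus-dependent, so punctuation handling is
deliberately the tokenizer's only opinionated step. A participant's
representation is the unit-normalized sum of the word vectors of every
in-space token occurrence — token-level, not type-level: "each word weighted
equally" is read as *per occurrence*, the convention of the LSA literature.
Untagged tokens count in the all-words scope and in no class scope.
A participant with no in-space token in a scope (or an exactly cancelling
sum) has an *absent* representation, never a zero vector.

The semantic scale for a target condition codes that condition +1 and the
other three −1 and predicts the coding by ordinary least squares with an
intercept under leave-one-subject-out. Design decisions:

* **Dimension screening.** Per fold, dimensions are ranked by absolute
  Pearson correlation with the coding on the training fold — for a binary
  target this is univariate OLS fit quality — and the top ⌊n/2⌋ enter the
  regression, where n is the number of *predicted* data points (80 → 40).
  The count is pinned to predicted points, not the fold's n − 1 training
  points. Zero-variance dimensions score 0 and sink to the bottom; ties
  break by ascending index.
* **Intercept.** Included: with 20-vs-60 unbalanced groups the intercept
  absorbs the base rate of the coding.
* **Singular folds.** Solved by minimum-norm least squares via the SVD
  pseudo-inverse; deterministic and logged.
* **Per-class scales.** The same procedure runs within each word class with
  at least 4 represented participants (smaller classes are dropped with a
  warning); participants lacking a class representation enter the
  combination stage at 0, the scale's neutral point since predictions
  straddle zero. The combined scale regresses the coding on the per-class
  scale values with the same leave-one-out scheme and no dimension
  screening (at most 14 features, below n/2).
* **z-transform.** `z = ((x - mean) / sd) / sqrt(n - 1)`, applied literally.
  Dividing a standardized score by √(n−1) once more is unconventional; the
  plain standardized score is recoverable as `z * sqrt(n - 1)`, and all
  t-tests and effect sizes are invariant to the choice because the transform
  is a fixed affine map per scale.

Predictive validity is the Pearson correlation between the ±1 codings and
the held-out predictions with a one-sided test of r > 0. For a two-group
coding this is the point-biserial correlation, so it is *identical* to the
pooled one-sided two-sample t-test on the scale values — one test under two
names.

## Hypothesis tests

The differential test fills two 4 × 5 grids (rows are scales in the order
multimodal, visual, auditory, olfactory; columns are all-others plus the
four conditions) with one-sided pooled-variance t p-values and Cohen's d
(n−1-weighted pooled SD). Pooled variance rather than Welch is the classical
default for this design. No multiplicity correction is applied by default,
matching the analysis style the package reproduces; Holm is available behind
a flag. The grids are asymmetric by construction — each row is computed on a
different scale.

Dominance ranks the unimodal conditions by ascending |d| between each
unimodal scale's own condition and the multimodal condition: a smaller
standardized distance means that modality sits closer to — contributes more
to — the multimodal representation. Ties fall back to the fixed order
visual, auditory, olfactory.

The triangular test works per 2-D projection onto a pair of unimodal scales
(three pairs by default, all six behind a flag). The triangle's vertices are
the three unimodal condition means; the multimodal condition contributes its
mean and a confidence circle. Two open choices:

* **The circle.** A 95% confidence region for a 2-D mean drawn as a circle:
  radius `1.96 * sqrt((var_x + var_y) / 2) / sqrt(n)`, i.e. 1.96 times the
  root-mean-square of the two per-axis standard errors. This matches "a 95%
  confidence interval of the mean" under isotropy and yields a circle rather
  than an ellipse. A spread (data-cloud) interpretation would multiply the
  radius by √n; it is not the default because the test concerns the location
  of the mean.
* **Overlap.** "Substantial overlap" is not a quantity, so both available
  operationalizations are reported: whether the multimodal *mean* is inside
  the triangle (barycentric classification, boundary tolerance 1e-12,
  collinear triangles are an error), and the *fraction* of the confidence
  circle inside the triangle, estimated by seeded Monte Carlo (≥ 10⁴ uniform
  draws in the circle) and cross-checked against an exact segment–circle
  intersection test, which decides the binary overlap flag.

## The synthetic-data generator

The generator exists so that every stage — file parsing included — runs and
is tested end to end without external data. It emulates the study design it
targets: 80 participants, 20 per condition, 15 cues each, retrieval
succeeding at rate 798/1200 so roughly 800 narratives result; narrative
lengths are negative binomial (mean 40, dispersion 10, floor 5), in the
range of brief oral event descriptions. The corpus side plants a known
semantic structure: 120 words partitioned into 8 topics, 5-grams drawn
topic-pure up to a 5% cross-topic leak, Zipf-shaped within-topic word
probabilities, and two synonym pairs per topic whose members share an
emission probability — so synonyms have matching co-occurrence profiles and
the synonym test has a true optimum near the topic count.

Condition structure is a topic-mixture model: each unimodal condition tilts
the uniform topic mixture towards its signature topic by `effect_size`; the
multimodal condition is a convex combination of the three unimodal mixtures
(weights configurable) optionally blended with a reserved supra-additive
topic. This is the minimal structure under which the three hypotheses have
ground truth: mixture weights *are* the dominance ordering, and convex
versus supra-additive mixing *is* the triangle verdict.

The default `effect_size = 0.015` is calibrated with
`calibrate_effect_size()` so that the population standardized difference
between a unimodal condition and the pooled rest, projected on its signal
axis in the default space, is about 0.8 — an effect size of the order
modality-comparison studies report. Recovery demonstrations (dominance,
triangle) use a deliberately large 0.15, where condition separation is
near-certain and what is being tested is the geometry, not the power.

What the generator does **not** emulate: real word frequency tails (120
words versus 10⁵), syntax and discourse structure, condition-correlated
narrative length, per-participant vocabulary idiosyncrasies, transcription
noise, or any dependence of retrieval failure on condition (missingness is
ignorable by construction). Tests passing on this generator therefore
validate the *machinery* — weighting, decomposition, fold hygiene,
calibration, geometry — not the linguistic realism of any conclusion about
real narratives.

## Statistical behavior, verified and known limits

The package's validation protocol (the acceptance tests) measures, at the
default study shape:

* the synonym test sits at chance on random pairs and below 10 on planted
  ones;
* the scale-validity test holds its nominal 5% type-I error on null data
  (1000 replicates) — slightly liberal drift is possible at much larger
  space dimensionality, because leave-one-out predictions are
  cross-correlated;
* dominance ordering and the convex/supra-additive triangle verdict are
  recovered in well over 80–90% of replicates at large planted effects;
* the whole pipeline is byte-reproducible from its seeds.

One limitation deserves emphasis. Leave-one-out regression scales
*attenuate*: with n = 80 participants, k = 8 dimensions and a population
axis-level d of 0.8 (point-biserial R² ≈ 0.11, comparable to k/n), the
out-of-sample predictions carry a scale-level d of roughly 0.45–0.5, and the
one-sided contrast detects the difference in only ~55–65% of replicates —
far below the ~92% a direct test on the true signal axis would achieve. This
is not an implementation artifact (the same attenuation appears when ideal
Gaussian data are pushed through the procedure) but a property of
regression-based scales at moderate signal-to-dimension ratios: detected
effects are conservative estimates of representational differences, and
power planning for such designs should anticipate the attenuation rather
than use axis-level effect sizes. Second, the one-vs-rest construction makes
the four scales statistically interdependent — a strongly separable
condition inside another scale's "rest" group can slightly bias that scale's
one-sided all-others contrast upward (observed at ~8–10% rejection against a
nominal 5% under a visual-only signal). The asymmetric comparison grids make
this visible rather than hiding it; pairwise columns are the cleaner read
when one condition dominates.

Problem sizes throughout the tests and the acceptance script (120-word
corpus, 30k 5-grams, 80 participants, 200–1000 replicates) are the package's
validation choices: large enough for stable rates, small enough to rerun
routinely.
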