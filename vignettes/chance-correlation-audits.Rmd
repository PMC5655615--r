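---
title: "Chance-correlation audits for QSAR models"
author: "ChanceQSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance-correlation audits for QSAR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A typical QSAR study fits models for a handful of compounds (often 20
to a few dozen) drawn from a pool of hundreds or thousands of molecular
descriptors, usually with some form of variable selection.  Under those
conditions respectable-looking training statistics arise by selection
alone: if a search may pick the best 3 of 89 descriptors for 21
compounds, the best of roughly 113,000 candidate equations will fit
*something*, signal or not.  Ordinary goodness-of-fit measures, and even
internal cross-validation, cannot distinguish a real structure-activity
relationship from this selection artefact.

The affordable remedy is to measure what pure chance achieves in the
*same* modelling situation and demand that the real model beat it.
ChanceQSAR implements the three standard null constructions,

* **y-scrambling** - permute the activity vector across compounds,
  leaving the descriptor matrix intact;
* **x-scrambling** - permute each descriptor column independently,
  preserving every marginal distribution, leaving activities intact;
* **pseudo-descriptors** - replace descriptor columns with draws from a
  chosen distribution family fitted to each column,

together with the model engines, validation statistics and the audit
harness needed to act on them.

## The audit procedure

`runChanceTest()` generates `nSets` randomized copies of the table
(`generateSets()`), applies the *identical* modelling pipeline to each
copy that is applied to the real data - descriptor-pool reduction, then
the engine's search - and records each copy's best training $r^2$
together with that model's cross-validated $q^2$.  The collection is
summarized as the mean highest score with its sample standard deviation
(n-1 denominator, since the sets are a sample of the null), and
thresholds

$$\text{mh} + k \cdot \text{SD}, \qquad k \in \{1,\ 2.3,\ 3\},$$

where $+2.3\,$SD is the conventional normal-theory stand-in for the
99th percentile.  `compareToChance()` applies the strict inequality
$r^2_{\text{real}} > \text{mh} + k\,\text{SD}$ and also reports the
empirical percentile of the real statistic among the null scores, which
makes no normality assumption; both are always available because the
per-set scores are kept in the returned `ChanceSummary`.

Defaults follow the usual scale of such experiments: 300 randomized
sets for regression audits, 25 for the (much costlier) classification
trees.

### Which q2 is "the" q2 of a set

When a search returns several models per set, the per-set statistic
pair is ambiguous: the best model's $q^2$, or the set's best $q^2$?
The default records the $q^2$ of the model with the highest $r^2$;
`collect = "max-q2"` switches to the per-set maximum.  The choice
matters little in practice but is exposed rather than hidden.

## Randomization details

* All randomness flows through R's Mersenne-Twister 19937 generator.
  Randomized set $i$ of a plan is produced from a stream seeded with
  `masterSeed + i`, and engine randomness (pool-reduction tie-breaks,
  the GA) for set $i$ from `masterSeed + 500000 + i`.  A whole audit is
  therefore a pure function of (input bytes, configuration, master
  seed), and replicate sets come from disjoint streams.
* Permutations use an explicit Fisher-Yates shuffle.  Identity
  permutations are *not* rejected: rejection would bias the null, and
  at $n \ge 6$ their probability is negligible.  Every set permutes the
  original column; permutations are never chained.
* Each target column is permuted independently.  With several activity
  columns, y-scrambling permutes them independently rather than
  jointly, matching the single-response use the audit is meant for.
* Distribution families for pseudo-descriptors are parameterized by
  moment fits to the original column: uniform(min, max); normal(mean,
  sample SD); Poisson(rate = mean); exponential(rate = 1/mean);
  binomial(trials = round(max), prob = mean/trials clamped to [0, 1]).
  The binomial rule is one defensible reading of an unparameterized
  family and is stated here prominently; numerical agreement with any
  other tool's parameterization is not a goal.  Family `"original"`
  means "keep the column's own values", i.e. x-scrambling.

## Model engines

The engines are deliberately plain stand-ins for the commercial tools
used in practice; the audit logic does not depend on which engine is
plugged in.

* **Subset-search MLR** (`mlrEngine`): enumerates every descriptor
  subset of size at most `maxVars` (default 3, the common "equation of
  up to three variables") and scores it by OLS training $r^2$ computed
  from the centred Gram matrix in compiled code.  Exhaustive
  enumeration is the oracle - nothing can score higher on the same
  pool - and is refused above 200,000 subsets, where the genetic
  search takes over: population 100, 200 generations, tournament
  selection of size 3, uniform crossover on descriptor index sets,
  swap mutation with probability 0.1, elitism 5.  These defaults are
  ordinary GA folklore, not a reproduction of any specific commercial
  implementation (whose internals - spline terms, lack-of-fit scoring -
  are out of scope), so identity with published model lists from such
  tools is not attainable and not claimed.
* **Fixed-subset OLS** (`fixedEngine`): no search at all.  Under a
  permutation null this engine has a closed-form calibration,
  $E[r^2] = k/(n-1)$ for $k$ predictors, which the test suite and the
  acceptance script verify at $n = 21$, $k = 3$ ($E[r^2] = 0.15$).
* **Classification tree** (`treeEngine`): greedy CART-style growth
  under Gini impurity with a depth cap (default 3).  Candidate
  thresholds are midpoints of consecutive sorted unique values; ties
  break to the lowest feature index, then the lowest threshold, so the
  fit is deterministic.  A row routes left when value <= threshold.
  This is hand-written rather than delegated to rpart because the
  audit needs exactly these tie-break and routing semantics (rpart
  serves as an independent cross-check in the tests).

Descriptor-pool reduction precedes every fit: constant and
near-constant columns are dropped (near-constant: the most frequent
value occupies more than 95% of rows, or variance below 1e-12 - the
usual practice names the step but not a rule, so one is fixed here),
then while any pair of surviving descriptors has $|r| > 0.90$ one
member of the offending pair is removed at random.  The surviving pool
provably contains no pair above the threshold, which is asserted by
brute-force scan in the tests.

## Validation statistics

* $r^2 = 1 - \mathrm{SS}_{\text{res}}/\mathrm{SS}_{\text{tot}}$.  A
  constant response gives $\mathrm{SS}_{\text{tot}} = 0$; the package
  defines $r^2 = 0$ with a warning in that case so that a degenerate
  scramble records a score instead of aborting an audit, keeping
  exactly `nSets` entries.
* $q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}_{\text{tot}}$ with the
  full-training-set mean in the denominator (the common PRESS
  convention).  Leave-one-out uses the exact hat-matrix identity
  $e_{(i)} = e_i/(1-h_{ii})$; the tests pin it to a literal
  refit-per-point oracle at 1e-12.  Leave-$m$-out enumerates all
  $\binom{n}{m}$ folds (1,330 at $n = 21$, $m = 3$) and averages each
  point's squared errors over the folds containing it before summing -
  exhaustive enumeration rather than random partitions, so the value
  is deterministic.
* Regression through the origin: $k = \sum y\hat y / \sum \hat y^2$,
  $R_0^2 = 1 - \sum(y - k\hat y)^2/\mathrm{SS}_{\text{tot}}$; the
  Golbraikh-Tropsha acceptability battery applies $q^2 > 0.5$,
  $R^2 > 0.6$, $(R^2 - R_0^2)/R^2 < 0.1$ and $0.85 \le k \le 1.15$
  with strict inequalities where written.
* $^cR_p^2 = \sqrt{r^2}\sqrt{r^2 - R_r^2}$, with $R_r^2$ the mean
  $r^2$ of the randomized models, passed explicitly (published tables
  are consistent with using the pseudo-descriptor uniform mean, but the
  function never guesses).  When $R_r^2 > r^2$ the value is NaN with a
  warning.
* $r_m^2 = R^2(1 - \sqrt{R^2 - R_0^2})$, in the single-orientation
  (observed vs predicted) form; the later averaged/delta variants are
  out of scope.  Note a small algebraic caveat: $r_m^2$ is *not*
  monotone in $R^2$ at fixed $R_0^2$ (its derivative is negative for
  small gaps), though it is monotone increasing in $R_0^2$ at fixed
  $R^2$; the property tests assert the true monotonicities.
* Randomization intercepts: each permuted refit contributes a point
  $(|\mathrm{cor}(y, y_{\pi})|, r^2_{\pi})$ (and likewise for $q^2$);
  an OLS line through these points plus the unpermuted anchor $(1,
  \text{true statistic})$ is extrapolated to zero correlation.
  Intercepts below 0.4 ($R^2_{\text{int}}$) and 0.05
  ($Q^2_{\text{int}}$) support a valid model.  The classical recipe is
  ambiguous about the anchor and the sign of the correlation; this
  implementation uses the absolute correlation and includes the anchor,
  and says so rather than leaving it implicit.
* Classification metrics are computed from confusion counts:
  ACC, PREC, SENS, SPEC, FALL = 1 - SPEC, and
  F1 = 2TP/(2TP+FP+FN).  Zero-denominator metrics are NaN, never 0.
  Computing F1 from counts can disagree in the second decimal with
  tables assembled by applying 2·PREC·SENS/(PREC+SENS) to
  already-rounded PREC and SENS cells (e.g. degenerate predict-all
  baselines where the count form gives 0.05 and the rounded-ratio form
  0.06, or 0.00 where the ratio form is NaN); the count form is the
  definition and is what this package reports.

## Reports and file handling

CSV I/O is strict RFC-4180-style: comma separator, mandatory header,
`.` decimal point, no locale handling; floats are written in the
shortest representation that parses back bit-identically, so
write-then-read is lossless.  SD files (V2000) are treated as opaque
byte sequences structured by `M  END`, `>  <FIELD>` and `$$$$`
markers: molblocks are never interpreted (no chemistry perception, no
V3000), records keep their own line terminators (CRLF dialects
survive), non-numeric data items pass through verbatim, and writing an
unmodified table reproduces the input file byte for byte.  Only the
value lines of fields that were actually randomized are rewritten.  A
record lacking a requested activity field is a hard error naming the
record - silently dropping data seemed the wrong default - with an
explicit `skipMissing` opt-in that drops and warns.  Blank molblock
titles get synthesized ids `rec<k>` so identifiers stay unique and
stable.

Reported tables round to 3 decimals (regression) or 2 (classification)
for display; everything is stored at full precision.

## What the synthetic generators do and do not emulate

`makeRegressionFixture()` draws standard-normal descriptors (optionally
with equicorrelated blocks, default within-block $r = 0.95$, chosen to
exercise the 0.90 intercorrelation filter) and builds the activity as a
linear signal plus Gaussian noise, recording the implied population
$R^2$ in the metadata.  `makeClassificationFixture()` draws two
Gaussian clouds with a configurable mean shift, at a default imbalance
of 100 actives to 3,600 decoys (1:36, a realistic virtual-screening
proportion).  `makeToySdf()` emits minimal one-carbon V2000 records.

These fixtures reproduce the *shapes* that make chance correlation
dangerous - few compounds, many descriptors, intercorrelation,
class imbalance - but not the marginal distributions, heavy tails or
block structure of real computed descriptor sets.  Passing audits on
fixtures therefore demonstrates the correctness and calibration of the
machinery (null means, threshold arithmetic, detection of a known
planted signal), not the behaviour of any particular descriptor
package on real molecules.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run, among others: the fixed
3-predictor null calibration over 2,000 scrambled sets at $n = 21$;
genetic-vs-exhaustive agreement over 100 (suite) / 50 (script) seeded
pools of 12 descriptors; pure-noise selection-effect curves for pools
of 10, 49 and 89 descriptors (200 / 50 replicates); and full-harness
verdict rates over 100 / 50 audits of 300 sets each with a planted
population $R^2 \approx 0.9$ and with no signal.  These sizes give
standard errors comfortably inside the asserted bounds while keeping a
complete run in a few minutes on one core.

## Known limitations

* No applicability-domain filtering of test compounds: the practice
  exists but has no single accepted definition, and none is invented
  here.
* No ROC/AUC or probability calibration for trees; only the six
  threshold metrics.
* Pseudo-descriptor columns are sampled independently; correlated
  pseudo-descriptor generation and stratified/block permutations are
  out of scope.
* The GA is a stand-in for evolutionary model selection generally, not
  a reimplementation of any proprietary tool.
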