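---
title: "Sparse CCA for brain-behavior association: models, reliability, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse CCA for brain-behavior association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincca)
```

## The analysis problem

The package links two participant-aligned data blocks: a behavioral block
(eight social-optimism-bias measures computed from a likelihood-rating
task plus sixteen questionnaire scale scores, 24 variables in its default
layout) and an imaging block of mean cortical thickness in 62 regions of
the Desikan-Killiany-Tourville (DKT) parcellation. The scientific
question is whether latent dimensions ("modes") of the behavioral block
covary with latent dimensions of regional thickness, which variables
carry each mode, and whether the modes survive permutation testing and
resampling-based reliability checks at a typical neuroimaging sample size
(a few dozen participants against 86 variables).

## Task scoring

Participants rate, on a 0-100 visual-analog scale, how likely each of 32
events (16 desirable, 16 undesirable) is to happen to each of four
fictional characters: a student (in-group), an elderly person, a
businessperson, and an alcoholic person. Cleaning applies two rules:

* **Anchor/default responders.** A rating is flagged when it rounds to
  1, 50 or 99 — the scale's extremes and its default position, where a
  non-answer is indistinguishable from a genuine "fifty-fifty". The
  three flag values are pooled into one per-participant proportion (over
  answered trials), and participants whose proportion exceeds the sample
  mean + 3 SD are excluded. A configuration switch applies three
  separate rules instead; the pooled rule is the default because the
  exclusion is one procedure, not three.
* **Missing trials** are dropped, with the dropped fraction reported.

The eight task measures per participant: raw-scale mean likelihoods for
desirable and undesirable events; four per-character optimism biases
computed on ratings z-standardized within participant (all answered
trials, both valences, sample SD) as mean desirable-z minus mean
undesirable-z; the warmth bias (student + elderly − businessperson −
alcoholic biases); and the overall bias magnitude (student + elderly +
businessperson − alcoholic — the alcoholic bias is typically a
*pessimism* bias, so it enters inverted). Z-standardization makes the
bias measures invariant to each participant's scale usage (shift and
positive rescaling), which is the point of the construction; the two raw
averages deliberately keep the original percentage scale. Whether those
two averages should instead enter later analysis z-scaled is not
determined by the construction; the raw scale is the default here.

## The sparse CCA model

Let $X_1$ ($n \times p_1$) and $X_2$ ($n \times p_2$) be the
column-standardized blocks. Each mode solves

$$\max_{u, v}\; u^\top X_1^\top X_2 v
  \quad \text{s.t.}\quad \|u\|_2 \le 1,\; \|v\|_2 \le 1,\;
  \|u\|_1 \le c_1,\; \|v\|_1 \le c_2,$$

the penalized matrix decomposition (PMD) of the cross-product matrix.
The L1 bounds ($1 \le c_j \le \sqrt{p_j}$) drive some weights to exactly
zero, which is what makes the analysis feasible with more variables than
participants and what licenses statements about individual variables.
The solver alternates soft-thresholded power iterations; the
soft-threshold level is found exactly on each step by solving the
piecewise quadratic for the L1 budget along the threshold path (a
bisection fallback covers degenerate tie cases). After each mode the
working matrix is deflated by the fitted rank-1 term
$d_k u_k v_k^\top$, so later modes ignore structure already explained.

Numerical conventions:

* **Initialization**: the leading right singular vector of the working
  matrix, projected into the feasible set so the objective is monotone
  from the first iteration. The fit is deterministic given the data and
  penalties; a seed argument exists only for degenerate ties.
* **Convergence**: maximum absolute weight change below `tol` (default
  1e-6), capped at `max_iter` (default 500) with a warning and a flag.
  A secondary plateau criterion (relative objective change below 1e-12)
  accepts solutions that oscillate between equivalent tied supports,
  which happens on exactly collinear (noise-free) inputs.
* **Signs**: each mode is flipped jointly so the largest-|weight| entry
  of $u$ is positive. A joint flip leaves the canonical correlation's
  natural sign intact; mode 1's is non-negative because the objective is
  maximized over both sign choices.
* **Tied maxima**: when the L1 budget is below $\sqrt{m}$ for $m$ tied
  maximal entries, the soft-threshold path cannot split the tie and the
  limit solution (all weight on one entry, deterministic tie-break) is
  returned.

### Within-block covariance: diagonal vs full

The default decomposes the raw cross-product, i.e. treats within-block
covariance as approximately diagonal. This is the standard sparse-CCA
formulation: it stays well-posed when $p > n$ and when variables within
a block are strongly correlated. Its loose-penalty limit is the leading
singular pair of the cross-covariance — *not* classical CCA.
`cov_structure = "full"` whitens each block by its within-block
covariance before the decomposition and maps the weights back; in the
loose-penalty limit this reproduces the classical first canonical
correlation exactly (verified in the test suite against an independent
generalized-eigenvalue oracle to 1e-6), at the price of requiring
$n > p_1 + p_2$. With an active L1 penalty under whitening the sparsity
acts in the whitened basis, so the default for sparse analyses remains
`"diagonal"`.

### Variance explained and mode truncation

The share of mode $k$ is $d_k^2 / \sum_j d_j^2$ over the computed modes,
where $d_j$ are the singular values of the successively deflated
matrices. This definition makes shares sum to 1, tends to shrink with
mode index, and reproduces the practice of truncating permutation and
reliability testing at the leading modes that cumulatively explain more
than 99%. An alternative redundancy-based definition would weight modes
by within-block variance; the deflation-based one is used because it is
what the deflation sequence actually measures.

### Penalties

The paper-scale penalty values are not recoverable, so the package
treats them as explicit inputs. When unspecified, `fit_scca` uses
$c_j = 1 + 0.35(\sqrt{p_j} - 1)$, a moderate point on the feasible
range. `select_penalties()` scores a small grid by mean out-of-sample
variate correlation over random half-splits, with either the maximum
("best") or the sparsest model within one standard error of it ("1se",
the default — the same convention glmnet uses for its regularization
path). A practical caveat, measured during development and worth
stating: the out-of-sample correlation is a *flat* function of the
penalties once the true support is captured, so CV distinguishes
penalty settings weakly at these problem sizes. Simulation studies in
this package therefore fix penalties on the scale of the planted
support (e.g. $c_1 = 1.5$ for a 3-variable support) rather than
pretending the tuning is sharp.

## Permutation inference

Significance of mode $k$'s canonical correlation is assessed by
shuffling the rows of block 2 relative to block 1 (participant
relabeling — the standard CCA null, which preserves each block's
internal covariance), refitting the full model with the same penalties,
and comparing the observed mode-$k$ correlation with its permuted
counterparts. P-values use the add-one estimator
$(1 + \#\{r^{perm} \ge r^{obs}\})/(1 + B)$, bounded below by $1/(B+1)$.
Penalties are *not* re-tuned inside the permutation loop: the test
addresses the association, not the tuning. Mode-wise comparison is the
default; a maxT variant (max over tested modes per permutation) gives
family-wise control, since no multiplicity correction is otherwise
applied. The replication-scale default is $B = 10\,000$; the package's
own simulations use $B$ in the hundreds, which resolves $p$ to ~0.005.

## Reliability battery

All resampling is driven by one seeded generator and is bit-reproducible.
Because CCA modes permute and flip freely across refits, every resampled
model is matched to the full-sample reference by greedy maximal
|cosine| of the concatenated weight vectors, then sign-aligned; the
matching permutation is recorded.

* **Leave-one-out influence**: refit without each participant; influence
  is the change in each mode's canonical correlation. Flags mark
  influences more than 3 SD from the mean influence. On clean data this
  screen still fires on a few per cent of participants (the influence
  distribution is mildly skewed and n tests are performed), so the
  reading is comparative: an outlier-*driven* mode shows a flag with an
  influence an order of magnitude above the rest, as the test suite's
  adversarial construction demonstrates.
* **Split-half weight transfer**: the sample is split in half repeatedly
  (training takes the larger half for odd n; the held-out half is
  standardized with the *training* moments, keeping the projection
  genuinely out-of-sample); training weights are applied to the held-out
  half and the held-out variate correlation per mode is recorded. The
  overfitting index is the mean training-minus-test gap. Degenerate
  splits (constant training column) are redrawn and counted.
* **RR-score**: for each resample and mode, every variable of both
  blocks is correlated with its block's held-out variate, and this test
  loading vector is correlated (absolute value) with the full-sample
  loading vector. The paper-scale description of this score is verbal;
  this formula is the package's operationalization and its main
  interpretive choice. Note the score has a weight-driven baseline well
  above zero — loadings of the variables that *build* a variate are high
  for any data — so RR-scores discriminate between modes (stable vs
  unstable) rather than against an absolute zero.
* **Sample-size check**: the split-half overfitting index as a function
  of subsample size. The index shrinks with n for a fixed signal; a
  study is judged to show only "marginal" overfitting when the mode-1
  index at the full n is below a configurable threshold (default 0.1 in
  correlation units).

## Post hoc reporting

For selected behavioral measures, partial Pearson correlations with all
62 regions control for height, weight, BMI, age and sex: both sides are
residualized on the covariates plus intercept and the residuals
correlated, with $p$ from the $t$ distribution on $n - 2 - q$ degrees of
freedom and an uncorrected threshold of 0.001. BMI is exactly collinear
with height and weight by construction; the residualizer switches to a
pseudoinverse with a warning rather than failing, because the covariate
list is part of the analysis contract. A variable fully explained by the
covariates is assigned a partial correlation of exactly 0 instead of
numerical noise. Weight tables report, per mode, variables with
|weight| above 0.2 in descending magnitude (the threshold is on the
absolute value because negative contributors are reported alongside
positive ones), with the full table always emitted.

## The synthetic-data generator

`generate_blocks()` draws, per planted mode, a standard-normal latent
factor pair with configurable correlation, adds rank-1 signal
$a_k z_k u_k^\top$ to each block, then independent Gaussian noise.
Thickness columns are affinely mapped to a plausible cortical scale
(means ~2.0-3.3 mm, SD 0.12 mm) — strictly monotone per column, so
standardization recovers the planted structure exactly. The defaults
mirror the target study shape: 47 participants, 24 behavioral variables,
62 DKT regions, one planted sparse mode with latent correlation 0.7 and
graded loadings (3 of 24 and 4 of 62 nonzero; graded rather than equal
because exactly equal loadings sit on an L1/L2 knife edge that penalizes
any budget below $\sqrt{k}$ into dropping a true variable — a property
of that special case, not of real effects). `generate_task_responses()`
emulates the rating task (128 trials per participant, character/valence
means ordered so group-level biases are similarly positive for student
and elderly, smaller for the businessperson, negative for the alcoholic;
~1% missing trials; optional all-50 responders to exercise cleaning).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: spatially correlated thickness noise
(regions are conditionally independent given the planted factors),
non-Gaussian behavioral distributions, item-level questionnaire
structure, and any coupling between the task's rating noise and the
questionnaire block. In the full-pipeline preset the planted behavioral
loadings are placed on questionnaire variables, because the eight task
measures are recomputed from raw ratings by the scoring stage and an
exact planted loading cannot be routed through that nonlinear path.

## Problem sizes used in the package's own studies

The replication-scale defaults ($B = 10\,000$ permutations and
resamples) are what `pipeline_config()` carries. The package's test
suite and acceptance studies use scaled-down designs chosen to keep the
Monte Carlo error well inside the margins they assert: 100 recovery
replicates at $n = 500$; 500 null studies at $B = 199$ for the type-I
rate (99% binomial band ±0.025 around 0.05); batches of 100-200
split-half resamples; pipeline runs at $B = 200$.

## Known limitations

* Penalty tuning by cross-validated variate correlation is weakly
  identified (flat objective); treat tuned penalties as a starting
  point, not an inference.
* The RR-score baseline is positive by construction (see above).
* With `cov_structure = "full"`, sparsity lives in the whitened basis;
  weights mapped back to variables are not exactly sparse.
* The deflation scheme does not enforce orthogonality of successive
  variates; shares can fluctuate modestly across neighboring modes.
* The 3-SD leave-one-out screen is a screen, not a test; its
  false-positive rate over n participants is a few per cent on clean
  data.
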