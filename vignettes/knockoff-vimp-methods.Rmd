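---
title: "Knockoff variable importance for random forests: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockoff variable importance for random forests: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package answers

A random forest predicting a binary health outcome from a correlated
feature panel is easy to fit and hard to interpret. The default
out-of-bag (OOB) permutation importance answers only "was this feature
used by *this* forest?", and because tree construction is randomized, a
feature that is merely correlated with a true risk factor gets split on —
and therefore looks important — without carrying any unique information.
Knockoff importance instead answers the conditional question: *how much
does predictive performance drop when the feature (or a named group of
features) is replaced by a statistically equivalent copy that carries no
outcome signal?*

# Second-order Gaussian knockoffs

For a feature matrix $X \in \mathbb{R}^{n\times p}$ with mean $\mu$ and
covariance $\Sigma$, a knockoff matrix $\tilde X$ is sampled so that the
joint second moments are

$$\mathrm{Cov}\big([X, \tilde X]\big) \;=\; G \;=\;
\begin{pmatrix} \Sigma & \Sigma - \mathrm{diag}(s)\\
\Sigma - \mathrm{diag}(s) & \Sigma \end{pmatrix},$$

sampled row-wise from the Gaussian conditional
$\tilde x_i \mid x_i \sim \mathcal N\!\big(\mu + (x_i-\mu)\,\Sigma^{-1}(\Sigma - \mathrm{diag}(s)),\;
2\,\mathrm{diag}(s) - \mathrm{diag}(s)\,\Sigma^{-1}\mathrm{diag}(s)\big).$

Assumptions worth stating plainly:

* **Gaussian approximation.** Only the first two joint moments are
  matched. Binary or ordinal columns get continuous knockoffs (no
  rounding); this mirrors how the construction is used in practice on
  mixed epidemiological panels and is adequate for forests, which only
  consume feature orderings and interactions.
* **Exchangeability is approximate.** With an estimated $\Sigma$ the
  swap-invariance of $G$ holds up to estimation error; the test suite
  verifies it empirically at Monte-Carlo tolerance (max-abs 0.05 at
  $n = 20{,}000$).
* **Knockoff nullity is exact by construction**: the outcome never enters
  the generator, so $\tilde X_j$ has no association with $y$ beyond what
  the other features explain.

## The decorrelation vector s

Power comes from decoupling knockoffs from their originals: larger $s_j$
means $\mathrm{corr}(X_j, \tilde X_j)$ smaller, bounded by $G \succeq 0$.
Two rules are provided:

* `solve_s_equi()` (default): on the correlation scale every coordinate
  gets $\min(2\lambda_{\min}(R), 1)$, then the vector is rescaled by
  $\mathrm{diag}(\Sigma)$. Closed form, dependency-free, and the
  documented default of the canonical second-order construction.
* `solve_s_sdp()`: maximizes $\sum_j s_j$ subject to
  $0 \le s_j \le 1$, $\mathrm{diag}(s) \preceq 2R$. With no semidefinite
  solver as a dependency, the program is solved by cyclic coordinate
  ascent with exact steps — for coordinate $j$ the largest feasible
  increase is $1/(M^{-1})_{jj}$ where $M = 2R - \mathrm{diag}(s)$, a Schur
  complement identity. Started at the (always feasible) equicorrelated
  point, the objective is monotone, so the result never falls below the
  default rule; for symmetric $2\times 2$ problems it reproduces the known
  optimum. A coordinate-wise maximal point is not guaranteed to be the
  global SDP optimum; the gap is irrelevant for the package's use.

## Numerical choices

* **Covariance shrinkage**: $(1-\gamma)\hat S + \gamma\,
  \mathrm{diag}(\hat S)$ with the analytic (Schafer–Strimmer) intensity
  for the off-diagonal entries as starting value, escalated geometrically
  until $\lambda_{\min}$ of the correlation matrix exceeds $10^{-8}$.
  Keeps the sampler well-posed when $p$ approaches $n$.
* **PSD tolerance**: eigenvalues of the conditional covariance down to
  $-10^{-10}$ (relative) are accepted and clipped to zero before the
  factorization; if $G$ fails the check, $s$ is backed off by factors of
  0.999. The degenerate limit $s = 0$ reproduces $\tilde X = X$ exactly.
* **Constant columns** are rejected by name (a zero-variance feature has
  no meaningful knockoff), as are non-positive-definite correlation
  specifications, with the offending block identified.

# The two importance measures

## Knockoff VIMP (dual forests)

One knockoff matrix is drawn for the *full* sample before the train/test
split, so train and test rows use the same draw — the swapped feature is
identically distributed in both. Then, per feature group $g$:

1. RF1 is trained on the true features of the training rows (regression
   forest on the 0/1 outcome — a probability machine).
2. RF2 is trained on the same rows with *all* columns of $g$ replaced by
   their knockoffs; identical hyperparameters, independent tree seed
   (tying the seeds would understate between-forest Monte-Carlo noise).
3. Both are scored on the held-out rows — RF1 on true features, RF2 with
   $g$ knocked off — at a probability threshold $t$, and the importance is
   the drop in sensitivity, specificity and accuracy.

The aggregate differences equal the mean of per-participant indicator
deltas over the relevant class (the per-participant deltas are retained on
the result), and the accuracy VIMP decomposes exactly as
$\pi\,\mathrm{VIMP}_{Sens} + (1-\pi)\,\mathrm{VIMP}_{Spec}$ with $\pi$ the
test prevalence — asserted to $10^{-12}$ in the tests. Where the
per-participant average for the class-specific VIMPs could be read as
either class-restricted or whole-sample, the class-restricted reading (i.e.
the metric difference itself) is adopted, since a sensitivity difference
*is* the positive-class mean of the deltas.

RF1 is trained once per study and reused across all groups; each group's
RF2 seed derives deterministically from the base seed and the group name,
so studies are reproducible as a whole and per group. Per-group failures
are recorded in an `error` column without aborting the remaining groups.

## OOB permutation VIMP

Two estimators are implemented because the literature uses both:

* `method = "substitution"` is the per-participant sub-forest algorithm
  stated in textbook form: for participant $i$, predict with only the
  trees whose bootstrap sample excluded $i$, score the accuracy indicator,
  substitute the feature's value with a random draw from the other
  participants (independently per participant, per repeat — drawn
  *with* replacement across participants), re-score, and average
  $P_i - P_i^*$ over contributing participants and `n_repeats` draws.
  Participants whose sub-forest is empty are skipped and counted, never
  imputed. This estimator is verified *exactly* against a brute-force
  walker that enumerates every (participant, tree, substitution) triple.
* `method = "permutation"` is the synchronized variant that standard
  software reports: one global permutation of the column per repeat,
  scored as the mean over trees of the drop in that tree's OOB accuracy.
  Averaging over (tree, participant) pairs instead of participant-level
  majority votes makes it far less noisy, and it is the estimator behind
  published OOB rankings — the package's demonstration of correlation
  inflation uses it, and the test suite cross-checks it against ranger's
  own `importance = "permutation"` on the same forest.

The accuracy indicator thresholds at 0.5 (majority vote in classification
mode) — deliberately so, because that implicit 0.5 operating point on a
rare outcome is one of the documented weaknesses of OOB importance that
the knockoff analysis, run at a tuned threshold, avoids.

# Tuning and threshold selection

`tune_forest()` scans the Cartesian grid
$\mathrm{mtry} = \max(1, \lfloor x\,p\rfloor)$,
$\mathrm{min.node.size} = \max(1, \mathrm{round}(N^{y}))$ for
$x, y \in (0,1]$ (default $0.1, 0.2, \ldots, 1$), scoring pooled
cross-validated RMSE of the held-out regression scores against the 0/1
outcome. Pooling over folds (rather than averaging per-fold RMSEs) is
invariant to fold-size imbalance. Ties break toward smaller `mtry`, then
smaller node size. $N$ defaults to the full sample size (the scale on
which such grids are quoted); a switch selects the per-fold training size.
The rounding rules (floor for `mtry`, round for node size, both floored at
1) are stated here once and used everywhere.

`youden_threshold()` scans candidate thresholds — midpoints between
consecutive sorted unique scores, plus 0 and 1, which together hit every
distinct classification of the sample under the `score >= t` rule — and
returns the smallest maximizer of $J = \text{sens} + \text{spec} - 1$
(ties within $10^{-12}$ are treated as exact, so floating-point noise
cannot override the tie-break; the smallest maximizer keeps sensitivity
maximal, the conservative choice for screening). The cross-validated
version reports per-fold thresholds with mean and sample SD; on rare
outcomes the mean lands far below 0.5, which is why the knockoff analysis
defaults to `threshold = "auto"` (the CV mean) rather than 0.5. An
explicit numeric threshold can be supplied to reproduce any published
operating point.

# The synthetic-data generator

The generator is first-class, tested code; it emulates the features of the
real study setting that the methods actually interact with:

* **Correlated continuous features**: block-exchangeable and AR(1)
  correlation blocks, including pairs above 0.7 — the regime in which OOB
  inflation appears. Draws are i.i.d. multivariate Gaussian via a
  Cholesky factor; identical seeds give bitwise-identical matrices.
* **Rare binary outcomes**: logistic link with the intercept root-solved
  so the expected prevalence over the realized sample matches the target
  (the defining equation is satisfied to $10^{-10}$; the empirical rather
  than population expectation is used, since the generator conditions on
  the drawn features). The canonical emulation prevalence is 0.027; fast
  test scenarios use 0.2–0.5, because stable sensitivity estimates at
  0.027 need sample sizes that have no place in a unit test.
* **Causal structure**: `make_bias_scenario()` builds the canonical
  contrast — X1 ⊥ X2 causal with chosen log-odds, X3 correlated with X2
  at a chosen $\rho$ but with generating coefficient exactly zero
  (assertable from the stored metadata), plus independent noise features —
  and `make_domain_scenario()` builds a two-level nested domain hierarchy
  with effects confined to named domains.
* **Seed discipline**: one base seed spawns per-stage substreams (feature
  draw, outcome draw, per-feature substitution streams, per-group forest
  seeds) through a string-hash derivation, so stages can be re-run
  independently and every pipeline output is byte-reproducible.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: non-Gaussian marginals (no copulas),
missingness and imputation, mixed measurement scales, and outcome models
beyond the logistic link. The demonstrations here show the *mechanisms*
(inflation under correlation, knockoff null calibration), not performance
on any particular cohort.

# Problem sizes and expected behavior

The test suite exercises the full pipeline at deliberately modest sizes,
chosen once as a balance between statistical resolution and a test run of
a few minutes: moment-fidelity checks at $n = 20{,}000$–$50{,}000$; the
inflation contrast at $n = 3{,}000$, $\rho = 0.9$, unit log-odds effects,
20 re-simulated replicates, 200-tree forests with default
$\mathrm{mtry} = \lfloor\sqrt p\rfloor$; null calibration at $n = 2{,}000$,
$p = 10$, 30 replicates. Two behaviors found while developing at these
sizes are worth recording:

* **Near-bagging abolishes inflation.** With $p = 8$, RMSE tuning selects
  `mtry` near $p$, and with almost every feature available at every split
  the forest has no reason to use the correlated null — the inflation
  mechanism needs randomized feature availability (small `mtry` relative
  to $p$, which is exactly the regime of a tuned high-dimensional panel,
  e.g. 15 of 157). The demonstration therefore uses the standard
  $\lfloor\sqrt p\rfloor$ default.
* **Estimator noise matters.** The participant-level substitution
  estimator is exact (oracle-verified) but noisy, because a sub-forest
  majority vote rarely flips; the synchronized-permutation estimator
  detects the same inflation with far less variance, which is why it is
  the one standard software reports and the one used for the headline
  contrast.
* **Simultaneous null intervals fail singly at the expected rate.** Twenty
  simultaneous 95% intervals on a perfectly calibrated null will miss zero
  about once; calibration claims should be read at the family level (the
  grand-mean checks), not feature by feature.

# Known limitations

Knockoff VIMPs cost two forests per group — organized domain hierarchies
keep the count manageable, and replicate mode (`knockoff_vimp_replicates`)
quantifies the split/forest/draw noise rather than hiding it. Correlated
causal features can dampen each other's singleton VIMPs (either can stand
in for the other); testing their union group is the recommended reading,
and the suite demonstrates the effect. Generating knockoffs once for the
full sample before splitting follows the canonical protocol but lets the
test rows inform the covariance estimate; with the sizes used here the
effect is negligible, and the choice is surfaced rather than silently
changed.
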