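---
title: "Sparse PLS outcome signatures under nested cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse PLS outcome signatures under nested cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

splscv implements two-block sparse partial least squares (SPLS) for
clinical signature discovery. Given a predictor block $X$ (n
participants by p mixed clinical features, each tagged with the
treatment phase in which it was measured) and an outcome block $Y$ (n by
q outcome measures), one latent variable (LV) is a pair of weight
vectors $(u, v)$ maximizing the cross-block covariance

$$\max_{u, v} \; u^\top X^\top Y v
  \quad \text{s.t.} \quad \|u\|_2 = \|v\|_2 = 1,\;
  \|u\|_1 \le c_u,\; \|v\|_1 \le c_v,$$

with $c_u \in [1, \sqrt p]$ and $c_v \in [1, \sqrt q]$ the l1 budgets
controlling sparsity ($c = 1$ forces a single nonzero weight, $c =
\sqrt{\dim}$ imposes none). Projecting each block onto its weights gives
per-participant latent scores $\xi = Xu$ and $\omega = Yv$; their
Pearson correlation $r$ — estimated on held-out data — measures the
association the LV captures, and $R^2 = r^2$ its share of shared
variance. The model is linear in the (z-scored) features; it assumes the
predictor-outcome association is expressible as a low-rank linear
cross-covariance, not that individual features are Gaussian.

The optimizer is the standard alternating scheme for penalized
rank-one matrix decomposition: iterate
$u \leftarrow P_{c_u}(M v)$, $v \leftarrow P_{c_v}(M^\top u)$ on
$M = X^\top Y$, where $P_c$ soft-thresholds and rescales to the unit
l2 sphere, with the threshold found by bisection so the l1 norm meets
the budget. Iteration starts from the leading right singular vector of
$M$ (deterministic — the core fit has no seed sensitivity) and stops
when the summed l2 change of the weights falls below $10^{-6}$ (cap
1000 iterations; non-convergence is flagged, not fatal). Without active
l1 constraints the fixed point is the leading singular pair of $M$.
Signs are fixed by flipping $(u, v)$ jointly so the largest-magnitude
outcome weight is positive, which makes favorable outcomes carry
positive weights in reports.

## Inference: nested cross-validation, permutations, deflation

All preprocessing is fitted strictly inside training partitions.
Features are z-transformed with the training fold's means and sample
SDs (denominator $n-1$); binary and ordinal features are z-scored
identically to continuous ones so weight magnitudes are comparable
across mixed types. Columns constant within a training fold are zeroed,
not dropped, keeping weight dimensions constant across folds. An
optional generic covariate residualization (least squares with
intercept, training-fitted) is available but off by default.

The nested loop follows the usual design: `outer_folds` (default 10)
estimate generalization; within each outer-training set,
`inner_folds` (default 10) select $(c_u, c_v)$ from a grid (default
5 × 5, log-spaced over the feasible ranges) by maximizing the mean
held-out latent-score correlation, with ties broken toward the sparser
pair. The refit on the full outer-training set is projected onto the
held-out fold; the mean held-out $r$ across outer folds is the LV
statistic and its square the reported $R^2$. Folds are stratified on
the three-level outcome grouping (continuously abstinent /
abstinent-at-follow-up only / not abstinent) so every fold sees all
outcome patterns.

Significance is assessed by permutation: rows of $Y$ are permuted
jointly — preserving the outcome block's internal structure while
destroying the cross-block association — and the outer-CV statistic is
recomputed under the observed fold structure and per-fold
hyperparameters (default 5000 permutations), giving
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$. Reusing folds and
per-fold budgets keeps the null directly comparable to the observed
statistic and the cost linear in $B$. While an LV is significant at
`alpha` (default 0.05) its component is removed from both blocks by
projection deflation, $X' = X(I - uu^\top)$, $Y' = Y(I - vv^\top)$, and
extraction continues on the deflated blocks; it stops at the first
non-significant LV.

Two design choices here were genuinely open:

* **Deflation space.** The weight vectors live in z-scored coordinates,
  so deflation is applied to globally z-scored copies of the blocks.
  Because in-fold standardization is invariant to per-column affine
  rescaling, this global scaling leaves every cross-validated statistic
  for the first LV unchanged; it only makes the deflation between
  successive LVs coherent. Deflating the raw-scale matrices instead
  leaves a rescaled echo of the removed component that the next round
  of in-fold z-scoring resurrects, and the pipeline then reports
  spurious extra LVs.
* **Consensus weights.** Each outer fold produces its own $(u, v)$; a
  single reported pair is needed for deflation and reporting. The
  per-fold pairs are sign-aligned (Procrustes, which for single vectors
  reduces to a sign choice), restricted to the majority support —
  features nonzero in at least half the folds, in the spirit of
  stability selection; plain averaging would smear mass over the union
  of fold supports — averaged element-wise, and re-projected onto the
  l1/l2 constraint at the consensus budget (the pair selected most
  often across folds, ties toward sparser). The consensus therefore
  satisfies the same feasible set as any single fit.

Weight stability is quantified by bootstrap ratios: the pair is refit
on `n_bootstraps` (default 500) row resamples (standardization refit
within each resample), each refit is sign-aligned to the reference
weights so symmetric sign flips do not cancel, and each feature's ratio
is the mean over aligned refits divided by their SD. Features with zero
bootstrap SD and zero mean get ratio 0. One master seed drives
independent child streams for folds, permutations and bootstraps, so
changing, say, the bootstrap count does not move the folds.

## The synthetic cohort generator

No clinical data ship with the package; `simulate_cohort()` generates
cohorts with the structure the analysis assumes, at the scale of the
motivating study design: n = 152 participants, 35 predictors split
17/12/6 across pre-/within-/post-treatment phases, and four outcomes
(two binary abstinence indicators, daily alcohol consumption in g/day,
abstinent days over a 180-day follow-up window).

The generative model draws latent factors $t_r \sim N(0,
\text{signal\_sd}^2)$ and sets each continuous feature to $\sum_r t_r
u_{rj} + N(0, \text{noise\_sd}^2)$ with unit-norm planted loadings; the
default plants one component on a six-feature support spanning all
three phases — sparse enough that an l1-constrained fit can identify
it. Binary features (default fractions roughly matching a clinical
covariate panel: 0.70/0.58/0.80 per phase) are thresholded at the
empirical quantile of a target prevalence (default 0.35); one pre-phase
feature is quartile-binned to an education-like 1–4 ordinal scale.
Within each phase continuous features come first, so the default
planted support carries exactly linear signal while thresholded
features carry attenuated, monotone signal.

Outcomes are built from a single abstinence propensity (the mean of the
two binary-outcome latent columns), thresholded at empirical order
statistics calibrated to the default group sizes 70/49/33. That makes
the deterministic couplings hold row-wise by construction: continuous
abstinence implies abstinence at follow-up; abstinent rows have zero
daily consumption (zero-inflation); continuously abstinent rows sit at
the 180-day cap of abstinent days, others at a censored linear
transform of their latent column (floor 0, cap 179, location/scale
defaults 60/50 days); non-abstinent consumption is a truncated linear
transform with location 92.2 and scale 88 g/day. With `raw_outcomes =
TRUE` the observation model is bypassed and the latent linear outcome
columns are emitted — the configuration under which linear-theory
recovery statements (e.g. convergence of the singular vectors of
$X^\top Y$ to the planted loadings) hold exactly. Under the default
couplings the outcome-side loadings are attenuated column-by-column by
the thresholding and censoring, so only the predictor-side loadings are
recoverable to high precision.

What the generator does **not** emulate: realistic marginal
distributions of each individual clinical variable, correlations among
predictors beyond the planted signature (noise is independent), or
longitudinal drinking trajectories. Passing tests therefore demonstrate
the statistical machinery is sound — calibrated type-I error,
power/recovery under a planted linear signature, no train/test leakage
— not that any particular clinical dataset satisfies the model.

## Numerical choices and degenerate inputs

* Bisection for the l1 projection: the exported `l1l2_project()`
  targets $|\,\|s\|_1 - c\,| \le 10^{-6}$; the internal fitting path
  uses $10^{-10}$, without which the alternating objective shows
  $\sim 10^{-5}$ non-monotonic wiggles.
* All-zero weight vectors (over-aggressive thresholding) are returned
  flagged rather than normalized; a fold whose held-out scores have
  zero variance contributes $r = 0$ with a warning; if every grid pair
  degenerates, the sparsest pair is returned with a warning.
* The Kruskal-Wallis test is tie-corrected (mid-ranks, correction
  $C = 1 - \sum(t^3 - t)/(N^3 - N)$) with the asymptotic chi-square
  p-value; the all-tied case is defined as $H = 0$, $p = 1$. The
  chi-square test is uncorrected Pearson, under which a deterministic
  binary mapping yields exactly $\chi^2 = N$. FDR correction is
  step-up Benjamini-Hochberg over the whole emitted descriptive table.
* Missing cells are rejected at load time (complete-case analysis);
  binary columns must be pre-encoded 0/1.
* Stratified folds give each label a per-fold count within 1 of
  proportionality and overall fold sizes as equal as possible;
  requesting more folds than the smallest class carries members only
  relaxes proportionality with a warning.

## Problem sizes in the test suite

The statistical property tests run at reduced but sufficient sizes
chosen for a laptop-class single core: type-I error calibration uses
200 null cohorts (n = 60) with 99 permutations each against the
acceptance band 1–10% at nominal 5%; planted-signature recovery uses 20
replicates at n = 300, signal/noise = 2, 199 permutations, 5 outer / 5
inner folds, asserting a median of exactly one significant LV and
median support Jaccard at least 0.5. Package defaults (10 × 10 folds,
5000 permutations, 500 bootstraps) reflect the full analysis design and
are what a real analysis should use.

## Known limitations

* Deflation uses the consensus weights, an estimate; its error leaves a
  small residual of the removed component that can surface as a weak
  extra LV at very high signal-to-noise ratios and sample sizes.
* Permutation reuses the observed per-fold hyperparameters rather than
  re-running the inner selection per permutation; this is the standard
  cost compromise and keeps the null conditional on the selected model
  complexity.
* The hyperparameter criterion is the held-out score correlation alone;
  no comparison against a non-sparse PLS baseline is performed.
* p-values are exchangeability-based under joint row permutation of the
  outcome block; they do not account for selection across multiple
  separately fitted models (the pipeline fits one model).
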