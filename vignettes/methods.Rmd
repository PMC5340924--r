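---
title: "Methods: GRM calibration and post-hoc CAT simulation for short ordinal questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GRM calibration and post-hoc CAT simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`catgrm` implements a five-stage psychometric evaluation pipeline for short
symptom questionnaires with three ordered response categories (0/1/2), of
the kind used to screen for psychosocial problems in primary care: four
scales (distress, depression, anxiety, somatization) of 16/6/12/16 items.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The measurement model

Each scale is treated as unidimensional: a latent trait $\theta$ (assumed
standard normal in the population) drives all of its items. Items follow
Samejima's graded response model (GRM). For a three-category item with
discrimination $\alpha > 0$ and ordered thresholds $\beta_1 < \beta_2$,
the boundary curves are

$$P^*_k(\theta) = \frac{1}{1 + e^{-\alpha(\theta - \beta_k)}}, \qquad k = 1, 2,$$

and the category probabilities are the adjacent differences
$P_0 = 1 - P^*_1$, $P_1 = P^*_1 - P^*_2$, $P_2 = P^*_2$. The thresholds
are the trait levels where a boundary probability is one half; the
discrimination is the steepness of those curves.

**Metric.** Slopes are logistic, without the 1.7 normal-ogive scaling
constant. Published discriminations such as 7.377 are treated as logistic
slopes. Calibrations with probit-metric software will differ by roughly
that factor; within this package everything (simulation, calibration,
information, CAT) is consistent on the logistic metric.

## Stage 1: descriptives

Raw five-option frequency responses ("no" … "very often or constantly",
coded 0–4) are collapsed to 0/1/2 by the scoring rule $\{2,3,4\} \to 2$;
already-coded data are detected (maximum code $\le 2$) and left alone.
Persons with any missing item are excluded (complete-case analysis; the
exclusion list and retention percentage are always reported). Scale totals
are plain sums, so a 16-item scale ranges over 0–32. Internal consistency
is Cronbach's $\alpha = \frac{k}{k-1}\left(1 - \sum_i s_i^2 / s_T^2\right)$
with $n-1$ variances, plus alpha-if-item-deleted. The standard error of a
mean total is $s_T/\sqrt{n}$ (also with the $n-1$ SD; at $n \approx 400$
the $n$ vs $n-1$ choice changes nothing at the reported precision).

## Stage 2: IRT assumptions

**Unidimensionality.** A one-factor model is fitted to the scale's
polychoric correlation matrix. Polychorics are two-step maximum
likelihood: thresholds fixed at normal quantiles of each margin, then the
latent correlation found by a bounded one-dimensional likelihood search on
$(-0.999, 0.999)$. The bivariate normal CDF is evaluated by 64-node
Gauss–Legendre quadrature of the conditional-probability integral, which
is accurate to ~1e-10 — far below sampling noise. Loadings are unweighted
least squares on the off-diagonal correlations; fit indices (CFI, TLI,
RMSEA, SRMR, with the conventional cut-offs > 0.95, > 0.95, < 0.06,
< 0.08) come from a normal-theory ML discrepancy chi-square with the
independence model as baseline.

Two caveats are deliberate. First, pairwise polychoric matrices can be
mildly indefinite; eigenvalues are clipped at 1e-6 and the matrix rescaled
to unit diagonal before fitting (gross indefiniteness, below -0.05, is an
error). Second, the normal-theory chi-square treats the polychoric matrix
as if it were an ML covariance estimate, which overstates misfit at
moderate samples: under exact one-factor truth RMSEA comes out near 0.09
at $n = 379$ but near 0.035 at $n = 2000$. The contract of this stage is
therefore threshold *verdicts at large n* and the SRMR/residual screen
(which is robust at both sizes), not third-decimal agreement with any
particular weighted-least-squares CFA estimator.

**Local independence.** Residuals are observed minus implied
($\lambda\lambda^\top$) polychoric correlations; unordered pairs with a
residual above 0.2 are flagged as possibly locally dependent, largest
first.

**Monotonicity.** Polytomous Loevinger coefficients:
$H_{ij} = \mathrm{cov}(X_i, X_j) / \mathrm{cov}_{\max}(X_i, X_j)$, where
the denominator is the covariance after sorting both score vectors — the
comonotonic maximum under the observed marginals. Item $H_i$ and the scale
$H$ pool numerators and denominators. Item $H_i > 0.3$ is read as adequate
monotonicity. Rest-score trace lines complement $H$: persons are binned by
total-minus-item, bins merged greedily from the low end until each holds
`min_group` persons, and decreases in the bin means beyond 1e-9 are
counted as violations. The 1e-9 tolerance only ignores float noise, so the
bin size must dominate binomial noise: with bins of ~50 persons even
GRM-generated data shows spurious decreases of up to ~0.2 at the sparse
extremes, while bins of $n/10$ (the conventional minimum for
manifest-monotonicity checks, and what the package's own property tests
use at $n = 5000$) show none.

## Stage 3: GRM calibration

`fit_grm_mml()` maximizes the marginal likelihood, integrating $\theta$
out over a fixed quadrature grid: `quad_points = 61` equally spaced nodes
on $[-4.5, 4.5]$ weighted by the standard normal density (renormalized).
For smooth, rapidly decaying posteriors this rectangle rule is
spectrally accurate; the package's tests verify EAP agreement with a
2001-point reference grid to better than 1e-6.

The EM iteration alternates person-posterior weights over the grid
(E-step) with per-item maximization of the expected complete-data
log-likelihood (M-step). Because the expected counts condense the data to
a $Q \times 3$ table per item, the M-step cost is independent of sample
size. Bounds are enforced by smooth reparameterization — $\alpha \in
(0.05, 50)$ through a scaled logistic, $\beta_1 \in (-10, 10)$ through
tanh, and $\beta_2 = \beta_1 + e^\delta$ so ordering can never be violated
— which keeps extreme items (slopes near 7) stable. Convergence is a
maximum absolute parameter change below `tol = 1e-5` within `max_iter =
500` EM sweeps; non-convergence is an error (with the log-likelihood
trail) by default, a warning on request. The log-likelihood is checked to
be non-decreasing across sweeps in the test suite. Standard errors are
per-item observed information: the numerical Hessian of the marginal
log-likelihood in that item's three parameters with the other items held
at their estimates (a block-diagonal approximation; cross-item information
is ignored).

Items missing an observed category cannot support two thresholds and are
calibrated as two-category items, flagged `degenerate`, with the missing
threshold imputed just outside the observable range so the returned bank
remains a valid GRM bank.

Category response curves (`crc_table()`, `autoplot()`) visualize each
item; `detect_crc_anomaly()` flags items whose middle category is modal at
no trait level — the empirical signature of thresholds so close together
that responders do not separate "sometimes" from a neighbouring option.

## Stage 4: differential item functioning

For each item, three nested cumulative-logit regressions of the response
on the scale's EAP trait estimate are fitted by maximum likelihood
(`MASS::polr`): trait only; plus group; plus trait-by-group interaction.
The group main effect carries uniform DIF, the interaction non-uniform
DIF. The effect size is the McFadden pseudo-$R^2$ change between adjacent
models, with 0.03 as the relevance criterion; because trivial effects turn
significant at large $n$ and relevant-looking changes can be noise at
small $n$, an item is flagged only when the $R^2$ change reaches 0.03
*and* the likelihood-ratio test is significant at 0.01 (a "significant and
relevant" two-part rule). Covariates are sex (0/1 as given) and,
optionally, age dichotomized at the sample median — chosen because a
median split is the assumption-free default when no substantive age
grouping is specified. The trait estimate is a single-pass EAP under the
calibrated bank, without iterative purification (out of scope).

Swapping the group labels is an exact symmetry of the model; with the
optimizer tightened (`reltol = 1e-12`) the $R^2$ changes are reproducible
to about 1e-8 across relabelling — the residual being iterative-ML
convergence noise, which no finite tolerance can push to zero.

## Stage 5: post-hoc CAT simulation

The CAT replays each person's complete recorded responses as if collected
adaptively; nothing is generated, so the loop is fully deterministic.

- **Trait estimator: EAP** with a standard-normal prior on the same
  61-node grid. EAP is defined from zero items onward — the estimate
  before any item is the prior mean 0, matching the convention that the
  trait "starts at 0" — and never diverges on all-0 or all-2 records, the
  exact pathology that maximum likelihood has for low-trait responders.
- **Item selection:** maximum Fisher information at the current estimate,
  $I(\theta) = \sum_k (dP_k/d\theta)^2 / P_k$, ties broken by the lowest
  bank row.
- **Stopping:** checked after every administered item (minimum one), SE
  rule before length cap: stop when the posterior SD is at or below
  `stop_se`; else when `max_items` is reached; else when the pool is
  exhausted. `stop_se = 0` therefore reproduces the full test — the final
  likelihood is accumulated in bank order so the full-administration CAT
  estimate equals the direct full-scale EAP bit for bit.

`se_grid()` tabulates mean/SD items administered and the Pearson (and
Spearman) correlation between CAT and full-scale trait estimates over
stopping thresholds 0.2–0.8 in steps of 0.1. `full_scale_reference_se()`
computes the cohort mean full-scale EAP SE and rounds it *up* to the
nearest grid value, so the precision rule can never demand less precision
than the full scale delivers; the unrounded value is attached and logged.
`combined_rule_report()` adds the half-length cap
($\lfloor k/2 \rfloor$ items) per scale, keeping the cap only where the
capped CAT/full correlation stays at or above `cap_corr_floor = 0.9` — the
data-driven analogue of dropping the cap for a scale whose estimates
degrade badly under it — and reports totals and the percent reduction
versus the full questionnaire.

## The synthetic-data generator

`fixture_bank()` provides a stable 50-item bank with the 16/6/12/16 scale
layout. Five items carry published parameter values (two full depression
parameter sets, 7.377/0.688/1.349 and 2.457/0.119/0.828, and three
reported discriminations, 3.483/5.527/1.855); the remaining parameters are
one fixed seeded draw with $\alpha \in [1, 3.5]$, $\beta_1 \in [-1, 1]$
and threshold spacing in $[0.5, 1.5]$ — ranges typical of calibrated
mental-health item banks.

`generate_cohort()` draws per-person traits jointly normal across the four
scales with an exchangeable correlation of 0.6 (a stand-in: the scales
measure related constructs, but no cross-scale trait correlation is
published for this population), simulates graded responses from the bank,
and attaches covariates matching the study sample's demographics (n = 379
complete responders, 66.8% female, age ~N(44.8, 16.5²) truncated to
16–87). `generate_dif_cohort()` builds a two-group cohort whose groups
share the same trait distribution and differ only in one item
(`inject_dif()`: a threshold shift for uniform DIF, optionally a slope
ratio for non-uniform DIF), so any detected group effect is item-level
bias, not impact. For local-dependence tests the suite builds a pair of
items whose latent inputs share an extra factor; its weight (1.2) is
chosen so the induced polychoric residual (~0.26) sits clearly above the
0.2 flagging threshold rather than on it.

What the generator does **not** emulate: real marginal response
distributions (the filler thresholds are symmetric around zero, whereas
clinical samples skew), item wording effects, missing-data mechanisms
(missingness is injected completely at random where needed), DIF of any
form unless injected, and multidimensionality beyond the injected
correlated-error pair. Tests passing on these data therefore demonstrate
that the *algorithms* are correct under their assumptions, not that any
particular real questionnaire satisfies those assumptions.

## Problem sizes and seeds

All simulations are seeded and bit-reproducible. The test suite uses the
smallest sizes at which each property is stable: n = 2000 for calibration
recovery (10 seeds across the full 50-item bank), assumption
self-consistency, and DIF power (1000 per group, 20 seeds, threshold shift
-0.8); n = 5000 for monotonicity traces; n = 379 for the study-scale
pipeline run in the acceptance script. The EAP/selection/trace oracles are
pure numerics and run at 100–200 random draws.

## Known limitations

- Three response categories only; the GRM machinery is written for the
  0/1/2 case throughout.
- One factor per scale; no bifactor or multidimensional alternatives.
- DIF screening is single-pass (no purification loop) and regression
  based; no Mantel–Haenszel variant.
- The fit-index chi-square is a normal-theory approximation whose
  absolute RMSEA/CFI values at n of a few hundred are conservative; read
  verdicts at large n, or lean on SRMR and the residual screen.
- The CAT is post-hoc: it reuses recorded answers and cannot capture
  order or administration-mode effects of a live adaptive test.
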