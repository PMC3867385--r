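---
title: "Biomarker panel discovery for neonatal sepsis: methods and design"
author: "sepsisPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker panel discovery for neonatal sepsis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisPanel)
```

## The problem

Blood culture, the gold standard for diagnosing neonatal sepsis, takes
one to two days and misses a substantial fraction of true infections.
Neonatal intensive care units therefore lean on rapid hematological
scores built from the complete blood count (CBC), possibly augmented
with newer markers such as the neutrophil CD64 index.  The scientific
question this package operationalizes is: *which small subset of
routinely available hematological biomarkers, taken together, carries
the most diagnostic information about sepsis?*

Ten candidate biomarkers are considered, in a fixed canonical order:
Age (day of life), WBC, Hgb, Hct, Plt, Segs, Bands, Lymph, Mono and
the CD64 index.  The analysis has two prongs:

1. **Selection.** For every panel size $k$, exhaustive canonical
   correlation analysis (CCA) finds the $k$-subset of biomarkers most
   correlated with the septic/nonseptic label.  Because the second
   variable set is the single label $y$, the canonical correlation of
   a subset $S$ reduces to the multiple correlation coefficient,
   $\rho(S) = \sqrt{r_S^{\top} R_{SS}^{-1} r_S}$, computed through a
   pseudo-inverse so collinear subsets degrade gracefully.  A greedy
   Forward Selection comparator shows where local search diverges from
   the global optimum.
2. **Validation.** Each selected panel is turned into a diagnostic
   classifier — a bagged 1-norm (sparse) linear support vector machine
   — and judged by TPR, TNR, PPV, NPV and ACC over repeated random
   learning/test divisions, with a LASSO logistic regression (LLR)
   comparator and an exhaustive all-subsets sweep as controls.

## Labels: the hematologic score and the three groups

An evaluation's label is defined operationally, not by chart review:

* **Group 1** (culture-proven sepsis): positive blood culture.
* **Group 2** (clinical sepsis): culture-negative but *positive
  hematologic score* — at least 2 of 4 criteria met: ANC outside
  `[ancLow, ancHigh]`, ABC $\ge$ `abcMin`, IT-ratio $\ge$
  `itRatioMin`, platelets $\le$ `pltMax`.
* **Group 3** (nonseptic): neither.

Groups 1 and 2 together form the septic class ($y = +1$).  All four
criteria use inclusive comparisons, matching the inclusive "2 or
more" rule.  The numeric thresholds are configuration with
implementer-chosen defaults from the neonatal scoring literature
(ANC outside 1750–25000 cells/mm³, ABC ≥ 2000 cells/mm³, IT ≥ 0.2,
Plt ≤ 150×10³/µL); they are printed in every report header so a run
is always interpretable without this document.

## The classifier

On standardized biomarkers $\tilde{x}$ (zero mean, unit SD; $n-1$
denominator), the decision function is $\mathrm{Score}(x) = w \cdot
\tilde{x} + b$, positive diagnosis iff $\mathrm{Score} \ge 0$
(inclusive).  Training solves

$$\min_{w, b, \xi \ge 0}\; \sum_j |w_j| \;+\; C^{+}\!\!\sum_{i: y_i = +1}\!\!\xi_i
\;+\; C^{-}\!\!\sum_{i: y_i = -1}\!\!\xi_i
\quad \text{s.t.}\quad y_i (w \cdot \tilde{x}_i + b) \ge 1 - \xi_i,$$

the 1-norm soft-margin SVM.  The $\ell_1$ penalty produces exact
zeros, so the classifier doubles as an embedded feature selector; the
bias is unpenalized (penalizing it would break translation
invariance).  Slack costs are class-balanced, $C^{+} N^{+} = C^{-}
N^{-}$, parameterized as $C^{\pm} = \mathrm{scale} \cdot n / (2
N^{\pm})$; predictions on separable data are invariant to the overall
scale, whose default of 1 is an exposed configuration choice.

### The linear program and its dual

The problem above is a linear program.  The package ships its own
dense bounded-variable revised simplex (C++), and solves the *dual* —
which has only $2k + 1$ rows for $k$ features, independent of the
number of samples — recovering the optimal $(w, b)$ from the simplex
multipliers and completing $\xi$ as the hinge $\max(0, 1 - y\,
\mathrm{Score})$, which provably leaves the objective unchanged at an
optimum.  A direct primal construction is retained as a cross-route;
the two agree to $10^{-8}$ on random instances and both agree with an
external LP solver in the test suite.  If the internal duality-gap
check ever exceeds $10^{-7}$ the fit transparently falls back to the
primal route.  Pricing is Dantzig with a Bland's-rule fallback
against cycling; feasibility tolerance is $10^{-9}$.  Vertex
non-uniqueness is accepted: tests compare objectives, not weight
vectors.

### Bagging and repeated divisions

The data are divided at random into a learning set (2/3) and test set
(1/3), stratified by class so small cohorts cannot lose a class into
one side (the division machinery is shared across feature subsets so
comparisons are paired).  On each learning set, `B` bootstrap
resamples (same size, with replacement; a resample missing a class is
redrawn and counted) each train one SSVM with costs computed on that
resample's class counts; the ensemble score is the *mean of the
member decision values* (not a majority vote), thresholded at zero.
Divisions are repeated `R` times and each measure is reported as mean
± SD over divisions, with zero-denominator measures propagated as
missing and excluded from the summary (silent zeros would bias it).
Production defaults are `B = 1000`, `R = 100`; the validation studies
in the tests and the acceptance script run reduced sizes (`B` 10–50,
`R` 5–20) chosen so each study completes in minutes on one CPU while
keeping Monte-Carlo error well below the effects being asserted.

Standardization is fitted **once on the full dataset** before
splitting, replicating the original analysis; a leakage-safe mode
(`standardizeOn = "learning"`) refits $\mu, \sigma$ on each learning
set for methodological comparison.  The default is faithful
replication, not best practice — the flag exists precisely to measure
the difference.

### The LLR comparator

`fitLLR()` fits $\min_w \sum_i \log(1 + e^{-y_i (w \cdot x_i + b)}) +
\lambda \|w\|_1$ (bias unpenalized) via glmnet coordinate descent
(penalty rescaled to glmnet's per-observation parameterization,
convergence threshold $10^{-12}$); at $\lambda = 0$ it reproduces the
unpenalized MLE to $10^{-6}$ against `glm()`.  When $\lambda$ is not
given it is chosen by 5-fold cross-validated binomial deviance over a
30-point log grid on the learning set — the selection rule is a
package choice, since none is canonical.

## ROC machinery

Thresholds sweep the distinct scores with the same inclusive $\ge$
convention as prediction, so the deployed operating point lies
exactly on its own curve; AUC is trapezoidal.  Curves from repeated
divisions are *vertically averaged*: each is linearly interpolated
onto a common 101-point FPR grid and the per-point mean and SD of TPR
are reported together with the mean member AUC.

## The synthetic cohort generator

The clinical dataset behind this style of analysis is not publicly
deposited, so the generator is a first-class module that defines the
study conditions for every end-to-end claim the package makes.

* **Marginals.** WBC, Plt, Bands and CD64 are right-skewed counts and
  are generated lognormal with exact mean/SD matching; the other six
  are Gaussian truncated at zero (their default moments put zero
  ≥ 2.9 SDs away, so truncation distorts means negligibly).  Pooled
  means and SDs of the five panel biomarkers are anchored to the
  published cohort table (WBC 14.04/8.70 ×10³/µL, Plt 231.37/103.38
  ×10³/µL, Segs 39.64/17.25 %, Bands 7.92/9.61 %, CD64 2.96/2.42);
  the other five use NICU-plausible defaults (Age 18/6 d,
  Hgb 15.5/2.5 g/dL, Hct 47/7 %, Lymph 35/12 %, Mono 8/4 %).
* **Group structure.** Septic/nonseptic mean differences are
  specified as standardized effects (defaults: Bands +1.2, CD64 +1.0,
  WBC +0.8, Plt −0.9, Segs −0.8 — the sign pattern of the published
  classifier weights, with Bands the strongest single marker).  The
  pooled mean is reproduced exactly for any prevalence; within-group
  SDs are CV-preserving for the log-scale markers (disease scales
  skewed counts multiplicatively), which keeps the pooled SD anchor
  within a few percent.
* **Correlation.** A hematologically plausible positive-definite
  target (Hgb–Hct 0.85, Segs–Lymph −0.55, Bands–CD64 0.45 exceeding
  |Bands–Plt| = 0.10, …).  Because lognormal transforms attenuate
  latent correlations, each pairwise latent value is back-solved
  (Nataf-style) so the *output* Pearson correlations match the
  target; the adjusted latent matrix is projected to the nearest
  correlation matrix only if needed, with a warning.
* **Internal consistency.** ANC, ABC and the IT-ratio are derived
  from WBC, Segs and Bands via the standard CBC identities, and
  group 2/group 3 membership is made consistent with the 2-of-4 rule:
  septic draws with a negative derived score are recorded
  culture-positive (they are group 1 by definition), and the few
  nonseptic draws with a positive derived score have their *stored
  score inputs* nudged just inside the thresholds — biomarker values
  are never touched, so the marginal and correlation structure is
  preserved exactly.  Both adjustment counts are kept in the cohort
  metadata.
* **Determinism.** Every stochastic entry point takes a seed and
  restores the caller's RNG stream; identical seeds give
  byte-identical cohorts.

### What the planted harness does and does not show

`plantedPanelCohort()` is the parameter-recovery harness: chosen
biomarkers get known standardized effects, and they are generated
mutually uncorrelated and uncorrelated with the noise markers.  That
makes the planted panel the population-optimal subset *by an
identifiable margin* — under the realistic correlation structure the
fifth panel member's population increment can sit below the sampling
noise floor at n = 600, in which case no selector could recover it
and "recovery" would not be a property of the method under test.  The
realistic default cohort keeps the full correlation structure and
duly exhibits the interesting phenomena (suppressor variables
entering the selection path with weak univariate correlation, greedy
Forward Selection diverging from the exhaustive optimum) — but for
those cohorts the package makes no ground-truth recovery claims.

Passing tests on these cohorts therefore demonstrate correctness of
the machinery and its statistical calibration under a known
generative model.  They do not demonstrate clinical performance: real
NICU data have repeated evaluations per infant (ignored here, as all
evaluations are treated as independent), missingness, batch effects,
and marginals that no ten-parameter family reproduces.

## Numerical and design choices

* CCA via least squares / pseudo-inverse rather than the generalized
  eigenproblem: mathematically identical for a univariate second set
  and numerically stabler; the eigenproblem route survives as a test
  oracle.  Computed subset correlations are clipped to $[0, 1]$
  within $10^{-12}$.
* Exhaustive enumeration in lexicographic order with strict `>`
  comparison, so ties resolve deterministically to the first-seen
  (lexicographically smallest) subset; the enumeration guard is
  p ≤ 25 for selection and p ≤ 12 for the all-subsets classifier
  sweep.
* Forward Selection recomputes the residual by least squares
  (intercept included) after each entry; a numerically zero residual
  appends the remaining markers in index order with a warning.
* The all-subsets validation reports full ranks of the CCA panel
  per measure rather than a "top 10%" display: ranks are the stable,
  testable quantity.
* Measures with empty denominators are `NA` and excluded from
  means/SDs with an exclusion count; they are never coerced to zero.
* The null-calibration study uses a *balanced* cohort: with
  class-balanced costs the chance-level accuracy equals the majority
  share only at balance — under imbalance the cost scheme
  deliberately de-weights the majority class, so the majority share
  is not the null expectation.
* Correlation-recovery testing compares the *across-seed average*
  sample correlation to the target: a single cohort's Frobenius
  distance at n = 2×10⁴ sits on the sampling-noise floor, so the
  averaged comparison is the test that actually detects generator
  bias.

## Problem sizes used by the shipped studies

The test suite and `scripts/acceptance.R` run: oracle comparisons at
n = 30–40; recovery studies at n = 600 (300/300) over up to 100
seeds with `R = 10`, `B = 25`; the exhaustive sweep over all 1023
subsets at `R = 10`, `B = 10`; and the demonstration pipeline on a
600-evaluation cohort (200 septic / 400 nonseptic).  These sizes were
chosen so Monte-Carlo error is small relative to every asserted
effect while a full run stays in the minutes range on a single CPU.

## Known limitations

* Longitudinal dependence between repeated evaluations of one infant
  is not modeled.
* The LP solver is dense; it is sized for tens of features and
  thousands of samples, not for genome-scale panels.
* LLR lambda selection (CV deviance) and the SSVM cost scale are
  conventions, not optimized choices; both are exposed in the
  configuration.
* Percentage-valued biomarkers are generated without their sum
  constraint (Segs + Bands + Lymph + Mono need not stay below 100),
  a deliberate simplification of the CBC differential.
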