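# sepsisPanel

Which small set of routine hematological biomarkers, taken *as a
group*, best reveals neonatal sepsis?  Blood culture is slow and
insensitive, and single-marker screens miss multivariate structure.
`sepsisPanel` implements a two-pronged panel-discovery analysis for
NICU sepsis evaluations over ten candidate biomarkers (Age, WBC, Hgb,
Hct, Plt, Segs, Bands, Lymph, Mono, neutrophil CD64 index):

1. **Exhaustive canonical-correlation selection.**  For each panel
   size k, every one of the C(10, k) subsets S is scored by its
   canonical correlation with the septic/nonseptic label y — which,
   for a univariate label, is the multiple correlation

   ρ(S) = √( r_S′ R_SS⁻¹ r_S ),

   computed via pseudo-inverse — and the globally best subset is kept,
   with enter/leave annotations and a greedy Forward Selection
   comparator.

2. **Sparse-SVM validation.**  Each panel becomes a diagnostic score
   `Score(x) = w·x̃ + b` (x̃ standardized; diagnosis positive iff
   Score ≥ 0), trained as a bagged ensemble of 1-norm SVMs

   min Σⱼ|wⱼ| + C⁺ Σ_{yᵢ=+1} ξᵢ + C⁻ Σ_{yᵢ=−1} ξᵢ
   s.t. yᵢ(w·x̃ᵢ + b) ≥ 1 − ξᵢ, ξ ≥ 0,

   a linear program (solved by the package's own bounded-variable
   revised simplex on the 2k+1-row dual) with class-balanced costs
   C⁺N⁺ = C⁻N⁻.  Performance (TPR, TNR, PPV, NPV, ACC) is averaged
   over repeated stratified learning/test divisions, with vertically
   averaged ROC curves, a LASSO-logistic (glmnet) comparator, and an
   exhaustive all-subsets sweep that ranks the selected panel against
   every alternative.

The package also implements the operational label itself — the
hematologic 2-of-4 score (ANC out of range, ABC and IT-ratio
elevated, platelets low) and the three-group outcome (culture-proven
/ clinical sepsis / nonseptic) — plus record-exclusion rules, and a
seeded synthetic cohort generator (lognormal/Gaussian margins with a
Nataf-adjusted correlation target, anchored to published pooled
moments) that defines the study conditions for all validation claims,
since the original clinical dataset is not publicly deposited.

## Worked example

```r
library(sepsisPanel)

cohort <- makeLabels(generateCohort(defaultCohortSpec(
  nPos = 200, nNeg = 400, seed = 7)))
cohort
#> SepsisCohort with 600 evaluations and 10 biomarkers
#>   groups: 143 culture-proven, 57 clinical, 400 nonseptic

X <- biomarkerMatrix(cohort); y <- sepsisLabels(cohort)
path <- bestSubsets(X, y)
path
#> SelectionPath over 10 biomarkers
#>   k= 1 rho=0.421  enter: CD64         leave:
#>   k= 2 rho=0.580  enter: WBC,Segs     leave: CD64
#>   k= 3 rho=0.664  enter: Lymph        leave:
#>   k= 4 rho=0.709  enter: Plt          leave:
#>   k= 5 rho=0.730  enter: Mono         leave:
#>   ...
#>   k=10 rho=0.755  enter: Hgb          leave:
#>   forward selection: CD64, Segs, WBC, Lymph, Plt, Mono, Bands, Age, Hct, Hgb

panel <- path@biomarkerNames[selectedSubset(path, 5)]
perf <- repeatedEvaluation(X, y, features = panel,
                           R = 20, B = 50, seed = 2, keepScores = TRUE)
perf
#> PerformanceSummary (SSVM, R = 20, features: WBC, Plt, Segs, Lymph, Mono)
#>        TPR   TNR   PPV   NPV   ACC
#> mean 0.877 0.875 0.783 0.935 0.876
#> sd   0.044 0.034 0.043 0.021 0.021
averageRoc(perf@rocs)
#> ROCCurve averaged over 20 divisions; mean AUC 0.952
```

Reading the output: the correlation path rises steeply to k ≈ 5 and
then flattens — five biomarkers carry essentially all the panel's
information about the label (ρ = 0.730 of 0.755).  The enter/leave
columns show genuinely multivariate behavior: CD64 is the strongest
*single* marker on this cohort but is displaced at k = 2 by the
{WBC, Segs} pair, and a suppressor marker (Lymph) enters with weak
univariate correlation — the same phenomena that motivate exhaustive
rather than greedy selection.  The k = 5 classifier reaches mean
accuracy 0.876 ± 0.021 over 20 random divisions with mean AUC 0.952.

The full pipeline (exclusions → labels → selection → SSVM + LLR →
ROC → all-subsets validation, with TSV/JSON artifacts and a
reproducibility manifest) runs as:

```r
res <- runPipeline(runConfig(spec = defaultCohortSpec(seed = 7),
                             outDir = "run1"))
```

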