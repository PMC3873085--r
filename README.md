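# comorbscreen

Two-stage density-estimation analysis of co-morbidity structure in matched
case–control cohorts built from administrative claims data, with migraine
and its preventive medications as the worked example.

## The problem

Large claims databases make it possible to ask which disorders co-occur
with an index disease more often than in the general population.  The
standard crude analysis — one 2×2 odds ratio per candidate co-morbidity,
cases versus age/sex-matched controls — treats the case population as
homogeneous.  It is not: medication exposure identifies subgroups of cases
(heavily treated, barely treated, treated with particular drug
combinations) whose co-morbidity risks differ substantially.  This package
implements an analysis that finds those subgroups from the exposure data
itself and recomputes the co-morbidity statistics within them.

Each subject carries a 10-element feature vector: treatment days and
cumulative milligram dosage for five preventive drugs (amitriptyline,
flunarizine, propranolol, topiramate, valproic acid), min–max normalized
per element.

**Stage 1 — likelihood-ratio screening.**  A relaxed variable kernel
density estimate (RVKDE) is fitted separately to the case and control
feature vectors:

    f̂(v) = (1/n) Σᵢ (1 / (√(2π) σᵢ))ᵈ exp(−‖v − sᵢ‖² / 2σᵢ²),
    σᵢ = β · R(sᵢ) √π / ((k+1) Γ(d/2 + 1))^(1/d)

one isotropic Gaussian per training sample, with bandwidth proportional to
the sample's k-nearest-neighbour radius R(sᵢ).  A case sᵢ is flagged a
*case of interest* when f̂(sᵢ)/f̂′(sᵢ) > threshold (f̂′ the control
density): its exposure profile is distinctively case-like.

**Stage 2 — interpretable clustering.**  The cases of interest are
clustered with a compact mixture of K weighted full-covariance Gaussian
components,

    f̂(v) = (1/Σwᵢ) Σᵢ (2π)^(−d/2) · wᵢ |Σᵢ|^(−1/2) exp(−½ (v−μᵢ)ᵀ Σᵢ⁻¹ (v−μᵢ)),

fitted by maximum-likelihood EM.  Since the model has K(d+2)(d+1)/2 free
parameters, the feature space is first reduced by factor analysis: KMO and
Bartlett adequacy checks, retention of eigenvalues strictly above 1,
varimax rotation, and selection of features with a rotated loading above
0.4.  Demographics and per-outcome odds ratios (Woolf 95% CI, chi-square /
Welch t tests) are then tabulated for case vs control, of-interest vs
remaining cases, and cluster 1 vs cluster 0.

The original claims source is not distributable, so the package ships a
synthetic matched-cohort generator (`generate_cohort()`) with the same
design: 1:5 age/sex-matched controls sharing each case's index date, a
planted high-exposure case subcluster, and outcome flags realizing
configurable case-vs-control odds ratios in expectation.

## Worked example

```r
library(comorbscreen)

cfg <- pipeline_config(cohort = cohort_config(n_cases = 1000, rng_seed = 2026),
                       rng_seed = 2026)
res <- run_pipeline(cfg, "run1")
#> [comorbscreen] simulating cohort: 1000 cases, 1:5 matching
#> [comorbscreen] min-max normalized 6000 x 10 feature matrix
#> [comorbscreen] screening: 288 of 1000 cases of interest (28.8%) at threshold 1
#> [comorbscreen] factor selection: KMO 0.510, Bartlett p 3.11e-128, 4 factor(s), ...
#> [comorbscreen] clustering: sizes cluster 0: 274, cluster 1: 14
#> [comorbscreen] run complete; artifacts in run1
```

28.8% of the simulated cases sit in regions of exposure space where the
case density exceeds the control density; the factor check (KMO 0.510 >
0.5, Bartlett p ≪ 0.001) admits the factor reduction; and the mixture
splits the screened cases into a majority low-exposure cluster 0 and a
small high-exposure cluster 1.  `run1/` then holds the labeled subject
table, the ratio table, the factor report, the serialized mixture model,
and demographics/odds-ratio tables for all three partitions.

The 2×2 machinery reproduces published-table arithmetic directly.  For
amitriptyline utilization in a cohort of 19,356 cases and 96,780 matched
controls with 211 and 335 utilizers respectively:

```r
odds_ratio(211, 19356 - 211, 335, 96780 - 335)
#> OR 3.173 (95% CI 2.669-3.772), p = 2.14e-43
```

A step-by-step version of the same pipeline, with commentary and tables
written under `results/analysis/`, is in the numbered scripts under
`analysis/` (run them in order, `01_simulate_cohort.R` …
`05_comorbidity_stats.R`).

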