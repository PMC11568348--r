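# spatialfda

Functional data analysis of spatial single-cell imaging data.

Multiplex immunofluorescence and related single-cell spatial assays produce,
for each tissue sample, the coordinates and phenotypes of hundreds of
thousands of cells. A central question is whether the spatial arrangement of
a cell type — say, clustering of immune cells in the tumor
microenvironment — carries prognostic information. Summarizing each sample
by a spatial statistic at one arbitrary radius throws information away;
`spatialfda` instead treats the whole summary *curve* as the unit of
analysis and connects it to patient outcomes with functional data analysis.

The pipeline, end to end:

1. **Spatial summary functions per sample.** For the cells of a phenotype
   observed in a window of area `|A|`, Ripley's K

   K̂(r) = |A| / (m(m−1)) · Σᵢ Σ_{j≠i} 1(dij ≤ r) · eij

   counts neighbor pairs within radius `r` with an edge-correction weight
   `eij` (translation correction on rectangles; border correction and the
   uncorrected form are also available). The nearest-neighbor function

   Ĝ(r) = (1/m) Σᵢ 1(dNNᵢ ≤ r)

   is the probability that a cell's nearest same-type (or, in the bivariate
   form, cross-type) neighbor lies within `r`. L̂(r) = √(K̂(r)/π) is the
   variance-stabilized companion. Under complete spatial randomness (CSR),
   K(r) = πr², L(r) = r, G(r) = 1 − exp(−λπr²).

2. **CSR baselines and the degree of clustering.** Each curve is compared
   either to the theoretical CSR form or to an empirical baseline obtained
   by permuting phenotype labels across the fixed cell locations (robust to
   tissue holes). `fundiff = observed − baseline` is the degree of
   clustering beyond chance; it is the default input to the later stages.

3. **Functional PCA.** `fit_fpca()` decomposes the curves into a mean plus
   orthonormal eigenfunctions with per-sample scores; `fit_mfpca()` splits
   the variation into between-subject and within-subject levels when
   subjects contribute several samples.

4. **Functional regression.** `fit_functional_cox()` fits the penalized
   functional Cox model log h(t) = log h₀(t) + Z'γ + ∫X(r)β(r)dr with a
   cubic B-spline expansion of β(r), a second-derivative penalty, and AIC
   smoothing selection; exp(β(r)) is a radius-specific hazard ratio with
   pointwise 95% bands, and `significant_range()` extracts the radii where
   the band excludes HR = 1. `fit_sofr()` does the analogue for continuous
   (identity link) and binary (logit link) outcomes.

5. **Simulators.** Poisson (CSR) and Thomas (clustered) point-process
   generators plus an outcome generator with a known β(r) make every stage
   testable offline against closed forms.

Everything is tidyverse-native: tabular inputs are data frames, results are
tibbles or carry `tidy()` / `glance()` methods, and each result type has an
`autoplot()`.

## Worked example

```r
library(spatialfda)

sim   <- simulate_study(n_subjects = 40, lambda = 300, p_immune = 0.3,
                        clustered = 0.5, seed = 7)
study <- make_study(sim$cells, sim$metadata)
summary(study)
#> spatial FDA study
#>   subjects: 40
#>   samples:  40
#>   cells per sample: min 242 / median 303.5 / max 353
#>   phenotype immune: 3522 cells
#>   phenotype other: 8443 cells

gset <- extract_summary_functions(study, metric = "G", marks = "immune",
                                  n_r = 50, baseline = "permutation",
                                  n_perm = 50, seed = 7)
fpca <- fit_fpca(gset, value = "fundiff")
fpca
#> FPCA of 'fundiff' curves: 40 samples, 8 components (pve 99.1%)
#>   eigenvalues: 0.002234, 0.0001602, 4.021e-05, ...

fit <- fit_functional_cox(gset, sim$metadata, time = "time", event = "event",
                          covariates = "age",
                          subjects = dplyr::distinct(sim$cells, sample_id, subject_id))
fit
#> functional Cox model: 40 subjects, 31 events; k_basis = 10
#>   lambda = 169.9, edf = 1.00, penalized log PL = -85.877
#>   scalar coefficients:
#>  term   estimate  std.error
#>   age 0.01673934 0.01627896
#>   HR bands contain 1 at every radius
```

The first FPCA eigenvalue dominates (half the samples are clustered, half
CSR, so a single "overall clustering level" component explains most curve
variation). At n = 40 the hazard-ratio bands contain 1 everywhere — the
survival signal in this small simulated cohort is too weak to localize; the
package's validation experiments (below) use n = 500 where the model
recovers a known β(r) reliably.

`autoplot(gset)`, `autoplot(fpca)` and `autoplot(fit)` draw the spaghetti
curves, the mean ± 1 SD component panels, and the hazard-ratio band with
its HR = 1 reference line.

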