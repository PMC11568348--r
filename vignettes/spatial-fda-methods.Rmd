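---
title: "Methods: spatial summary functions, FPCA, and functional survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial summary functions, FPCA, and functional survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialfda)
```

This vignette is the package's account of its statistical machinery: the
models and estimators, the assumptions behind them, the tunable parameters
and their defaults, the numerical choices, what the simulators do and do
not emulate, and the known limitations.

## The data model

A study links three tables by keys. The **cell table** has one row per
segmented, phenotyped cell: `sample_id`, `subject_id`, coordinates `x`, `y`
in microns, and phenotype information — either logical indicator columns
(`phenotype_*`) or one categorical `phenotype` column, normalized
internally to indicators. The **metadata table** has one row per subject
with outcomes and scalar covariates. Derived objects (curve sets, FPCA
fits, regression fits) attach to the study under keys built from
`(metric, variate, marks)`. Curves are always keyed by `sample_id` and
carry the sample-to-subject map, because subjects may contribute several
tissue samples: multilevel FPCA needs the replication, and regression
averages a subject's curves by default.

Upstream image processing — segmentation, phenotyping, batch correction —
is out of scope; the cell table is the interface. Samples the user might
deem low quality stay in the container; exclusion happens at curve
extraction via `min_cells` (default 2, the minimum for the estimators to be
defined at all; stricter thresholds are a study-level choice and are
reported per excluded sample).

## Spatial summary functions

Cell positions in one sample are treated as a realization of a planar point
process observed in a window. Windows are axis-aligned rectangles; when no
tissue boundary is supplied, the bounding box of the sample's cells is
used. Rectangles are the only supported shape because the translation
edge-correction below is rectangle-specific and no boundary format for
irregular tissue outlines is standardized at this layer; for strongly
non-rectangular tissue the permutation baseline (which conditions on the
observed cell locations) is the appropriate comparison, not the
theoretical one.

For `m` cells of the target phenotype with pairwise distances $d_{ij}$:

$$\hat K(r) = \frac{|A|}{m(m-1)} \sum_i \sum_{j \ne i}
  \mathbb{1}(d_{ij} \le r)\, e_{ij}, \qquad
  \hat G(r) = \frac{1}{m}\sum_i \mathbb{1}(d^{NN}_i \le r),$$

with $\hat L(r) = \sqrt{\hat K(r)/\pi}$ and bivariate forms that count
cross-phenotype pairs ($\hat K_{12}$) or nearest cross-type neighbors
($\hat G_{12}$). Ties at exactly $d = r$ count as inside (closed
inequality, matching the indicator). Three corrections are provided:

* `none` — $e_{ij} \equiv 1$; used by the exactness oracles.
* `translation` (default for K and L) — on a rectangle with sides $a, b$,
  $e_{ij} = ab / \{(a - |\Delta x_{ij}|)(b - |\Delta y_{ij}|)\}$, the
  reciprocal of the fraction of pair translations kept inside the window;
  weights are $\ge 1$.
* `border` (default for G) — the reduced-sample estimator: only cells
  further than $r$ from the boundary contribute at radius $r$, with the
  retained count renormalizing; undefined (NA) where no cells remain.
  K supports a border variant the same way. Isotropic correction is not
  implemented.

Monotonicity of $\hat K$ in $r$ is guaranteed for `none` and `translation`;
the border variant can be locally non-monotone because the retained set
changes with $r$.

**Radius grid.** Shared across samples. Default: 100 equally spaced radii
from 0 to one quarter of the window's shorter side — the usual conservative
range beyond which edge-corrected estimates destabilize. In batch
extraction the quarter-side of the *smallest* eligible window is used so
every sample is estimated on identical radii.

**CSR baselines.** The theoretical forms are $\pi r^2$, $r$, and
$1 - e^{-\lambda \pi r^2}$ with $\hat\lambda = m/|A|$ (the second mark's
intensity for bivariate G). The empirical baseline re-assigns phenotype
labels uniformly at random across the fixed cell locations (`n_perm`
permutations, default 100, seed-deterministic) and averages the recomputed
curves; because locations are held fixed, it automatically accounts for
holes and inhomogeneity in where cells could be observed. Optional
pointwise quantile envelopes across permutations are exposed; the *mean*
is what enters `fundiff`.

**Degree of clustering.** `fundiff = observed − baseline` (permutation
baseline when computed, theoretical otherwise), oriented so positive values
mean more clustering than chance. For G it reads as the probability beyond
chance of a neighbor within radius $r$.

**User metrics.** `register_summary_plugin()` accepts any
`function(pattern, marks, grid) -> curve`; plugins get batch extraction and
the permutation baseline unchanged (no theoretical baseline — there is no
closed form to offer). A plugin failure on one sample flags that sample and
the batch continues. This is also the intended hook for entropy-type
multivariate summaries, which are deliberately not built in.

## Functional principal component analysis

Curves $X_i(r)$ on the shared grid are decomposed as
$X_i(r) = \mu(r) + \sum_k \xi_{ik}\phi_k(r)$. The estimator is deliberately
plain: pointwise mean, sample covariance of the demeaned curves, and an
eigendecomposition taken with trapezoidal quadrature weights — solve the
symmetric problem on $W^{1/2} C W^{1/2}$ and map eigenvectors back by
$W^{-1/2}$ — so eigenfunctions are orthonormal under integration on the
grid (uniform or not). Negative eigenvalues (numerical) truncate to zero.
Components are kept until the cumulative proportion of variance reaches
`pve` (default 0.99; `npc` overrides). Scores are quadrature projections of
the demeaned curves; they are exactly mean-zero by construction.

Two conventions make fits reproducible: eigenfunction signs are fixed so
$\int \phi_k > 0$ (tie-break: positive value at the largest-magnitude
point), and no smoothing is applied by default — K/G curves are already
smooth, and the unsmoothed estimator is exactly reproducible and satisfies
the Parseval identity (total eigenvalue mass equals integrated pointwise
variance) up to rounding. `smooth = TRUE` switches on penalized-spline
smoothing of the mean and of the covariance surface (diagonal excluded, to
avoid absorbing the white-noise nugget), via mgcv.

Missing values are tolerated only as leading/trailing runs of the grid
(border-corrected G produces them at large $r$); those radii are trimmed
before fitting, and interior missingness is an error rather than silently
imputed.

**Multilevel FPCA.** With $n_i$ samples per subject, the within-subject
covariance is estimated from deviations around subject means
($K_W = \sum_{ij} D_{ij}D_{ij}'/\sum_i (n_i - 1)$), and the between-subject
covariance from subject means with the standard method-of-moments bias
correction $K_B = \widehat{\mathrm{Cov}}(\bar Y_i) - K_W \cdot
\overline{1/n_i}$. Each level is eigendecomposed as above. The variance
share $\rho = \sum\lambda^{(1)} / (\sum\lambda^{(1)} + \sum\lambda^{(2)})$
summarizes how much variation is between subjects. Scores are direct
quadrature projections (no BLUP shrinkage); with the moderate noise levels
of summary curves this is accurate and keeps the estimator free of tuning
parameters.

## Functional regression

The functional Cox model is
$\log h_i(t) = \log h_0(t) + Z_i'\gamma + \int X_i(r)\beta(r)\,dr$, with
the scalar-on-function analogue replacing the hazard by an identity- or
logit-linked mean. Design choices:

* **Basis.** $\beta(r) = \sum_l b_l\theta_l(r)$ with cubic B-splines,
  default dimension 10, equally spaced interior knots. The functional term
  discretizes to a design block $Z_{il} = \sum_j w_j X_i(r_j)\theta_l(r_j)$
  with trapezoid weights. Curves are mean-centered across subjects first;
  the baseline hazard (or intercept) absorbs the center.
* **Penalty.** Second-derivative penalty
  $S_{lm} = \int \theta_l''\theta_m''$, computed by dense-grid quadrature;
  its null space contains all linear functions of $r$. In addition, a small
  fixed ridge — $10^{-2}$ of the average information diagonal, applied to
  the functional block only — pins the coefficient directions that the
  observed curves do not span. Summary curves are often effectively
  low-rank (a handful of FPCA components), which leaves most of a
  10-dimensional basis unidentified by the likelihood; without the ridge
  those directions drift freely in the penalty null space. The ridge is two
  orders of magnitude below the curvature of identified directions: in the
  degenerate test where curves are constant in $r$, the fitted hazard ratio
  still agrees with an unpenalized scalar Cox model to about 0.2%.
* **Fitting.** The penalized partial likelihood (Breslow tie handling)
  $\ell(b,\gamma) - \tfrac{\lambda}{2}b'Sb$ is maximized by Newton
  iterations with step halving; risk-set sums use prefix accumulation over
  times sorted in decreasing order, so a fit at $n = 500$ takes a fraction
  of a second. Convergence is declared when the quadratic model predicts a
  relative gain below $10^{-8}$, with a cap of 100 iterations.
* **Smoothing selection.** $\lambda$ minimizes
  $AIC = -2\ell + 2\,\mathrm{edf}$, with
  $\mathrm{edf} = \mathrm{tr}\{(H+\lambda S)^{-1}H\}$, over a 20-point
  log-spaced grid scaled to the data (descending, warm-started). AIC
  differences under 2 are not meaningful, so among candidates within 2 of
  the minimum the smoothest fit wins; on low-rank curve sets the AIC
  profile is flat across decades of $\lambda$ and the plain argmin would
  land arbitrarily deep in the undersmoothed plateau. REML selection was
  deliberately not implemented; AIC keeps the estimator self-contained, at
  the cost of possibly selecting slightly different $\lambda$ than a
  mixed-model formulation would.
* **Inference.** Pointwise Wald bands from
  $\mathrm{se}(r)^2 = \theta(r)'(H+\lambda S)^{-1}\theta(r)$, reported on
  the hazard-ratio scale as $\exp(\hat\beta \pm z_{0.975}\,\mathrm{se})$.
  Bands are pointwise, not simultaneous; `significant_range()` returns the
  maximal radius intervals where the band excludes HR = 1 (coefficient 0
  for scalar-on-function fits). Identity-link fits select $\lambda$ by GCV
  and scale the covariance by the dispersion; logit fits use penalized IRLS
  with AIC, and report separation (|linear predictor| > 30) as an error
  advising a stronger penalty.
* **Repeated samples.** Subjects with several samples enter regression with
  their curves averaged. This is a pragmatic default — the multilevel
  structure belongs to MFPCA — and a single-sample-per-subject analysis can
  be had by filtering the curve set first.

## Simulators

`simulate_poisson()` (homogeneous Poisson = CSR) and `simulate_thomas()`
(Poisson parents, Poisson(μ) offspring with isotropic Gaussian(σ)
displacement; parents drawn in a 4σ guard band so boundary clusters are
unbiased) generate marked patterns with seed-deterministic output.
`simulate_outcomes()` generates curves from a two-component model
$X_i = \mu + \xi_{i1}\phi_1 + \xi_{i2}\phi_2 + \varepsilon_i$ (defaults:
orthonormal sine/cosine pair with score variances 4 and 1 on a 101-point
unit grid) and outcomes from the linear predictor
$\eta_i = \int X_i\beta$: survival times by inverse transform under an
exponential or Weibull baseline with independent uniform censoring whose
bound is calibrated by root-finding to a target censoring fraction
(default 30%), plus Gaussian and Bernoulli outcomes. The true $\eta$ and
the full generating spec (JSON-serializable, including the calibrated
censoring bound) are returned for testability. `simulate_study()` wraps the
point-process generators into a whole cohort (cells + metadata tables)
with a chosen fraction of subjects carrying Thomas-clustered immune cells.

What the simulators emulate: realistic cell counts, CSR-vs-clustered
contrasts with known closed forms, multi-sample subjects, outcome models
with a known functional effect. What they do not emulate: tissue holes and
irregular boundaries, spatial inhomogeneity of cell density, phenotype
misclassification, batch effects, or correlations between phenotypes
beyond label shuffling. Passing tests therefore certify the estimators and
models under their stated assumptions, not robustness to those real-data
complications — with the partial exception of the permutation baseline,
whose conditioning on observed locations is exactly the mechanism that
carries over to imperfect tissue.

## Validation experiments and problem sizes

The test suite validates each stage against an independent route: exact
double-loop oracles for every estimator with `correction = "none"` (50
random patterns up to 50 points); calibration of the corrected estimators
against closed CSR forms (200 Poisson(100) patterns for translation-K
within 5% of $\pi r^2$ on $r \in [0.05, 0.2]$; 500 Poisson(200) patterns
for border-G within 0.02 of its closed form at $r \le 0.05$); the
permutation null (50 patterns × 50 permutations, mean `fundiff` within
Monte Carlo error of zero); FPCA recovery of known components (200 curves,
cosine similarity ≥ 0.95, eigenvalue ratio within 25%); functional Cox
recovery of $\beta(r) = \sin(\pi r/r_{max})$ at $n = 500$ over 100 seeded
replicates with a β-aligned curve generator, plus 200 null replicates for
band coverage; and the degenerate constant-curve reduction to a scalar Cox
fit (agreement within 2%, via the survival package as the independent
reference). These sizes keep the whole suite under a few minutes while
leaving Monte Carlo error well below the tolerances tested.
`scripts/acceptance.R` re-runs the same experiments (50 recovery and 100
null Cox replicates) from a single seed and writes every measured number to
JSON.

## Known limitations

* **K under strong clustering is ratio-biased.** The $m(m-1)$
  normalization makes $\hat K$ exactly match its definition per pattern,
  but across realizations of a cluster process with few clusters per
  window (κ|A| ≈ 10) the *mean* of $\hat K$ deviates from the closed-form
  K by order $1/(\kappa|A|)$ — about +15% at small $r$ for the Thomas
  parameters used in the tests, with the sign flipping at larger $r$. This
  is a property of the estimator, not of the simulator: normalizing the
  same pair counts by the known intensity removes it. The corresponding
  strict mean-versus-theory assertion in the acceptance suite documents
  this bias by failing at those parameters; single-pattern inference, the
  permutation baseline, and all CSR calibrations are unaffected.
* Rectangular windows only; no isotropic correction; no inhomogeneous K/G
  or pair-correlation function.
* FPCA uses dense shared grids (no sparse-design conditional-expectation
  scoring) and MFPCA scores are unshrunken projections.
* Functional Cox bands are pointwise; simultaneous inference and
  time-varying or nonlinear (additive) functional effects are out of
  scope.
* With strongly low-rank curve sets, $\beta(r)$ is only identified within
  the span of the observed curve variation; the ridge reports a smooth,
  near-zero estimate in the unidentified directions rather than refusing
  to fit. Interpret $\hat\beta$ through the curves' leading components
  (e.g., via FPCA) when in doubt.
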