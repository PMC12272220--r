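---
title: "Methods: homotopic connectivity, laterality, and their statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homotopic connectivity, laterality, and their statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homolat)
```

## The two measures

For a symmetric parcellation given as a table of homotopic pairs (left
region, right region, cortical hierarchy zone), the package computes, per
subject, from a Fisher-z functional connectivity matrix:

- **HoFC** of pair *i*: the z-value between the pair's left region and its
  right counterpart. It quantifies functional homotopy.
- **Intrahemispheric integration** `L_i` (`R_i`): the *signed* sum of
  z-values between the left (right) member and every other region of the
  same hemisphere. Positive and negative correlations both count; the
  homotopic counterpart is contralateral and therefore excluded, as is the
  region itself.
- **Laterality index** `LI_i = |L_i - R_i| / (|L_i| + |R_i|)`, in [0, 1].
  LI is invariant to a global rescaling of the z-matrix and undefined
  (returned as `NaN`, never 0) when `|L| + |R| = 0`, since a zero total
  carries no directional information.
- **Mean FC**: the mean of all off-diagonal z-values, used as a global
  covariate in every across-subject model.

All region indexing is by label through the pair map, never by column
position, so any column ordering of the input series gives identical
measures.

## Time-series preparation

The resting chain is detrend → nuisance regression → band-pass
(0.01–0.1 Hz); the task chain is nuisance regression → high-pass
(>0.01 Hz) → task-event regression → fixation-frame removal →
per-run standardization → concatenation. Each step is a linear operator
per column, so the chains are deterministic and order-exact.

Three choices here were genuinely open and are package decisions:

- **Filter family and order.** Only the bands are inherent to the
  analysis; the implementation uses an order-2 Butterworth applied
  forward–backward (zero phase), the common neuroimaging default. Ringing
  and edge transients are mild at order 2; tests check ≥90% amplitude
  retention at 0.05 Hz and ≤10% at 0.5 Hz for TR = 0.72 s.
- **Fit-then-drop for background connectivity.** The task-event
  regression is fitted on *all* frames and fixation frames are dropped
  from the residuals afterwards. Fitting only on non-fixation frames
  would truncate HRF tails that extend into fixation blocks and bias the
  betas.
- **Per-run standardization before concatenation.** Runs differ in
  offset and scale; concatenating unstandardized residuals would convert
  between-run level differences into spurious positive correlation.

The Friston-24 motion expansion is `[p(t), p(t-1), p(t)^2, p(t-1)^2]`
per parameter, lag zero-padded at the first frame.

## The synthetic cohort

The generator is the package's ground-truth source, not a fixture. Each
subject receives per-pair homotopic correlation targets and asymmetry
increments drawn around configured values; a region correlation matrix is
assembled with:

- homotopic entries = the pair's target,
- left–left entries = `intra_base + (asym_i + asym_j)/4` and right–right
  entries the mirror image (so a common asymmetry `a` raises left
  coupling by `a/2` and lowers right coupling equally, leaving the mean
  integration level asymmetry-free),
- a flat cross-hemisphere background elsewhere.

If the assembled target is indefinite it is projected to the nearest
positive-semidefinite correlation matrix by eigenvalue clipping at zero
and unit-diagonal renormalization; the maximum adjustment is reported and
a deviation of realized homotopic correlations beyond 0.1 warns. Ground
truth (true HoFC, L, R, LI per subject) is computed from the *realized*
covariance with the same formulas the measurement module applies to data,
so measured and true values provably converge as the run length grows
(checked at T = 100,000 within ±0.02 for HoFC).

The `coupling` parameter correlates a subject's homotopic deviations with
their asymmetry deviations; `coupling = -0.8` plants the negative
across-subject HoFC–LI association the group statistics are designed to
detect. Age enters as a linear drift of the targets around the mid-range
age. Temporal autocorrelation is AR(1) applied to innovations that carry
the target cross-covariance (`x_t = ar1 x_{t-1} + sqrt(1-ar1^2) e_t`,
stationary start), which leaves the zero-lag covariance exactly at its
target. One master seed expands to per-subject, per-session seeds through
a fixed counter scheme, so a second session redraws noise while keeping
every subject's parameters — exactly a test-retest design.

What the generator does *not* emulate: physiological (non-Gaussian)
noise, motion artifacts, spatial smoothness, hemodynamic nonlinearity,
and distance-dependent connectivity structure. Passing tests therefore
certify the statistical machinery under the model's assumptions, not
robustness to every property of real BOLD data.

Family phenotypes are drawn with covariance
`h2 (2 Phi) + (1 - h2) I` per trait and cross-trait genetic covariance
`rho_g sqrt(h2_1 h2_2) (2 Phi)`, with `Phi` the pedigree kinship matrix.

## Reliability

Pattern similarity is the Pearson correlation of a subject's regional
measure map across two sessions (pairwise `NaN` deletion, ≥3 finite
pairs). The regional coefficient is **ICC(2,1)** — two-way random
effects, absolute agreement, single measure — chosen because it is the
standard test-retest convention and penalizes constant session offsets;
the variant in use is stated prominently since ICC(3,1) can differ
materially. It is computed from the two-way ANOVA mean squares and tested
against a brute-force `aov()` oracle.

## Group statistics

Partial correlation residualizes both variables on an intercept plus
covariates and correlates the residuals, with `df = n - 2 - k`. Zone
comparisons use Welch's heteroscedastic ANOVA with Games-Howell post hoc
tests (Welch t, Welch–Satterthwaite df, studentized-range reference),
appropriate because zone variances differ by construction. Bonferroni
adjustment is `min(1, p m)` with `m` settable independently of the vector
length. The comparison of HoFC–LI correlations between brain states uses
the independent-sample Fisher z test — a fidelity choice: the states are
measured within subjects, and a dependent-correlation correction would be
more efficient, but the simple z test is what the analysis convention
prescribes; its p-values are therefore conservative in this setting. Age
groups (18–39 / 40–59 / 60–87) are exposed as configuration, not
hard-coded.

## Canonical correlation analysis

Both variable blocks are column-wise residualized on their covariate sets
and standardized. The CCA core is the QR/SVD factorization of the
whitened cross-covariance (the `canoncorr` algorithm); no regularization
is applied — a rank-deficient block produces a reduced-rank fit with a
warning instead, matching the reference tool's behaviour. Mode signs are
arbitrary in CCA; the package fixes them so each X-variate correlates
positively with its highest-|loading| X variable. Significance per mode
uses Bartlett's approximate chi-squared
`-(n - 1 - (p+q+1)/2) sum_{i>=k} log(1 - r_i^2)` with
`(p-k+1)(q-k+1)` df, embedded in a permutation test: rows of the Y block
are permuted (the scheme left open by the convention; permuting one block
suffices for exchangeability under the null), and the add-one estimator
`p = (1 + #{perm >= obs}) / (B + 1)` guarantees valid, never-zero
p-values. Loadings are variable–variate correlations; |loading| > 0.3
(strict) flags a variable as contributive.

## Heritability

Kinship is computed by the recursive tabular method with founders
unrelated and MZ co-twins forced to `phi = 0.5`. The variance-component
model is **AE** (additive genetic + environment) fitted by **maximum
likelihood**: the likelihood is diagonalized by a one-time
eigendecomposition of `2 Phi`, the total variance is profiled out, and
the univariate fit reduces to a 1-D optimization over `h2 in [0, 1]`
started from 0.1/0.5/0.9 with explicit boundary candidates. The fast path
is tested for equality with a dense multivariate-normal likelihood on a
50-individual problem to 1e-6. The test of `h2 = 0` lies on the parameter
boundary, so the LRT reference is the 50:50 mixture of a point mass at
zero and chi-squared(1); calibration is verified at ≤7% rejections at
alpha = 0.05 over 500 null replicates. The bivariate model adds
`rho_g sqrt(sg1 sg2) (2 Phi) + rho_e sqrt(se1 se2) I` cross-covariance,
optimized over log-variances and atanh-correlations with multi-start
BFGS/Nelder-Mead; `rho_g = 0` is tested by a 1-df LRT (interior
parameter). A household/shared-environment component is deliberately
omitted: the model decomposes variance into additive genetic and
environmental parts only. When either trait has near-zero heritability
the genetic correlation is undefined and reported `NaN`.

## Mediation

The between-subject model is the standard four-step chain on standardized
variables: `c` from `y ~ x + cov`, `a` from `m ~ x + cov`, `b` and `c'`
from `y ~ x + m + cov`; the decomposition `c = c' + a b` holds exactly
for OLS and is asserted to 1e-10. The indirect effect `a b` gets a
**percentile** bootstrap CI (the bootstrap type being otherwise
unspecified in the convention), resampling subjects; the bootstrap is
vectorized through weighted cross-products so the default 10,000
replicates are cheap. The two-condition within-participant model takes
`a = mean(Δm)`, `c = mean(Δy)` (differences standardized), and `b`, `c'`
from the regression of Δy on Δm plus the mean-centered mediator average
and covariates — centered regressors make `c = c' + a b` exact here too.
Identical conditions are a degenerate contrast handled explicitly
(`a = c = 0`, `b = 0`, CI covers zero). Region masks for mediation are
explicit inputs; a mask is admitted only if every required path is
significant with a consistent sign across member pairs, enforced by
`mask_average()`.

## Numerical conventions

- The FC diagonal is undefined on the z scale and stored `NaN`;
  off-diagonal |r| = 1 is an error (degenerate signal), not an infinity.
- `NaN` LI values propagate through zone averages (`NaN`-aware means) and
  pattern similarity (pairwise deletion) rather than being imputed.
- PSD repair: eigenvalue clipping at 0 with unit-diagonal
  renormalization, adjustment magnitude reported.
- All stochastic functions take explicit integer seeds; the pipeline
  derives stage seeds from one master seed by fixed offsets, and reruns
  are verified byte-identical via MD5 manifests.

## Problem sizes used in validation

The bundled checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerances while keeping the suite quick on a laptop:
measurement consistency at T = 100,000 frames with 4 pairs; coupling
recovery at 200 subjects, 20 pairs, T = 2,000 (null calibration over 25
replicate cohorts at T = 200); Welch calibration over 2,000 replicates;
permutation-p uniformity over 200 datasets at 500 permutations;
heritability at 150 MZ + 150 DZ twin pairs with 500 null replicates;
mediation recovery at n = 500 with 2,000 bootstrap replicates and null
coverage over 500 replicates at n = 200. The demo pipeline uses 16
subjects, 4 pairs and 300 frames per run — a smoke configuration whose
estimates are intentionally noisy.

## Known limitations

- The Gaussian surrogate cannot reveal sensitivity to non-Gaussian or
  nonstationary noise, motion, or parcellation misassignment.
- Plain CCA is unstable when n is not comfortably larger than p + q; the
  package warns rather than regularizes.
- The AE heritability model cannot separate shared-environment from
  additive-genetic variance in twin-only samples; h2 estimates absorb
  common environment.
- Mediation is associational; no causal identification is claimed, and
  the within-participant model assumes the mediator–outcome relation is
  homogeneous across conditions.
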