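---
title: "Discover-then-project mapping of connectome-behavior associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discover-then-project mapping of connectome-behavior associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeproject)
```

## The analysis in one paragraph

`edgeproject` relates functional network connectivity (FNC) -- Pearson
correlations between pairs of independent-component time courses -- to
behavioral and clinical measures in a two-cohort design. In a large
*reference* cohort, every connectivity feature (edge) is tested in a
covariate-adjusted GLM against a behavioral outcome and a
Benjamini-Hochberg (BH) FDR threshold selects a discovery set; the set's
robustness is probed with outcome-shuffling permutations and 70% bootstrap
subsampling. The discovery set is then *projected* onto an independent
target cohort: only those edges are tested against symptom scales, with the
FDR family restricted to the discovered edges. Finally, a tapered
sliding-window analysis clusters windowed connectivity into recurring
*states*, and per-subject state occupancy rates (OCRs) are regressed on
symptoms. Seeded synthetic generators provide ground-truth cohorts so every
stage is testable end to end.

## Static connectivity and the edge family

For a scan of `T` timepoints and `C` components the connectivity matrix
holds the Pearson correlation of every component pair; with the standard
53-component template this yields `53 * 52 / 2 = 1378` features. Edges are
indexed row-major over the upper triangle -- (1,2), (1,3), ..., (1,C),
(2,3), ... -- and this single ordering is used by every module and file
format. Components and edges are 1-based throughout, inside the code as
well as in outputs: R is a 1-based language and published component tables
for this template number components from 1, so carrying a 0-based internal
convention would only manufacture off-by-one hazards.

Correlations enter the models raw, not Fisher z-transformed: the
connectivity estimate is defined directly as the correlation coefficient,
and on the narrow range of typical FNC values the transform is close to the
identity while changing the units of every reported coefficient. Because
part of the dynamic-connectivity tool tradition z-transforms before
modeling, `pearson_fc()` and `dfnc_tensor()` expose a `fisher_z` switch;
the default is raw `r`.

## Edge-wise GLM discovery

Each edge is tested with ordinary least squares of the outcome on the
covariate design plus that edge,

`outcome ~ intercept + covariates + edge`,

so the reported `beta` is in outcome units per unit correlation. The
reference-cohort adjustment set is age, age squared, sex, the age-by-sex
interaction and acquisition site; the target cohort adds income, years of
education and trauma type. Categorical covariates are reference-coded with
the alphabetically first level as baseline; sex is coded 0/1. Subjects with
any missing required field are dropped per model with a logged count. A
rank-deficient design is a hard error naming the collinear columns.

Implementation-wise the fits use Frisch-Waugh residualization: the
covariate design is QR-factored once, outcome and all edges are
residualized against it, and the edge-term statistics are recovered from
residual cross-products with `df = n - rank - 1`. This is algebraically
identical to refitting the full model per edge (the test suite verifies
agreement with `lm()` to 1e-8) and makes scanning 1378 edges across
thousands of subjects essentially free. Alongside `beta`, `SE`, `t` and the
two-sided `p`, the effect-size correlate
`partial_r = sign(t) * sqrt(t^2 / (t^2 + df))` is reported -- the magnitude
conventionally quoted next to edge coefficients.

FDR control is Benjamini-Hochberg across exactly the full edge family (all
C(C-1)/2 tests per outcome). Binary phenotypes (e.g. an absent/present
anhedonia indicator) use the same least-squares machinery with the group
indicator as the regressor of interest and the edge as response
(`group_discover()`); a linear model on a 0/1 regressor is the
covariate-adjusted two-group comparison, and the `t` statistic is identical
under the exchange of edge and indicator roles.

### Permutation validation

`permutation_validate()` re-tests the discovered edges only (the discovery
set is held fixed, not re-selected per shuffle, matching a validation of an
already-selected set), shuffling the outcome vector while covariate and
edge rows stay aligned -- the shuffle therefore also breaks
outcome-covariate links, which is the literal reading of "shuffle the
scores and rerun the regression". Empirical p-values use the add-one
convention `(1 + #{|t*| >= |t|}) / (1 + n_perm)`, so they are never zero
and the attainable floor is `1/(n_perm + 1)`.

### Bootstrap sensitivity

`bootstrap_sensitivity()` reruns the *entire* discovery -- GLM scan plus
BH selection -- on subsamples of `round(frac * n)` subjects drawn without
replacement (70% by default; 14047 subjects yield 9833) and reports each
edge's selection frequency. Sampling with replacement is available as an
option, but the subsampling-without-replacement default matches the stated
"subsampled 70% of the data" procedure.

## Constrained projection

`project_edges()` fits the target cohort's GLM for each discovered edge and
applies BH across exactly `m = |discovery set|` tests. Families are kept
per symptom scale (stress, anxiety and depression each adjusted
separately): the per-scale results are reported separately downstream, and
pooling heterogeneous scales into one family would couple their thresholds
for no analytic gain; a pooled family remains possible by concatenating
p-values into one `bh_fdr()` call. Site enters only as a covariate -- no
further harmonization is applied.

## Dynamic connectivity, states and occupancy

Windows are tapered: a rectangle of 20 TRs is convolved with a discrete
Gaussian of sd 3 TRs (support +/- ceiling(3 sigma)), the central 20 samples
are kept and normalized to sum 1. At a repetition time of 2.36 s the window
spans 47.2 s, inside the 30-60 s range generally considered sensitive to
connectivity dynamics. The taper is applied as *weights inside a weighted
Pearson estimator* (weighted means, variances and covariances); with
uniform weights this reduces exactly to the static estimator on the window
slice, which pins down the otherwise ambiguous notion of a "tapered
window". The step is 1 TR, the standard choice in this pipeline family;
229 timepoints then give exactly 210 windows of length 20.

Windowed edge vectors are pooled across subjects and clustered with
k-means under the squared-Euclidean objective. Clustering is performed on a
*designated edge subset* -- in the intended workflow the union of
discovered edges -- not on the full connectome vector. The implementation
is a hand-written Lloyd iteration because several details needed pinning
down deterministically:

* `n_init = 10` seeded initializations (centers drawn from data rows), best
  objective wins; up to 1000 Lloyd iterations each. A literal "1000
  iterations" is ambiguous between replicates and iterations, so both knobs
  are exposed and recorded in run metadata.
* assignment ties break to the lowest-index centroid;
* an emptied cluster is re-seeded at the point farthest from its assigned
  centroid (deterministic given the seed);
* the per-iteration objective is recorded; the suite asserts it never
  increases across iterations.

The number of states is chosen by the elbow of the dispersion ratio
`r(k) = within / between` over candidates k = 2..9. "Elbow" is formalized
as the k with the maximum discrete curvature (second difference) of
`r(k)`, ties to the smaller k; if the smallest candidate already leaves
essentially no within-cluster dispersion (`r <= 1e-8`, the point-mass
case) it is selected directly, and all-identical rows are an error.

Occupancy rates divide each subject's window count per state by the total
windows, so the k rates sum to 1 per subject. Because OCRs are
compositional, `ocr_glm()` fits each state's OCR in its own GLM (never all
k together with an intercept -- that design is singular) and applies BH
across the states-by-scales family. At k = 2 the two fits are exact
mirrors, a property the suite asserts.

## The synthetic generators

`gen_static_cohort()` emulates the cross-subject design: covariates are
drawn per cohort (reference: age uniform on 45-85, two sexes, three sites;
target: age 18-75, five sites, income, education years, trauma type), the
behavior is `mean + covariate effects + noise`, and each subject's latent
correlation matrix is a block network-structured base (within-network 0.25,
between 0 by default) perturbed on planted edges in proportion to the
standardized covariate-independent behavior component `z`. A planted
"standardized effect" `s` is calibrated to be the *partial correlation
between the observed edge feature and behavior*: since an empirical
correlation from `T` timepoints carries sampling noise of roughly
`(1 - rho^2)/sqrt(T - 1)`, the latent slope is
`delta = s * sigma_noise / sqrt(1 - s^2)`. The subject's time series is
then sampled from the perturbed matrix and the *empirical* correlations
form the edge table, so the discovery path sees realistic estimator noise.
A small deterministic subset of edges (10% by default) carries linear age
and sex effects, exercising the covariate adjustment. Perturbed matrices
that leave the positive-definite cone are repaired by eigenvalue clipping
with renormalized unit diagonal, and every repair is counted in the truth
record.

`gen_dynamic_cohort()` emulates within-scan regime switching: `k_true`
states, each a block correlation pattern raising one component group from
the baseline 0.1 to 0.7; a first-order Markov chain at TR resolution with
self-transition `1 - 1/dwell` (mean dwell 30 TRs by default); window-level
truth defined as the majority state within each window, ties going to the
state appearing earliest in the window; and a symptom drawn as
`intercept + sum_i b_i * OCR_i + noise` with default coupling
`(0, +10, -10)` -- a neutral state, a risk state and an opposing protective
state -- with noise sd 1. The defaults (306 subjects, 229 timepoints,
k = 3) mirror the target-cohort geometry.

What the generators deliberately do **not** emulate: hemodynamics and BOLD
forward physics, physiological noise and scanner drift, temporal
autocorrelation within states, site-specific distribution shifts beyond a
site label, non-Gaussian heavy-tailed behavior scores, and measurement
error in the phenotypes. Passing recovery tests on these cohorts therefore
demonstrates that the *estimators and selection logic* behave as designed
under the assumed generative structure -- not that real imaging data meet
those assumptions.

## Numerical choices and edge cases

* Constant time-course columns give `NA` correlation markers, never silent
  zeros; constant edges are skipped with a flag in mass fits.
* Degenerate windows (zero weighted variance) yield `NA` features and must
  be resolved before clustering.
* `bh_fdr()` refuses NA/NaN inputs so a family can never silently shrink.
* Permutation and bootstrap draws, k-means initializations and all
  generators run single-threaded from explicit seeds; identical seeds give
  bitwise-identical results regardless of machine worker configuration.
* Edge tables round-trip through CSV at 17 significant digits, i.e. exact
  double precision.
* Top-edge listings order by ascending p with ties broken by ascending
  edge index.

## Problem sizes used for validation

The packaged validation suite exercises the pipeline at the following
scales, chosen to make each property measurable with comfortable
Monte-Carlo margins: null and planted-recovery discovery runs use
53-component cohorts of 2000 subjects (50 and 20 seeds respectively;
planted effects 0.15 on 10 edges); elbow recovery uses 30-subject
three-state cohorts over 20 seeds; occupancy recovery and
coupling-sign tests use the full 306-subject dynamic default over 50
seeds. Module tests use smaller 6-10 component cohorts. The acceptance
script (`scripts/acceptance.R`) recomputes the same quantities from
scratch at these sizes.

## Known limitations

* OLS is used even for binary outcomes by default (matching the linear
  covariate-adjusted group comparison); no logistic alternative is fitted.
* The elbow criterion needs at least three candidate k values for a
  curvature; shorter ranges fall back to the minimum-ratio candidate.
* State matching against reference patterns is exhaustive over
  permutations and limited to k <= 8.
* Whole-scan statistics beyond occupancy (dwell times, transition counts)
  are out of scope.
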