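---
title: "Methods: thermogenic flexibility and thermal heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermogenic flexibility and thermal heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
data do and do not emulate, and the places where the design was genuinely
open and a choice had to be made.

## The scientific question

Phenotypic flexibility — the reversible adjustment of a trait within an
individual's lifetime — is predicted to be greatest in populations that
experience the most environmental variation. The pipeline tests this
prediction for thermogenic capacity in juncos, small temperate songbirds
that raise their maximal heat production (summit metabolism, M_sum) in the
cold. Three lines of evidence are combined: a field survey relating M_sum
to recent weather across taxa, a range-wide genotype–environment
association, and a common-garden acclimation experiment on populations
from climates differing in annual temperature range (BIO7, `T_range`).

## Respirometry: from trace to M_sum

A trial records excurrent O2 fraction at ~1 Hz while dry heliox
(21% O2 / 79% He) flows through the chamber at a constant measured rate,
with animal-free baseline segments before and after.

* **Drift model.** The effective incurrent fraction FiO2(t) is the linear
  interpolation, in time, between the mean pre- and post-baseline
  excurrent fractions (anchored at each segment's mean timestamp). Linear
  drift is the simplest model consistent with correcting slow sensor or
  supply drift; anything faster fails QC anyway.
* **VO2.** For a dry, CO2-scrubbed excurrent stream with flow measured
  downstream, `VO2 = flow · (FiO2(t) − FeO2(t)) / (1 − FiO2(t))`
  (ml O2 min⁻¹). Samples with FeO2 above the reference beyond a 5×10⁻⁴
  tolerance are physically impossible and are flagged out of the windows.
  An optional first-order washout ("instantaneous") correction advances
  FeO2 by `(V_eff/flow)·dFeO2/dt`; it is off by default because effective
  chamber volumes are rig-specific and rarely known precisely.
* **M_sum.** The highest mean VO2 over any contiguous 300-s window,
  computed on samples; ties break to the earliest window. This equals
  exhaustive window enumeration (property-tested).
* **QC.** A measurement passes when |baseline drift| ≤ `drift_max`
  (default 0.005 O2 fraction) and the flow CV ≤ `flow_cv_max` (default
  5%). These two defaults are package choices, not published constants —
  review them for any new instrument.

A small non-invariance is worth knowing: adding a constant offset to FeO2
and both baselines cancels exactly in the depletion numerator but not in
the `1/(1 − FiO2)` denominator, so M_sum shifts by about 0.25% per 0.002
of offset. The drift correction is therefore "absorbing" to first order
only.

## Acclimatization windows and standardization

Environmental predictors are means over the `k` days *strictly preceding*
capture (k = 7…14); the capture day itself is excluded — the phrase
"preceding capture" is taken literally, and dates are handled as plain
calendar dates. A missing day inside a window is an error, never silently
imputed. Daily temperature range is `tmax − tmin`. Continuous predictors
are standardized by two standard deviations (n−1 estimator), which puts
them on a scale comparable to binary predictors; the raw sd is retained so
slopes can be back-transformed.

## Field models and reaction norms

For each variable × window candidate the model is the Gaussian OLS fit
`M_sum = M_b + taxon × variable` (2-SD standardized continuous
predictors, taxon a factor with the widespread *oreganus* group as
reference when present). Candidates, plus window-free elevation and the
null `M_b + taxon`, are ranked by AIC with the Gaussian constant included
and the residual variance counted as a parameter — the convention under
which printed AIC values of standard software are comparable.
Standardization happens on the complete-case subset actually fitted.

Per-taxon raw reaction norms (ml O2 min⁻¹ °C⁻¹) are
`(β_ref + β_interaction) / (2·sd_raw)`; back-transformation, rather than
per-taxon refitting, matches the reported units and is exactly equivalent
to stratified fits when no terms are shared (tested). The
flexibility-versus-heterogeneity step regresses these slopes on each
taxon's mean annual temperature range, averaged over *individuals'*
capture sites (individuals, not unique sites, are the weighting unit — a
deliberate, documented choice).

## Genotype–environment association

Sites are filtered in pipeline order: mean depth < 5 or > 50, minor allele
count < 3, site missingness > 50%, individuals > 60% missing, site
missingness > 5% (recomputed), and a Hardy–Weinberg exact test per species
at p < 0.001 — a site is removed if it fails in *any* species, the
conservative reading of "assessed by species". The HWE test is the exact
conditional enumeration over heterozygote counts. Missing genotypes are
imputed with the species-modal genotype; modal ties break to the lower
dosage code (deterministic, counted).

The genotype matrix is column-centered but **not** variance-scaled for PCA
and RDA (scaling is exposed as a flag; the default keeps common variants
at their natural weight, and the original analysis does not state
scaling). The partial RDA residualizes both genotypes and climate on the
conditioning variables (PC1–PC2 plus intercept), fits the multivariate
least squares, and takes constrained axes from the SVD of the fitted
values. Raw fractions (conditional, constrained, residual) sum to one;
adjusted fractions use the Ezekiel correction, with the conditioned
fraction computed as `adjR²(X∪C) − adjR²(C)` — the same convention as
standard variance-partitioning software, against which the implementation
is cross-checked in the tests.

Permutation tests permute rows of the residualized climate matrix,
re-residualize the permuted copy on the conditioning variables (without
this re-projection the permuted design retains a component inside the
conditioning space that explains exactly zero of the conditioned
response, deflating the permuted F distribution and grossly inflating
rejections), and use the add-one convention
`(count ≥ observed + 1)/(n_perm + 1)` (999 model / 299 axis permutations
by default). Axis tests are sequential: each axis is tested against the
residual after absorbing the preceding axes into the conditioning set.

One inferential caveat deserves emphasis. The permutation argument is
exact for a *label-invariant* null: individuals exchangeable and climate
unrelated to genotype. When neutral population structure extends beyond
the conditioned axes — with five populations, PC1–PC2 span only half of
the between-population space — any population-level climate variable
genuinely explains some of the remaining neutral differentiation, and the
model test rejects. That is correct detection of association, but it is
association with *structure*, not necessarily with selection; it is the
same reason conditioning on PCs is described as a partial correction in
the GEA literature. The package's size checks therefore run under
panmixia, and significant results on structured data should be read
jointly with the variance partition (which variable dominates) rather
than as evidence of adaptation per se.

Variance partitioning defaults to **marginal** fractions — each variable
alone, conditioned on the PCs — because per-variable values that sum to
less than the constrained total under collinearity match the structure of
the reported per-variable table; unique (leave-one-out) fractions are the
alternative mode. Which decomposition the original analysis used is not
stated; both are provided.

F_ST is the Weir–Cockerham variance-components estimator with the
weighted (ratio-of-sums) combination across loci; sites monomorphic
across the populations compared contribute zero components. Collinearity
screens: greedy pruning of |r| ≥ 0.70 pairs (dropping the member with the
higher mean |r|) and a VIF < 5 guard inside the RDA.

## Distance comparisons

Genetic distance is `θ/(1−θ)`; environmental distance is the Euclidean
norm over the 2-SD-standardized retained climate variables; geographic
distance is haversine on a sphere of radius 6371.0088 km (ellipsoidal
refinements are far below the noise at inter-population scales). The
partial Mantel statistic is the Pearson correlation of the off-diagonal
residuals of A|C and B|C; significance permutes object labels of the
first matrix, one-sided on the upper tail with the add-one convention.
The tail convention and permutation target are not stated in the original
report; these defaults are documented and the r statistic is symmetric in
its first two arguments (tested).

## The acclimation mixed model

The focal model is
`ΔM_sum = β0 + β_mb·z(M_b) + β_t·cold + β_tr·z(T_range) + β_int·cold·z(T_range) + u_pop + ε`
with 2-SD standardized continuous predictors and treatment coded
control = 0, cold = 1. How pairwise F_ST should enter as a "random
effect" is the central modelling gap: the implementation uses a
population-level Gaussian effect with correlation `1 − θ` (similarity
declining in differentiation), projected to the nearest PSD matrix by
eigenvalue clipping with the diagonal renormalized to one. An alternative
interpretation — a Gaussian kernel `exp(−d/λ)` on linearized F_ST — is
available behind a flag. Both are interpretations, and results should be
read with that in mind.

The sampler is a conjugate Gibbs scheme: a joint multivariate-normal
block draw for (β, u) and inverse-gamma draws for both variances. Priors
default to N(0, 10⁸) on fixed effects and IG(0.001, 0.001) on variances —
weakly-informative stand-ins for the "default priors" of standard MCMC
mixed-model software, and configurable. The default schedule is 1,000,000
iterations, 10,000 burn-in, thinning 100; 10⁵ iterations give
indistinguishable summaries on these problem sizes and are used in the
tests. pMCMC is `2·min(Pr(β>0), Pr(β<0))` floored at one over the number
of retained samples; an autocorrelation-based effective sample size is
reported per parameter, and divergent variance draws are capped and
counted rather than propagated. With the random effect switched off and
diffuse priors the posterior collapses onto the closed-form Bayesian
regression posterior, which is the oracle used in the tests.

CVs of flexibility are `100·sd/mean` within population (cold and control
groups separately) and are regressed on `T_range`; the control-group
pre/post comparison is a two-sided paired t-test.

## What the synthetic data emulate — and what they do not

The generator module produces every input with known truth, under one
master seed (sub-seeds derived deterministically; identical configs give
byte-identical outputs).

* **Traces**: ramp–plateau–decline VO2 profiles inverted through the VO2
  equation onto a drifting baseline with Gaussian sensor noise (defaults:
  0.05 %O2 h⁻¹ drift, 5×10⁻⁴ noise sd, 500 ml min⁻¹ flow, plateau longer
  than the averaging window so the planted M_sum is exactly the
  drift-free window maximum).
* **Weather**: seasonal sinusoid for the daily midpoint, a separately
  modulated daily range, and plausible covarying precipitation, vapor
  pressure, radiation and daylength. The day-to-day sd of the daily range
  (4.5 °C, within the continental range) is what makes adjacent
  acclimatization windows statistically distinguishable: window means of
  length k and k+1 share all their seasonal and site variance and differ
  only through day-level noise, so too-smooth weather would make the
  planted 8-day window unidentifiable at any realistic sample size. No
  spatial autocorrelation, no weather extremes.
* **Field survey**: 5 taxa × 100 individuals across 4 sites each, capture
  dates spread over the year; M_sum built from the 8-day window of daily
  temperature range with per-taxon slopes 0.10–0.27 ml O2 min⁻¹ °C⁻¹,
  collinear with taxon T_range, mass effect 0.5 ml O2 min⁻¹ g⁻¹, residual
  sd 0.8. These magnitudes were chosen once to reproduce the reported
  effect scale (standardized daily-range effect near 2 per 2 SD and model
  R² near 0.5); the paper does not state raw slopes or residual
  variances, so those remain free, documented parameters — not claims
  about the study.
* **Genotypes**: a two-level Balding–Nichols hierarchy. A flat island
  model puts the planted environmental cline into the leading principal
  components, which the partial RDA then conditions away — a structure
  unlike the real radiation, whose deepest splits are phylogeographic
  rather than climatic. Lineage splits (3 lineages, interleaved across
  the gradient, carrying 60% of the total differentiation) reproduce the
  intended situation: PC1–PC2 capture lineages, while the cline — planted
  logit-linearly at 5% of loci with 0.8 logits per SD of the site
  variable — survives conditioning. Total differentiation still equals
  the F_ST target (the two levels compose as `(1−F) = (1−F_L)(1−F_W)`).
  Climate is drawn at the locality level (4 localities per population)
  under the pairwise-|r| < 0.70 and VIF < 5 constraints a pruned variable
  set satisfies, mirroring specimen-level climate extraction. No linkage
  disequilibrium, no isolation-by-distance, no migration dynamics.
* **Acclimation**: 5 populations spanning 21 °C of T_range, 10 birds per
  population per treatment, with the reported standardized effect sizes
  planted (mass 0.53, cold 0.62, interaction 0.60 per 2 SD) and the cold
  group's residual sd decreasing log-linearly in T_range (slope −0.8 per
  2 SD), planting the negative CV–T_range relationship. The generator
  deliberately does **not** plant a mass–T_range correlation: layering it
  on top of the planted fixed effects drives the cold-group mean change
  toward zero in the least variable populations, where the CV (a ratio
  statistic) becomes sign-unstable and the planted prediction is no
  longer identifiable at these sample sizes. The parameter exists
  (`mass_trange_beta`) for exploring exactly that fragility.

Passing tests on these data show the estimators recover what was planted
under the stated noise — they do not certify behavior under real-data
pathologies (instrument artifacts, relatedness within populations,
linkage, spatially structured climate error).

## Numerical choices and degenerate inputs

Window means are computed by cumulative sums (ties to the earliest
window); the genotype PCA and RDA run on SVDs with rank tolerance 10⁻⁹;
permutation p-values always include the observed statistic (+1
convention); the Gibbs sampler regularizes a singular similarity matrix
by flooring eigenvalues at 10⁻⁸ of the largest before inversion; CV is
undefined (NA, with a warning) when the mean is numerically zero;
single-population F_ST is NA with a warning; a constant vector cannot be
2-SD standardized (error); a monomorphic site has HWE p = 1.

## Problem sizes

The shipped configuration — 2,000 loci × 100 individuals, 500 field
birds, 100 acclimation birds, 999/299 permutations, 10⁵–10⁶ MCMC
iterations — was chosen so a full run and the test suite execute
comfortably on a single CPU while keeping every recovery property
comfortably powered; all sizes scale through `sim_config()` and the
pipeline configuration.

## Known limitations

The F_ST-to-covariance construction is an interpretation (two are
offered); the field models are fixed-effects only (no spatial or
repeated-measures structure, matching the single-measure field design);
the respirometry stage does not parse proprietary acquisition formats;
and the synthetic calibration cannot validate the unpublished constants
of the original trace-processing scripts — the drift and window contracts
here are the documented stand-in.
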