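# thermoflex

Does the amount of temperature variation a population experiences predict
how *flexible* its physiology is? `thermoflex` implements a complete,
tested analysis pipeline for that question in juncos (*Junco* spp.), small
temperate songbirds that raise their summit metabolism — the maximal
cold-induced oxygen-consumption rate, M_sum — when it gets cold. The
package is aimed at ecophysiologists and evolutionary biologists who work
with respirometry, SNP, and acclimation-experiment data, and at anyone who
wants a fully synthetic, ground-truthed testbed for this class of
landscape-physiology analysis.

The pipeline has six stages, each exposed as ordinary R functions and
driven by the numbered scripts in `analysis/`:

1. **Synthetic data** (`sim_config()`, `gen_*()`) — generates every input
   with known truth: respirometry traces with a planted M_sum, daily
   weather with a seasonal cycle, hierarchical island-model genotypes with
   an allele-frequency cline in annual temperature range, and an
   acclimation experiment with a planted treatment × T_range interaction.
2. **Respirometry** (`process_trace()`) — drift-corrects each trace
   between bracketing baselines, computes
   VO₂ = flow · (FiO₂(t) − FeO₂(t)) / (1 − FiO₂(t)), extracts M_sum as the
   highest 5-min mean, and applies drift/flow QC.
3. **Environmental windows** (`build_env_features()`,
   `standardize_2sd()`) — per-individual means of each weather variable
   over the 7–14 days preceding capture, plus T_d_range = Tmax − Tmin.
4. **Field models** (`select_model()`, `reaction_norm_slopes()`) — ranks
   M_sum = M_b + taxon × variable candidates by AIC, back-transforms the
   winning model's taxon reaction norms to ml O₂ min⁻¹ °C⁻¹, and
   regresses them on each taxon's mean annual temperature range (BIO7).
5. **Population genomics** (`filter_sites()`, `partial_rda()`,
   `variance_partition()`, `weir_fst_pairwise()`, `partial_mantel()`) —
   SNP filtering, species-modal imputation, genotype PCA, a partial
   redundancy analysis conditioned on PC1–PC2 with permutation tests,
   per-variable variance partitioning, weighted Weir–Cockerham F_ST, and
   genetic/environmental/geographic distance comparisons.
6. **Acclimation** (`fit_delta_model()`, `gibbs_lmm()`, `cv_vs_trange()`)
   — a Gibbs-sampled Bayesian linear mixed model of thermogenic
   flexibility ΔM_sum (post- minus pre-acclimation) with an F_ST-derived
   population covariance, plus the CV-of-flexibility regression and the
   control-group paired t-test.

The methods vignette (`vignettes/thermogenic-flexibility.Rmd`) documents
the models, the tunable parameters and their defaults, and the design
decisions in detail.

## Worked example

Generate a full synthetic study and run it end to end:

```r
library(thermoflex)
res <- run_pipeline(list(seed = 1), out_dir = "results/run1")
```

or stage by stage:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_respirometry.R
Rscript analysis/03_field_models.R
Rscript analysis/04_popgen_gea.R
Rscript analysis/05_distance_tests.R
Rscript analysis/06_acclimation.R
```

With the default configuration (seed 1) the drivers print, among other
things:

```
M_sum mean = 7.022 ml O2/min; max |error| vs planted 7.0 = 1.03%
best candidate: t_d_range (8-day window); R2 = 0.733, AIC = 1202.1
Delta-AIC dropping the taxon interaction: 26.7; adding season: 1.43
flexibility ~ annual temperature range: R2 = 0.91, beta = 0.00794 ml O2/min/degC per degC, p = 0.011, n = 5
PC1+PC2 explain 7.4% of genetic variance
  constrained: 0.09937 raw / 0.02559 adjusted R2
model p = 0.001; axis p: 0.00333 0.00333 0.0367 0.753
top climate variable: bio7 (annual temperature range planted as causal)
partial Mantel (genetic ~ environment | geography): r = 0.07, p = 0.422, n = 5
 cold:trange_std 0.559  0.273 0.843 0.000101 9900
CV ~ T_range (cold): beta = -6.24 %/degC, R2 = 0.82, p = 0.035, n = 5
```

Reading these: the trace processor recovers the planted summit metabolism
to ~1%; model selection identifies exactly the planted predictor (daily
temperature range averaged over the 8 days before capture) and the taxon ×
environment interaction it was generated with; taxon reaction norms
increase with native annual temperature range (R² = 0.91 against a planted
perfectly collinear design); the partial RDA finds the planted
annual-temperature-range cline on top of lineage structure (bio7 ranks
first in the variance partition, model p = 0.001); and the acclimation
mixed model recovers the planted cold × T_range interaction (posterior
mean 0.56 for a planted 0.60, pMCMC < 0.001), with the cold group's CV of
flexibility declining in T_range as planted.

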