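#!/usr/bin/env Rscript
# Stage 3 -- field acclimatization analysis: build per-individual
# environmental predictors over 7-14-day windows preceding capture, rank
# every variable x window candidate of M_sum = M_b + taxon x variable by
# AIC, back-transform the winning model's taxon reaction norms to raw
# slopes, and regress those slopes on each taxon's mean annual temperature
# range.

library(thermoflex)

pheno <- read.csv("results/data/pheno_field.csv")
pheno$date <- as.Date(pheno$date)
weather <- read.csv("results/data/weather.csv")
weather$date <- as.Date(weather$date)
sites <- read.csv("results/data/sites_field.csv")

env <- build_env_features(pheno, weather, windows = 7:14, sites = sites)
sel <- select_model(pheno, env, windows = 7:14)
write.csv(sel$ranking, "results/field_ranking.csv", row.names = FALSE)

best <- sel$best
message("best candidate: ", best$variable,
        if (!is.na(best$window)) paste0(" (", best$window, "-day window)"),
        "; R2 = ", round(best$r2, 3), ", AIC = ", round(best$aic, 1))
message("Delta-AIC dropping the taxon interaction: ",
        round(sel$delta_aic_interaction, 1),
        "; adding season: ", round(sel$delta_aic_season, 2))

norms <- reaction_norm_slopes(best)
write.csv(norms, "results/reaction_norms.csv", row.names = FALSE)
print(norms)

trange <- taxon_mean_trange(pheno, sites)
flex <- flexibility_vs_heterogeneity(norms, trange)
message("flexibility ~ annual temperature range: R2 = ",
        round(flex$r2, 2), ", beta = ", signif(flex$beta, 3),
        " ml O2/min/degC per degC, p = ", signif(flex$p, 2),
        ", n = ", flex$n)
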