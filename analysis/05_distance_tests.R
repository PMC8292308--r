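#!/usr/bin/env Rscript
# Stage 5 -- do environmental and genetic distances covary once geography
# is controlled?  Build pairwise Weir-Cockerham F_ST (linearized as
# theta/(1-theta)), Euclidean climate distance over the pruned variable
# set, and great-circle geographic distance, then run the partial Mantel
# test of genetic vs environmental distance conditioned on geography.

library(thermoflex)

SEED <- as.integer(Sys.getenv("THERMOFLEX_SEED", "1"))
popmap <- read.csv("results/data/popmap.csv")
g <- read_geno_vcf("results/data/genotypes.vcf", popmap = popmap)
bio <- read.csv("results/data/bioclim.csv")
coords <- read.csv("results/data/pop_coords.csv")

gi <- impute_major(filter_sites(g)$geno)
fst <- weir_fst_pairwise(gi)
write.csv(data.frame(pop = rownames(fst$theta), fst$theta),
          "results/fst.csv", row.names = FALSE)
print(fst)

gen_d <- linearize_fst(fst)
clim_vars <- c("bio2", "bio7", "bio8", "bio9", "bio10", "bio14", "bio18",
               "bio19")
pop_bio <- aggregate(bio[, clim_vars],
                     list(site = sub("_L\\d+$", "", bio$site)), mean)
keep <- correlation_prune(pop_bio[, clim_vars], r_max = 0.70)$keep
message("retained climate variables for environmental distance: ",
        paste(keep, collapse = ", "))
env_d <- env_distance(pop_bio, keep)
geo_d <- geodesic_distance(coords)

mant <- partial_mantel(gen_d, env_d, geo_d, n_perm = 999, seed = SEED + 13)
jsonlite::write_json(mant, "results/mantel.json", auto_unbox = TRUE,
                     digits = NA)
message("partial Mantel (genetic ~ environment | geography): r = ",
        round(mant$r, 2), ", p = ", mant$p, ", n = ", mant$n)
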