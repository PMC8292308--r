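#!/usr/bin/env Rscript
# Stage 1 -- generate every synthetic input the downstream analyses consume:
# respirometry traces with a known summit metabolic rate, a multi-site field
# survey with planted taxon reaction norms, hierarchical island-model
# genotypes with an allele-frequency cline in annual temperature range, a
# locality-level climate table, and a common-garden acclimation experiment
# with a planted treatment x T_range interaction.
#
# Outputs go to results/data/.  Change SEED to regenerate a different draw
# of the same study design.

library(thermoflex)

SEED <- as.integer(Sys.getenv("THERMOFLEX_SEED", "1"))
out <- "results/data"
dir.create(file.path(out, "traces"), showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = SEED)
print(cfg)

for (i in 1:20)
  write_trace(gen_resp_trace(cfg, seed_offset = i),
              file.path(out, "traces", sprintf("trace%03d.csv", i)))
message("wrote 20 traces (true M_sum = ", cfg$trace$true_msum, " ml O2/min)")

fd <- gen_field_dataset(cfg)
write.csv(fd$pheno, file.path(out, "pheno_field.csv"), row.names = FALSE)
write.csv(fd$weather, file.path(out, "weather.csv"), row.names = FALSE)
write.csv(fd$sites, file.path(out, "sites_field.csv"), row.names = FALSE)
message("field survey: ", nrow(fd$pheno), " individuals, ",
        length(unique(fd$pheno$site)), " sites; planted slopes ",
        paste(round(fd$truth$slopes, 3), collapse = "/"))

gea <- gen_gea_dataset(cfg)
write_geno_vcf(gea$geno, file.path(out, "genotypes.vcf"))
write.csv(gea$bioclim, file.path(out, "bioclim.csv"), row.names = FALSE)
write.csv(data.frame(id = rownames(gea$geno$geno),
                     pop = as.character(gea$geno$pop),
                     species = as.character(gea$geno$species),
                     locality = gea$locality),
          file.path(out, "popmap.csv"), row.names = FALSE)
write.csv(gea$geno$coords, file.path(out, "pop_coords.csv"),
          row.names = FALSE)
message("genotypes: ", nrow(gea$geno$geno), " individuals x ",
        ncol(gea$geno$geno), " loci (", length(gea$truth$adaptive),
        " adaptive)")

acc <- gen_acclimation_dataset(cfg)
write.csv(acc$records, file.path(out, "acclimation.csv"), row.names = FALSE)
write.csv(data.frame(pop = rownames(acc$fst), acc$fst),
          file.path(out, "fst_true.csv"), row.names = FALSE)
message("acclimation: ", nrow(acc$records),
        " individuals; planted interaction = ", acc$truth$beta_int)
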