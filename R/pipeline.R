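default_run_config <- function() {
  list(
    seed = 1L,
    n_traces = 20L,
    stages = list(simulate = TRUE, respirometry = TRUE, field = TRUE,
                  gea = TRUE, distances = TRUE, acclimation = TRUE),
    thresholds = list(drift_max = 0.005, flow_cv_max = 0.05,
                      r_max = 0.70, vif_max = 5),
    windows = 7:14,
    filter = list(min_mean_dp = 5, max_mean_dp = 50, mac = 3,
                  max_missing1 = 0.5, ind_missing_max = 0.6,
                  max_missing2 = 0.05, hwe_p = 0.001),
    perm = list(model = 999, axes = 299, mantel = 999),
    mcmc = list(n_iter = 1e5, burn_in = 1e4, thin = 50),
    sim = list()
  )
}

merge_config <- function(defaults, user, path = "") {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop_tf("unknown config key(s): %s",
            paste(paste0(path, bad), collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !identical(nm, "sim")) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

log_line <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' Run the full synthetic-to-results pipeline
#'
#' Configuration-driven orchestration of every stage: synthetic-data
#' generation, respirometry processing, field model selection, the
#' genotype-environment association (filtering, imputation, PCA, partial
#' RDA with permutation tests and variance partitioning), distance-matrix
#' comparisons (F_ST linearization, environmental and geodesic distances,
#' partial Mantel) and the acclimation mixed-model analysis.  Every stage
#' writes CSV/JSON outputs under `out_dir` and a `manifest.json` records
#' the configuration, seeds, per-stage timings and the MD5 checksum of
#' every output file; rerunning with an identical configuration reproduces
#' identical checksums.
#'
#' @param config nested list overriding the defaults (unknown keys are
#'   rejected), or the path of a YAML file holding such a list.  Keys:
#'   `seed`, `n_traces`, `stages` (logical toggles), `thresholds`
#'   (`drift_max`, `flow_cv_max`, `r_max`, `vif_max`), `windows`,
#'   `filter` (site-filter parameters), `perm` (permutation counts),
#'   `mcmc` (sampler schedule), `sim` (overrides forwarded to
#'   [sim_config()]).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with each stage's in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- proc.time()[3]
  timings <- list()
  res <- list(config = cfg)
  sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))

  stage <- function(name, code) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    log_line(quiet, "[%s] starting", name)
    t0 <- proc.time()[3]
    out <- force(code)
    timings[[name]] <<- round(proc.time()[3] - t0, 2)
    log_line(quiet, "[%s] done in %.1fs", name, timings[[name]])
    out
  }

  res$simulate <- stage("simulate", {
    tr_dir <- file.path(out_dir, "traces")
    dir.create(tr_dir, showWarnings = FALSE)
    for (i in seq_len(cfg$n_traces))
      write_trace(gen_resp_trace(sim, seed_offset = i),
                  file.path(tr_dir, sprintf("trace%03d.csv", i)))
    field <- gen_field_dataset(sim)
    write.csv(field$pheno, file.path(out_dir, "pheno_field.csv"),
              row.names = FALSE)
    write.csv(field$weather, file.path(out_dir, "weather.csv"),
              row.names = FALSE)
    write.csv(field$sites, file.path(out_dir, "sites_field.csv"),
              row.names = FALSE)
    acc <- gen_acclimation_dataset(sim)
    write.csv(acc$records, file.path(out_dir, "acclimation.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(acc$fst), file.path(out_dir, "fst_true.csv"))
    gea <- gen_gea_dataset(sim, r_max = cfg$thresholds$r_max,
                           vif_max = cfg$thresholds$vif_max)
    write_geno_vcf(gea$geno, file.path(out_dir, "genotypes.vcf"))
    write.csv(gea$bioclim, file.path(out_dir, "bioclim.csv"),
              row.names = FALSE)
    write.csv(data.frame(id = rownames(gea$geno$geno),
                         pop = as.character(gea$geno$pop),
                         locality = gea$locality),
              file.path(out_dir, "popmap.csv"), row.names = FALSE)
    list(field = field, acc = acc, gea = gea)
  })

  res$respirometry <- stage("respirometry", {
    tab <- process_trace_dir(file.path(out_dir, "traces"),
                             drift_max = cfg$thresholds$drift_max,
                             flow_cv_max = cfg$thresholds$flow_cv_max)
    write.csv(tab, file.path(out_dir, "msum.csv"), row.names = FALSE)
    tab
  })

  res$field <- stage("field", {
    fd <- res$simulate$field
    env <- build_env_features(fd$pheno, fd$weather, windows = cfg$windows,
                              sites = fd$sites)
    sel <- select_model(fd$pheno, env, windows = cfg$windows)
    norms <- reaction_norm_slopes(sel$best)
    trange <- taxon_mean_trange(fd$pheno, fd$sites)
    flex <- flexibility_vs_heterogeneity(norms, trange)
    write.csv(sel$ranking, file.path(out_dir, "field_ranking.csv"),
              row.names = FALSE)
    write.csv(norms, file.path(out_dir, "reaction_norms.csv"),
              row.names = FALSE)
    list(env = env, selection = sel, norms = norms, trange = trange,
         flex = flex)
  })

  res$gea <- stage("gea", {
    gea_in <- res$simulate$gea
    bio <- gea_in$bioclim
    filt <- do.call(filter_sites, c(list(gea_in$geno), cfg$filter))
    write.csv(filt$report, file.path(out_dir, "filter_report.csv"),
              row.names = FALSE)
    gimp <- impute_major(filt$geno)
    pca <- pca_genotypes(gimp, n_axes = 4)
    write.csv(data.frame(id = rownames(pca$scores), pca$scores),
              file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    loc <- gea_in$locality[match(rownames(gimp$geno),
                                 rownames(gea_in$geno$geno))]
    idx <- match(loc, bio$site)
    clim <- sapply(gea_in$clim_vars,
                   function(v) standardize_2sd(bio[[v]][idx]))
    rda <- partial_rda(gimp$geno, clim, condition = pca$scores[, 1:2],
                       vif_max = cfg$thresholds$vif_max)
    perm <- permutation_anova(rda, n_perm_model = cfg$perm$model,
                              n_perm_axis = cfg$perm$axes,
                              seed = cfg$seed + 11)
    vp <- variance_partition(gimp$geno, clim, condition = pca$scores[, 1:2])
    write.csv(vp, file.path(out_dir, "variance_partition.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(adj_r2_constrained = rda$adj_r2_constrained,
           adj_r2_conditional = rda$adj_r2_conditional,
           pseudo_f = rda$pseudo_f, p_model = perm$p_model,
           p_axis = as.list(perm$p_axis)),
      file.path(out_dir, "rda_summary.json"), auto_unbox = TRUE, digits = NA)
    list(filter = filt, pca = pca, rda = rda, perm = perm, varpart = vp,
         geno_imputed = gimp, clim = clim)
  })

  res$distances <- stage("distances", {
    gea_in <- res$simulate$gea
    gimp <- res$gea$geno_imputed %||% gea_in$geno
    fst <- weir_fst_pairwise(gimp)
    gen_d <- linearize_fst(fst)
    # population-level climate: mean of each population's locality values
    bio <- gea_in$bioclim
    pop_of_loc <- sub("_L\\d+$", "", bio$site)
    pop_bio <- aggregate(bio[, gea_in$clim_vars], list(site = pop_of_loc),
                         mean)
    keep <- correlation_prune(pop_bio[, gea_in$clim_vars],
                              r_max = cfg$thresholds$r_max)$keep
    env_d <- env_distance(pop_bio, keep)
    geo_d <- geodesic_distance(gea_in$geno$coords)
    mant <- partial_mantel(gen_d, env_d, geo_d, n_perm = cfg$perm$mantel,
                           seed = cfg$seed + 13)
    write.csv(as.data.frame(fst$theta), file.path(out_dir, "fst.csv"))
    jsonlite::write_json(mant, file.path(out_dir, "mantel.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fst = fst, mantel = mant, gen_d = gen_d, env_d = env_d,
         geo_d = geo_d)
  })

  res$acclimation <- stage("acclimation", {
    acc <- res$simulate$acc
    post <- fit_delta_model(acc$records, acc$fst,
                            n_iter = cfg$mcmc$n_iter,
                            burn_in = cfg$mcmc$burn_in,
                            thin = cfg$mcmc$thin, seed = cfg$seed + 17)
    write.csv(post$fixed, file.path(out_dir, "delta_model_posterior.csv"),
              row.names = FALSE)
    r <- acc$records
    r$delta <- r$post_msum - r$pre_msum
    cv_tab <- do.call(rbind, lapply(split(r, list(r$population, r$treatment)),
      function(d) data.frame(population = d$population[1],
                             treatment = d$treatment[1],
                             trange = d$trange[1],
                             cv = cv_percent(d$delta))))
    cold <- cv_tab[cv_tab$treatment == "cold", ]
    ctrl <- cv_tab[cv_tab$treatment == "control", ]
    cvreg <- cv_vs_trange(cold$cv, cold$trange)
    cvreg_ctrl <- cv_vs_trange(ctrl$cv, ctrl$trange)
    ctrl_rows <- r[r$treatment == "control", ]
    tt <- paired_ttest(ctrl_rows$pre_msum, ctrl_rows$post_msum)
    write.csv(cv_tab, file.path(out_dir, "cv_table.csv"), row.names = FALSE)
    list(posterior = post, cv_table = cv_tab, cv_regression = cvreg,
         cv_regression_control = cvreg_ctrl, paired_t_control = tt)
  })

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("thermoflex")),
    seed = cfg$seed,
    config = cfg,
    timings_s = timings,
    total_s = round(proc.time()[3] - t_all, 2),
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
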