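# Reference-scale simulation-based calibration experiment for the land-use
# effect: 150 species, 80 clusters x 3 points, 4 visits. Occupancy is
# generated from intercept + land use + species intercepts + species
# land-use slopes; detection from an intercept + species intercepts
# (p about 0.5), and the same model is refitted by MAP + short chains.
recovery_replicate <- function(rep_seed, n_species = 150, n_clusters = 80,
                               chains = 2, warmup = 150, iter = 250,
                               beta_lu = 1.0) {
  L <- make_landscape(extent_km = c(60, 60), seed = rep_seed)
  pool <- make_species_pool(L, n_species = n_species, n_families = 30,
                            traits = list(binary = NULL, continuous = NULL),
                            seed = rep_seed + 1)
  des <- make_sampling_design(L, n_clusters = n_clusters,
                              seed = rep_seed + 2)
  p <- default_occ_params(pool)
  p$intercept <- -0.5; p$land_use <- beta_lu
  p$elev[] <- 0; p$elev_lowland[] <- 0; p$d2r_scale <- 0
  p$sd_species <- 1; p$sd_sp_lu <- 0.75
  p$sd_family <- 0; p$sd_sp_elev <- 0; p$sd_fam_lu <- 0
  p$sd_sp_cluster <- 0; p$sd_sp_subregion <- 0
  tr <- simulate_truth(L, pool, des, params = p, seed = rep_seed + 3)
  dp <- default_det_params(pool, des$n_observers)
  dp$intercept <- 0; dp$observer[] <- 0; dp$time <- 0; dp$land_use <- 0
  for (nm in grep("^sd_", names(dp), value = TRUE)) dp[[nm]] <- 0
  dp$sd_species <- 0.5
  det <- simulate_detections(tr, des, pool, det_params = dp,
                             seed = rep_seed + 4)
  spec <- msom_model_spec(occ_terms = "land_use",
                          occ_re = c("species", "sp_lu"),
                          det_terms = character(0), det_re = "species")
  fit <- suppressWarnings(
    fit_occupancy(det, tr$features, pool, des, spec = spec,
                  method = "mcmc", chains = chains, warmup = warmup,
                  iter = iter, seed = rep_seed))
  blu <- fit$draws[, "beta_occ[land_use]"]
  ci <- quantile(blu, c(0.05, 0.95))
  est <- colMeans(fit$draws[, grep("re_occ_sp_lu\\[",
                                   colnames(fit$draws))]) + mean(blu)
  list(covered = ci[1] <= beta_lu && beta_lu <= ci[2],
       rank_cor = cor(est, tr$re$w_lu_sp + beta_lu, method = "spearman"),
       ci = ci, mean = mean(blu))
}
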