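#' Predict posterior occupancy on the pixel grid
#'
#' Produces the occupancy cube: per posterior draw and per species, the
#' predicted occupancy probability of every landscape pixel under a
#' hypothetical all-forest and all-pasture scenario. For each pixel the
#' species-by-subregion effect is drawn once (shared across the pixel's
#' subregion) and the species-by-cluster effect is sampled
#' `n_cluster_samples` times (default 16, one per 500-m sub-cell of a 2-km
#' pixel), inverse-logit transformed and averaged on the probability scale.
#' Species-pixel pairs failing biogeographic clipping get occupancy 0.
#'
#' @param fit an `msom_occfit`.
#' @param landscape,pool the landscape and species pool used for the fit.
#' @param pixel_ids optional subset of pixels to predict (default all).
#' @param draw_ids optional subset of stored draws (default all).
#' @param n_cluster_samples cluster-effect samples per pixel (default 16).
#' @param scenarios scenarios to predict, subset of c("forest", "pasture").
#' @param seed integer seed for the random-effect sampling.
#' @return an `msom_cube` [species, pixel, scenario, draw].
#' @export
predict_occupancy <- function(fit, landscape, pool, pixel_ids = NULL,
                              draw_ids = NULL, n_cluster_samples = 16,
                              scenarios = c("forest", "pasture"), seed = 1) {
  if (!all(scenarios %in% c("forest", "pasture")))
    stop("scenario must be 'forest' or 'pasture'")
  spec <- fit$model$spec
  px <- landscape$pixels
  if (!is.null(pixel_ids)) px <- px[px$pixel_id %in% pixel_ids, ]
  npx <- nrow(px)
  S <- nrow(pool$species)
  draws <- fit$draws
  if (is.null(draw_ids)) draw_ids <- seq_len(nrow(draws))
  D <- length(draw_ids)

  feats <- species_point_features(
    data.frame(point_id = px$pixel_id, x_km = px$x_km, y_km = px$y_km,
               elevation_m = px$elevation_m, pixel_id = px$pixel_id),
    pool, landscape)
  feats <- clip_pairs(feats, d2r_max_km = max(spec$d2r_limits),
                      elev_window = c(-3, 3))
  e <- matrix(feats$std_elevation, S, npx, byrow = TRUE)
  d2r <- matrix(feats$distance_to_range_km, S, npx, byrow = TRUE)
  retained <- matrix(feats$retained, S, npx, byrow = TRUE)
  kb <- d2r_bin(d2r, spec$d2r_limits, spec$d2r_n_bins)
  kb[!retained | is.na(kb)] <- 0L

  fam <- pool$species$family_id
  m <- ifelse(pool$species$lowland, 1, -1)
  tr <- pool$traits
  sub <- subregion_id(px$x_km, px$y_km, spec$subregion_km)
  nsub <- max(sub)

  cn <- colnames(draws)
  gv <- function(d, name, default = 0) {
    j <- match(name, cn)
    if (is.na(j)) default else draws[d, j]
  }
  gvec <- function(d, prefix, n) {
    j <- match(paste0(prefix, "[", seq_len(n), "]"), cn)
    out <- numeric(n)
    out[!is.na(j)] <- draws[d, j[!is.na(j)]]
    out
  }

  set.seed(child_seed(seed, 30))
  cube <- array(0, c(S, npx, length(scenarios), D))
  K <- spec$d2r_n_bins - 1L
  trait_names <- colnames(tr)
  for (di in seq_len(D)) {
    d <- draw_ids[di]
    u_sp <- gvec(d, "re_occ_species", S)
    u_fam <- gvec(d, "re_occ_family", max(fam))
    w_elev <- gvec(d, "re_occ_sp_elev", S)
    w_lu <- gvec(d, "re_occ_sp_lu", S)
    w_flu <- gvec(d, "re_occ_fam_lu", max(fam))
    sd_cl <- exp(gv(d, "log_sd_occ_sp_cluster", -Inf))
    sd_sub <- exp(gv(d, "log_sd_occ_sp_subregion", -Inf))
    if (!is.finite(sd_cl)) sd_cl <- 0
    if (!is.finite(sd_sub)) sd_sub <- 0

    b1 <- gv(d, "beta_occ[elev_linear]"); b2 <- gv(d, "beta_occ[elev_quad]")
    b1m <- gv(d, "beta_occ[elev_linear_lowland]")
    b2m <- gv(d, "beta_occ[elev_quad_lowland]")
    blu <- gv(d, "beta_occ[land_use]")
    b0 <- gv(d, "beta_occ[intercept]")
    bt <- sapply(trait_names, function(nm)
      gv(d, paste0("beta_occ[trait_", nm, "]")))
    blt <- sapply(trait_names, function(nm)
      gv(d, paste0("beta_occ[lu_trait_", nm, "]")))
    bd2r <- gv(d, "b_d2r")
    u_z <- gvec(d, "uzeta", max(K - 1, 0))
    zeta <- if (K > 0) {
      ez <- exp(c(u_z, 0)); ez / sum(ez)
    } else numeric(0)
    Qc <- c(0, cumsum(zeta))

    eta0 <- b0 + (b1 + b1m * m) * e + (b2 + b2m * m) * e^2 +
      u_sp + u_fam[fam] + w_elev * e
    if (K > 0) eta0 <- eta0 + bd2r * matrix(Qc[kb + 1], S, npx)
    if (length(trait_names) > 0) {
      eta0 <- eta0 + as.numeric(tr %*% bt)
      lu_tr <- as.numeric(tr %*% blt)
    } else lu_tr <- numeric(S)

    eps_sub <- matrix(rnorm(S * nsub, 0, sd_sub), S, nsub)
    for (sc in seq_along(scenarios)) {
      lu <- if (scenarios[sc] == "forest") 1 else -1
      eta <- eta0 + lu * (blu + w_lu + w_flu[fam] + lu_tr) +
        eps_sub[, sub, drop = FALSE]
      acc <- matrix(0, S, npx)
      for (r in seq_len(n_cluster_samples))
        acc <- acc + plogis(eta + matrix(rnorm(S * npx, 0, sd_cl), S, npx))
      psi <- acc / n_cluster_samples
      psi[!retained] <- 0
      cube[, , sc, di] <- psi
    }
  }
  dimnames(cube) <- list(NULL, NULL, scenarios, NULL)
  attr(cube, "pixel_info") <- px
  class(cube) <- c("msom_cube", "array")
  cube
}
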