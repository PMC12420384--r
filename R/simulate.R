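#' Default occupancy-process parameters for the truth simulator
#'
#' Every coefficient of the occupancy linear predictor and every
#' random-effect standard deviation, on the logit scale. Binary predictors
#' (land use, the lowland elevation-curve modifier, binary traits) are coded
#' -1/+1 with forest = +1.
#'
#' @param pool an `msom_species_pool` (trait names are taken from it).
#' @return named list of generating parameters.
#' @export
default_occ_params <- function(pool) {
  tr <- colnames(pool$traits)
  list(
    intercept = -0.5,
    elev = c(linear = 0.3, quad = -1.2),
    elev_lowland = c(linear = 0.1, quad = 0.2),
    d2r_scale = -3, d2r_zeta = rep(1 / 7, 7), d2r_n_bins = 8,
    d2r_limits = c(-160, 160),
    land_use = 0.6,
    traits = setNames(rep(0, length(tr)), tr),
    land_use_traits = setNames(
      ifelse(tr == "forest_dependent", 0.8, 0), tr),
    sd_species = 1, sd_family = 0.5, sd_sp_elev = 0.4, sd_sp_lu = 0.5,
    sd_fam_lu = 0.3, sd_sp_cluster = 0.7, sd_sp_subregion = 0.7
  )
}

#' Default detection-process parameters
#'
#' @param pool an `msom_species_pool`.
#' @param n_observers number of observers in the design.
#' @return named list of generating parameters (logit scale).
#' @export
default_det_params <- function(pool, n_observers = 3) {
  tr <- colnames(pool$traits)
  obs <- rnorm(n_observers, 0, 0.3)
  list(
    intercept = -0.3,
    observer = obs - mean(obs),
    time = -0.2,
    land_use = 0.1,
    traits = setNames(rep(0, length(tr)), tr),
    sd_species = 0.8, sd_family = 0.4, sd_sp_observer = 0.2,
    sd_sp_time = 0.2, sd_sp_lu = 0.3, sd_fam_lu = 0.2
  )
}

check_params <- function(params, required, label) {
  missing <- setdiff(required, names(params))
  if (length(missing) > 0)
    stop(sprintf("missing %s parameter(s): %s", label,
                 paste(missing, collapse = ", ")))
}

lu_code <- function(land_use) ifelse(land_use == "forest", 1, -1)

#' Simulate latent occupancy truth
#'
#' Generates latent occupancy states for every retained species-point pair
#' under the occupancy model the package fits: logit occupancy is the sum of
#' an intercept, species-standardized elevation (linear and quadratic, with a
#' -1/+1 lowland modifier interacting with both terms), a monotonic
#' distance-to-range effect, a land-use effect, trait main effects, land-use
#' x trait interactions, species and family random intercepts, species
#' elevation slopes, species and family land-use slopes, and species-by-
#' cluster and species-by-subregion random intercepts. Latent presence z is
#' Bernoulli(psi), independent across pairs.
#'
#' @param landscape an `msom_landscape`.
#' @param pool an `msom_species_pool`.
#' @param design an `msom_design`.
#' @param params occupancy parameters, see [default_occ_params()]; missing
#'   coefficients raise an error naming the term.
#' @param seed integer seed.
#' @param subregion_km subregion blocking scale in km (default 20).
#' @return an object of class `msom_truth`: list with `pairs` (retained
#'   species-point pairs with psi_true and z), `features` (clipped feature
#'   table), the random-effect values, the generating `params`, and the
#'   point-level subregion assignment.
#' @export
simulate_truth <- function(landscape, pool, design, params = NULL, seed = 1,
                           subregion_km = 20) {
  if (is.null(params)) params <- default_occ_params(pool)
  check_params(params, c("intercept", "elev", "elev_lowland", "d2r_scale",
                         "d2r_zeta", "land_use", "traits", "land_use_traits",
                         "sd_species", "sd_family", "sd_sp_elev", "sd_sp_lu",
                         "sd_fam_lu", "sd_sp_cluster", "sd_sp_subregion"),
               "occupancy")
  pts <- design$points
  feats <- clip_pairs(species_point_features(pts, pool, landscape))
  pairs <- feats[feats$retained, c("species_id", "point_id",
                                   "distance_to_range_km", "std_elevation")]
  set.seed(child_seed(seed, 4))

  sp <- pool$species
  S <- nrow(sp); Fam <- max(sp$family_id)
  C <- nrow(design$clusters)
  sub_id <- subregion_id(pts$x_km, pts$y_km, subregion_km)
  R <- max(sub_id)
  re <- list(
    u_sp = rnorm(S, 0, params$sd_species),
    u_fam = rnorm(Fam, 0, params$sd_family),
    w_elev = rnorm(S, 0, params$sd_sp_elev),
    w_lu_sp = rnorm(S, 0, params$sd_sp_lu),
    w_lu_fam = rnorm(Fam, 0, params$sd_fam_lu),
    u_sp_cluster = matrix(rnorm(S * C, 0, params$sd_sp_cluster), S, C),
    u_sp_subregion = matrix(rnorm(S * R, 0, params$sd_sp_subregion), S, R)
  )

  pi_row <- match(pairs$point_id, pts$point_id)
  s <- pairs$species_id
  f <- sp$family_id[s]
  cl <- pts$cluster_id[pi_row]
  sr <- sub_id[pi_row]
  lu <- lu_code(pts$land_use[pi_row])
  e <- pairs$std_elevation
  m <- ifelse(sp$lowland[s], 1, -1)
  k <- d2r_bin(pairs$distance_to_range_km,
               params$d2r_limits %||% c(-160, 160),
               params$d2r_n_bins %||% 8)
  tr <- pool$traits[s, , drop = FALSE]
  bt <- params$traits[colnames(tr)]
  blt <- params$land_use_traits[colnames(tr)]
  if (anyNA(bt)) stop("missing occupancy parameter(s): traits for ",
                      paste(colnames(tr)[is.na(bt)], collapse = ", "))

  eta <- params$intercept +
    (params$elev["linear"] + params$elev_lowland["linear"] * m) * e +
    (params$elev["quad"] + params$elev_lowland["quad"] * m) * e^2 +
    monotonic_effect(k, params$d2r_scale, params$d2r_zeta) +
    params$land_use * lu +
    drop(tr %*% bt) + lu * drop(tr %*% blt) +
    re$u_sp[s] + re$u_fam[f] + re$w_elev[s] * e +
    re$w_lu_sp[s] * lu + re$w_lu_fam[f] * lu +
    re$u_sp_cluster[cbind(s, cl)] + re$u_sp_subregion[cbind(s, sr)]

  pairs$psi_true <- plogis(as.numeric(eta))
  pairs$z <- rbinom(nrow(pairs), 1, pairs$psi_true)
  structure(list(pairs = pairs, features = feats, re = re, params = params,
                 subregion = data.frame(point_id = pts$point_id,
                                        subregion_id = sub_id),
                 seed = seed),
            class = "msom_truth")
}

#' @export
print.msom_truth <- function(x, ...) {
  cat("msom_truth:", nrow(x$pairs), "retained species-point pairs;",
      "mean psi", round(mean(x$pairs$psi_true), 3), "\n")
  invisible(x)
}

#' Simulate detection histories
#'
#' Generates per-visit binary detections conditional on the latent truth:
#' a present species is detected with probability p from a logit-linear
#' detection model (observer effects, time-after-sunrise slope, land use,
#' species traits, and species / family / species-by-observer random
#' intercepts plus species time slopes and species and family land-use
#' slopes); an absent species is never detected.
#'
#' @param truth an `msom_truth`.
#' @param design the `msom_design` used to generate the truth.
#' @param pool the `msom_species_pool`.
#' @param det_params detection parameters, see [default_det_params()].
#' @param seed integer seed.
#' @return a data.frame (class `msom_detections`) with one row per retained
#'   species-point-visit: point_id, species_id, visit_index, y, observer_id,
#'   time_after_sunrise_h, land_use, plus attribute `p_true`.
#' @export
simulate_detections <- function(truth, design, pool, det_params = NULL,
                                seed = 1) {
  if (is.null(det_params)) {
    set.seed(child_seed(seed, 5))
    det_params <- default_det_params(pool, design$n_observers)
  }
  check_params(det_params, c("intercept", "observer", "time", "land_use",
                             "traits", "sd_species", "sd_family",
                             "sd_sp_observer", "sd_sp_time", "sd_sp_lu",
                             "sd_fam_lu"), "detection")
  if (!all(design$visits$point_id %in% design$points$point_id))
    stop("visit references unknown point")
  set.seed(child_seed(seed, 6))
  sp <- pool$species
  S <- nrow(sp); Fam <- max(sp$family_id); O <- design$n_observers
  re <- list(
    v_sp = rnorm(S, 0, det_params$sd_species),
    v_fam = rnorm(Fam, 0, det_params$sd_family),
    v_sp_obs = matrix(rnorm(S * O, 0, det_params$sd_sp_observer), S, O),
    w_time = rnorm(S, 0, det_params$sd_sp_time),
    w_lu_sp = rnorm(S, 0, det_params$sd_sp_lu),
    w_lu_fam = rnorm(Fam, 0, det_params$sd_fam_lu)
  )

  # long table: every retained pair x its visits
  visits <- design$visits
  vis_by_point <- split(seq_len(nrow(visits)), visits$point_id)
  idx <- rep(seq_len(nrow(truth$pairs)),
             lengths(vis_by_point[as.character(truth$pairs$point_id)]))
  vrow <- unlist(vis_by_point[as.character(truth$pairs$point_id)],
                 use.names = FALSE)
  s <- truth$pairs$species_id[idx]
  f <- sp$family_id[s]
  o <- visits$observer_id[vrow]
  t_std <- (visits$time_after_sunrise_h[vrow] - 3) / 1.5
  lu <- lu_code(design$points$land_use[match(visits$point_id[vrow],
                                             design$points$point_id)])
  tr <- pool$traits[s, , drop = FALSE]
  bt <- det_params$traits[colnames(tr)]

  eta <- det_params$intercept + det_params$observer[o] +
    det_params$time * t_std + det_params$land_use * lu +
    drop(tr %*% bt) +
    re$v_sp[s] + re$v_fam[f] + re$v_sp_obs[cbind(s, o)] +
    re$w_time[s] * t_std + re$w_lu_sp[s] * lu + re$w_lu_fam[f] * lu
  p <- plogis(as.numeric(eta))
  z <- truth$pairs$z[idx]
  y <- rbinom(length(p), 1, p * z)

  out <- data.frame(point_id = visits$point_id[vrow],
                    species_id = s,
                    visit_index = visits$visit_index[vrow],
                    y = y,
                    observer_id = o,
                    time_after_sunrise_h = visits$time_after_sunrise_h[vrow],
                    land_use = design$points$land_use[
                      match(visits$point_id[vrow], design$points$point_id)])
  attr(out, "p_true") <- p
  attr(out, "re") <- re
  attr(out, "det_params") <- det_params
  class(out) <- c("msom_detections", "data.frame")
  out
}
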