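#' Occupancy model specification
#'
#' Declares which terms enter the occupancy and detection linear predictors
#' and the (zero-centred Gaussian) prior scales. All binary predictors are
#' coded -1/+1 (forest = +1); continuous predictors are standardized;
#' distance-to-range enters through a monotonic ordinal effect.
#'
#' Default priors are Normal(0, 1.5) for intercepts and the monotonic-effect
#' scale, Normal(0, 1) for slopes, half-Normal(0, 1) for random-effect
#' standard deviations and a uniform simplex for the monotonic increments.
#'
#' @param occ_terms fixed occupancy terms, subset of c("elev", "d2r",
#'   "land_use", "traits", "lu_traits").
#' @param occ_re occupancy random effects, subset of c("species", "family",
#'   "sp_elev", "sp_lu", "fam_lu", "sp_cluster", "sp_subregion").
#' @param det_terms fixed detection terms, subset of c("observer", "time",
#'   "land_use", "traits").
#' @param det_re detection random effects, subset of c("species", "family",
#'   "sp_observer", "sp_time", "sp_lu", "fam_lu").
#' @param prior_intercept,prior_slope,prior_re_sd,prior_d2r prior scales.
#' @param d2r_n_bins,d2r_limits binning of the distance-to-range effect.
#' @param subregion_km spatial blocking scale for the subregion effect.
#' @return a list of class `msom_model_spec`.
#' @export
msom_model_spec <- function(occ_terms = c("elev", "d2r", "land_use",
                                          "traits", "lu_traits"),
                            occ_re = c("species", "family", "sp_elev",
                                       "sp_lu", "fam_lu", "sp_cluster",
                                       "sp_subregion"),
                            det_terms = c("observer", "time", "land_use",
                                          "traits"),
                            det_re = c("species", "family", "sp_observer",
                                       "sp_time", "sp_lu", "fam_lu"),
                            prior_intercept = 1.5, prior_slope = 1,
                            prior_re_sd = 1, prior_d2r = 1.5,
                            d2r_n_bins = 8, d2r_limits = c(-160, 160),
                            subregion_km = 20) {
  structure(list(occ_terms = occ_terms, occ_re = occ_re,
                 det_terms = det_terms, det_re = det_re,
                 prior_intercept = prior_intercept,
                 prior_slope = prior_slope, prior_re_sd = prior_re_sd,
                 prior_d2r = prior_d2r, d2r_n_bins = d2r_n_bins,
                 d2r_limits = d2r_limits, subregion_km = subregion_km),
            class = "msom_model_spec")
}

dense_group <- function(key) match(key, unique(key))

#' Build model matrices and grouping indices for the occupancy model
#'
#' Assembles the fixed-effect design matrices (occupancy and detection),
#' the distance-to-range bin index, and dense grouping indices for every
#' random-effect term, from a detection table and clipped species-point
#' features. Binary predictors come out coded -1/+1 and land use uses
#' forest = +1.
#'
#' @param detections an `msom_detections` table (or data.frame with the same
#'   columns).
#' @param features clipped feature table from [clip_pairs()]; clipping must
#'   already be applied.
#' @param pool the `msom_species_pool`.
#' @param design the `msom_design`.
#' @param spec an `msom_model_spec`.
#' @return a list holding pair and visit tables, design matrices, random
#'   effect structures and the parameter packing, ready for the fitting
#'   backend.
#' @export
build_occ_data <- function(detections, features, pool, design,
                           spec = msom_model_spec()) {
  if (!all(detections$land_use %in% c("forest", "pasture")))
    stop("unknown land-use label")
  ret <- features[features$retained, ]
  key_all <- paste(detections$species_id, detections$point_id)
  key_ret <- paste(ret$species_id, ret$point_id)
  detections <- detections[key_all %in% key_ret, ]
  o <- order(detections$species_id, detections$point_id,
             detections$visit_index)
  det <- detections[o, ]
  pkey <- paste(det$species_id, det$point_id)
  pair_id <- dense_group(pkey)
  pairs <- det[!duplicated(pkey),
               c("species_id", "point_id", "land_use")]
  N <- nrow(pairs)
  fidx <- match(paste(pairs$species_id, pairs$point_id), key_ret)
  pairs$std_elevation <- ret$std_elevation[fidx]
  pairs$d2r <- ret$distance_to_range_km[fidx]

  pts <- design$points
  prow <- match(pairs$point_id, pts$point_id)
  sp <- pool$species
  s <- pairs$species_id
  lu <- lu_code(pairs$land_use)
  e <- pairs$std_elevation
  m <- ifelse(sp$lowland[s], 1, -1)
  tr <- pool$traits[s, , drop = FALSE]

  Xocc <- cbind(intercept = rep(1, N))
  prior_occ <- spec$prior_intercept
  if ("elev" %in% spec$occ_terms) {
    Xocc <- cbind(Xocc, elev_linear = e, elev_quad = e^2,
                  elev_linear_lowland = e * m, elev_quad_lowland = e^2 * m)
    prior_occ <- c(prior_occ, rep(spec$prior_slope, 4))
  }
  if ("land_use" %in% spec$occ_terms) {
    Xocc <- cbind(Xocc, land_use = lu)
    prior_occ <- c(prior_occ, spec$prior_slope)
  }
  if ("traits" %in% spec$occ_terms && ncol(tr) > 0) {
    colnames(tr) <- paste0("trait_", colnames(pool$traits))
    Xocc <- cbind(Xocc, tr)
    prior_occ <- c(prior_occ, rep(spec$prior_slope, ncol(tr)))
  }
  if ("lu_traits" %in% spec$occ_terms && ncol(pool$traits) > 0) {
    ltr <- pool$traits[s, , drop = FALSE] * lu
    colnames(ltr) <- paste0("lu_trait_", colnames(pool$traits))
    Xocc <- cbind(Xocc, ltr)
    prior_occ <- c(prior_occ, rep(spec$prior_slope, ncol(ltr)))
  }

  use_d2r <- "d2r" %in% spec$occ_terms
  K <- if (use_d2r) spec$d2r_n_bins - 1L else 0L
  kbin <- if (use_d2r) d2r_bin(pairs$d2r, spec$d2r_limits, spec$d2r_n_bins)
  else integer(N)

  fam <- sp$family_id[s]
  cl <- pts$cluster_id[prow]
  sub <- subregion_id(pts$x_km, pts$y_km, spec$subregion_km)[prow]
  re_terms <- list()
  add_re <- function(lst, name, group, x, is_det) {
    lst[[name]] <- list(group = as.integer(group - 1L), x = as.numeric(x),
                        n_groups = max(group), sd_scale = spec$prior_re_sd,
                        is_det = is_det)
    lst
  }
  ones <- rep(1, N)
  if ("species" %in% spec$occ_re)
    re_terms <- add_re(re_terms, "occ_species", s, ones, FALSE)
  if ("family" %in% spec$occ_re)
    re_terms <- add_re(re_terms, "occ_family", fam, ones, FALSE)
  if ("sp_elev" %in% spec$occ_re)
    re_terms <- add_re(re_terms, "occ_sp_elev", s, e, FALSE)
  if ("sp_lu" %in% spec$occ_re)
    re_terms <- add_re(re_terms, "occ_sp_lu", s, lu, FALSE)
  if ("fam_lu" %in% spec$occ_re)
    re_terms <- add_re(re_terms, "occ_fam_lu", fam, lu, FALSE)
  if ("sp_cluster" %in% spec$occ_re)
    re_terms <- add_re(re_terms, "occ_sp_cluster",
                       dense_group(paste(s, cl)), ones, FALSE)
  if ("sp_subregion" %in% spec$occ_re)
    re_terms <- add_re(re_terms, "occ_sp_subregion",
                       dense_group(paste(s, sub)), ones, FALSE)

  # detection side (per visit row)
  M <- nrow(det)
  vs <- det$species_id
  vfam <- sp$family_id[vs]
  vlu <- lu_code(det$land_use)
  t_std <- (det$time_after_sunrise_h - 3) / 1.5
  obs <- det$observer_id
  n_obs <- max(obs)
  Wdet <- cbind(intercept = rep(1, M))
  prior_det <- spec$prior_intercept
  if ("observer" %in% spec$det_terms && n_obs > 1) {
    for (oo in 2:n_obs) {
      col <- ifelse(obs == oo, 1, ifelse(obs == 1, -1, 0))
      Wdet <- cbind(Wdet, col)
      colnames(Wdet)[ncol(Wdet)] <- paste0("observer_", oo)
      prior_det <- c(prior_det, spec$prior_slope)
    }
  }
  if ("time" %in% spec$det_terms) {
    Wdet <- cbind(Wdet, time = t_std)
    prior_det <- c(prior_det, spec$prior_slope)
  }
  if ("land_use" %in% spec$det_terms) {
    Wdet <- cbind(Wdet, land_use = vlu)
    prior_det <- c(prior_det, spec$prior_slope)
  }
  if ("traits" %in% spec$det_terms && ncol(pool$traits) > 0) {
    dtr <- pool$traits[vs, , drop = FALSE]
    colnames(dtr) <- paste0("trait_", colnames(pool$traits))
    Wdet <- cbind(Wdet, dtr)
    prior_det <- c(prior_det, rep(spec$prior_slope, ncol(dtr)))
  }
  vones <- rep(1, M)
  if ("species" %in% spec$det_re)
    re_terms <- add_re(re_terms, "det_species", vs, vones, TRUE)
  if ("family" %in% spec$det_re)
    re_terms <- add_re(re_terms, "det_family", vfam, vones, TRUE)
  if ("sp_observer" %in% spec$det_re)
    re_terms <- add_re(re_terms, "det_sp_observer",
                       dense_group(paste(vs, obs)), vones, TRUE)
  if ("sp_time" %in% spec$det_re)
    re_terms <- add_re(re_terms, "det_sp_time", vs, t_std, TRUE)
  if ("sp_lu" %in% spec$det_re)
    re_terms <- add_re(re_terms, "det_sp_lu", vs, vlu, TRUE)
  if ("fam_lu" %in% spec$det_re)
    re_terms <- add_re(re_terms, "det_fam_lu", vfam, vlu, TRUE)

  pair_start <- c(0L, cumsum(tabulate(pair_id, nbins = N)))

  # parameter packing
  P <- ncol(Xocc); Q <- ncol(Wdet)
  i_beta_occ <- 0L
  i_b <- P
  i_uzeta <- P + 1L
  i_beta_det <- P + (if (K > 0) K else 0L)
  pos <- i_beta_det + Q
  re_val_off <- integer(length(re_terms))
  re_sd_off <- integer(length(re_terms))
  nm <- c(paste0("beta_occ[", colnames(Xocc), "]"))
  if (K > 0) nm <- c(nm, "b_d2r", paste0("uzeta[", seq_len(K - 1), "]"))
  nm <- c(nm, paste0("beta_det[", colnames(Wdet), "]"))
  for (t in seq_along(re_terms)) {
    re_val_off[t] <- pos
    G <- re_terms[[t]]$n_groups
    nm <- c(nm, paste0("re_", names(re_terms)[t], "[", seq_len(G), "]"))
    pos <- pos + G
    re_sd_off[t] <- pos
    nm <- c(nm, paste0("log_sd_", names(re_terms)[t]))
    pos <- pos + 1L
  }
  npar <- pos

  # likelihood-invariant translation moves between a fixed effect and its
  # centred random-effect vector (same covariate on every row)
  tm <- list()
  add_tm <- function(tm, col, Xnames, term) {
    j <- match(col, Xnames)
    t <- match(term, names(re_terms))
    if (!is.na(j) && !is.na(t)) {
      base <- if (grepl("^det", term)) i_beta_det else i_beta_occ
      pr <- if (grepl("^det", term)) prior_det[j] else prior_occ[j]
      tm[[length(tm) + 1]] <- list(beta_idx = base + j - 1L,
                                   re_term = t - 1L, prior_sd = pr)
    }
    tm
  }
  tm <- add_tm(tm, "intercept", colnames(Xocc), "occ_species")
  tm <- add_tm(tm, "land_use", colnames(Xocc), "occ_sp_lu")
  tm <- add_tm(tm, "elev_linear", colnames(Xocc), "occ_sp_elev")
  tm <- add_tm(tm, "intercept", colnames(Wdet), "det_species")
  tm <- add_tm(tm, "land_use", colnames(Wdet), "det_sp_lu")

  list(
    cpp = list(Xocc = Xocc, Wdet = Wdet, kbin = as.integer(kbin),
               y = as.integer(det$y), pair_of = as.integer(pair_id - 1L),
               pair_start = as.integer(pair_start),
               prior_sd_occ = prior_occ, prior_sd_det = prior_det,
               prior_sd_b = spec$prior_d2r, K = as.integer(K),
               re_terms = re_terms,
               off = list(i_beta_occ = i_beta_occ, i_b = i_b,
                          i_uzeta = i_uzeta, i_beta_det = i_beta_det,
                          re_val_off = as.integer(re_val_off),
                          re_sd_off = as.integer(re_sd_off),
                          npar = as.integer(npar))),
    trans_moves = tm, par_names = nm, npar = npar,
    pairs = pairs, det = det, spec = spec,
    re_names = names(re_terms)
  )
}

#' Fit the multi-species occupancy model
#'
#' Fits the biogeographically constrained multi-species occupancy model by
#' maximum a posteriori optimization (`method = "map"`; random-effect
#' standard deviations held at their prior scales) or by adaptive
#' Metropolis-within-Gibbs MCMC initialized at the MAP (`method = "mcmc"`).
#' Split R-hat and bulk effective sample size are recorded for every saved
#' parameter; parameters with R-hat >= 1.02 are flagged (not failed).
#'
#' @param detections an `msom_detections` table.
#' @param features clipped species-point features ([clip_pairs()]).
#' @param pool,design the species pool and sampling design.
#' @param spec an `msom_model_spec`.
#' @param method "mcmc" or "map".
#' @param chains,warmup,iter MCMC configuration.
#' @param seed integer seed; fits are reproducible given (data, spec, seed).
#' @param save_local logical; store draws of the local (cluster / subregion /
#'   observer) random-effect values as well (memory heavy).
#' @return an object of class `msom_occfit` with elements `draws` (matrix,
#'   iterations x saved parameters), `chain` (chain index per row), `map`
#'   (named full MAP vector), `diagnostics` (data.frame with rhat and
#'   ess_bulk), `model` (the built model data) and `method`.
#' @export
fit_occupancy <- function(detections, features, pool, design,
                          spec = msom_model_spec(), method = c("mcmc", "map"),
                          chains = 4, warmup = 250, iter = 250, seed = 1,
                          save_local = FALSE) {
  method <- match.arg(method)
  md <- build_occ_data(detections, features, pool, design, spec)
  npar <- md$npar
  par0 <- numeric(npar)
  sd_idx <- grep("^log_sd_", md$par_names)
  par0[sd_idx] <- log(0.5)
  nlp0 <- occ_nlp(par0, md$cpp)
  if (!is.finite(nlp0))
    stop("non-finite likelihood at initialization")

  free <- setdiff(seq_len(npar), sd_idx)
  obj <- function(th) {
    p <- par0; p[free] <- th; occ_nlp(p, md$cpp)
  }
  grd <- function(th) {
    p <- par0; p[free] <- th; occ_nlp_grad(p, md$cpp)[free]
  }
  # limited-memory BFGS: the joint mode can have tens of thousands of
  # random-effect coordinates
  opt <- optim(par0[free], obj, grd, method = "L-BFGS-B",
               control = list(maxit = 300))
  map <- par0; map[free] <- opt$par
  names(map) <- md$par_names

  local_re <- grep("^re_(occ_sp_cluster|occ_sp_subregion|det_sp_observer)\\[",
                   md$par_names)
  save_idx <- if (save_local) seq_len(npar) else
    setdiff(seq_len(npar), local_re)
  diagnostics <- NULL

  if (method == "map") {
    draws <- matrix(map[save_idx], nrow = 1,
                    dimnames = list(NULL, md$par_names[save_idx]))
    chain <- 1L
  } else {
    per_chain <- vector("list", chains)
    for (ch in seq_len(chains)) {
      set.seed(child_seed(seed, 20 + ch))
      init <- map + rnorm(npar, 0, 0.1)
      res <- occ_mwg(init, md$cpp, warmup, iter,
                     as.integer(save_idx - 1L), md$trans_moves, 0.2)
      per_chain[[ch]] <- res$draws
    }
    draws <- do.call(rbind, per_chain)
    colnames(draws) <- md$par_names[save_idx]
    chain <- rep(seq_len(chains), each = iter)
    diagnostics <- mcmc_diagnostics(per_chain, md$par_names[save_idx])
    n_flag <- sum(diagnostics$rhat >= 1.02, na.rm = TRUE)
    if (n_flag > 0)
      warning(sprintf("%d parameter(s) flagged with split R-hat >= 1.02",
                      n_flag))
  }
  structure(list(draws = draws, chain = chain, map = map,
                 diagnostics = diagnostics, model = md, method = method,
                 seed = seed),
            class = "msom_occfit")
}

#' @export
print.msom_occfit <- function(x, ...) {
  cat("msom_occfit (", x$method, "): ", nrow(x$model$pairs),
      " species-point pairs, ", x$model$npar, " parameters, ",
      nrow(x$draws), " stored draws\n", sep = "")
  if (!is.null(x$diagnostics)) {
    cat("  max split R-hat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 3),
        "; min bulk ESS:", round(min(x$diagnostics$ess_bulk, na.rm = TRUE)),
        "\n")
  }
  invisible(x)
}

# Split R-hat and a bulk-ESS estimate across chains (list of iter x par
# matrices). Plain (not rank-normalized) split-halves version.
mcmc_diagnostics <- function(per_chain, par_names) {
  halves <- list()
  for (m in per_chain) {
    n <- nrow(m)
    h <- floor(n / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(n - h + 1):n, , drop = FALSE]))
  }
  n <- nrow(halves[[1]]); m <- length(halves)
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(x) apply(x, 2, var))
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1)
  vars <- matrix(vars, nrow = 1) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W < 1e-12] <- 1
  ess <- sapply(seq_along(par_names), function(j) {
    rho_sum <- 0
    for (h in halves) {
      x <- h[, j] - mean(h[, j])
      v <- sum(x^2)
      if (v < 1e-12) return(m * n)
      lag <- 1
      while (lag < n - 1) {
        r <- sum(x[1:(n - lag)] * x[(lag + 1):n]) / v
        if (r < 0.05) break
        rho_sum <- rho_sum + r / m
        lag <- lag + 1
      }
    }
    m * n / (1 + 2 * rho_sum)
  })
  data.frame(parameter = par_names, rhat = rhat, ess_bulk = ess,
             row.names = NULL)
}
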