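test_that("monotonic effect accumulates the simplex with the sign of the scale", {
  zeta <- c(0.5, 0.3, 0.2)
  expect_equal(monotonic_effect(0, 2, zeta), 0)
  expect_equal(monotonic_effect(3, 2, zeta), 2)
  expect_equal(monotonic_effect(1, 2, zeta), 1)
  out <- monotonic_effect(0:3, -1.5, zeta)
  expect_true(all(diff(out) <= 0))
  expect_error(monotonic_effect(1, 1, c(0.5, 0.6)), "simplex")
  expect_error(monotonic_effect(5, 1, zeta), "0..K")
})

test_that("marginal likelihood matches hand values and the enumeration oracle", {
  expect_equal(marginal_loglik_point(0.5, c(0.5, 0.5), c(1, 0)),
               log(0.125))
  expect_equal(marginal_loglik_point(0.5, rep(0.5, 4), rep(0, 4)),
               log(0.53125))
  expect_error(marginal_loglik_point(0.5, numeric(0), numeric(0)),
               "visits")
  # brute-force sum over the latent state
  enum <- function(psi, p, y) {
    log(psi * prod(p^y * (1 - p)^(1 - y)) +
          (1 - psi) * as.numeric(sum(y) == 0))
  }
  set.seed(99)
  for (r in 1:200) {
    J <- sample(1:5, 1)
    psi <- runif(1); p <- runif(J); y <- rbinom(J, 1, 0.4)
    expect_equal(marginal_loglik_point(psi, p, y), enum(psi, p, y),
                 tolerance = 1e-12)
  }
})

test_that("backend negative log posterior matches an independent R computation", {
  w <- tiny_world(seed = 21, n_species = 8, n_clusters = 6)
  tr <- simulate_truth(w$L, w$pool, w$des, seed = 1)
  det <- simulate_detections(tr, w$des, w$pool, seed = 1)
  md <- build_occ_data(det, tr$features, w$pool, w$des)
  set.seed(5)
  par <- rnorm(md$npar, 0, 0.3)

  # likelihood part recomputed in R from scratch
  cpp <- md$cpp
  K <- cpp$K
  zeta <- exp(c(par[(cpp$off$i_uzeta + 1):(cpp$off$i_uzeta + K - 1)], 0))
  zeta <- zeta / sum(zeta)
  eta_occ <- drop(cpp$Xocc %*% par[1:ncol(cpp$Xocc)]) +
    par[cpp$off$i_b + 1] * c(0, cumsum(zeta))[cpp$kbin + 1]
  eta_det <- drop(cpp$Wdet %*%
                    par[(cpp$off$i_beta_det + 1):
                          (cpp$off$i_beta_det + ncol(cpp$Wdet))])
  for (t in seq_along(cpp$re_terms)) {
    re <- cpp$re_terms[[t]]
    u <- par[(cpp$off$re_val_off[t] + 1):(cpp$off$re_val_off[t] + re$n_groups)]
    contrib <- u[re$group + 1] * re$x
    if (re$is_det) eta_det <- eta_det + contrib
    else eta_occ <- eta_occ + contrib
  }
  ll <- 0
  for (i in seq_len(nrow(md$pairs))) {
    v <- (cpp$pair_start[i] + 1):cpp$pair_start[i + 1]
    ll <- ll + marginal_loglik_point(plogis(eta_occ[i]),
                                     plogis(eta_det[v]), cpp$y[v])
  }
  nlp <- occ_nlp(par, cpp)
  # difference must equal the (parameter-only) prior, so check likelihood
  # via two parameter vectors to cancel the prior of untouched blocks
  expect_true(is.finite(nlp))
  par2 <- par; par2[1] <- par2[1] + 0.1
  eta_occ2 <- eta_occ + 0.1 * cpp$Xocc[, 1]
  ll2 <- 0
  for (i in seq_len(nrow(md$pairs))) {
    v <- (cpp$pair_start[i] + 1):cpp$pair_start[i + 1]
    ll2 <- ll2 + marginal_loglik_point(plogis(eta_occ2[i]),
                                       plogis(eta_det[v]), cpp$y[v])
  }
  dprior <- -0.5 * (par2[1]^2 - par[1]^2) / cpp$prior_sd_occ[1]^2
  expect_equal(occ_nlp(par2, cpp) - nlp, -(ll2 - ll) - dprior,
               tolerance = 1e-8)
})

test_that("analytic gradient matches finite differences", {
  w <- tiny_world(seed = 22, n_species = 5, n_clusters = 4)
  tr <- simulate_truth(w$L, w$pool, w$des, seed = 2)
  det <- simulate_detections(tr, w$des, w$pool, seed = 2)
  md <- build_occ_data(det, tr$features, w$pool, w$des)
  set.seed(7)
  par <- rnorm(md$npar, 0, 0.2)
  g <- occ_nlp_grad(par, md$cpp)
  idx <- c(1, 3, md$cpp$off$i_b + 1, md$cpp$off$i_uzeta + 1,
           md$cpp$off$i_beta_det + 1,
           md$cpp$off$re_val_off[1] + 1, md$cpp$off$re_sd_off[1] + 1,
           md$npar)
  h <- 1e-6
  for (j in idx) {
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    num <- (occ_nlp(pp, md$cpp) - occ_nlp(pm, md$cpp)) / (2 * h)
    expect_equal(g[j], num, tolerance = 1e-4)
  }
})

test_that("null data recover null coefficients and seeds reproduce draws", {
  w <- tiny_world(seed = 23, n_species = 15, n_clusters = 10)
  p0 <- default_occ_params(w$pool)
  p0$intercept <- 0; p0$land_use <- 0; p0$d2r_scale <- 0
  p0$elev[] <- 0; p0$elev_lowland[] <- 0
  p0$traits[] <- 0; p0$land_use_traits[] <- 0
  for (nm in grep("^sd_", names(p0), value = TRUE)) p0[[nm]] <- 0.1
  tr <- simulate_truth(w$L, w$pool, w$des, params = p0, seed = 3)
  det <- simulate_detections(tr, w$des, w$pool, seed = 3)
  fit <- fit_occupancy(det, tr$features, w$pool, w$des, method = "mcmc",
                       chains = 2, warmup = 150, iter = 150, seed = 1)
  for (nm in c("beta_occ[land_use]", "beta_occ[elev_linear]")) {
    dr <- fit$draws[, nm]
    expect_lt(abs(mean(dr)), 3 * sd(dr) + 1e-6)
  }
  fit_b <- fit_occupancy(det, tr$features, w$pool, w$des, method = "mcmc",
                         chains = 2, warmup = 150, iter = 150, seed = 1)
  expect_identical(fit$draws, fit_b$draws)
  expect_false(identical(
    fit$draws,
    fit_occupancy(det, tr$features, w$pool, w$des, method = "mcmc",
                  chains = 2, warmup = 150, iter = 150, seed = 2)$draws))
})

test_that("prior pushforward is not concentrated at extreme probabilities", {
  # draw coefficients from the default priors for a typical -1/+1 covariate
  # row: intercept N(0,1.5), five slopes N(0,1) on +/-1 covariates
  set.seed(31)
  n <- 5000
  eta <- rnorm(n, 0, 1.5)
  for (j in 1:5) eta <- eta + rnorm(n, 0, 1) * sample(c(-1, 1), n, TRUE)
  psi <- plogis(eta)
  expect_gte(mean(psi > 0.01 & psi < 0.99), 0.90)
})

test_that("pixel prediction reduces to the linear predictor when cluster SD is zero", {
  L <- make_landscape(extent_km = c(20, 20), n_regions = 1,
                      n_topo_units = 1, seed = 41)
  pool <- make_species_pool(L, n_species = 1, n_families = 1,
                            endemic_fraction = 0, range_frac = c(0.99, 0.999),
                            elev_breadth_m = c(8000, 8000),
                            lowland_fraction = 1,
                            traits = list(binary = NULL, continuous = NULL),
                            seed = 1)
  pool$species$elev_min_m <- 0; pool$species$elev_max_m <- 8000
  spec <- msom_model_spec(occ_terms = "land_use", occ_re = character(0),
                          det_terms = character(0), det_re = character(0))
  b0 <- 0.4; blu <- 0.3
  draws <- matrix(c(b0, blu), 1, 2,
                  dimnames = list(NULL, c("beta_occ[intercept]",
                                          "beta_occ[land_use]")))
  fit <- structure(list(draws = draws, model = list(spec = spec)),
                   class = "msom_occfit")
  cube <- predict_occupancy(fit, L, pool, seed = 1)
  expect_equal(unname(cube[1, , "forest", 1]),
               rep(plogis(b0 + blu), 100), tolerance = 1e-12)
  expect_equal(unname(cube[1, , "pasture", 1]),
               rep(plogis(b0 - blu), 100), tolerance = 1e-12)
  expect_true(all(cube >= 0 & cube <= 1))
  expect_error(predict_occupancy(fit, L, pool, scenarios = "meadow"),
               "scenario")
})

test_that("16-sample cluster averaging approximates the logit-normal mean", {
  L <- make_landscape(extent_km = c(20, 20), n_regions = 1,
                      n_topo_units = 1, seed = 42)
  pool <- make_species_pool(L, n_species = 1, n_families = 1,
                            range_frac = c(0.99, 0.999),
                            traits = list(binary = NULL, continuous = NULL),
                            seed = 1)
  pool$species$elev_min_m <- 0; pool$species$elev_max_m <- 8000
  pool$species$lowland <- TRUE
  spec <- msom_model_spec(occ_terms = "land_use",
                          occ_re = "sp_cluster",
                          det_terms = character(0), det_re = character(0))
  b0 <- 0.5
  draws <- matrix(c(b0, 0, log(1)), 1, 3,
                  dimnames = list(NULL, c("beta_occ[intercept]",
                                          "beta_occ[land_use]",
                                          "log_sd_occ_sp_cluster")))
  fit <- structure(list(draws = draws, model = list(spec = spec)),
                   class = "msom_occfit")
  cube <- predict_occupancy(fit, L, pool, seed = 7)
  # high-resolution Monte-Carlo oracle for E[plogis(b0 + N(0,1))]
  set.seed(1)
  oracle <- mean(plogis(b0 + rnorm(1e6)))
  avg <- mean(cube[1, , "forest", 1])  # average over 100 pixels
  expect_lt(abs(avg - oracle), 0.02)
})
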