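test_that("pair dissimilarities match the formulas and the vegan oracle", {
  comm <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1),
                d = c(1, 0, 1, 0))
  dis <- pair_dissimilarities(comm)
  r_ab <- dis[dis$site_i == 1 & dis$site_j == 2, ]
  expect_equal(r_ab$sorensen, 0)   # identical communities
  expect_equal(r_ab$simpson, 0)
  r_ac <- dis[dis$site_i == 1 & dis$site_j == 3, ]
  expect_equal(r_ac$sorensen, 1)   # disjoint communities
  expect_equal(r_ac$simpson, 1)
  r_ad <- dis[dis$site_i == 1 & dis$site_j == 4, ]
  expect_equal(r_ad$a, 1)  # a = 1, b = 1, c = 1
  expect_equal(r_ad$sorensen, 2 / 4)
  expect_equal(r_ad$simpson, 1 / 2)
  # a=2, b=1, c=1
  comm2 <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1))
  d2 <- pair_dissimilarities(comm2)
  expect_equal(d2$sorensen, 1 / 3)
  expect_equal(d2$simpson, 1 / 3)

  # simpson <= sorensen globally, and Sorensen agrees with vegan
  set.seed(12)
  comm3 <- matrix(rbinom(15 * 30, 1, 0.3), 15, 30)
  comm3[1, ] <- 0  # a site with zero species is retained with d = 1
  d3 <- pair_dissimilarities(comm3)
  expect_true(all(d3$simpson <= d3$sorensen + 1e-12))
  expect_true(all(d3$sorensen[d3$site_i == 1 | d3$site_j == 1] == 1))
  if (requireNamespace("vegan", quietly = TRUE)) {
    vd <- as.matrix(vegan::vegdist(comm3[-1, ], method = "bray",
                                   binary = TRUE))
    d3b <- pair_dissimilarities(comm3[-1, ])
    expect_equal(d3b$sorensen, vd[cbind(d3b$site_i, d3b$site_j)],
                 tolerance = 1e-12)
  }
})

test_that("I-spline basis is monotone, bounded and hits its endpoints", {
  k <- c(0, 3, 10)
  expect_equal(unname(ispline_basis(0, k)[1, ]), c(0, 0, 0))
  expect_equal(unname(ispline_basis(10, k)[1, ]), c(1, 1, 1))
  expect_error(ispline_basis(1, c(0, 0, 1)), "increasing")
  set.seed(13)
  for (r in 1:20) {
    kk <- sort(runif(3, 0, 100))
    if (any(diff(kk) < 1e-3) ) next
    x <- seq(kk[1] - 5, kk[3] + 5, length.out = 1000)
    B <- ispline_basis(x, kk)
    expect_true(all(B >= 0 & B <= 1))
    expect_true(all(apply(B, 2, function(col) all(diff(col) >= -1e-12))))
  }
})

test_that("GDM link identity and non-negativity constraints hold", {
  set.seed(14)
  n <- 100
  x <- runif(n, 0, 10)
  d <- 1 - exp(-(0.2 + 0.5 * ispline_basis(x, c(0, 5, 10))[, 2]))
  fit <- fit_gdm(d, pred_pair = list(g = x))
  expect_true(fit$alpha0 >= 0)
  expect_true(all(unlist(fit$coefs) >= 0))
  # identical-site pair with all-zero predictors: d_hat = 1 - exp(-alpha0)
  pred0 <- predict(fit, pred_pair = list(g = fit$knots$g[1]))
  expect_equal(pred0, 1 - exp(-fit$alpha0))
  # predictions stay in [0, 1)
  pr <- predict(fit, pred_pair = list(g = x))
  expect_true(all(pr >= 0 & pr < 1))
})

test_that("a known GDM is recovered within 0.05 RMS of its partial curve", {
  set.seed(15)
  n <- 800
  x <- runif(n, 0, 1)
  knots <- c(0, 0.5, 1)
  w_true <- c(0.5, 0.3, 0.2)
  eta <- 0.1 + drop(ispline_basis(x, knots) %*% w_true)
  d <- pmin(pmax(1 - exp(-eta) + rnorm(n, 0, 0.02), 0), 1)
  fit <- fit_gdm(d, pred_pair = list(g = x), knots = list(g = knots))
  grid <- seq(0, 1, length.out = 200)
  f_true <- drop(ispline_basis(grid, knots) %*% w_true)
  f_fit <- partial_distance(fit, "g", grid, rep(0, 200))
  expect_lt(sqrt(mean((f_fit - f_true)^2)), 0.05)
})

test_that("partial distances are symmetric-origin, capped by the total height", {
  fit <- structure(list(alpha0 = 0.1,
                        coefs = list(g = c(w1 = 0.4, w2 = 0.2, w3 = 0.1)),
                        knots = list(g = c(0, 2, 10)),
                        predictors = "g", site_level = character(0)),
                   class = "msom_gdm")
  expect_equal(partial_distance(fit, "g", 3, 3), 0)
  expect_equal(partial_distance(fit, "g", 10, 0), 0.7)  # sum of weights
  cv <- partial_curve(fit, "g")
  expect_true(all(diff(cv$f) >= -1e-12))
  expect_error(partial_distance(fit, "q", 1, 2), "unknown predictor")
})

test_that("Bayesian bootstrap uses normalized Dirichlet weights and is seeded", {
  set.seed(16)
  n_sites <- 12
  pts <- t(combn(n_sites, 2))
  x <- runif(nrow(pts), 0, 5)
  d <- pmin(1 - exp(-(0.1 + 0.3 * x / 5)) + rnorm(nrow(pts), 0, 0.02), 1)
  ens <- bayesian_bootstrap(pmax(d, 0), pred_pair = list(g = x),
                            sites = pts, n = 25, seed = 3)
  expect_equal(length(ens$fits), 25)
  expect_equal(rowSums(ens$weights), rep(1, 25))
  expect_true(all(ens$weights >= 0))
  ens2 <- bayesian_bootstrap(pmax(d, 0), pred_pair = list(g = x),
                             sites = pts, n = 25, seed = 3)
  expect_equal(ens$fits[[5]]$coefs, ens2$fits[[5]]$coefs)
  bd <- ens$curve_band("g")
  expect_true(all(bd$lo <= bd$mean + 1e-12 & bd$mean <= bd$hi + 1e-12))
})

test_that("conditional presence probabilities follow Bayes rule", {
  # psi = 0.5, p = 0.5, J = 2, no detections: 0.125 / 0.625 = 0.2
  expect_equal(conditional_z_prob(0.5, 0.25, FALSE), 0.2)
  expect_equal(conditional_z_prob(0.5, 0.25, TRUE), 1)
  # p -> 1 with no detections: presence probability -> 0
  expect_lt(conditional_z_prob(0.5, 1e-12, FALSE), 1e-11)
  # enumeration oracle
  set.seed(17)
  for (r in 1:50) {
    psi <- runif(1); p <- runif(3)
    q <- prod(1 - p)
    oracle <- psi * q / (psi * q + (1 - psi))
    expect_equal(conditional_z_prob(psi, q, FALSE), oracle)
  }
})

test_that("detection-corrected communities honour certain detections", {
  w <- tiny_world(seed = 18, n_species = 12, n_clusters = 8)
  tr <- simulate_truth(w$L, w$pool, w$des, seed = 2)
  det <- simulate_detections(tr, w$des, w$pool, seed = 2)
  fit <- fit_occupancy(det, tr$features, w$pool, w$des, method = "mcmc",
                       chains = 2, warmup = 100, iter = 50, seed = 1,
                       save_local = TRUE)
  comms <- detection_corrected_communities(fit, n_draws = 10, seed = 4)
  expect_equal(length(comms), 10)
  detected <- aggregate(y ~ point_id + species_id, det, max)
  detected <- detected[detected$y == 1, ]
  for (r in c(1, 10)) {
    m <- comms[[r]]
    idx <- cbind(match(detected$point_id, as.integer(rownames(m))),
                 match(detected$species_id, as.integer(colnames(m))))
    expect_true(all(m[idx] == 1))
  }
  expect_error(detection_corrected_communities(fit, n_draws = 1e5),
               "exceeds")
})
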