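test_that("landscape grid has the right geometry and labelling", {
  L <- make_landscape(extent_km = c(40, 40), pixel_size_km = 2, seed = 1)
  expect_equal(nrow(L$pixels), 400)  # (40/2)^2
  expect_setequal(unique(diff(sort(unique(L$pixels$x_km)))), 2)
  expect_true(all(L$pixels$elevation_m >= 0 & L$pixels$elevation_m <= 3500))
  # every pixel belongs to exactly one region and one topo unit
  expect_false(anyNA(L$pixels$region_id))
  expect_false(anyNA(L$pixels$topo_unit_id))

  L1 <- make_landscape(n_regions = 1, seed = 2)
  expect_equal(unique(L1$pixels$region_id), 1L)

  expect_identical(make_landscape(seed = 7)$pixels,
                   make_landscape(seed = 7)$pixels)
  expect_error(make_landscape(extent_km = c(-10, 40)), "positive")
  expect_error(make_landscape(n_regions = 0), "n_regions")
  expect_error(make_landscape(extent_km = c(41, 40)), "divisible")
})

test_that("regions and topographic units cut across one another", {
  L <- make_landscape(n_regions = 4, n_topo_units = 3, seed = 5)
  tab <- table(L$pixels$region_id, L$pixels$topo_unit_id)
  # every region spans every topographic unit (bands are orthogonal)
  expect_true(all(tab > 0))
})

test_that("species pool respects endemism, trait coding and moments", {
  w <- tiny_world(seed = 3)
  pool <- w$pool
  expect_true(all(lengths(pool$ranges) > 0))
  expect_true(all(pool$species$elev_min_m < pool$species$elev_max_m))
  bin <- attr(pool$traits, "binary")
  expect_true(all(pool$traits[, bin] %in% c(-1, 1)))

  # full endemism: no range spans two regions
  L2 <- make_landscape(n_regions = 2, seed = 9)
  p2 <- make_species_pool(L2, n_species = 40, endemic_fraction = 1,
                          seed = 10)
  spans <- vapply(p2$ranges, function(r)
    length(unique(L2$pixels$region_id[match(r, L2$pixels$pixel_id)])),
    numeric(1))
  expect_true(all(spans == 1))

  expect_equal(nrow(make_species_pool(w$L, n_species = 971,
                                      seed = 1)$species), 971)

  # sample trait moments match configuration within Monte-Carlo error
  big <- make_species_pool(w$L, n_species = 5000, seed = 11,
                           traits = list(binary = c(bt = 0.5),
                                         continuous = list(ct = c(0.3, 2))))
  ct <- big$traits[, "ct"]
  expect_lt(abs(mean(ct) - 0.3), 3 * 2 / sqrt(5000))
  expect_lt(abs(sd(ct) - 2), 3 * 2 / sqrt(2 * 5000))
  bt <- big$traits[, "bt"]
  expect_lt(abs(mean(bt == 1) - 0.5), 3 * 0.5 / sqrt(5000))
})

test_that("sampling design honours spacing, pairing and visit structure", {
  w <- tiny_world(seed = 4, n_clusters = 16)
  des <- w$des
  expect_true(all(table(des$points$cluster_id) %in% 2:3))
  for (cl in unique(des$points$cluster_id)) {
    p <- des$points[des$points$cluster_id == cl, ]
    expect_gte(min(dist(cbind(p$x_km, p$y_km))), 0.2)
  }
  expect_true(all(table(des$visits$point_id) == 4))
  # pasture clusters pair with forest clusters at <21 km and <200 m
  cl <- des$clusters
  pas <- cl[cl$land_use == "pasture", ]
  par <- cl[match(pas$pair_id, cl$cluster_id), ]
  expect_true(all(sqrt((pas$x_km - par$x_km)^2 +
                         (pas$y_km - par$y_km)^2) < 21))
  expect_true(all(abs(pas$elevation_m - par$elevation_m) < 200))
})

test_that("null occupancy parameters give psi = 0.5 and coding identity holds", {
  w <- tiny_world(seed = 5)
  p0 <- default_occ_params(w$pool)
  for (nm in c("intercept", "land_use", "d2r_scale"))
    p0[[nm]] <- 0
  p0$elev[] <- 0; p0$elev_lowland[] <- 0
  p0$traits[] <- 0; p0$land_use_traits[] <- 0
  for (nm in grep("^sd_", names(p0), value = TRUE)) p0[[nm]] <- 0
  tr <- simulate_truth(w$L, w$pool, w$des, params = p0, seed = 1)
  expect_true(all(tr$pairs$psi_true == 0.5))

  # land-use coefficient: logit difference between scenarios is 2 * beta
  p1 <- p0; p1$land_use <- 0.7
  tr1 <- simulate_truth(w$L, w$pool, w$des, params = p1, seed = 1)
  lu <- w$des$points$land_use[match(tr1$pairs$point_id,
                                    w$des$points$point_id)]
  lf <- qlogis(tr1$pairs$psi_true[lu == "forest"][1])
  lp <- qlogis(tr1$pairs$psi_true[lu == "pasture"][1])
  expect_equal(lf - lp, 2 * 0.7, tolerance = 1e-10)

  expect_error(simulate_truth(w$L, w$pool, w$des,
                              params = p0[setdiff(names(p0), "land_use")]),
               "land_use")
})

test_that("latent states are Bernoulli(psi) draws", {
  w <- tiny_world(seed = 6, n_species = 40, n_clusters = 20)
  p0 <- default_occ_params(w$pool)
  for (nm in c("land_use", "d2r_scale")) p0[[nm]] <- 0
  p0$intercept <- qlogis(0.3)
  p0$elev[] <- 0; p0$elev_lowland[] <- 0
  p0$traits[] <- 0; p0$land_use_traits[] <- 0
  for (nm in grep("^sd_", names(p0), value = TRUE)) p0[[nm]] <- 0
  tr <- simulate_truth(w$L, w$pool, w$des, params = p0, seed = 3)
  n <- nrow(tr$pairs)
  expect_gt(n, 1000)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(tr$pairs$z) - 0.3), 3 * se)
})

test_that("detections respect the latent state and detection probability", {
  w <- tiny_world(seed = 7, n_species = 30, n_clusters = 20)
  tr <- simulate_truth(w$L, w$pool, w$des, seed = 2)
  dp <- default_det_params(w$pool, w$des$n_observers)
  dp$observer[] <- 0; dp$time <- 0; dp$land_use <- 0; dp$traits[] <- 0
  for (nm in grep("^sd_", names(dp), value = TRUE)) dp[[nm]] <- 0
  dp$intercept <- qlogis(0.4)
  det <- simulate_detections(tr, w$des, w$pool, det_params = dp, seed = 3)

  z <- tr$pairs$z[match(paste(det$species_id, det$point_id),
                        paste(tr$pairs$species_id, tr$pairs$point_id))]
  expect_true(all(det$y[z == 0] == 0))  # no false positives
  yz <- det$y[z == 1]
  expect_lt(abs(mean(yz) - 0.4), 3 * sqrt(0.4 * 0.6 / length(yz)))

  # p = 1 and z = 1 implies detection on every visit
  dp1 <- dp; dp1$intercept <- 50
  det1 <- simulate_detections(tr, w$des, w$pool, det_params = dp1, seed = 3)
  z1 <- tr$pairs$z[match(paste(det1$species_id, det1$point_id),
                         paste(tr$pairs$species_id, tr$pairs$point_id))]
  expect_true(all(det1$y[z1 == 1] == 1))

  # determinism
  det_b <- simulate_detections(tr, w$des, w$pool, det_params = dp, seed = 3)
  expect_identical(det$y, det_b$y)
})

test_that("visits are conditionally independent given presence", {
  w <- tiny_world(seed = 8, n_species = 40, n_clusters = 24)
  tr <- simulate_truth(w$L, w$pool, w$des, seed = 4)
  # homogeneous detection so pooling pairs cannot induce spurious
  # association between visits
  dp <- default_det_params(w$pool, w$des$n_observers)
  dp$observer[] <- 0; dp$time <- 0; dp$land_use <- 0; dp$traits[] <- 0
  for (nm in grep("^sd_", names(dp), value = TRUE)) dp[[nm]] <- 0
  n_sig <- 0; n_rep <- 20
  for (r in seq_len(n_rep)) {
    det <- simulate_detections(tr, w$des, w$pool, det_params = dp,
                               seed = 100 + r)
    z <- tr$pairs$z[match(paste(det$species_id, det$point_id),
                          paste(tr$pairs$species_id, tr$pairs$point_id))]
    d1 <- det[det$visit_index == 1 & z == 1, ]
    d2 <- det[det$visit_index == 2 & z == 1, ]
    key <- paste(d1$species_id, d1$point_id)
    y2 <- d2$y[match(key, paste(d2$species_id, d2$point_id))]
    pv <- suppressWarnings(chisq.test(table(d1$y, y2))$p.value)
    if (!is.na(pv) && pv < 0.01) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_rep, 0.05 + 1e-9)
})

test_that("no detection row survives biogeographic clipping removal", {
  w <- tiny_world(seed = 9)
  tr <- simulate_truth(w$L, w$pool, w$des, seed = 1)
  det <- simulate_detections(tr, w$des, w$pool, seed = 1)
  feats <- tr$features
  removed <- feats[!feats$retained, ]
  expect_false(any(paste(det$species_id, det$point_id) %in%
                     paste(removed$species_id, removed$point_id)))
})
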