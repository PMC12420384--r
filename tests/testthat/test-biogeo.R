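test_that("species-standardized elevation maps limits to -1 and +1", {
  expect_equal(std_elevation(1000, 1000, 2000), -1)
  expect_equal(std_elevation(1500, 1000, 2000), 0)
  expect_equal(std_elevation(2000, 1000, 2000), 1)
  expect_equal(std_elevation(2500, 1000, 2000), 2)  # unbounded outside
  expect_error(std_elevation(100, 2000, 2000), "degenerate")
})

test_that("distance to range is signed and respects topographic units", {
  # one topo unit, one region, flat 100x20 km strip
  L <- make_landscape(extent_km = c(100, 20), n_regions = 1,
                      n_topo_units = 1, seed = 1)
  px <- L$pixels
  # range: all pixels with x < 20
  range_px <- px$pixel_id[px$x_km < 20]
  d_out <- distance_to_range(51, 9, 1, range_px, L)  # 51 - 19 = 32
  expect_equal(d_out, 32)
  d_in <- distance_to_range(1, 9, 1, range_px, L)  # 20 km to first non-range
  expect_lt(d_in, 0)
  expect_equal(d_in, -20)

  # species with range only in a different topographic unit: sentinel
  L2 <- make_landscape(extent_km = c(40, 40), n_topo_units = 2,
                       n_regions = 1, seed = 2)
  u1 <- L2$pixels$pixel_id[L2$pixels$topo_unit_id == 1]
  pt_u2 <- L2$pixels[L2$pixels$topo_unit_id == 2, ][1, ]
  d <- distance_to_range(pt_u2$x_km, pt_u2$y_km, 2, u1, L2)
  expect_true(is.na(d))
})

test_that("clipping retains exactly the pairs meeting all three criteria", {
  f <- data.frame(species_id = 1, point_id = 1:5,
                  distance_to_range_km = c(200, -5, 10, NA, -5),
                  std_elevation = c(0, 3.5, 0, 0, 0),
                  in_season = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cf <- clip_pairs(f)
  expect_equal(cf$retained, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  rem <- attr(cf, "removals")
  expect_equal(unname(rem["distance"]), 1)
  expect_equal(unname(rem["elevation"]), 1)
  expect_equal(unname(rem["no_range_in_unit"]), 1)
  expect_equal(unname(rem["season"]), 1)
  # idempotent
  cf2 <- clip_pairs(cf)
  expect_equal(cf2$retained, cf$retained)
})

test_that("valley barrier is the lower point's elevation across ranges", {
  expect_equal(valley_barrier(500, 2000, "A", "A"), 0)
  expect_equal(valley_barrier(500, 2000, "A", "B"), 500)
  expect_equal(valley_barrier(0, 3000, "A", "B"), 0)
  expect_error(valley_barrier(0, 0, NA, "B"), "missing")
})

test_that("mountain barrier is ceiling minus the higher point across the divide", {
  expect_equal(mountain_barrier(0, 0, "east", "east"), 0)
  expect_equal(mountain_barrier(0, 0, "east", "west"), 4100)
  expect_equal(mountain_barrier(1000, 3000, "east", "west"), 1100)
  expect_equal(mountain_barrier(1000, 5000, "east", "west"), 0)  # floored
  expect_error(mountain_barrier(0, 0, NA, "west"), "missing")
})

test_that("barriers are symmetric and monotone in the relevant elevation", {
  set.seed(42)
  for (r in 1:50) {
    e <- runif(2, 0, 4000)
    rg <- sample(c("A", "B"), 2, replace = TRUE)
    sd_ <- sample(c("east", "west"), 2, replace = TRUE)
    expect_equal(valley_barrier(e[1], e[2], rg[1], rg[2]),
                 valley_barrier(e[2], e[1], rg[2], rg[1]))
    expect_equal(mountain_barrier(e[1], e[2], sd_[1], sd_[2]),
                 mountain_barrier(e[2], e[1], sd_[2], sd_[1]))
  }
  # grid monotonicity
  hi <- seq(0, 4100, by = 100)
  mb <- mountain_barrier(rep(0, length(hi)), hi, "east", "west")
  expect_true(all(diff(mb) <= 0))
  vb <- valley_barrier(hi, rep(4100, length(hi)), "A", "B")
  expect_true(all(diff(vb) >= 0))
})

test_that("site pair table is consistent with the barrier definitions", {
  pts <- data.frame(point_id = 1:3, x_km = c(0, 3, 4), y_km = 0,
                    elevation_m = c(100, 2000, 700),
                    range_id = c(1, 1, 2), side = c("west", "east", "east"),
                    precip_mm = c(1000, 2000, 1500))
  pr <- site_pair_table(pts)
  expect_equal(nrow(pr), 3)
  r12 <- pr[pr$point_i == 1 & pr$point_j == 2, ]
  expect_equal(r12$geo_km, 3)
  expect_equal(r12$valley_m, 0)       # same mountain range
  expect_equal(r12$mountain_m, 4100 - 2000)
  r13 <- pr[pr$point_i == 1 & pr$point_j == 3, ]
  expect_equal(r13$valley_m, 100)     # lower point's elevation
  expect_equal(r13$mountain_m, 4100 - 700)
})

test_that("subregion gridding matches an independent re-gridding", {
  x <- c(1, 16, 26, 1); y <- c(1, 1, 1, 30)
  id <- subregion_id(x, y, cell_km = 20)
  expect_equal(id[1], id[2])   # 15 km apart, same 20-km cell
  expect_false(id[1] == id[3]) # 25 km apart, different cells
  # independent re-gridding oracle
  oracle <- as.integer(factor(paste(x %/% 20, y %/% 20),
                              levels = unique(paste(x %/% 20, y %/% 20))))
  expect_equal(id, oracle)
})

test_that("model matrices use -1/+1 coding with forest positive", {
  w <- tiny_world(seed = 11)
  tr <- simulate_truth(w$L, w$pool, w$des, seed = 1)
  det <- simulate_detections(tr, w$des, w$pool, seed = 1)
  md <- build_occ_data(det, tr$features, w$pool, w$des)
  X <- md$cpp$Xocc
  lu <- X[, "land_use"]
  expect_true(all(lu %in% c(-1, 1)))
  expect_true(all(lu[md$pairs$land_use == "forest"] == 1))
  bin_cols <- paste0("trait_", attr(w$pool$traits, "binary"))
  expect_true(all(X[, bin_cols] %in% c(-1, 1)))
  # lowland modifier is a -1/+1 multiplier on both elevation columns
  expect_equal(abs(X[, "elev_linear_lowland"]), abs(X[, "elev_linear"]))
  expect_equal(abs(X[, "elev_quad_lowland"]), abs(X[, "elev_quad"]))
  bad <- det; bad$land_use[1] <- "urban"
  expect_error(build_occ_data(bad, tr$features, w$pool, w$des), "land-use")
})

test_that("d2r bins are ordered over the clipping window", {
  expect_equal(d2r_bin(-160), 0L)
  expect_equal(d2r_bin(159.9), 7L)
  expect_equal(d2r_bin(0), 4L)  # first bin past the midpoint edge
  k <- d2r_bin(seq(-159, 159, by = 1))
  expect_true(all(diff(k) >= 0))
})
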