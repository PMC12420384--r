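# Shared fixtures: small synthetic worlds and random occupancy cubes built
# in code at test time.

tiny_world <- function(seed = 1, n_species = 20, n_clusters = 10,
                       extent = c(40, 40), n_regions = 4) {
  L <- make_landscape(extent_km = extent, n_regions = n_regions, seed = seed)
  pool <- make_species_pool(L, n_species = n_species, n_families = 6,
                            seed = seed + 1)
  des <- make_sampling_design(L, n_clusters = n_clusters, seed = seed + 2)
  list(L = L, pool = pool, des = des)
}

# random cube with controllable structure; psi in (0, 1)
random_cube <- function(S = 12, P = 20, D = 3, seed = 1,
                        region_id = NULL) {
  set.seed(seed)
  f <- array(rbeta(S * P * D, 1.2, 2), c(S, P, D))
  p <- array(rbeta(S * P * D, 1, 3), c(S, P, D))
  info <- data.frame(pixel_id = seq_len(P),
                     x_km = (seq_len(P) - 0.5) * 2, y_km = 1,
                     region_id = region_id %||% rep(1:2, length.out = P))
  occupancy_cube(f, p, info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
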