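#' Generate a synthetic gridded landscape
#'
#' Builds a regular 2-km pixel grid with a smooth elevation surface (a sum of
#' Gaussian ridges, so montane gradients and lowlands coexist), contiguous
#' biogeographic regions, topographic units that cut across the regions, a
#' mountain-range label per pixel, a side-of-divide label (the analogue of the
#' east-Andes crest used by the mountain-barrier covariate), and a smooth
#' annual-precipitation surface.
#'
#' Regions are one-dimensional Voronoi bands along the x axis and topographic
#' units are bands along the y axis, so the two tessellations are contiguous
#' and strongly cut across one another.
#'
#' @param extent_km numeric length-2, landscape width and height in km; must
#'   be divisible by `pixel_size_km`.
#' @param pixel_size_km pixel edge length in km (default 2).
#' @param n_regions number of biogeographic regions (>= 1).
#' @param n_topo_units number of topographic units (>= 1).
#' @param elev_range numeric length-2, min and max elevation in metres.
#' @param n_ridges number of Gaussian ridges in the elevation surface.
#' @param divide_frac x position of the biogeographic divide, as a fraction of
#'   the landscape width.
#' @param precip_range numeric length-2, annual precipitation range (mm).
#' @param seed integer seed; the landscape is deterministic given the
#'   configuration and seed.
#' @return an object of class `msom_landscape`: a list with `pixels` (a
#'   data.frame with columns pixel_id, x_km, y_km, elevation_m, topo_unit_id,
#'   region_id, range_id, side, precip_mm), `pixel_size_km`, `extent_km` and
#'   the generating configuration.
#' @export
make_landscape <- function(extent_km = c(40, 40), pixel_size_km = 2,
                           n_regions = 4, n_topo_units = 3,
                           elev_range = c(0, 3500), n_ridges = 2,
                           divide_frac = 0.5,
                           precip_range = c(1000, 4000), seed = 1) {
  if (any(extent_km <= 0)) stop("landscape extent must be positive")
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (n_topo_units < 1) stop("n_topo_units must be >= 1")
  if (any(extent_km %% pixel_size_km != 0))
    stop("extent_km must be divisible by pixel_size_km")

  set.seed(child_seed(seed, 1))
  nx <- extent_km[1] / pixel_size_km
  ny <- extent_km[2] / pixel_size_km
  cx <- (seq_len(nx) - 0.5) * pixel_size_km
  cy <- (seq_len(ny) - 0.5) * pixel_size_km
  px <- expand.grid(x_km = cx, y_km = cy)

  # elevation: sum of Gaussian ridges along random lines, rescaled to range
  elev <- rep(0, nrow(px))
  for (r in seq_len(n_ridges)) {
    theta <- runif(1, 0, pi)
    x0 <- runif(1, 0, extent_km[1])
    y0 <- runif(1, 0, extent_km[2])
    width <- runif(1, 0.1, 0.3) * max(extent_km)
    amp <- runif(1, 0.5, 1)
    d <- abs(cos(theta) * (px$y_km - y0) - sin(theta) * (px$x_km - x0))
    elev <- elev + amp * exp(-d^2 / (2 * width^2))
  }
  rng <- range(elev)
  if (diff(rng) < 1e-12) {
    elev <- rep(mean(elev_range), length(elev))
  } else {
    elev <- elev_range[1] + diff(elev_range) * (elev - rng[1]) / diff(rng)
  }

  region_centres <- sort(runif(n_regions, 0, extent_km[1]))
  region_id <- apply(abs(outer(px$x_km, region_centres, "-")), 1, which.min)
  topo_centres <- sort(runif(n_topo_units, 0, extent_km[2]))
  topo_unit_id <- apply(abs(outer(px$y_km, topo_centres, "-")), 1, which.min)

  # precipitation: linear west-east gradient plus a smooth seeded bump
  bx <- runif(1, 0, extent_km[1]); by <- runif(1, 0, extent_km[2])
  bump <- exp(-((px$x_km - bx)^2 + (px$y_km - by)^2) /
                (2 * (0.25 * max(extent_km))^2))
  pr <- px$x_km / extent_km[1] + 0.3 * bump
  precip <- precip_range[1] + diff(precip_range) * (pr - min(pr)) / diff(range(pr))

  pixels <- data.frame(
    pixel_id = seq_len(nrow(px)),
    x_km = px$x_km, y_km = px$y_km,
    elevation_m = elev,
    topo_unit_id = as.integer(topo_unit_id),
    region_id = as.integer(region_id),
    range_id = as.integer(topo_unit_id),
    side = ifelse(px$x_km < divide_frac * extent_km[1], "west", "east"),
    precip_mm = precip
  )
  structure(list(pixels = pixels, pixel_size_km = pixel_size_km,
                 extent_km = extent_km, n_regions = as.integer(n_regions),
                 n_topo_units = as.integer(n_topo_units),
                 elev_range = elev_range, seed = seed),
            class = "msom_landscape")
}

#' @export
print.msom_landscape <- function(x, ...) {
  cat("msom_landscape:", nrow(x$pixels), "pixels of", x$pixel_size_km,
      "km;", x$n_regions, "regions,", x$n_topo_units, "topographic units\n")
  cat("  elevation", round(min(x$pixels$elevation_m)), "-",
      round(max(x$pixels$elevation_m)), "m\n")
  invisible(x)
}

#' Generate a synthetic species pool
#'
#' Simulates species with contiguous geographic ranges (a configurable
#' fraction endemic to a single biogeographic region, which drives
#' beta-diversity), elevational niches, family membership, and binary
#' (coded -1/+1) and continuous (standardized) traits.
#'
#' @param landscape an `msom_landscape`.
#' @param n_species number of species (>= 1).
#' @param n_families number of synthetic families species are assigned to.
#' @param endemic_fraction fraction of species whose range is restricted to
#'   one biogeographic region.
#' @param range_frac length-2 range of the fraction of the landscape (or
#'   region, for endemics) covered by a species range; log-uniform draw.
#' @param elev_breadth_m length-2 range of elevational niche breadths (m).
#' @param lowland_fraction fraction of species whose elevational minimum is
#'   forced to zero (they get the lowland elevation-curve modifier).
#' @param traits trait configuration: list with `binary` (named vector of
#'   probabilities of the +1 level) and `continuous` (named list of c(mean,
#'   sd)).
#' @param seed integer seed.
#' @return an object of class `msom_species_pool`: list with `species` (a
#'   data.frame: species_id, family_id, elev_min_m, elev_max_m, lowland,
#'   season_start, season_end), `ranges` (list of pixel-id vectors), and
#'   `traits` (species x trait matrix; attribute "binary" names the -1/+1
#'   columns).
#' @export
make_species_pool <- function(landscape, n_species = 150, n_families = 30,
                              endemic_fraction = 0.3,
                              range_frac = c(0.05, 0.6),
                              elev_breadth_m = c(600, 2600),
                              lowland_fraction = 0.3,
                              traits = list(
                                binary = c(forest_dependent = 0.5,
                                           barrier_restricted = 0.3),
                                continuous = list(log_mass = c(0, 1))),
                              seed = 1) {
  if (!inherits(landscape, "msom_landscape")) stop("landscape required")
  if (nrow(landscape$pixels) == 0) stop("empty landscape")
  if (n_species < 1) stop("n_species must be >= 1")
  set.seed(child_seed(seed, 2))
  px <- landscape$pixels
  er <- landscape$elev_range

  endemic <- runif(n_species) < endemic_fraction
  home_region <- sample(sort(unique(px$region_id)), n_species, replace = TRUE)
  ranges <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    cand <- if (endemic[s]) which(px$region_id == home_region[s]) else
      seq_len(nrow(px))
    frac <- exp(runif(1, log(range_frac[1]), log(range_frac[2])))
    n_take <- max(1L, round(frac * length(cand)))
    seed_px <- cand[sample.int(length(cand), 1)]
    d <- (px$x_km[cand] - px$x_km[seed_px])^2 +
      (px$y_km[cand] - px$y_km[seed_px])^2
    ranges[[s]] <- px$pixel_id[cand[order(d)[seq_len(n_take)]]]
  }

  lowland <- runif(n_species) < lowland_fraction
  breadth <- runif(n_species, elev_breadth_m[1], elev_breadth_m[2])
  centre <- runif(n_species, er[1], er[2])
  elev_min <- ifelse(lowland, 0, pmax(er[1], centre - breadth / 2))
  elev_max <- pmax(elev_min + breadth, elev_min + 100)

  tr_bin <- traits$binary %||% numeric(0)
  tr_con <- traits$continuous %||% list()
  tmat <- matrix(0, n_species, length(tr_bin) + length(tr_con),
                 dimnames = list(NULL, c(names(tr_bin), names(tr_con))))
  for (nm in names(tr_bin))
    tmat[, nm] <- ifelse(runif(n_species) < tr_bin[[nm]], 1, -1)
  for (nm in names(tr_con))
    tmat[, nm] <- rnorm(n_species, tr_con[[nm]][1], tr_con[[nm]][2])
  attr(tmat, "binary") <- names(tr_bin)

  species <- data.frame(
    species_id = seq_len(n_species),
    family_id = sample.int(n_families, n_species, replace = TRUE),
    elev_min_m = elev_min, elev_max_m = elev_max,
    lowland = lowland, endemic = endemic,
    season_start = NA_integer_, season_end = NA_integer_  # resident default
  )
  structure(list(species = species, ranges = ranges, traits = tmat,
                 n_families = as.integer(n_families), seed = seed),
            class = "msom_species_pool")
}

#' @export
print.msom_species_pool <- function(x, ...) {
  cat("msom_species_pool:", nrow(x$species), "species,",
      length(unique(x$species$family_id)), "families;",
      sum(x$species$endemic), "endemics\n")
  invisible(x)
}

#' Generate a clustered point-count sampling design
#'
#' Lays out paired forest/pasture clusters of point-count stations mirroring
#' a field protocol of clusters of three (occasionally two) points with 200 m
#' minimum spacing, four visits per point on consecutive days, and a small
#' team of observers. Pasture clusters are paired with forest clusters at
#' <200 m elevation difference and <21 km distance when `paired = TRUE`.
#'
#' @param landscape an `msom_landscape`.
#' @param n_clusters total number of clusters (split evenly between forest
#'   and pasture).
#' @param points_per_cluster 2 or 3 points per cluster.
#' @param n_visits visits per point (2-4; default 4).
#' @param n_observers number of observers.
#' @param paired logical; pair pasture clusters to forest clusters.
#' @param max_pair_km maximum pairing distance in km.
#' @param max_pair_elev_m maximum pairing elevation difference in metres.
#' @param seed integer seed.
#' @return an object of class `msom_design`: list with `clusters`, `points`
#'   and `visits` data.frames.
#' @export
make_sampling_design <- function(landscape, n_clusters = 80,
                                 points_per_cluster = 3, n_visits = 4,
                                 n_observers = 3, paired = TRUE,
                                 max_pair_km = 21, max_pair_elev_m = 200,
                                 seed = 1) {
  if (!inherits(landscape, "msom_landscape")) stop("landscape required")
  if (!points_per_cluster %in% 2:3) stop("points_per_cluster must be 2 or 3")
  if (!n_visits %in% 2:4) stop("n_visits must be in 2..4")
  set.seed(child_seed(seed, 3))
  px <- landscape$pixels
  ext <- landscape$extent_km
  n_forest <- ceiling(n_clusters / 2)
  n_pasture <- n_clusters - n_forest

  nearest_elev <- function(x, y) {
    i <- max.col(-(outer(x, px$x_km, "-")^2 + outer(y, px$y_km, "-")^2),
                 ties.method = "first")
    list(elev = px$elevation_m[i], region = px$region_id[i], pixel = i)
  }

  fx <- runif(n_forest, 1, ext[1] - 1)
  fy <- runif(n_forest, 1, ext[2] - 1)
  fe <- nearest_elev(fx, fy)
  # pasture partners: displaced draws accepted when pairing constraints hold
  px_x <- numeric(n_pasture); px_y <- numeric(n_pasture)
  pair_of <- rep(NA_integer_, n_pasture)
  for (i in seq_len(n_pasture)) {
    partner <- ((i - 1) %% n_forest) + 1
    for (try in 1:200) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0.5, if (paired) min(max_pair_km / 2, 8) else 8)
      x <- min(max(fx[partner] + rad * cos(ang), 0.5), ext[1] - 0.5)
      y <- min(max(fy[partner] + rad * sin(ang), 0.5), ext[2] - 0.5)
      e <- nearest_elev(x, y)$elev
      if (!paired || abs(e - fe$elev[partner]) < max_pair_elev_m) break
    }
    px_x[i] <- x; px_y[i] <- y; pair_of[i] <- partner
  }

  clusters <- data.frame(
    cluster_id = seq_len(n_clusters),
    x_km = c(fx, px_x), y_km = c(fy, px_y),
    land_use = rep(c("forest", "pasture"), c(n_forest, n_pasture)),
    pair_id = c(seq_len(n_forest), pair_of)
  )
  ne <- nearest_elev(clusters$x_km, clusters$y_km)
  clusters$region_id <- ne$region
  clusters$elevation_m <- ne$elev

  # points: >= 0.2 km spacing within a cluster, offsets within ~0.5 km
  pts <- do.call(rbind, lapply(seq_len(n_clusters), function(cl) {
    repeat {
      ox <- runif(points_per_cluster, -0.5, 0.5)
      oy <- runif(points_per_cluster, -0.5, 0.5)
      if (points_per_cluster == 1 ||
          min(dist(cbind(ox, oy))) >= 0.2) break
    }
    data.frame(cluster_id = cl,
               x_km = pmin(pmax(clusters$x_km[cl] + ox, 0), ext[1]),
               y_km = pmin(pmax(clusters$y_km[cl] + oy, 0), ext[2]),
               land_use = clusters$land_use[cl])
  }))
  pts$point_id <- seq_len(nrow(pts))
  npts <- nearest_elev(pts$x_km, pts$y_km)
  pts$elevation_m <- npts$elev
  pts$pixel_id <- px$pixel_id[npts$pixel]
  pts <- pts[, c("point_id", "cluster_id", "x_km", "y_km", "elevation_m",
                 "pixel_id", "land_use")]

  visits <- expand.grid(point_id = pts$point_id,
                        visit_index = seq_len(n_visits))
  visits <- visits[order(visits$point_id, visits$visit_index), ]
  cl_of <- pts$cluster_id[match(visits$point_id, pts$point_id)]
  obs_by_cluster_visit <- matrix(
    sample.int(n_observers, n_clusters * n_visits, replace = TRUE),
    n_clusters, n_visits)
  visits$observer_id <- obs_by_cluster_visit[
    cbind(cl_of, visits$visit_index)]
  visits$time_after_sunrise_h <- runif(nrow(visits), 0, 6)
  visits$date <- 100L + as.integer(visits$visit_index)  # day of year
  rownames(visits) <- NULL

  structure(list(clusters = clusters, points = pts, visits = visits,
                 n_visits = as.integer(n_visits),
                 n_observers = as.integer(n_observers), seed = seed),
            class = "msom_design")
}

#' @export
print.msom_design <- function(x, ...) {
  cat("msom_design:", nrow(x$clusters), "clusters,", nrow(x$points),
      "points,", nrow(x$visits), "visits (",
      sum(x$points$land_use == "forest"), "forest /",
      sum(x$points$land_use == "pasture"), "pasture points )\n")
  invisible(x)
}

#' Total field-observation effort of a design
#'
#' @param n_visits number of point visits conducted.
#' @param minutes_per_visit duration of one point count in minutes
#'   (default 10).
#' @return total observation minutes.
#' @export
survey_effort_minutes <- function(n_visits, minutes_per_visit = 10) {
  n_visits * minutes_per_visit
}
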