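#' Species-standardized elevation
#'
#' Linearly rescales elevation onto a species-specific scale where the
#' species' elevational minimum maps to -1 and its maximum to +1; the map is
#' unbounded outside the niche.
#'
#' @param e_m elevation(s) in metres.
#' @param species_min_m,species_max_m the species' elevational limits (m);
#'   `species_max_m` must exceed `species_min_m`. Both are recycled.
#' @return dimensionless standardized elevation.
#' @export
std_elevation <- function(e_m, species_min_m, species_max_m) {
  if (any(species_max_m <= species_min_m))
    stop("degenerate elevational range: species_max_m must exceed species_min_m")
  -1 + 2 * (e_m - species_min_m) / (species_max_m - species_min_m)
}

#' Signed distance to a species' range within a topographic unit
#'
#' Distance from sites to the nearest edge of a species' mapped range,
#' negative for in-range sites, positive outside, computed only against range
#' pixels lying in the same topographic unit as the site. When the species
#' has no range in the site's unit the result is `NA` (a sentinel; such
#' species-site pairs are later removed by biogeographic clipping).
#'
#' The range edge is approximated on the pixel grid: for an out-of-range
#' site, the distance to the nearest in-unit range pixel centre; for an
#' in-range site, the negated distance to the nearest in-unit non-range
#' pixel centre (or to the unit's farthest extent when the range fills the
#' unit).
#'
#' @param x_km,y_km site coordinates (vectors).
#' @param topo_unit_id topographic unit of each site.
#' @param range_pixels integer vector of pixel ids forming the species range.
#' @param landscape an `msom_landscape`.
#' @return signed distance in km per site (negative inside the range).
#' @export
distance_to_range <- function(x_km, y_km, topo_unit_id, range_pixels,
                              landscape) {
  px <- landscape$pixels
  if (length(range_pixels) == 0) stop("species has an empty range")
  in_range <- px$pixel_id %in% range_pixels
  out <- rep(NA_real_, length(x_km))
  for (u in unique(topo_unit_id)) {
    sites <- which(topo_unit_id == u)
    rp <- which(in_range & px$topo_unit_id == u)
    if (length(rp) == 0) next  # sentinel NA: no range in this unit
    np <- which(!in_range & px$topo_unit_id == u)
    d_in <- sqrt(outer(x_km[sites], px$x_km[rp], "-")^2 +
                   outer(y_km[sites], px$y_km[rp], "-")^2)
    nearest_range <- apply(d_in, 1, min)
    inside <- nearest_range <= landscape$pixel_size_km / sqrt(2) + 1e-9
    if (length(np) > 0) {
      d_out <- sqrt(outer(x_km[sites], px$x_km[np], "-")^2 +
                      outer(y_km[sites], px$y_km[np], "-")^2)
      nearest_nonrange <- apply(d_out, 1, min)
    } else {
      nearest_nonrange <- rep(max(landscape$extent_km), length(sites))
    }
    out[sites] <- ifelse(inside, -nearest_nonrange, nearest_range)
  }
  out
}

#' Species-point biogeographic features
#'
#' Computes, for every species-point combination, the signed
#' distance-to-range (within topographic units), the species-standardized
#' elevation, and the in-season flag, ready for biogeographic clipping.
#'
#' @param points data.frame with point_id, x_km, y_km, elevation_m and either
#'   pixel_id or coordinates resolvable against the landscape.
#' @param pool an `msom_species_pool`.
#' @param landscape an `msom_landscape`.
#' @param dates optional day-of-year of the survey period midpoint used for
#'   the seasonality gate; ignored for resident species.
#' @return data.frame with one row per species-point pair: species_id,
#'   point_id, distance_to_range_km (NA when the species has no range in the
#'   point's unit), std_elevation, in_season.
#' @export
species_point_features <- function(points, pool, landscape, dates = NULL) {
  px <- landscape$pixels
  topo <- px$topo_unit_id[match(points$pixel_id, px$pixel_id)]
  if (anyNA(topo)) {
    i <- max.col(-(outer(points$x_km, px$x_km, "-")^2 +
                     outer(points$y_km, px$y_km, "-")^2),
                 ties.method = "first")
    topo <- px$topo_unit_id[i]
  }
  sp <- pool$species
  out <- vector("list", nrow(sp))
  for (s in seq_len(nrow(sp))) {
    d2r <- distance_to_range(points$x_km, points$y_km, topo,
                             pool$ranges[[s]], landscape)
    se <- std_elevation(points$elevation_m, sp$elev_min_m[s], sp$elev_max_m[s])
    resident <- is.na(sp$season_start[s])
    in_season <- if (resident || is.null(dates)) rep(TRUE, nrow(points)) else
      dates >= sp$season_start[s] & dates <= sp$season_end[s]
    out[[s]] <- data.frame(species_id = sp$species_id[s],
                           point_id = points$point_id,
                           distance_to_range_km = d2r,
                           std_elevation = se,
                           in_season = in_season)
  }
  do.call(rbind, out)
}

#' Biogeographic clipping of species-point pairs
#'
#' Applies the retention rule defining which species-point combinations
#' enter the occupancy model: distance-to-range below a cutoff (160 km by
#' default), species-standardized elevation strictly inside a window ((-3, 3)
#' by default), and in season. Pairs with a sentinel (NA) distance-to-range
#' (no range in the point's topographic unit) are removed.
#'
#' @param features output of [species_point_features()].
#' @param d2r_max_km distance-to-range cutoff in km.
#' @param elev_window open interval of retained standardized elevations.
#' @return `features` with a logical `retained` column; per-criterion removal
#'   counts attached as attribute "removals".
#' @export
clip_pairs <- function(features, d2r_max_km = 160, elev_window = c(-3, 3)) {
  no_unit <- is.na(features$distance_to_range_km)
  far <- !no_unit & features$distance_to_range_km >= d2r_max_km
  out_elev <- features$std_elevation <= elev_window[1] |
    features$std_elevation >= elev_window[2]
  out_season <- !features$in_season
  features$retained <- !(no_unit | far | out_elev | out_season)
  attr(features, "removals") <- c(no_range_in_unit = sum(no_unit),
                                  distance = sum(far),
                                  elevation = sum(out_elev),
                                  season = sum(out_season))
  features
}

#' Valley-barrier distance between two sites
#'
#' Zero for site pairs on the same mountain range; otherwise the elevation of
#' the lower site, so valley barriers weigh most heavily on high-elevation
#' avifaunas. Symmetric in site order.
#'
#' @param elev_i,elev_j site elevations (m).
#' @param range_i,range_j mountain-range labels.
#' @return barrier distance in metres (vectorized).
#' @export
valley_barrier <- function(elev_i, elev_j, range_i, range_j) {
  if (anyNA(range_i) || anyNA(range_j)) stop("missing mountain-range label")
  ifelse(range_i == range_j, 0, pmin(elev_i, elev_j))
}

#' Mountain-barrier distance between two sites
#'
#' Zero for site pairs on the same side of the major biogeographic divide;
#' otherwise a ceiling constant (4,100 m by default, the highest elevation
#' sampled in the motivating study) minus the elevation of the higher site,
#' floored at zero, so mountain barriers weigh most heavily on low-elevation
#' avifaunas. Symmetric in site order.
#'
#' @param elev_i,elev_j site elevations (m).
#' @param side_i,side_j side-of-divide labels.
#' @param ceiling_m barrier ceiling in metres (default 4100).
#' @return barrier distance in metres (vectorized).
#' @export
mountain_barrier <- function(elev_i, elev_j, side_i, side_j,
                             ceiling_m = 4100) {
  if (anyNA(side_i) || anyNA(side_j)) stop("missing side-of-divide label")
  ifelse(side_i == side_j, 0, pmax(ceiling_m - pmax(elev_i, elev_j), 0))
}

#' All within-stratum site-pair distances for dissimilarity modelling
#'
#' Builds the site-pair predictor table for the generalized dissimilarity
#' models: geographic distance, pairwise valley- and mountain-barrier
#' distances, and the two sites' elevations and annual precipitation.
#'
#' @param points data.frame of sites: point_id, x_km, y_km, elevation_m, and
#'   optionally range_id / side / precip_mm (filled from the landscape via
#'   pixel_id when absent).
#' @param landscape an `msom_landscape` (optional when points carry
#'   range_id, side and precip_mm already).
#' @param ceiling_m mountain-barrier ceiling (m).
#' @return data.frame of all unordered site pairs: point_i, point_j, geo_km,
#'   valley_m, mountain_m, elev_i, elev_j, precip_i, precip_j.
#' @export
site_pair_table <- function(points, landscape = NULL, ceiling_m = 4100) {
  if (!is.null(landscape)) {
    px <- landscape$pixels
    idx <- match(points$pixel_id, px$pixel_id)
    if (is.null(points$range_id)) points$range_id <- px$range_id[idx]
    if (is.null(points$side)) points$side <- px$side[idx]
    if (is.null(points$precip_mm)) points$precip_mm <- px$precip_mm[idx]
  }
  n <- nrow(points)
  if (n < 2) stop("need at least two sites")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  data.frame(
    point_i = points$point_id[i], point_j = points$point_id[j],
    geo_km = sqrt((points$x_km[i] - points$x_km[j])^2 +
                    (points$y_km[i] - points$y_km[j])^2),
    valley_m = valley_barrier(points$elevation_m[i], points$elevation_m[j],
                              points$range_id[i], points$range_id[j]),
    mountain_m = mountain_barrier(points$elevation_m[i],
                                  points$elevation_m[j],
                                  points$side[i], points$side[j], ceiling_m),
    elev_i = points$elevation_m[i], elev_j = points$elevation_m[j],
    precip_i = points$precip_mm[i], precip_j = points$precip_mm[j]
  )
}

#' Distance-to-range bin index for the monotonic effect
#'
#' Discretizes signed distance-to-range into ordered categories over a
#' symmetric window; category 0 is the most in-range bin, so the monotonic
#' effect accumulates as a species gets farther out of range.
#'
#' @param d2r_km signed distance to range (km).
#' @param limits window over which bins are spread.
#' @param n_bins number of equal-width bins.
#' @return integer bin index in 0..(n_bins - 1).
#' @export
d2r_bin <- function(d2r_km, limits = c(-160, 160), n_bins = 8) {
  edges <- seq(limits[1], limits[2], length.out = n_bins + 1)
  pmin(pmax(findInterval(d2r_km, edges[-c(1, n_bins + 1)]), 0L),
       n_bins - 1L)
}

#' Assign points to subregions on an axis-aligned grid
#'
#' Groups points into square subregions (20-km cells by default), the
#' spatial blocking scale used for the subregion random effect.
#'
#' @param x_km,y_km point coordinates.
#' @param cell_km subregion cell size in km.
#' @return integer subregion ids (dense, starting at 1).
#' @export
subregion_id <- function(x_km, y_km, cell_km = 20) {
  key <- paste(floor(x_km / cell_km), floor(y_km / cell_km))
  match(key, unique(key))
}
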