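#' Random hexagonal grid over a landscape
#'
#' Tiles the landscape with regular hexagons of a nominal area, applying a
#' uniform random offset (within one cell span) and a uniform random
#' rotation in [0, 60) degrees to avoid artefacts of any particular grid
#' configuration. Pixels are assigned to the hexagon containing their
#' centre; cells are retained only when their member-pixel area covers at
#' least a minimum fraction (default 60 percent) of the hexagon area.
#'
#' @param landscape an `msom_landscape`.
#' @param area_km2 nominal hexagon area in square km.
#' @param seed integer seed (grid deterministic given seed).
#' @param min_overlap minimum covered-area fraction for a cell to be kept.
#' @param rotate,offset set FALSE to pin rotation / offset at zero (the
#'   reference tiling).
#' @return list of class `msom_hexgrid`: `cells` (list of integer vectors of
#'   member pixel indices), `info` (data.frame: cell_id, n_pixels,
#'   overlap_frac, centre coordinates), `area_km2`, `rotation_deg`,
#'   `offset_km` and `vertices` (list of 6 x 2 matrices, landscape frame).
#' @export
make_hex_grid <- function(landscape, area_km2, seed = 1, min_overlap = 0.6,
                          rotate = TRUE, offset = TRUE) {
  if (area_km2 <= 0) stop("hexagon area must be positive")
  px <- landscape$pixels
  size <- sqrt(2 * area_km2 / (3 * sqrt(3)))  # circumradius
  set.seed(child_seed(seed, 50))
  theta <- if (rotate) runif(1, 0, pi / 3) else 0
  off <- if (offset) runif(2, 0, sqrt(3) * size) else c(0, 0)

  # transform pixel centres into the grid frame
  xr <- cos(-theta) * (px$x_km - off[1]) - sin(-theta) * (px$y_km - off[2])
  yr <- sin(-theta) * (px$x_km - off[1]) + cos(-theta) * (px$y_km - off[2])
  # pointy-top axial coordinates with cube rounding
  qf <- (sqrt(3) / 3 * xr - yr / 3) / size
  rf <- (2 / 3 * yr) / size
  xq <- qf; xz <- rf; xy <- -xq - xz
  rq <- round(xq); rr <- round(xz); ry <- round(xy)
  dq <- abs(rq - xq); dr <- abs(rr - xz); dy <- abs(ry - xy)
  fix_q <- dq > dr & dq > dy
  fix_r <- !fix_q & dr > dy
  rq[fix_q] <- -ry[fix_q] - rr[fix_q]
  rr[fix_r] <- -ry[fix_r] - rq[fix_r]

  key <- paste(rq, rr)
  cells <- split(seq_len(nrow(px)), key)
  pixel_area <- landscape$pixel_size_km^2
  overlap <- lengths(cells) * pixel_area / area_km2
  keep <- overlap >= min_overlap
  cells <- cells[keep]
  if (length(cells) == 0)
    warning("no hexagon cell meets the overlap criterion at area ",
            area_km2, " km2")
  uq <- as.numeric(sub(" .*", "", names(cells)))
  ur <- as.numeric(sub(".* ", "", names(cells)))
  cx_g <- size * sqrt(3) * (uq + ur / 2)
  cy_g <- size * 1.5 * ur
  cx <- cos(theta) * cx_g - sin(theta) * cy_g + off[1]
  cy <- sin(theta) * cx_g + cos(theta) * cy_g + off[2]
  ang <- theta + pi / 6 + (0:5) * pi / 3
  vertices <- lapply(seq_along(cells), function(i)
    cbind(cx[i] + size * cos(ang), cy[i] + size * sin(ang)))
  info <- data.frame(cell_id = seq_along(cells),
                     n_pixels = unname(lengths(cells)),
                     overlap_frac = unname(overlap[keep]),
                     x_km = cx, y_km = cy)
  structure(list(cells = unname(cells), info = info, area_km2 = area_km2,
                 rotation_deg = theta * 180 / pi, offset_km = off,
                 vertices = vertices),
            class = "msom_hexgrid")
}

#' @export
print.msom_hexgrid <- function(x, ...) {
  cat("msom_hexgrid:", length(x$cells), "cells of", x$area_km2,
      "km2 (rotation", round(x$rotation_deg, 1), "deg)\n")
  invisible(x)
}

#' Multiplicative beta-diversity of a cell
#'
#' Gamma diversity (thresholded species-pool richness of the whole cell)
#' divided by the mean alpha diversity (pool richness of each member pixel).
#' Always at least 1, since the cell pool contains every pixel pool.
#'
#' @param cube an `msom_cube`.
#' @param cell integer vector of member pixel indices.
#' @param tau occupancy threshold.
#' @param draw posterior draw index.
#' @return multiplicative beta-diversity (NA with a warning when mean alpha
#'   is zero).
#' @export
multiplicative_beta <- function(cube, cell, tau = 0.2, draw = 1) {
  if (length(cell) < 1) stop("cell must have at least one member pixel")
  gamma <- length(species_pool(cube, cell, tau, draw))
  alpha <- vapply(cell, function(i)
    length(species_pool(cube, i, tau, draw)), numeric(1))
  if (mean(alpha) == 0) {
    warning("cell skipped: mean alpha diversity is zero")
    return(NA_real_)
  }
  gamma / mean(alpha)
}

#' Excess regional biodiversity loss of a cell
#'
#' The log-ratio of the cell-scale loss metric (percent decline of the
#' sensitivity quantile over the cell's species pool) to the average of its
#' member pixels' local loss metrics; zero means regional losses equal local
#' losses and one means regional losses about 2.7-fold worse.
#'
#' @param cube an `msom_cube`.
#' @param cell integer vector of member pixel indices.
#' @param tau occupancy threshold.
#' @param q sensitivity quantile (0.5 = the median species).
#' @param draw posterior draw index.
#' @param local_average "decline" (default) averages the pixels' percent
#'   declines; "sensitivity" averages the pixels' sensitivity quantiles and
#'   converts at the end.
#' @return log-ratio of regional to mean local loss (NA when either level
#'   has non-positive loss; such cell-draw pairs are counted by callers).
#' @export
excess_regional_loss <- function(cube, cell, tau = 0.2, q = 0.5, draw = 1,
                                 local_average = c("decline", "sensitivity")) {
  local_average <- match.arg(local_average)
  pool_r <- species_pool(cube, cell, tau, draw)
  if (length(pool_r) == 0) return(NA_real_)
  S_r <- species_sensitivity(cube, cell, draw)
  reg <- community_metric(S_r[pool_r], q)$decline_pct
  loc <- vapply(cell, function(i) {
    pool_i <- species_pool(cube, i, tau, draw)
    if (length(pool_i) == 0) return(NA_real_)
    S_i <- species_sensitivity(cube, i, draw)
    if (local_average == "decline")
      community_metric(S_i[pool_i], q)$decline_pct
    else community_metric(S_i[pool_i], q)$value
  }, numeric(1))
  loc <- loc[!is.na(loc)]
  if (length(loc) == 0) return(NA_real_)
  mean_loc <- if (local_average == "decline") mean(loc) else
    100 * (1 - 1 / mean(loc))
  if (is.na(reg) || reg <= 0 || mean_loc <= 0) return(NA_real_)
  log(reg / mean_loc)
}

#' Cell-by-draw scaling records across an area ladder
#'
#' For each posterior draw, lays a fresh random hexagonal grid (per area in
#' the ladder) and computes each retained cell's multiplicative
#' beta-diversity and excess regional loss.
#'
#' @param cube an `msom_cube` whose pixel_info carries coordinates.
#' @param landscape the `msom_landscape` the cube was predicted on.
#' @param areas area ladder in square km.
#' @param tau occupancy threshold.
#' @param q sensitivity quantile.
#' @param draws draw indices (default all).
#' @param seed integer seed.
#' @return data.frame: area_km2, draw, cell_id, n_pixels, beta_mult, excess;
#'   attribute "n_excluded" counts cell-draw pairs lost to non-positive
#'   losses.
#' @export
hex_scaling_records <- function(cube, landscape,
                                areas = c(290, 860, 2600, 7800, 23000, 70000),
                                tau = 0.2, q = 0.5, draws = NULL, seed = 1) {
  if (is.null(draws)) draws <- seq_len(n_draws(cube))
  pi <- cube_pixel_info(cube)
  sub <- landscape
  sub$pixels <- landscape$pixels[match(pi$pixel_id, landscape$pixels$pixel_id), ]
  out <- list(); n_excluded <- 0L
  for (d in draws) {
    for (a in areas) {
      grid <- make_hex_grid(sub, a, seed = child_seed(seed, d * 7 + which(areas == a)))
      for (ci in seq_along(grid$cells)) {
        cell <- grid$cells[[ci]]
        bm <- multiplicative_beta(cube, cell, tau, d)
        ex <- suppressWarnings(excess_regional_loss(cube, cell, tau, q, d))
        if (is.na(bm) || is.na(ex)) { n_excluded <- n_excluded + 1L; next }
        out[[length(out) + 1]] <- data.frame(
          area_km2 = a, draw = d, cell_id = ci,
          n_pixels = length(cell), beta_mult = bm, excess = ex)
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Per-draw OLS of excess regional loss against beta-diversity
#'
#' Closed-form ordinary least squares of the log excess-loss ratio on
#' multiplicative beta-diversity, fitted independently within each posterior
#' draw (the grid is descriptive, so no within-draw standard errors), with a
#' pointwise 90 percent band of the fitted lines across draws.
#'
#' @param records data.frame with columns draw, beta_mult, excess (e.g. from
#'   [hex_scaling_records()], optionally filtered to one area).
#' @param min_cells draws with fewer cells are skipped.
#' @return list of class `msom_scalingfit`: `coefs` (per draw slope and
#'   intercept), and `band(x)` returning mean / lo / hi of fitted lines.
#' @export
fit_scaling_regression <- function(records, min_cells = 3) {
  by_draw <- split(records, records$draw)
  coefs <- do.call(rbind, lapply(by_draw, function(r) {
    if (nrow(r) < min_cells) return(NULL)
    b <- cov(r$beta_mult, r$excess) / var(r$beta_mult)
    a <- mean(r$excess) - b * mean(r$beta_mult)
    data.frame(draw = r$draw[1], intercept = a, slope = b)
  }))
  band <- function(x) {
    fits <- outer(coefs$slope, x) + coefs$intercept
    data.frame(x = x, mean = colMeans(fits),
               lo = apply(fits, 2, quantile, 0.05),
               hi = apply(fits, 2, quantile, 0.95))
  }
  structure(list(coefs = coefs, band = band), class = "msom_scalingfit")
}

#' @export
print.msom_scalingfit <- function(x, ...) {
  cat("msom_scalingfit:", nrow(x$coefs), "per-draw OLS fits; mean slope",
      round(mean(x$coefs$slope), 3), ", mean intercept",
      round(mean(x$coefs$intercept), 3), "\n")
  invisible(x)
}
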