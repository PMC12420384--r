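#' Construct an occupancy cube
#'
#' The occupancy cube is the currency passed from the occupancy model to all
#' downstream metrics: occupancy probability indexed by species x pixel x
#' scenario (hypothetical all-forest and all-pasture landscapes) x posterior
#' draw. Species-pixel pairs removed by biogeographic clipping carry 0.
#'
#' @param forest,pasture arrays of occupancy probabilities, species x pixel
#'   (x draw); a matrix is treated as a single draw.
#' @param pixel_info optional data.frame with one row per pixel (pixel_id,
#'   x_km, y_km, region_id, ...) attached for scoped metrics.
#' @return an `msom_cube`: numeric array [species, pixel, scenario, draw]
#'   with scenario dimnames c("forest", "pasture").
#' @export
occupancy_cube <- function(forest, pasture, pixel_info = NULL) {
  if (length(dim(forest)) == 2) forest <- array(forest, c(dim(forest), 1))
  if (length(dim(pasture)) == 2) pasture <- array(pasture, c(dim(pasture), 1))
  stopifnot(all(dim(forest) == dim(pasture)))
  if (any(forest < 0 | forest > 1 | pasture < 0 | pasture > 1))
    stop("occupancy probabilities must lie in [0, 1]")
  d <- dim(forest)
  cube <- array(0, c(d[1], d[2], 2, d[3]),
                dimnames = list(NULL, NULL, c("forest", "pasture"), NULL))
  cube[, , 1, ] <- forest
  cube[, , 2, ] <- pasture
  attr(cube, "pixel_info") <- pixel_info
  class(cube) <- c("msom_cube", "array")
  cube
}

#' @export
print.msom_cube <- function(x, ...) {
  d <- dim(x)
  cat("msom_cube:", d[1], "species x", d[2], "pixels x 2 scenarios x",
      d[4], "draws\n")
  invisible(x)
}

n_draws <- function(cube) dim(cube)[4]
n_cube_species <- function(cube) dim(cube)[1]
n_cube_pixels <- function(cube) dim(cube)[2]

cube_pixel_info <- function(cube) {
  pi <- attr(cube, "pixel_info")
  if (is.null(pi))
    pi <- data.frame(pixel_id = seq_len(n_cube_pixels(cube)))
  pi
}
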