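#' Species sensitivity to habitat conversion
#'
#' The ratio of a species' total predicted occupancy under an all-forest
#' scenario to its total under an all-pasture scenario over a set of pixels.
#' S = 1 means no response; S > 1 means the species loses from conversion.
#' Species whose pasture total is numerically zero get an infinite sentinel
#' (they are excluded, with a count, by [community_metric()]).
#'
#' @param cube an `msom_cube`.
#' @param scope integer pixel indices (columns of the cube) defining the
#'   area; default all pixels.
#' @param draw posterior draw index.
#' @param eps pasture totals below this are treated as zero.
#' @return numeric vector of sensitivities, one per species.
#' @export
species_sensitivity <- function(cube, scope = NULL, draw = 1, eps = 1e-9) {
  if (is.null(scope)) scope <- seq_len(n_cube_pixels(cube))
  if (length(scope) == 0) stop("scope must be non-empty")
  f <- cube[, scope, 1, draw, drop = FALSE]
  p <- cube[, scope, 2, draw, drop = FALSE]
  num <- apply(f, 1, sum)
  den <- apply(p, 1, sum)
  out <- num / den
  out[den < eps] <- Inf
  out
}

#' Thresholded species pool of a scope
#'
#' All species whose occupancy probability reaches a threshold (default 0.2)
#' on at least one pixel of the scope, in either scenario. Local pools use a
#' single pixel as the scope.
#'
#' @param cube an `msom_cube`.
#' @param scope integer pixel indices; default all pixels.
#' @param tau occupancy threshold in (0, 1); alternates 0.1 and 0.3.
#' @param draw posterior draw index.
#' @return integer vector of species indices in the pool.
#' @export
species_pool <- function(cube, scope = NULL, tau = 0.2, draw = 1) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  if (is.null(scope)) scope <- seq_len(n_cube_pixels(cube))
  x <- cube[, scope, , draw, drop = FALSE]
  mx <- apply(x, 1, max)
  which(mx >= tau)
}

#' Community loss metric: sensitivity quantiles and percent decline
#'
#' Quantiles (default 25th, 50th, 75th percentiles, linear interpolation
#' between order statistics) of the species-sensitivity distribution over a
#' pool, with the associated percent decline 100 * (1 - 1/Q).
#'
#' @param sensitivities numeric vector of species sensitivities (a pool's
#'   values); non-finite entries are dropped with a count.
#' @param q quantile levels.
#' @return data.frame with q, value (the sensitivity quantile) and
#'   decline_pct; attribute "n_excluded" counts dropped non-finite values.
#' @export
community_metric <- function(sensitivities, q = c(0.25, 0.5, 0.75)) {
  keep <- is.finite(sensitivities)
  n_exc <- sum(!keep)
  s <- sensitivities[keep]
  if (length(s) == 0) stop("empty species pool: no finite sensitivities")
  v <- unname(quantile(s, q, type = 7))
  out <- data.frame(q = q, value = v, decline_pct = 100 * (1 - 1 / v))
  attr(out, "n_excluded") <- n_exc
  out
}

region_scopes <- function(cube, regions) {
  if (is.null(regions)) {
    pi <- cube_pixel_info(cube)
    if (is.null(pi$region_id)) stop("no region ids available")
    regions <- pi$region_id
  }
  split(seq_len(n_cube_pixels(cube)), regions)
}

#' Regional sensitivity relative to the all-region community
#'
#' For each region and posterior draw, the ratio of the region's community
#' loss metric to the study-wide metric, both computed on study-wide species
#' sensitivities with the pool selecting species. Values below one mean the
#' region is less sensitive than the community across all regions.
#'
#' @param cube an `msom_cube`.
#' @param regions region id per pixel (defaults to the cube's pixel_info).
#' @param tau occupancy threshold for the species pools.
#' @param q quantile of the sensitivity distribution.
#' @param draws draw indices (default up to 100).
#' @return data.frame region x draw with region metric, study metric and
#'   their ratio; regions with empty pools are flagged NA.
#' @export
regional_relative_sensitivity <- function(cube, regions = NULL, tau = 0.2,
                                          q = 0.5, draws = NULL) {
  scopes <- region_scopes(cube, regions)
  if (is.null(draws)) draws <- seq_len(min(100, n_draws(cube)))
  out <- list()
  for (d in draws) {
    S <- species_sensitivity(cube, draw = d)
    full_pool <- species_pool(cube, tau = tau, draw = d)
    m_full <- community_metric(S[full_pool], q)$value
    for (r in names(scopes)) {
      pool_r <- species_pool(cube, scopes[[r]], tau, d)
      m_r <- if (length(pool_r) == 0) NA_real_ else
        community_metric(S[pool_r], q)$value
      out[[length(out) + 1]] <- data.frame(
        region = r, draw = d, q = q, metric_region = m_r,
        metric_study = m_full, ratio = m_r / m_full)
    }
  }
  do.call(rbind, out)
}

#' Region-pooling trajectory of relative sensitivity
#'
#' Generates random sequences of regions, each starting from one region and
#' sequentially adding regions until all are present; for each sequence
#' length k the species pool is the union of the first k regions' pools and
#' the community metric is computed on study-wide sensitivities restricted
#' to that pool, relative to the all-region metric. Sequence-averaged
#' relative sensitivities are summarized per k by their posterior mean and
#' 90 percent interval.
#'
#' @param cube an `msom_cube`.
#' @param regions region id per pixel (defaults to the cube's pixel_info).
#' @param tau occupancy threshold.
#' @param q sensitivity quantile.
#' @param n_sequences number of random region sequences (default 1000).
#' @param draws posterior draw indices (default up to 100).
#' @param seed integer seed for the sequences.
#' @return list of class `msom_pooling`: `summary` (per k: mean, lo, hi of
#'   the sequence-averaged relative sensitivity, and mean excess_pct = the
#'   percent by which the all-region loss exceeds the k-region loss),
#'   `per_draw` (k x draw matrix of sequence averages), `n_sequences`.
#' @export
pooling_trajectory <- function(cube, regions = NULL, tau = 0.2, q = 0.5,
                               n_sequences = 1000, draws = NULL, seed = 1) {
  if (n_sequences < 1) stop("n_sequences must be >= 1")
  scopes <- region_scopes(cube, regions)
  R <- length(scopes)
  if (R < 2) stop("need at least 2 regions")
  if (is.null(draws)) draws <- seq_len(min(100, n_draws(cube)))
  set.seed(child_seed(seed, 40))
  seqs <- replicate(n_sequences, sample.int(R), simplify = FALSE)

  rel <- array(NA_real_, c(R, length(draws)))
  exc <- array(NA_real_, c(R, length(draws)))
  for (di in seq_along(draws)) {
    d <- draws[di]
    S <- species_sensitivity(cube, draw = d)
    pools <- lapply(scopes, function(sc) species_pool(cube, sc, tau, d))
    full_pool <- sort(unique(unlist(pools)))
    q_of <- function(pool) {  # fast path of community_metric's quantile
      s <- S[pool]; s <- s[is.finite(s)]
      quantile(s, q, type = 7, names = FALSE)
    }
    m_full <- q_of(full_pool)
    acc_rel <- numeric(R); acc_exc <- numeric(R)
    in_pool <- matrix(FALSE, n_cube_species(cube), R)
    for (r in seq_len(R)) in_pool[pools[[r]], r] <- TRUE
    for (sq in seqs) {
      member <- rep(FALSE, n_cube_species(cube))
      for (k in seq_len(R)) {
        member <- member | in_pool[, sq[k]]
        m_k <- q_of(which(member))
        acc_rel[k] <- acc_rel[k] + m_k / m_full
        acc_exc[k] <- acc_exc[k] + (m_full / m_k - 1)
      }
    }
    rel[, di] <- acc_rel / n_sequences
    exc[, di] <- acc_exc / n_sequences
  }
  summary <- data.frame(
    k = seq_len(R),
    mean = rowMeans(rel),
    lo = apply(rel, 1, quantile, 0.05),
    hi = apply(rel, 1, quantile, 0.95),
    excess_pct = 100 * rowMeans(exc))
  structure(list(summary = summary, per_draw = rel,
                 n_sequences = n_sequences, draws = draws, tau = tau, q = q),
            class = "msom_pooling")
}

#' @export
print.msom_pooling <- function(x, ...) {
  cat("msom_pooling:", nrow(x$summary), "region counts,",
      x$n_sequences, "sequences,", length(x$draws), "draws\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
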