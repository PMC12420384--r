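#' Pairwise Sorensen and Simpson dissimilarities
#'
#' For every unordered pair of sites, the shared-species count a, the
#' per-site unique counts b and c, the Sorensen dissimilarity
#' (b + c) / (2a + b + c) and the Simpson dissimilarity (the turnover
#' component of Sorensen) min(b, c) / (a + min(b, c)). Pairs where both
#' quantities are undefined (two empty communities) take the d = 1
#' convention and are flagged.
#'
#' @param comm binary site x species matrix (presence = 1).
#' @param site_ids optional site identifiers (default row indices).
#' @return data.frame of all site pairs: site_i, site_j, a, b, c, sorensen,
#'   simpson, empty_pair flag.
#' @export
pair_dissimilarities <- function(comm, site_ids = NULL) {
  comm <- (comm > 0) * 1
  n <- nrow(comm)
  if (n < 2) stop("need at least two sites")
  if (is.null(site_ids)) site_ids <- seq_len(n)
  A <- tcrossprod(comm)
  rs <- rowSums(comm)
  ij <- which(upper.tri(A), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  a <- A[ij]
  b <- rs[i] - a
  c_ <- rs[j] - a
  den_s <- 2 * a + b + c_
  sor <- ifelse(den_s == 0, 1, (b + c_) / den_s)
  mbc <- pmin(b, c_)
  den_t <- a + mbc
  sim <- ifelse(den_t == 0, 1, mbc / den_t)
  data.frame(site_i = site_ids[i], site_j = site_ids[j],
             a = a, b = b, c = c_, sorensen = sor, simpson = sim,
             empty_pair = den_s == 0)
}

#' Order-2 I-spline basis with knots at (min, median, max)
#'
#' Three monotone non-decreasing piecewise-quadratic basis functions, each
#' 0 at or below the first knot and 1 at or above the last, the standard
#' construction used by generalized dissimilarity models.
#'
#' @param x evaluation points.
#' @param knots strictly increasing numeric length 3 (min, median, max).
#' @return length(x) x 3 matrix of basis values in [0, 1].
#' @export
ispline_basis <- function(x, knots) {
  if (length(knots) != 3 || any(diff(knots) <= 0))
    stop("knots must be strictly increasing (min, median, max)")
  a <- knots[1]; b <- knots[2]; c_ <- knots[3]
  x1 <- pmin(pmax(x, a), b)
  x2 <- pmin(pmax(x, a), c_)
  x3 <- pmin(pmax(x, b), c_)
  i1 <- 1 - ((b - x1) / (b - a))^2
  i2 <- ifelse(x2 <= b,
               (x2 - a)^2 / ((b - a) * (c_ - a)),
               1 - (c_ - x2)^2 / ((c_ - b) * (c_ - a)))
  i3 <- ((x3 - b) / (c_ - b))^2
  cbind(i1, i2, i3)
}

gdm_design <- function(pred_pair, pred_site, knots = NULL) {
  preds <- c(names(pred_pair), names(pred_site))
  if (length(preds) == 0) stop("at least one predictor required")
  if (is.null(knots)) {
    knots <- list()
    for (nm in names(pred_pair)) {
      v <- pred_pair[[nm]]
      knots[[nm]] <- c(min(v), median(v), max(v))
    }
    for (nm in names(pred_site)) {
      v <- c(pred_site[[nm]][, 1], pred_site[[nm]][, 2])
      knots[[nm]] <- c(min(v), median(v), max(v))
    }
  }
  X <- NULL; cols <- character(0); usable <- character(0)
  for (nm in names(pred_pair)) {
    k <- knots[[nm]]
    if (any(diff(k) <= 0)) next  # constant predictor: drop
    X <- cbind(X, ispline_basis(pred_pair[[nm]], k))
    cols <- c(cols, paste0(nm, "_", 1:3)); usable <- c(usable, nm)
  }
  for (nm in names(pred_site)) {
    k <- knots[[nm]]
    if (any(diff(k) <= 0)) next
    B <- abs(ispline_basis(pred_site[[nm]][, 1], k) -
               ispline_basis(pred_site[[nm]][, 2], k))
    X <- cbind(X, B)
    cols <- c(cols, paste0(nm, "_", 1:3)); usable <- c(usable, nm)
  }
  if (!is.null(X)) colnames(X) <- cols
  list(X = X, knots = knots, predictors = usable,
       site_level = names(pred_site))
}

#' Fit a generalized dissimilarity model
#'
#' Minimizes the weighted squared error between observed dissimilarities and
#' 1 - exp(-eta) with eta a non-negative intercept plus non-negative
#' I-spline terms (three basis functions per predictor, knots at the
#' predictor's minimum, median and maximum), so every partial response is
#' monotone non-decreasing. Pairwise predictors (geographic distance,
#' barrier separations) enter directly; site-level predictors (elevation,
#' precipitation) enter as the absolute difference of the two sites'
#' transformed values.
#'
#' @param d observed dissimilarities in [0, 1], one per site pair.
#' @param pred_pair named list of pairwise-distance predictors (numeric
#'   vectors aligned with `d`).
#' @param pred_site named list of site-level predictors, each a 2-column
#'   matrix (value at site i, value at site j).
#' @param weights optional non-negative pair weights (default uniform).
#' @param knots optional named list of length-3 knot vectors (defaults to
#'   min / median / max of each predictor's values).
#' @return object of class `msom_gdm`: `alpha0`, `coefs` (named list of
#'   3-vectors, all non-negative), `knots`, `rms` (weighted RMS residual),
#'   `predictors`.
#' @export
fit_gdm <- function(d, pred_pair = list(), pred_site = list(),
                    weights = NULL, knots = NULL) {
  des <- gdm_design(pred_pair, pred_site, knots)
  n <- length(d)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  X <- des$X
  if (is.null(X)) {  # all predictors degenerate: intercept-only fit
    eta_hat <- -log(1 - min(max(sum(w * d), 0), 0.999))
    return(structure(list(alpha0 = max(eta_hat, 0), coefs = list(),
                          knots = des$knots, rms = sqrt(sum(w * (d - sum(w * d))^2)),
                          predictors = character(0),
                          site_level = des$site_level),
                     class = "msom_gdm"))
  }
  obj <- function(th) {
    eta <- th[1] + drop(X %*% th[-1])
    r <- d - (1 - exp(-eta))
    sum(w * r^2)
  }
  grad <- function(th) {
    eta <- th[1] + drop(X %*% th[-1])
    ee <- exp(-eta)
    r <- d - (1 - ee)
    g_eta <- -2 * w * r * ee
    c(sum(g_eta), drop(crossprod(X, g_eta)))
  }
  th0 <- c(0.05, rep(0.05, ncol(X)))
  opt <- nlminb(th0, obj, grad, lower = rep(0, length(th0)),
                control = list(iter.max = 500))
  th <- opt$par
  coefs <- split(th[-1], rep(des$predictors, each = 3))[des$predictors]
  coefs <- lapply(coefs, function(v) setNames(v, paste0("w", 1:3)))
  structure(list(alpha0 = th[1], coefs = coefs, knots = des$knots,
                 rms = sqrt(opt$objective), predictors = des$predictors,
                 site_level = des$site_level),
            class = "msom_gdm")
}

#' @export
print.msom_gdm <- function(x, ...) {
  cat("msom_gdm: intercept", round(x$alpha0, 4), "; predictors:",
      paste(x$predictors, collapse = ", "), "; rms", round(x$rms, 4), "\n")
  invisible(x)
}

#' Fitted partial ecological distance along one predictor
#'
#' The contribution f_j of predictor j to eta, evaluated as
#' |f_j(x1) - f_j(x2)|; with `x2` at the predictor's minimum this traces the
#' partial-distance curve from the gradient's origin.
#'
#' @param fit an `msom_gdm`.
#' @param predictor predictor name.
#' @param x1,x2 gradient positions (vectorized).
#' @return partial ecological distance(s).
#' @export
partial_distance <- function(fit, predictor, x1, x2) {
  if (!predictor %in% names(fit$coefs)) stop("unknown predictor: ", predictor)
  k <- fit$knots[[predictor]]
  w <- fit$coefs[[predictor]]
  f1 <- drop(ispline_basis(x1, k) %*% w)
  f2 <- drop(ispline_basis(x2, k) %*% w)
  abs(f1 - f2)
}

#' Partial-distance curve over a predictor's gradient
#'
#' @param fit an `msom_gdm` (or element of a bootstrap ensemble).
#' @param predictor predictor name.
#' @param n grid size.
#' @return data.frame x, f (curve from the gradient minimum).
#' @export
partial_curve <- function(fit, predictor, n = 200) {
  k <- fit$knots[[predictor]]
  x <- seq(k[1], k[3], length.out = n)
  data.frame(x = x, f = partial_distance(fit, predictor, x, rep(k[1], n)))
}

#' Predicted dissimilarity from a fitted GDM
#'
#' @param object an `msom_gdm`.
#' @param pred_pair,pred_site predictors as in [fit_gdm()].
#' @param ... unused.
#' @return predicted dissimilarities in [0, 1).
#' @export
predict.msom_gdm <- function(object, pred_pair = list(), pred_site = list(),
                             ...) {
  eta <- rep(object$alpha0, max(1, length(pred_pair[[1]] %||%
                                            pred_site[[1]][, 1])))
  for (nm in object$predictors) {
    k <- object$knots[[nm]]
    w <- object$coefs[[nm]]
    if (nm %in% object$site_level) {
      B <- abs(ispline_basis(pred_site[[nm]][, 1], k) -
                 ispline_basis(pred_site[[nm]][, 2], k))
    } else B <- ispline_basis(pred_pair[[nm]], k)
    eta <- eta + drop(B %*% w)
  }
  1 - exp(-eta)
}

#' Bayesian-bootstrap ensemble of GDM fits
#'
#' Draws site-level Dirichlet(1, ..., 1) weights per replicate, propagates
#' them to pair weights as the renormalized product of the two sites'
#' weights, and fits one GDM per replicate (default 400).
#'
#' @param d,pred_pair,pred_site as in [fit_gdm()].
#' @param sites 2-column matrix of site indices (i, j) per pair, used to map
#'   site weights to pairs.
#' @param n_sites number of distinct sites.
#' @param n number of bootstrap replicates (default 400).
#' @param seed integer seed.
#' @param knots optional shared knot list (defaults to the full-data knots,
#'   held fixed across replicates).
#' @return object of class `msom_gdm_ensemble`: list of fits, the weight
#'   matrix (replicates x sites), and `curve_band(predictor)` giving the
#'   mean and 90 percent band of partial curves.
#' @export
bayesian_bootstrap <- function(d, pred_pair = list(), pred_site = list(),
                               sites, n_sites = max(sites), n = 400,
                               seed = 1, knots = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(knots)) knots <- gdm_design(pred_pair, pred_site)$knots
  set.seed(child_seed(seed, 60))
  W <- matrix(rexp(n * n_sites), n, n_sites)
  W <- W / rowSums(W)
  fits <- vector("list", n)
  for (r in seq_len(n)) {
    pw <- W[r, sites[, 1]] * W[r, sites[, 2]]
    pw <- pw / sum(pw)
    fits[[r]] <- fit_gdm(d, pred_pair, pred_site, weights = pw, knots = knots)
  }
  curve_band <- function(predictor, n_grid = 100) {
    k <- knots[[predictor]]
    x <- seq(k[1], k[3], length.out = n_grid)
    M <- sapply(fits, function(f)
      if (predictor %in% names(f$coefs))
        partial_distance(f, predictor, x, rep(k[1], n_grid))
      else rep(0, n_grid))
    data.frame(x = x, mean = rowMeans(M),
               lo = apply(M, 1, quantile, 0.05),
               hi = apply(M, 1, quantile, 0.95))
  }
  structure(list(fits = fits, weights = W, knots = knots,
                 curve_band = curve_band),
            class = "msom_gdm_ensemble")
}

#' @export
print.msom_gdm_ensemble <- function(x, ...) {
  cat("msom_gdm_ensemble:", length(x$fits), "Bayesian-bootstrap replicates\n")
  invisible(x)
}

#' Detection-corrected community tables from the occupancy posterior
#'
#' Samples the latent presence state from its conditional distribution per
#' posterior draw: certain presence wherever the species was detected at the
#' point, and otherwise Bernoulli with probability
#' psi * prod_j(1 - p_j) / (psi * prod_j(1 - p_j) + 1 - psi).
#'
#' @param fit an `msom_occfit` fitted with `save_local = TRUE` (the
#'   conditional needs every random-effect value) or by MAP.
#' @param n_draws number of posterior draws to use (error when exceeding the
#'   stored draws).
#' @param seed integer seed.
#' @return list with one binary point x species presence matrix per draw
#'   (rownames = point ids, colnames = species ids).
#' @export
detection_corrected_communities <- function(fit, n_draws = 400, seed = 1) {
  md <- fit$model
  if (n_draws > nrow(fit$draws))
    stop("n_draws exceeds available posterior draws (",
         nrow(fit$draws), ")")
  if (ncol(fit$draws) != md$npar)
    stop("fit must store all parameters (refit with save_local = TRUE)")
  pairs <- md$pairs
  pts <- sort(unique(pairs$point_id))
  sps <- sort(unique(pairs$species_id))
  pair_start <- md$cpp$pair_start
  y <- md$cpp$y
  N <- nrow(pairs)
  any_det <- vapply(seq_len(N), function(i)
    any(y[(pair_start[i] + 1):pair_start[i + 1]] == 1), logical(1))
  set.seed(child_seed(seed, 70))
  draw_ids <- if (n_draws == nrow(fit$draws)) seq_len(n_draws) else
    sample.int(nrow(fit$draws), n_draws)
  out <- vector("list", n_draws)
  for (r in seq_len(n_draws)) {
    par <- as.numeric(fit$draws[draw_ids[r], ])
    et <- occ_eta(par, md$cpp)
    psi <- plogis(et$eta_occ)
    lq <- vapply(seq_len(N), function(i) {
      v <- (pair_start[i] + 1):pair_start[i + 1]
      sum(plogis(-et$eta_det[v], log.p = TRUE))
    }, numeric(1))
    pz <- conditional_z_prob(psi, exp(lq), any_det)
    z <- rbinom(N, 1, pz)
    m <- matrix(0L, length(pts), length(sps),
                dimnames = list(pts, sps))
    m[cbind(match(pairs$point_id, pts), match(pairs$species_id, sps))] <- z
    out[[r]] <- m
  }
  out
}
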