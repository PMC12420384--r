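#' Monotonic ordinal effect of a binned covariate
#'
#' The monotonic-effect construction used for distance-to-range: a scale
#' coefficient multiplied by the cumulative sum of a simplex over the ordered
#' bins, so the contribution is monotone in the bin index with the sign of
#' the scale.
#'
#' @param k integer bin index (vectorized), in 0..length(zeta); 0 contributes
#'   nothing and the top bin contributes the full scale.
#' @param b scale coefficient.
#' @param zeta simplex of bin increments (non-negative, sums to 1).
#' @return contribution to the logit-scale linear predictor.
#' @export
monotonic_effect <- function(k, b, zeta) {
  if (any(zeta < 0) || abs(sum(zeta) - 1) > 1e-8)
    stop("zeta must be a simplex (non-negative, summing to 1)")
  if (any(k < 0 | k > length(zeta))) stop("bin index out of 0..K")
  b * c(0, cumsum(zeta))[k + 1]
}

#' Marginal log-likelihood of one detection history
#'
#' The occupancy-model likelihood with the latent presence state summed out:
#' log of psi times the Bernoulli likelihood of the visit history plus, when
#' no visit detected the species, (1 - psi).
#'
#' @param psi occupancy probability.
#' @param p per-visit detection probabilities (length J >= 1).
#' @param y per-visit binary detections (length J).
#' @return the marginal log-probability of `y`.
#' @export
marginal_loglik_point <- function(psi, p, y) {
  if (length(y) == 0) stop("no visits: J must be >= 1")
  if (length(p) == 1) p <- rep(p, length(y))
  logD <- sum(y * log(p) + (1 - y) * log1p(-p))
  if (any(y == 1)) log(psi) + logD
  else log(psi * exp(logD) + (1 - psi))
}

#' Conditional presence probability given an all-zero detection history
#'
#' Bayes-rule update of the latent presence state: with any detection the
#' species is present with certainty; with none, presence probability is
#' psi * prod(1 - p) / (psi * prod(1 - p) + 1 - psi).
#'
#' @param psi occupancy probability (vectorized).
#' @param q_prod product over visits of (1 - p_j) (vectorized).
#' @param any_det logical, any detection across visits.
#' @return conditional probability that z = 1.
#' @export
conditional_z_prob <- function(psi, q_prod, any_det) {
  ifelse(any_det, 1, psi * q_prod / (psi * q_prod + 1 - psi))
}
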