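#' Euclidean distance between a person and an item position
#'
#' @param w,z Numeric coordinate vectors of equal length.
#' @return The Euclidean distance `sqrt(sum((w - z)^2))`.
#' @examples
#' euclidean_distance(c(3, 4), c(0, 0)) # 5
#' @export
euclidean_distance <- function(w, z) {
  if (length(w) != length(z)) {
    abort(sprintf("Coordinate lengths differ: length(w) = %d, length(z) = %d.",
                  length(w), length(z)))
  }
  sqrt(sum((w - z)^2))
}

# person-by-item distance matrix, N x J
lsirm_distances <- function(Z, W) {
  Z <- as.matrix(Z); W <- as.matrix(W)
  d2 <- outer(rowSums(Z^2), rep(1, nrow(W))) +
    outer(rep(1, nrow(Z)), rowSums(W^2)) - 2 * Z %*% t(W)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Response probability of the latent space item response model
#'
#' The probability of a correct/endorsed response is
#' `plogis(theta + beta - gamma * d(w, z))`: the person and item intercepts
#' raise it, the person-item distance in the latent space lowers it. Under
#' joint maximum likelihood the distance weight `gamma` is not a free
#' parameter (it is absorbed into the coordinate scale) and fitting always
#' uses `gamma = 1`; the argument exists for simulation and evaluation.
#'
#' @param theta Person intercept (scalar or vector).
#' @param beta Item intercept (scalar or vector, recycled against `theta`).
#' @param w,z Item and person coordinate vectors (equal length), or `NULL`
#'   together with `distance` supplied directly.
#' @param gamma Positive distance weight, default 1.
#' @param distance Optional precomputed distance, bypassing `w`, `z`.
#' @return Probability in (0, 1).
#' @examples
#' lsirm_prob(0, 0, w = c(1, 1), z = c(1, 1)) # 0.5
#' @export
lsirm_prob <- function(theta, beta, w = NULL, z = NULL, gamma = 1,
                       distance = NULL) {
  if (gamma < 0) abort("`gamma` must be non-negative.")
  d <- distance %||% euclidean_distance(w, z)
  plogis(theta + beta - gamma * d)
}

#' Joint log-likelihood of a binary LSIRM
#'
#' Bernoulli log-likelihood summed over the observed cells only (missing
#' cells contribute nothing, the missing-at-random treatment). Probabilities
#' are clamped to `[1e-12, 1 - 1e-12]` to keep the value finite.
#'
#' @param data Response data (anything accepted by [lsirm_data()]).
#' @param theta,beta Person and item intercept vectors.
#' @param Z,W Person (N x D) and item (J x D) coordinate matrices.
#' @param gamma Distance weight; fitting uses 1 (see [lsirm_prob()]).
#' @return The scalar log-likelihood.
#' @export
lsirm_loglik <- function(data, theta, beta, Z, W, gamma = 1) {
  dat <- lsirm_data(data)
  Z <- as.matrix(Z); W <- as.matrix(W)
  stopifnot(length(theta) == dat$n_persons, length(beta) == dat$n_items,
            nrow(Z) == dat$n_persons, nrow(W) == dat$n_items)
  P <- plogis(outer(as.numeric(theta), as.numeric(beta), "+") -
                gamma * lsirm_distances(Z, W))
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  sum((dat$values * log(P) + (1 - dat$values) * log(1 - P))[dat$observed])
}

#' L2-penalized joint log-likelihood
#'
#' [lsirm_loglik()] minus `lambda / 2` times the sum of squares of all
#' parameters; with `lambda = 1` the penalty matches the effect of standard
#' normal priors on every parameter. `lambda = 0` recovers the unpenalized
#' likelihood exactly.
#'
#' @inheritParams lsirm_loglik
#' @param lambda Non-negative penalty strength.
#' @export
lsirm_penalized_loglik <- function(data, theta, beta, Z, W, lambda = 1) {
  if (lambda < 0) abort("`lambda` must be non-negative.")
  lsirm_loglik(data, theta, beta, Z, W) -
    (lambda / 2) * (sum(theta^2) + sum(beta^2) + sum(Z^2) + sum(W^2))
}

#' Analytic gradients of the (penalized) joint log-likelihood
#'
#' Partial derivatives with respect to the person intercepts, item
#' intercepts, and both coordinate matrices. The distance derivative uses the
#' unit direction vector; at a person-item distance of exactly zero the
#' coordinate subgradient 0 is used.
#'
#' @inheritParams lsirm_penalized_loglik
#' @param lambda Penalty strength; 0 gives the unpenalized gradients.
#' @return A list with elements `theta`, `beta`, `Z`, `W` shaped like the
#'   inputs.
#' @export
lsirm_gradients <- function(data, theta, beta, Z, W, lambda = 0) {
  dat <- lsirm_data(data)
  Z <- as.matrix(Z); W <- as.matrix(W)
  theta <- as.numeric(theta); beta <- as.numeric(beta)
  D <- lsirm_distances(Z, W)
  P <- plogis(outer(theta, beta, "+") - D)
  R <- (dat$values - P) * dat$observed
  S <- R / D
  S[D == 0] <- 0
  g <- list(
    theta = rowSums(R) - lambda * theta,
    beta = colSums(R) - lambda * beta,
    Z = -(Z * rowSums(S)) + S %*% W - lambda * Z,
    W = t(S) %*% Z - W * colSums(S) - lambda * W)
  g
}
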