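#' Optimizer control settings
#'
#' @param max_iter Maximum number of full block-update sweeps.
#' @param rel_tol Convergence tolerance on the relative change of the
#'   objective between sweeps.
#' @param step_init Initial gradient-ascent step size per parameter block;
#'   backtracking halves it (up to 10 times per update) whenever a step would
#'   decrease the objective, so the objective trace is non-decreasing.
#' @return A list of class `lsirm_control`.
#' @export
lsirm_control <- function(max_iter = 2000, rel_tol = 1e-6, step_init = 0.1) {
  stopifnot(max_iter >= 1, rel_tol > 0, step_init > 0)
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 step_init = step_init), class = "lsirm_control")
}

#' Default norm bounds for constrained estimation
#'
#' The constrained estimator (cJML) bounds the Euclidean norm of each
#' person parameter vector `(theta_p, z_p)` and each item parameter vector
#' `(beta_j, w_j)`, both of length `D + 1`. Defaults follow the
#' `5 * sqrt(dim)`-style recipe for constrained joint likelihood estimation
#' of multidimensional IRT models with the dimension count replaced by
#' `D + 1`: `C_item = 5 * sqrt(D + 1)` and `C_person = 2 * sqrt(D + 1)`.
#' Both are overridable in [fit_lsirm()]. The implied uniform-ball priors
#' have per-coordinate variance `C^2 / (D + 3)`, larger than the unit
#' variance of the normal prior the penalized estimator mimics, so the
#' constrained estimator is the least restrictive of the two.
#'
#' @param dim Latent space dimension D >= 1.
#' @return A list with `C_person` and `C_item`.
#' @examples
#' default_constraints(2)
#' @export
default_constraints <- function(dim) {
  stopifnot(dim >= 1)
  list(C_person = 2 * sqrt(dim + 1), C_item = 5 * sqrt(dim + 1))
}

#' Project a vector onto a Euclidean norm ball
#'
#' Returns `v` unchanged if `||v|| <= C`, else rescales it to norm `C`.
#' This is the gradient-projection step of the constrained estimator.
#'
#' @param v Numeric vector.
#' @param C Positive radius.
#' @export
project_to_ball <- function(v, C) {
  stopifnot(C > 0)
  n <- sqrt(sum(v^2))
  if (n <= C) v else v * (C / n)
}

# echelon fixed-zero pattern for W: entry (anchors[k], d) fixed for d > k
echelon_fixed <- function(J, D, anchors) {
  Wfix <- matrix(0L, J, D)
  if (D > 1) {
    for (k in seq_len(D - 1)) Wfix[anchors[k], (k + 1):D] <- 1L
  }
  Wfix
}

# i.i.d. N(0, 0.1^2) start values with echelon-fixed entries of W zeroed
random_init <- function(N, J, D, Wfix) {
  W <- matrix(rnorm(J * D, sd = 0.1), J, D)
  W[Wfix == 1] <- 0
  list(theta = rnorm(N, sd = 0.1), beta = NULL, Z = matrix(rnorm(N * D, sd = 0.1), N, D),
       W = W)
}

#' Fit a latent space item response model by regularized joint maximum
#' likelihood
#'
#' Embeds persons and items in a `dim`-dimensional Euclidean space and
#' estimates all person and item parameters jointly as fixed effects by
#' gradient ascent, regularized either by an L2 penalty (`method = "pjml"`,
#' the analogue of standard normal priors) or by norm constraints on the
#' person and item parameter vectors enforced through gradient projection
#' (`method = "cjml"`, the analogue of uniform-ball priors). The latent
#' space is identified during optimization by the echelon constraint (fixed
#' zeros in the anchor rows of the item coordinates) plus a deterministic
#' sign convention applied on exit.
#'
#' For pJML the parameter blocks theta, beta, Z, W are updated sequentially
#' within each sweep; for cJML the person block `(theta, Z)` and the item
#' block `(beta, W)` alternate, each followed by projection onto its norm
#' ball. Backtracking line search guarantees a non-decreasing objective
#' trace. Missing responses are excluded from the likelihood
#' (missing-at-random).
#'
#' Ordinal items (`ordinal = TRUE`) are fitted through the sequential
#' (continuation-ratio) model: each item is expanded into cumulative binary
#' dummy items (see [sequential_expand()]) that share the item's single
#' coordinate vector, and the binary machinery above is applied to the
#' expansion, which is likelihood-equivalent to the sequential model.
#'
#' @param data Wide person-by-item responses: a data frame, matrix, or
#'   [lsirm_data()] object.
#' @param dim Latent space dimension D.
#' @param method `"pjml"` (penalized) or `"cjml"` (constrained).
#' @param lambda Penalty strength for pJML (default 1, matching standard
#'   normal priors).
#' @param C_person,C_item Norm bounds for cJML; defaults from
#'   [default_constraints()].
#' @param ordinal Logical; fit the sequential ordinal model.
#' @param anchors Indices of the `dim - 1` echelon anchor items (default the
#'   first `dim - 1` items).
#' @param init `NULL` for random initialization, or a list with `theta`,
#'   `beta`, `Z`, `W` start values (`W` at original-item level for ordinal
#'   fits; `beta` at dummy level, or `NULL` to draw randomly).
#' @param seed Integer seed making the random initialization (and hence the
#'   whole fit) reproducible; `NULL` uses the current RNG state.
#' @param control An [lsirm_control()] list.
#' @return An object of class `lsirm_fit`. Use [tidy()] for a parameter
#'   tibble, [glance()] for a one-row fit summary, [autoplot()] for the
#'   latent-space map, and `$thresholds` for ordinal category effects.
#' @examples
#' sim <- simulate_lsirm(n_persons = 80, n_items = 12, seed = 1)
#' fit <- fit_lsirm(sim$data, dim = 2, seed = 2,
#'                  control = lsirm_control(max_iter = 50))
#' glance(fit)
#' @export
fit_lsirm <- function(data, dim = 2, method = c("pjml", "cjml"), lambda = 1,
                      C_person = NULL, C_item = NULL, ordinal = FALSE,
                      anchors = NULL, init = NULL, seed = NULL,
                      control = lsirm_control()) {
  method <- match.arg(method)
  dat <- lsirm_data(data, ordinal = ordinal)
  check_no_empty(dat)
  if (lambda < 0) abort("`lambda` must be non-negative.")
  stopifnot(dim >= 1)

  if (ordinal) {
    expansion <- sequential_expand(dat)
    bin <- expansion$data
    item_of <- expansion$item_map$item_index
  } else {
    expansion <- NULL
    bin <- dat
    item_of <- seq_len(dat$n_items)
  }
  N <- bin$n_persons
  Jd <- bin$n_items          # dummy-level columns
  J <- dat$n_items           # original items (coordinate blocks)
  if (J < dim) abort(sprintf("Need at least dim = %d items; got %d.", dim, J))
  anchors <- anchors %||% seq_len(max(dim - 1, 0))
  if (length(anchors) < dim - 1 || anyDuplicated(anchors) ||
      any(anchors < 1 | anchors > J)) {
    abort(sprintf("`anchors` must be %d distinct item indices.", dim - 1))
  }
  Wfix <- echelon_fixed(J, dim, anchors)

  defaults <- default_constraints(dim)
  C_person <- C_person %||% defaults$C_person
  C_item <- C_item %||% defaults$C_item
  stopifnot(C_person > 0, C_item > 0)

  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(init)) init <- random_init(N, J, dim, Wfix)
  theta0 <- init$theta %||% rnorm(N, sd = 0.1)
  beta0 <- init$beta %||% rnorm(Jd, sd = 0.1)
  Z0 <- as.matrix(init$Z %||% matrix(rnorm(N * dim, sd = 0.1), N, dim))
  W0 <- as.matrix(init$W %||% matrix(rnorm(J * dim, sd = 0.1), J, dim))
  W0[Wfix == 1] <- 0
  stopifnot(length(theta0) == N, length(beta0) == Jd,
            all(dim(Z0) == c(N, dim)), all(dim(W0) == c(J, dim)))

  res <- lsirm_fit_core(
    Y = bin$values, M = bin$observed * 1, item = item_of - 1L, Wfix = Wfix,
    method = method, lambda = lambda, C_person = C_person, C_item = C_item,
    theta = theta0, beta = beta0, Z = Z0, W = W0,
    max_iter = control$max_iter, rel_tol = control$rel_tol,
    step_init = control$step_init)

  if (!res$converged) {
    warn(sprintf("Fit did not converge in %d sweeps (relative change %.2e).",
                 control$max_iter, abs(diff(tail2(res$trace))) /
                   (abs(res$trace[length(res$trace) - 1]) + 1e-10)))
  }
  if (res$clamped && isTRUE(getOption("lsjml.verbose", FALSE))) {
    inform("Some response probabilities were clamped during optimization.")
  }

  # deterministic sign convention (zero pattern already enforced during fitting)
  rot <- echelon_rotate(res$W, res$Z, anchors = anchors)

  thresholds <- NULL
  if (ordinal) {
    thresholds <- expansion$item_map
    thresholds$estimate <- as.numeric(res$beta)
  }

  structure(list(
    theta = as.numeric(res$theta), beta = as.numeric(res$beta),
    Z = rot$Z, W = rot$W,
    objective = res$objective,
    loglik = lsirm_loglik_core(bin$values, bin$observed * 1, item_of - 1L,
                               res$theta, res$beta, rot$Z, rot$W, 1),
    trace = as.numeric(res$trace), converged = res$converged,
    n_iter = res$n_iter, clamped = res$clamped,
    method = method, dim = dim,
    lambda = if (method == "pjml") lambda else NULL,
    C_person = if (method == "cjml") C_person else NULL,
    C_item = if (method == "cjml") C_item else NULL,
    anchors = anchors, rotation = rot$record,
    ordinal = ordinal, thresholds = thresholds, expansion = expansion,
    item_names = dat$item_names,
    n_persons = N, n_items = J, n_dummy_items = Jd,
    seed = seed, control = control), class = "lsirm_fit")
}

tail2 <- function(x) x[c(length(x) - 1, length(x))]

#' @export
print.lsirm_fit <- function(x, ...) {
  cat(sprintf("<lsirm_fit> %s, D = %d, %d persons x %d items%s\n",
              x$method, x$dim, x$n_persons, x$n_items,
              if (x$ordinal) sprintf(" (%d dummy items)", x$n_dummy_items) else ""))
  cat(sprintf("  objective %.3f, log-likelihood %.3f, %d sweeps, %s\n",
              x$objective, x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predicted response probabilities
#'
#' Model probabilities `plogis(theta_p + beta_j - d(w_j, z_p))` for selected
#' person-item cells (for ordinal fits, `item` indexes the expanded dummy
#' items, i.e. category boundaries).
#'
#' @param object An `lsirm_fit`.
#' @param cells Optional data frame or 2-column matrix of (person, item)
#'   indices; default all cells.
#' @param ... Unused.
#' @return A tibble with `person`, `item`, `.fitted`.
#' @export
predict.lsirm_fit <- function(object, cells = NULL, ...) {
  if (is.null(cells)) {
    cells <- cbind(rep(seq_len(object$n_persons), object$n_dummy_items),
                   rep(seq_len(object$n_dummy_items), each = object$n_persons))
  }
  cells <- as.matrix(as.data.frame(cells))[, 1:2, drop = FALSE]
  item_of <- if (object$ordinal) object$expansion$item_map$item_index
             else seq_len(object$n_items)
  p <- cells[, 1]
  j <- cells[, 2]
  i <- item_of[j]
  d <- sqrt(rowSums((object$Z[p, , drop = FALSE] - object$W[i, , drop = FALSE])^2))
  tibble::tibble(person = p, item = j,
                 .fitted = plogis(object$theta[p] + object$beta[j] - d))
}
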