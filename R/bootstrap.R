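#' Nonparametric bootstrap uncertainty for an LSIRM fit
#'
#' Resamples persons (rows) with replacement `B` times, refits the model
#' with the same options, and aligns every replicate to the point estimate
#' (echelon rotation and sign convention, then orthogonal Procrustes onto
#' the point estimate's item configuration) so that rotational and
#' reflectional indeterminacy cannot inflate the spread. Standard errors are
#' standard deviations across aligned replicates; for each item a 2-D
#' confidence ellipse is derived from the empirical covariance of its
#' aligned coordinates scaled by the chi-square(2) quantile at `level`.
#'
#' Coordinates held at zero by the echelon constraint are invariant across
#' replicates; their standard errors are reported as 0 and the item flagged
#' `constrained` (its uncertainty region degenerates to a line).
#'
#' Person-level standard errors are computed across the replicates in which
#' that person's row was drawn at least once.
#'
#' @param fit A converged `lsirm_fit` (binary or ordinal).
#' @param data The responses the fit was estimated on.
#' @param B Number of bootstrap replicates (>= 1).
#' @param level Ellipse confidence level in (0, 1), default 0.99.
#' @param seed Optional integer seed.
#' @param warm_start If `TRUE`, each replicate fit starts at the point
#'   estimate (resampled rows carry their person parameters): identical
#'   resamples then give identical refits, and refits are fast. The default
#'   `FALSE` uses a fresh random initialization per replicate, which also
#'   propagates the fit's own initialization variability into the standard
#'   errors and gives better-calibrated ellipses.
#' @return An object of class `lsirm_boot`: tibbles `item_se` (intercept and
#'   coordinate SEs, `constrained` flag), `person_se`, `ellipses` (center,
#'   semi-axes, angle per item), the replicate count used, and the aligned
#'   replicate coordinates (`W_reps`, an array J x D x B_ok).
#' @export
lsirm_bootstrap <- function(fit, data, B = 200, level = 0.99, seed = NULL,
                            warm_start = FALSE) {
  stopifnot(inherits(fit, "lsirm_fit"), B >= 1, level > 0, level < 1)
  dat <- lsirm_data(data, ordinal = fit$ordinal)
  if (dat$n_persons != fit$n_persons || dat$n_items != fit$n_items) {
    abort("`data` does not match the fitted model's dimensions.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, B)

  J <- fit$n_items
  D <- fit$dim
  W_reps <- array(NA_real_, c(J, D, B))
  beta_reps <- matrix(NA_real_, fit$n_dummy_items, B)
  theta_reps <- matrix(NA_real_, fit$n_persons, B)
  Z_reps <- array(NA_real_, c(fit$n_persons, D, B))
  n_fail <- 0
  for (b in seq_len(B)) {
    rows <- sample.int(dat$n_persons, replace = TRUE)
    vals <- dat$values[rows, , drop = FALSE]
    vals[!dat$observed[rows, , drop = FALSE]] <- NA
    init <- if (warm_start) {
      list(theta = fit$theta[rows], beta = fit$beta,
           Z = fit$Z[rows, , drop = FALSE], W = fit$W)
    } else NULL
    rb <- tryCatch(
      fit_lsirm(lsirm_data(vals, ordinal = fit$ordinal), dim = D,
                method = fit$method, lambda = fit$lambda %||% 1,
                C_person = fit$C_person, C_item = fit$C_item,
                ordinal = fit$ordinal, anchors = fit$anchors, init = init,
                seed = rep_seeds[b], control = fit$control),
      error = function(e) NULL)
    if (is.null(rb) || !rb$converged) {
      n_fail <- n_fail + 1
      next
    }
    al <- align_to_reference(rb$W, rb$Z, W_ref = fit$W)
    W_reps[, , b] <- al$W
    beta_reps[, b] <- rb$beta
    # map person parameters back to the original rows (first occurrence)
    first <- match(seq_len(dat$n_persons), rows)
    ok <- !is.na(first)
    theta_reps[ok, b] <- rb$theta[first[ok]]
    Z_reps[ok, , b] <- al$Z[first[ok], , drop = FALSE]
  }
  if (n_fail > 0.2 * B) {
    abort(sprintf("%d of %d bootstrap replicate fits failed.", n_fail, B))
  }
  used <- which(!is.na(W_reps[1, 1, ]))
  B_ok <- length(used)

  fixed <- echelon_fixed(J, D, fit$anchors)
  se_mat <- apply(W_reps[, , used, drop = FALSE], c(1, 2), sd)
  se_mat[fixed == 1] <- 0
  item_se <- tibble::tibble(
    item_index = seq_len(J), item = fit$item_names,
    constrained = rowSums(fixed) > 0)
  for (d in seq_len(D)) item_se[[paste0("se_w", d)]] <- se_mat[, d]
  item_se$se_beta <- if (fit$ordinal) NA_real_ else
    apply(beta_reps[, used, drop = FALSE], 1, sd)

  person_se <- tibble::tibble(
    person = seq_len(fit$n_persons),
    n_reps = rowSums(!is.na(theta_reps[, used, drop = FALSE])),
    se_theta = apply(theta_reps[, used, drop = FALSE], 1, sd, na.rm = TRUE))

  chi_q <- qchisq(level, df = 2)
  ellipses <- if (D < 2) tibble::tibble() else purrr::map_dfr(seq_len(J), function(i) {
    reps <- t(W_reps[i, 1:2, used, drop = TRUE])
    reps <- matrix(reps, ncol = 2)
    S <- stats::cov(reps)
    # fixed coordinates have exactly zero variance; the ellipse degenerates
    e <- eigen(S, symmetric = TRUE)
    v <- pmax(e$values, 0)
    tibble::tibble(item_index = i, item = fit$item_names[i],
                   center_1 = fit$W[i, 1], center_2 = fit$W[i, 2],
                   axis_1 = sqrt(v[1] * chi_q), axis_2 = sqrt(v[2] * chi_q),
                   angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                   constrained = any(fixed[i, 1:2] == 1))
  })

  structure(list(B = B, B_used = B_ok, n_failed = n_fail, level = level,
                 item_se = item_se, person_se = person_se, ellipses = ellipses,
                 W_reps = W_reps[, , used, drop = FALSE], seed = seed),
            class = "lsirm_boot")
}

#' @export
print.lsirm_boot <- function(x, ...) {
  cat(sprintf("<lsirm_boot> %d replicates (%d used), %g%% ellipses\n",
              x$B, x$B_used, 100 * x$level))
  print(as.data.frame(head(x$item_se, 5)), row.names = FALSE)
  invisible(x)
}
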