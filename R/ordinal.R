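#' Expand ordinal items into cumulative binary dummy items
#'
#' The sequential (continuation-ratio) ordinal LSIRM treats each category
#' boundary of an item as a conditional binary step. It is fitted by
#' recoding every ordinal item with `C` observed categories into `C - 1`
#' cumulative binary dummy items: for a response `y` in `0..C-1`, dummy `c`
#' (for `c = 1..C-1`) equals 1 if `y >= c`, equals 0 if `y == c - 1`, and is
#' missing if `y < c - 1` (the sequential process already stopped at an
#' earlier boundary). Original missing responses propagate to all dummies of
#' the item. Categories never observed for an item are collapsed out (codes
#' relabelled to consecutive integers) before expansion, with a notice.
#'
#' All dummies of one original item share that item's single latent
#' coordinate vector when fitted, which makes the expanded binary likelihood
#' identical to the sequential-model likelihood.
#'
#' @param data Ordinal responses (anything accepted by
#'   `lsirm_data(..., ordinal = TRUE)`).
#' @return A list with `data` (the binary `lsirm_data` expansion),
#'   `item_map` (tibble mapping each dummy column to its original
#'   `item_index`, `item` name and `boundary`), and `dropped` (tibble of
#'   collapsed never-observed categories, possibly empty).
#' @examples
#' y <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
#' sequential_expand(y)$item_map
#' @export
sequential_expand <- function(data) {
  dat <- lsirm_data(data, ordinal = TRUE)
  N <- dat$n_persons
  cols <- list()
  map <- list()
  dropped <- list()
  for (j in seq_len(dat$n_items)) {
    obs <- dat$observed[, j]
    y <- dat$values[, j]
    levels_obs <- sort(unique(y[obs]))
    if (length(levels_obs) < 2) {
      abort(sprintf("Item %d ('%s') has a single observed category; no information.",
                    j, dat$item_names[j]))
    }
    full_range <- 0:max(levels_obs)
    unused <- setdiff(full_range, levels_obs)
    if (length(unused)) {
      inform(sprintf("Item %d ('%s'): unobserved categor%s %s collapsed out.",
                     j, dat$item_names[j],
                     if (length(unused) > 1) "ies" else "y",
                     paste(unused, collapse = ", ")))
      dropped[[length(dropped) + 1]] <-
        tibble::tibble(item_index = j, item = dat$item_names[j], category = unused)
    }
    # relabel to consecutive codes 0..C'-1
    yr <- match(y, levels_obs) - 1L
    C <- length(levels_obs)
    for (cc in seq_len(C - 1)) {
      d <- ifelse(!obs | yr < cc - 1, NA_real_, as.numeric(yr >= cc))
      cols[[length(cols) + 1]] <- d
      map[[length(map) + 1]] <-
        tibble::tibble(item_index = j, item = dat$item_names[j], boundary = cc)
    }
  }
  bin <- do.call(cbind, cols)
  item_map <- dplyr::bind_rows(map)
  colnames(bin) <- paste0(item_map$item, "_ge", item_map$boundary)
  list(data = lsirm_data(bin, ordinal = FALSE),
       item_map = item_map,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped)
                 else tibble::tibble(item_index = integer(), item = character(),
                                     category = integer()))
}

#' Sequential-model log-likelihood of ordinal responses
#'
#' Direct evaluation of the continuation-ratio likelihood: a response in
#' category `y` of an item with thresholds `beta_j1..beta_j,C-1` contributes
#' the probability of passing boundaries `1..y` and failing boundary
#' `y + 1` (if any), each boundary a logistic step in
#' `theta_p + beta_jc - d(w_j, z_p)`. Equals the joint log-likelihood of the
#' cumulative dummy expansion for any parameter values.
#'
#' @param data Ordinal responses.
#' @param theta Person intercepts.
#' @param thresholds List (per item) of numeric boundary effects, or the
#'   `thresholds` tibble of an ordinal [fit_lsirm()].
#' @param Z,W Person and (original-item) coordinate matrices.
#' @return Scalar log-likelihood.
#' @export
sequential_loglik <- function(data, theta, thresholds, Z, W) {
  dat <- lsirm_data(data, ordinal = TRUE)
  if (is.data.frame(thresholds)) {
    thresholds <- split(thresholds$estimate, thresholds$item_index)
  }
  Z <- as.matrix(Z); W <- as.matrix(W)
  D <- lsirm_distances(Z, W)
  ll <- 0
  for (j in seq_len(dat$n_items)) {
    obs <- which(dat$observed[, j])
    lev <- sort(unique(dat$values[obs, j]))
    yr <- match(dat$values[obs, j], lev) - 1L
    b <- thresholds[[j]]
    for (k in seq_along(obs)) {
      p <- obs[k]
      eta <- theta[p] + b - D[p, j]
      y <- yr[k]
      if (y > 0) ll <- ll + sum(log(pmin(pmax(plogis(eta[seq_len(y)]), 1e-12), 1 - 1e-12)))
      if (y < length(b)) ll <- ll + log(pmin(pmax(1 - plogis(eta[y + 1]), 1e-12), 1 - 1e-12))
    }
  }
  ll
}

#' Check the ordering of estimated ordinal thresholds
#'
#' The sequential model identifies each boundary effect separately; no
#' ordering is enforced during optimization. This diagnostic flags items
#' whose estimated boundary effects are not monotonically decreasing in the
#' boundary index.
#'
#' @param fit An ordinal `lsirm_fit`.
#' @return A tibble with one row per item and a logical `ordered` column.
#' @export
threshold_ordering <- function(fit) {
  stopifnot(inherits(fit, "lsirm_fit"), isTRUE(fit$ordinal))
  fit$thresholds |>
    dplyr::group_by(.data$item_index, .data$item) |>
    dplyr::summarise(ordered = !is.unsorted(rev(.data$estimate)),
                     .groups = "drop")
}
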