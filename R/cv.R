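#' Partition the observed cells of a response matrix into K folds
#'
#' Cell-wise folds: every observed (person, item) cell is assigned to
#' exactly one of `K` folds by sampling without replacement. When the
#' number of observed cells is not a multiple of `K`, the remainder cells
#' go to the first folds, so fold sizes differ by at most one.
#'
#' @param data Responses (anything accepted by [lsirm_data()]).
#' @param K Number of folds (>= 2).
#' @param seed Optional integer seed.
#' @return A tibble with `person`, `item`, `fold` for every observed cell.
#' @export
make_folds <- function(data, K, seed = NULL) {
  dat <- lsirm_data(data, ordinal = TRUE) # accept any integer coding
  stopifnot(K >= 2)
  idx <- which(dat$observed, arr.ind = TRUE)
  n <- nrow(idx)
  if (K > n) abort(sprintf("K = %d exceeds the %d observed cells.", K, n))
  if (!is.null(seed)) withr::local_seed(seed)
  sizes <- rep(n %/% K, K)
  r <- n %% K
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ord <- sample.int(n)
  tibble::tibble(person = idx[ord, 1], item = idx[ord, 2],
                 fold = rep(seq_len(K), sizes))
}

#' Unnormalized classification error
#'
#' Number of held-out responses misclassified when predicting 1 for
#' probabilities `p >= 0.5` (the tie at exactly 0.5 classifies as 1).
#'
#' @param y Held-out 0/1 responses.
#' @param p Predicted probabilities, same length.
#' @return Non-negative integer-valued count.
#' @export
uce <- function(y, p) {
  stopifnot(length(y) == length(p))
  sum(abs(y - as.numeric(p >= 0.5)))
}

#' Unnormalized ROC error
#'
#' `n * (1 - AUC)` where AUC is the area under the ROC curve computed by
#' the rank (Mann-Whitney) formula with midranks for ties, and `n` the
#' number of held-out cells. If only one response class is present the AUC
#' is defined as 0.5 with a warning.
#'
#' @inheritParams uce
#' @export
ure <- function(y, p) {
  stopifnot(length(y) == length(p))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warn("Held-out responses contain a single class; AUC set to 0.5.")
    auc <- 0.5
  } else {
    r <- rank(p) # midranks
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  length(y) * (1 - auc)
}

#' Residual sum of squares of held-out predictions
#'
#' @inheritParams uce
#' @export
rss <- function(y, p) {
  stopifnot(length(y) == length(p))
  sum((y - p)^2)
}

#' Select the latent-space dimension by cell-wise K-fold cross-validation
#'
#' One random cell-wise fold partition is shared across all candidate
#' dimensions. For each candidate `D` and each fold, the model is refitted
#' with the fold's cells set to missing, the held-out cells are predicted,
#' and three error metrics are accumulated: the unnormalized classification
#' error ([uce()]), the unnormalized ROC error ([ure()]), and the residual
#' sum of squares ([rss()]). For every metric the selected dimension
#' minimizes the total over folds, with ties broken toward the smaller
#' (more parsimonious) dimension. Cross-validated selection tends to err by
#' overselecting (too large a dimension) rather than underselecting.
#'
#' @param data Binary responses.
#' @param dims Candidate dimensions, e.g. `1:3`.
#' @param K Number of folds (default 10).
#' @param method,lambda,C_person,C_item,control Passed to [fit_lsirm()].
#' @param seed Integer seed controlling the fold partition and the fold
#'   fits' initializations.
#' @return An object of class `lsirm_cv`: list with tibbles `metrics`
#'   (per dimension and fold), `totals` (per dimension), `selected`
#'   (per metric), the fold partition, and any non-converged fold fits.
#' @examples
#' sim <- simulate_lsirm(n_persons = 60, n_items = 12, seed = 1)
#' cv <- lsirm_cv(sim$data, dims = 1:2, K = 2, seed = 2,
#'                control = lsirm_control(max_iter = 30))
#' cv$selected
#' @export
lsirm_cv <- function(data, dims = 1:3, K = 10, method = "pjml", lambda = 1,
                     C_person = NULL, C_item = NULL, seed = NULL,
                     control = lsirm_control()) {
  dat <- lsirm_data(data)
  if (length(dims) == 0) abort("`dims` must be non-empty.")
  if (!is.null(seed)) withr::local_seed(seed)
  folds <- make_folds(dat, K)
  fit_seeds <- sample.int(.Machine$integer.max, length(dims) * K)

  rows <- list()
  failures <- list()
  for (di in seq_along(dims)) {
    D <- dims[di]
    for (k in seq_len(K)) {
      held <- folds[folds$fold == k, ]
      vals <- dat$values
      masked <- vals
      masked[cbind(held$person, held$item)] <- NA
      fit <- fit_lsirm(masked, dim = D, method = method, lambda = lambda,
                       C_person = C_person, C_item = C_item,
                       seed = fit_seeds[(di - 1) * K + k], control = control)
      if (!fit$converged) {
        failures[[length(failures) + 1]] <- tibble::tibble(dim = D, fold = k)
      }
      p <- predict(fit, cells = held[, c("person", "item")])$.fitted
      y <- vals[cbind(held$person, held$item)]
      rows[[length(rows) + 1]] <- tibble::tibble(
        dim = D, fold = k, n = nrow(held),
        uce = uce(y, p), ure = ure(y, p), rss = rss(y, p))
    }
  }
  metrics <- dplyr::bind_rows(rows)
  totals <- metrics |>
    dplyr::group_by(.data$dim) |>
    dplyr::summarise(dplyr::across(c("uce", "ure", "rss"), sum), .groups = "drop")
  selected <- tibble::tibble(
    metric = c("uce", "ure", "rss"),
    dim = unname(vapply(c("uce", "ure", "rss"), function(m) {
      totals$dim[which.min(totals[[m]])] # which.min: first minimum, dims ascending
    }, numeric(1))))
  structure(list(metrics = metrics, totals = totals, selected = selected,
                 folds = folds, dims = sort(dims), K = K, method = method,
                 seed = seed,
                 failures = if (length(failures)) dplyr::bind_rows(failures)
                            else tibble::tibble(dim = numeric(), fold = integer())),
            class = "lsirm_cv")
}

#' Replicated cross-validated dimension-selection study
#'
#' Repeats the dimension-selection experiment: each replication generates a
#' fresh dataset from the standard two-dimensional design
#' ([simulate_lsirm()]), runs cell-wise K-fold cross-validation over the
#' candidate dimensions, and records the selected dimension per metric.
#' Summarize with `table()` or the true-positive rate
#' `mean(dim == 2)` per metric.
#'
#' @param n_reps Number of replications.
#' @param n_persons,n_items,gamma Generator design (defaults: the smaller
#'   sample size of the simulation design).
#' @param dims,K,method,lambda,control Passed to [lsirm_cv()].
#' @param seed Integer seed; replication seeds are derived from it.
#' @return A tibble with `rep`, `metric`, `dim` (the selected dimension).
#' @export
cv_selection_study <- function(n_reps = 50, n_persons = 500, n_items = 24,
                               gamma = 1, dims = 1:3, K = 10,
                               method = "pjml", lambda = 1, seed = NULL,
                               control = lsirm_control()) {
  if (!is.null(seed)) withr::local_seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, 2 * n_reps), ncol = 2)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    sim <- simulate_lsirm(n_persons = n_persons, n_items = n_items,
                          gamma = gamma, seed = rep_seeds[r, 1])
    cv <- suppressWarnings(
      lsirm_cv(sim$data, dims = dims, K = K, method = method, lambda = lambda,
               seed = rep_seeds[r, 2], control = control))
    dplyr::mutate(cv$selected, rep = r, .before = 1)
  })
}

#' @export
print.lsirm_cv <- function(x, ...) {
  cat(sprintf("<lsirm_cv> %d-fold cell-wise cross-validation, %s, D in {%s}\n",
              x$K, x$method, paste(x$dims, collapse = ", ")))
  print(as.data.frame(x$totals), row.names = FALSE)
  cat("selected:",
      paste(sprintf("%s -> D = %g", x$selected$metric, x$selected$dim),
            collapse = ", "), "\n")
  invisible(x)
}
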