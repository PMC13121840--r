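#' Tidy an LSIRM fit into a parameter tibble
#'
#' @param x An `lsirm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `entity` ("person"/"item"), `index`,
#'   `term` (`intercept`, `coord_<d>`, or `threshold_<c>` for ordinal
#'   items) and `estimate`.
#' @export
tidy.lsirm_fit <- function(x, ...) {
  person <- dplyr::bind_rows(
    tibble::tibble(entity = "person", index = seq_len(x$n_persons),
                   term = "intercept", estimate = x$theta),
    tidyr::pivot_longer(
      tibble::as_tibble(x$Z, .name_repair = ~ paste0("coord_", seq_len(x$dim))) |>
        dplyr::mutate(entity = "person", index = dplyr::row_number()),
      dplyr::starts_with("coord_"), names_to = "term", values_to = "estimate"))
  item_int <- if (x$ordinal) {
    tibble::tibble(entity = "item", index = x$thresholds$item_index,
                   term = paste0("threshold_", x$thresholds$boundary),
                   estimate = x$thresholds$estimate)
  } else {
    tibble::tibble(entity = "item", index = seq_len(x$n_items),
                   term = "intercept", estimate = x$beta)
  }
  item <- dplyr::bind_rows(
    item_int,
    tidyr::pivot_longer(
      tibble::as_tibble(x$W, .name_repair = ~ paste0("coord_", seq_len(x$dim))) |>
        dplyr::mutate(entity = "item", index = dplyr::row_number()),
      dplyr::starts_with("coord_"), names_to = "term", values_to = "estimate"))
  dplyr::bind_rows(person, item) |>
    dplyr::select("entity", "index", "term", "estimate") |>
    dplyr::arrange(.data$entity, .data$index)
}

#' One-row summary of an LSIRM fit
#'
#' @inheritParams tidy.lsirm_fit
#' @export
glance.lsirm_fit <- function(x, ...) {
  tibble::tibble(method = x$method, dim = x$dim,
                 n_persons = x$n_persons, n_items = x$n_items,
                 ordinal = x$ordinal,
                 logLik = x$loglik, objective = x$objective,
                 n_iter = x$n_iter, converged = x$converged,
                 clamped = x$clamped,
                 lambda = x$lambda %||% NA_real_,
                 C_person = x$C_person %||% NA_real_,
                 C_item = x$C_item %||% NA_real_)
}

#' Observed responses with fitted probabilities
#'
#' @inheritParams tidy.lsirm_fit
#' @param data The responses the model was fitted to.
#' @export
augment.lsirm_fit <- function(x, data, ...) {
  dat <- if (x$ordinal) sequential_expand(data)$data else lsirm_data(data)
  cells <- which(dat$observed, arr.ind = TRUE)
  pred <- predict(x, cells = cells)
  pred$y <- dat$values[cells]
  pred$.resid <- pred$y - pred$.fitted
  pred
}

#' Tidy cross-validation totals
#'
#' @param x An `lsirm_cv`.
#' @param ... Unused.
#' @return Long tibble with `dim`, `metric`, `value`, and whether that
#'   dimension is the metric's selection.
#' @export
tidy.lsirm_cv <- function(x, ...) {
  x$totals |>
    tidyr::pivot_longer(c("uce", "ure", "rss"),
                        names_to = "metric", values_to = "value") |>
    dplyr::left_join(dplyr::rename(x$selected, selected_dim = "dim"),
                     by = "metric") |>
    dplyr::mutate(selected = .data$dim == .data$selected_dim) |>
    dplyr::select("dim", "metric", "value", "selected")
}

#' @rdname tidy.lsirm_cv
#' @export
glance.lsirm_cv <- function(x, ...) {
  tibble::tibble(K = x$K, method = x$method,
                 dims = paste(x$dims, collapse = ","),
                 dim_uce = x$selected$dim[x$selected$metric == "uce"],
                 dim_ure = x$selected$dim[x$selected$metric == "ure"],
                 dim_rss = x$selected$dim[x$selected$metric == "rss"],
                 n_failed_folds = nrow(x$failures))
}

#' Tidy bootstrap standard errors
#'
#' @param x An `lsirm_boot`.
#' @param ... Unused.
#' @export
tidy.lsirm_boot <- function(x, ...) x$item_se
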