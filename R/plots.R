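#' Plot the estimated latent space
#'
#' Persons as gray points, items as labelled red points, on the first two
#' latent dimensions (in the echelon orientation).
#'
#' @param object An `lsirm_fit` with `dim >= 2`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsirm_fit <- function(object, ...) {
  if (object$dim < 2) abort("Latent-space map needs dim >= 2.")
  persons <- tibble::tibble(x = object$Z[, 1], y = object$Z[, 2])
  items <- tibble::tibble(x = object$W[, 1], y = object$W[, 2],
                          label = object$item_names)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = persons, ggplot2::aes(.data$x, .data$y),
                        color = "grey60", alpha = 0.5, size = 0.8) +
    ggplot2::geom_point(data = items, ggplot2::aes(.data$x, .data$y),
                        color = "red2", size = 2) +
    ggplot2::geom_text(data = items,
                       ggplot2::aes(.data$x, .data$y, label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = sprintf("Latent space (%s, D = %d)",
                                  object$method, object$dim)) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation error against candidate dimension
#'
#' One panel per metric, each rescaled so shapes are comparable; the
#' selected dimension is marked.
#'
#' @param object An `lsirm_cv`.
#' @param ... Unused.
#' @export
autoplot.lsirm_cv <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$dim, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "red2", `FALSE` = "black"),
                                guide = "none") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = object$dims) +
    ggplot2::labs(x = "latent dimension D", y = "total held-out error") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap confidence ellipses for item positions
#'
#' Item point estimates with their confidence ellipses (a line segment for
#' items with an echelon-fixed coordinate), persons omitted.
#'
#' @param object An `lsirm_boot`.
#' @param n_points Points per ellipse outline.
#' @param ... Unused.
#' @export
autoplot.lsirm_boot <- function(object, n_points = 120, ...) {
  ell <- object$ellipses
  if (nrow(ell) == 0) abort("No ellipses available (fit has dim < 2).")
  outlines <- purrr::map_dfr(seq_len(nrow(ell)), function(i) {
    tt <- seq(0, 2 * pi, length.out = n_points)
    a <- ell$axis_1[i]; b <- ell$axis_2[i]; ang <- ell$angle[i]
    x <- a * cos(tt); y <- b * sin(tt)
    tibble::tibble(item = ell$item[i],
                   x = ell$center_1[i] + x * cos(ang) - y * sin(ang),
                   y = ell$center_2[i] + x * sin(ang) + y * cos(ang))
  })
  ggplot2::ggplot() +
    ggplot2::geom_path(data = outlines,
                       ggplot2::aes(.data$x, .data$y, group = .data$item),
                       color = "red2", linewidth = 0.3) +
    ggplot2::geom_point(data = ell,
                        ggplot2::aes(.data$center_1, .data$center_2,
                                     shape = .data$constrained),
                        color = "red2", size = 2) +
    ggplot2::geom_text(data = ell,
                       ggplot2::aes(.data$center_1, .data$center_2,
                                    label = .data$item),
                       vjust = -0.9, size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 8, `FALSE` = 16),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = sprintf("%g%% confidence ellipses (%d bootstrap replicates)",
                                  100 * object$level, object$B_used)) +
    ggplot2::theme_minimal()
}
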