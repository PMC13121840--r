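#' Write an LSIRM fit to plain-text files
#'
#' Exports the person table (intercepts and coordinates), the item table
#' (intercepts or thresholds, coordinates in the echelon orientation), and
#' run metadata (method, dimension, regularization, seed, anchors, sign
#' convention, convergence, objective) so a fit can be reloaded or plotted
#' elsewhere.
#'
#' @param fit An `lsirm_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"lsirm"`.
#' @return Invisibly, the paths written: `<prefix>_persons.csv`,
#'   `<prefix>_items.csv` (plus `<prefix>_thresholds.csv` for ordinal fits)
#'   and `<prefix>_meta.json`.
#' @export
write_lsirm <- function(fit, dir, prefix = "lsirm") {
  stopifnot(inherits(fit, "lsirm_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  persons <- data.frame(person = seq_len(fit$n_persons), theta = fit$theta)
  for (d in seq_len(fit$dim)) persons[[paste0("z", d)]] <- fit$Z[, d]
  items <- data.frame(item_index = seq_len(fit$n_items), item = fit$item_names)
  if (!fit$ordinal) items$beta <- fit$beta
  for (d in seq_len(fit$dim)) items[[paste0("w", d)]] <- fit$W[, d]

  p_persons <- file.path(dir, paste0(prefix, "_persons.csv"))
  p_items <- file.path(dir, paste0(prefix, "_items.csv"))
  p_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  write.csv(persons, p_persons, row.names = FALSE)
  write.csv(items, p_items, row.names = FALSE)
  paths <- c(p_persons, p_items, p_meta)
  if (fit$ordinal) {
    p_thr <- file.path(dir, paste0(prefix, "_thresholds.csv"))
    write.csv(as.data.frame(fit$thresholds), p_thr, row.names = FALSE)
    paths <- c(paths, p_thr)
  }
  meta <- list(method = fit$method, dim = fit$dim, ordinal = fit$ordinal,
               lambda = fit$lambda, C_person = fit$C_person,
               C_item = fit$C_item, anchors = fit$anchors,
               sign_flips = fit$rotation$sign_flips,
               sign_convention = "W[d, d] >= 0 on the anchor rows",
               seed = fit$seed, converged = fit$converged,
               n_iter = fit$n_iter, objective = fit$objective,
               loglik = fit$loglik,
               control = unclass(fit$control))
  jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}

#' Read back parameter tables written by [write_lsirm()]
#'
#' @param dir Directory containing the files.
#' @param prefix File-name prefix used at write time.
#' @return A list with `persons`, `items` tibbles, optional `thresholds`,
#'   and `meta`.
#' @export
read_lsirm <- function(dir, prefix = "lsirm") {
  persons <- tibble::as_tibble(read.csv(file.path(dir, paste0(prefix, "_persons.csv"))))
  items <- tibble::as_tibble(read.csv(file.path(dir, paste0(prefix, "_items.csv"))))
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  thr_path <- file.path(dir, paste0(prefix, "_thresholds.csv"))
  list(persons = persons, items = items,
       thresholds = if (file.exists(thr_path))
         tibble::as_tibble(read.csv(thr_path)) else NULL,
       meta = meta)
}

#' Write bootstrap standard errors and ellipse parameters
#'
#' Per-item standard-error table as CSV and the confidence-ellipse
#' parameters (center, semi-axes, angle, level) as JSON.
#'
#' @param boot An `lsirm_boot`.
#' @param dir Output directory.
#' @param prefix File-name prefix, default `"boot"`.
#' @return Invisibly, the paths written.
#' @export
write_lsirm_boot <- function(boot, dir, prefix = "boot") {
  stopifnot(inherits(boot, "lsirm_boot"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_csv <- file.path(dir, paste0(prefix, "_item_se.csv"))
  p_json <- file.path(dir, paste0(prefix, "_ellipses.json"))
  write.csv(as.data.frame(boot$item_se), p_csv, row.names = FALSE)
  jsonlite::write_json(
    list(B = boot$B, B_used = boot$B_used, level = boot$level,
         seed = boot$seed, ellipses = boot$ellipses),
    p_json, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(c(p_csv, p_json))
}

#' Write a cross-validation summary table
#'
#' One row per candidate dimension, columns RSS, UCE, URE (the layout used
#' for reporting model-fit indices), as CSV, plus the per-fold metrics and
#' selections as JSON.
#'
#' @param cv An `lsirm_cv`.
#' @param dir Output directory.
#' @param prefix File-name prefix, default `"cv"`.
#' @return Invisibly, the paths written.
#' @export
write_lsirm_cv <- function(cv, dir, prefix = "cv") {
  stopifnot(inherits(cv, "lsirm_cv"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- data.frame(D = cv$totals$dim, RSS = cv$totals$rss,
                    UCE = cv$totals$uce, URE = cv$totals$ure)
  p_csv <- file.path(dir, paste0(prefix, "_table.csv"))
  p_json <- file.path(dir, paste0(prefix, "_detail.json"))
  write.csv(tab, p_csv, row.names = FALSE)
  jsonlite::write_json(
    list(K = cv$K, method = cv$method, seed = cv$seed,
         selected = cv$selected, metrics = cv$metrics),
    p_json, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(c(p_csv, p_json))
}
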