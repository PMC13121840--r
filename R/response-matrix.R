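#' Construct a validated person-by-item response matrix
#'
#' Converts a wide data frame or matrix of item responses (rows = persons,
#' columns = items) into the internal response-matrix representation used by
#' the fitting functions. Binary items must be coded 0/1; ordinal items use
#' consecutive integer codes starting at 0. `NA` marks a missing response;
#' missing cells are excluded from the likelihood (missing-at-random).
#'
#' @param data A data frame or integer/numeric matrix, persons in rows and
#'   items in columns. All columns must be numeric; use [read_responses()] to
#'   read delimited files with an ID column.
#' @param ordinal Logical; if `TRUE` values `0..C_j-1` per item are allowed,
#'   otherwise only 0/1.
#' @return An object of class `lsirm_data`: a list with integer matrix
#'   `values`, logical matrix `observed`, counts `n_persons`, `n_items`, the
#'   `ordinal` flag and, for ordinal data, per-item observed category counts.
#' @examples
#' y <- matrix(c(1, 0, 0, 1), 2, 2)
#' lsirm_data(y)
#' @export
lsirm_data <- function(data, ordinal = FALSE) {
  if (inherits(data, "lsirm_data")) return(data)
  if (is.data.frame(data)) {
    non_num <- !vapply(data, is.numeric, logical(1))
    if (any(non_num)) {
      abort(paste0("All item columns must be numeric; non-numeric: ",
                   paste(names(data)[non_num], collapse = ", "),
                   ". Use read_responses() for files with an ID column."))
    }
    data <- as.matrix(data)
  }
  if (!is.matrix(data)) abort("`data` must be a matrix or data frame.")
  storage.mode(data) <- "double"
  observed <- is.finite(data)
  vals <- data
  vals[!observed] <- 0
  if (any(vals[observed] != round(vals[observed]))) {
    bad <- which(observed & data != round(data), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-integer response at row %d, column %d.", bad[1], bad[2]))
  }
  if (any(vals[observed] < 0)) abort("Responses must be non-negative integers.")
  if (!ordinal && any(vals[observed] > 1)) {
    bad <- which(observed & data > 1, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Value %d at row %d, column %d is not binary; use ordinal = TRUE for polytomous items.",
      data[bad[1], bad[2]], bad[1], bad[2]))
  }
  item_names <- colnames(data) %||% paste0("item", seq_len(ncol(data)))
  categories <- vapply(seq_len(ncol(vals)), function(j) {
    length(unique(vals[observed[, j], j]))
  }, integer(1))
  structure(
    list(values = vals, observed = observed,
         n_persons = nrow(vals), n_items = ncol(vals),
         ordinal = ordinal, item_names = item_names,
         n_categories = if (ordinal) categories else NULL),
    class = "lsirm_data")
}

#' @export
print.lsirm_data <- function(x, ...) {
  cat(sprintf("<lsirm_data> %d persons x %d items (%s), %d observed cells\n",
              x$n_persons, x$n_items,
              if (x$ordinal) "ordinal" else "binary", sum(x$observed)))
  invisible(x)
}

#' Read a person-by-item response matrix from a delimited file
#'
#' Reads CSV (or TSV, auto-detected from a `.tsv`/`.txt` extension) with an
#' optional header row of item names and an optional leading person-ID column.
#'
#' @param path Path to the file.
#' @param missing_code String(s) coding a missing response (default `"NA"`).
#' @param ordinal Logical, passed to [lsirm_data()].
#' @param id_col Name or index of a person-ID column to drop, or `NULL`.
#' @param header Logical; does the file have a header row?
#' @return An `lsirm_data` object.
#' @export
read_responses <- function(path, missing_code = "NA", ordinal = FALSE,
                           id_col = NULL, header = TRUE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, header = header, na.strings = missing_code,
                 check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort("No data rows in the file.")
  if (!is.null(id_col)) {
    idx <- if (is.character(id_col)) match(id_col, names(df)) else as.integer(id_col)
    if (anyNA(idx)) abort("`id_col` not found in the file.")
    df <- df[, -idx, drop = FALSE]
  }
  non_num <- !vapply(df, is.numeric, logical(1))
  if (any(non_num)) {
    for (j in which(non_num)) {
      conv <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(!is.na(df[[j]]) & is.na(conv))
      if (length(bad)) {
        abort(sprintf("Non-integer cell at row %d, column %s ('%s').",
                      bad[1], names(df)[j], df[bad[1], j]))
      }
      df[[j]] <- conv
    }
  }
  dat <- lsirm_data(df, ordinal = ordinal)
  check_no_empty(dat)
  dat
}

# fitting a row/column with no observed cells is meaningless; rejected
# before any optimization
check_no_empty <- function(dat) {
  if (any(rowSums(dat$observed) == 0)) {
    abort(sprintf("Row %d has no observed responses.",
                  which(rowSums(dat$observed) == 0)[1]))
  }
  if (any(colSums(dat$observed) == 0)) {
    abort(sprintf("Column %d ('%s') has no observed responses.",
                  which(colSums(dat$observed) == 0)[1],
                  dat$item_names[which(colSums(dat$observed) == 0)[1]]))
  }
  invisible(dat)
}
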