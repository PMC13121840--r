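#' Rotate a latent configuration to the echelon-identified orientation
#'
#' The latent space of an LSIRM is identified only up to rotation and
#' reflection: any orthogonal transform applied to both person and item
#' coordinates leaves every person-item distance, and hence the likelihood,
#' unchanged. The echelon convention removes this indeterminacy a priori by
#' driving the upper-triangular entries of the first `D - 1` anchor rows of
#' the item-coordinate matrix to zero (`W[j, d] = 0` for `d > j`), via a
#' product of plane (Givens) rotations, and then flipping the sign of each
#' dimension so that `W[d, d] >= 0`. The same transform is applied to the
#' person coordinates, so all distances are preserved.
#'
#' @param W Item coordinate matrix, J x D (J >= D).
#' @param Z Optional person coordinate matrix, N x D, rotated along.
#' @param anchors Indices of the D - 1 anchor items carrying the zero
#'   constraints (default: the first D - 1 rows). The sign convention uses
#'   rows `anchors` plus the next item.
#' @return A list with rotated `W`, `Z` (or `NULL`), and `record`: the D x D
#'   orthogonal matrix `R` applied on the right (sign flips included), the
#'   Givens `angles` with their axis pairs, and the per-dimension
#'   `sign_flips`.
#' @examples
#' W <- matrix(c(1, 0, 1, 1), 2, 2)
#' echelon_rotate(W)$W # row 1 on axis 1 only
#' @export
echelon_rotate <- function(W, Z = NULL, anchors = NULL) {
  W <- as.matrix(W)
  D <- ncol(W)
  if (nrow(W) < D) abort("Need at least D items to carry the echelon constraints.")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (ncol(Z) != D) abort("Z and W must have the same number of columns.")
  }
  anchors <- anchors %||% seq_len(max(D - 1, 0))
  if (length(anchors) < D - 1) abort("Need D - 1 anchor items.")
  sign_rows <- c(anchors[seq_len(D - 1)], setdiff(seq_len(nrow(W)), anchors)[1])

  R <- diag(D)
  angles <- list()
  Wr <- W
  if (D > 1) {
    for (k in seq_len(D - 1)) {
      j <- anchors[k]
      for (d in seq(D, k + 1)) {
        a <- Wr[j, k]; b <- Wr[j, d]
        r <- sqrt(a^2 + b^2)
        if (r == 0) {
          warn(sprintf("Anchor item %d has zero norm in the (%d, %d) plane; rotation skipped.",
                       j, k, d))
          next
        }
        cth <- a / r; sth <- b / r
        G <- diag(D)
        G[k, k] <- cth; G[d, d] <- cth
        G[d, k] <- sth; G[k, d] <- -sth
        # columns k, d mixed so that the (j, d) entry becomes zero
        Wr <- Wr %*% G
        R <- R %*% G
        angles[[length(angles) + 1]] <- list(plane = c(k, d), angle = atan2(sth, cth))
      }
    }
  }
  flips <- ifelse(Wr[cbind(sign_rows, seq_len(D))] < 0, -1, 1)
  Wr <- sweep(Wr, 2, flips, "*")
  R <- sweep(R, 2, flips, "*")
  list(W = Wr,
       Z = if (is.null(Z)) NULL else Z %*% R,
       record = list(R = R, angles = angles, sign_flips = flips,
                     anchors = anchors))
}

#' Align a latent configuration to a reference item configuration
#'
#' Finds the orthogonal matrix Q (rotation or reflection) minimizing
#' `||W %*% Q - W_ref||` in the least-squares (orthogonal Procrustes) sense
#' and applies it to both coordinate matrices, preserving all distances.
#' Used to compare solutions across estimators, replications, or bootstrap
#' replicates, where an a-priori echelon orientation is not available or
#' leaves a residual reflection.
#'
#' @param W,Z Item and person coordinate matrices to transform.
#' @param W_ref Reference item coordinates, same shape as `W`.
#' @return List with transformed `W`, `Z` (or `NULL`), and `Q`.
#' @export
align_to_reference <- function(W, Z = NULL, W_ref) {
  W <- as.matrix(W); W_ref <- as.matrix(W_ref)
  if (!all(dim(W) == dim(W_ref))) abort("`W` and `W_ref` must have the same shape.")
  M <- crossprod(W, W_ref)
  s <- svd(M)
  if (min(s$d) < 1e-12 * max(s$d, 1e-300)) {
    # rank-deficient cross-product: fall back to the echelon convention
    out <- echelon_rotate(W, Z)
    return(list(W = out$W, Z = out$Z, Q = out$record$R))
  }
  Q <- s$u %*% t(s$v)
  list(W = W %*% Q, Z = if (is.null(Z)) NULL else as.matrix(Z) %*% Q, Q = Q)
}
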