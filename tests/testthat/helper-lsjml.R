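# shared fixtures built in code

# small random model instance with a partly missing response matrix
random_instance <- function(N = 6, J = 5, D = 2, miss = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- matrix(rbinom(N * J, 1, 0.5), N, J)
  if (miss > 0) {
    drop_idx <- sample(N * J, floor(miss * N * J))
    Y[drop_idx] <- NA
  }
  list(Y = Y,
       theta = rnorm(N, sd = 0.6), beta = rnorm(J, sd = 0.6),
       Z = matrix(rnorm(N * D), N, D), W = matrix(rnorm(J * D), J, D))
}

# central finite differences of a scalar function of a parameter vector
numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- x
    e[i] <- x[i] + h
    up <- f(e)
    e[i] <- x[i] - h
    (up - f(e)) / (2 * h)
  }, numeric(1))
}

quiet_fit <- function(...) suppressMessages(suppressWarnings(fit_lsirm(...)))
quiet_cv <- function(...) suppressMessages(suppressWarnings(lsirm_cv(...)))
quiet_boot <- function(...) suppressMessages(suppressWarnings(lsirm_bootstrap(...)))

# sequential-model (continuation-ratio) ordinal data generator used by the
# ordinal recovery tests
simulate_ordinal <- function(N, J, C, seed) {
  set.seed(seed)
  theta <- rnorm(N)
  Z <- matrix(rnorm(N * 2), N, 2)
  W <- cbind(seq(1.5, -1.5, length.out = J), rnorm(J, sd = 0.8))
  thr <- replicate(J, sort(runif(C - 1, -1.5, 1.5), decreasing = TRUE),
                   simplify = FALSE)
  Dm <- as.matrix(dist(rbind(Z, W)))[1:N, N + 1:J]
  Y <- matrix(0L, N, J)
  for (j in 1:J) {
    for (p in 1:N) {
      y <- 0L
      for (cc in seq_len(C - 1)) {
        if (runif(1) < plogis(theta[p] + thr[[j]][cc] - Dm[p, j])) y <- cc
        else break
      }
      Y[p, j] <- y
    }
  }
  list(Y = Y, theta = theta, Z = Z, W = W, thr = thr)
}

random_orthogonal <- function(D) {
  qr.Q(qr(matrix(rnorm(D * D), D, D)))
}
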