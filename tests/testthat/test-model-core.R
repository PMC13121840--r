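test_that("euclidean distance has metric properties and rotation invariance", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(3, 4), c(0, 0)), 5)
  expect_error(euclidean_distance(c(1, 2, 3), c(1, 2)), "length")
  set.seed(11)
  for (i in 1:10) {
    D <- sample(1:4, 1)
    w <- rnorm(D); z <- rnorm(D)
    Q <- random_orthogonal(D)
    expect_equal(euclidean_distance(drop(w %*% Q), drop(z %*% Q)),
                 euclidean_distance(w, z), tolerance = 1e-12)
    expect_equal(euclidean_distance(w, z), euclidean_distance(z, w))
  }
})

test_that("response probability is the logistic of intercepts minus weighted distance", {
  expect_equal(lsirm_prob(0, 0, w = c(1, 2), z = c(1, 2)), 0.5)
  # theta + beta - gamma*d = 0.5 + 1.0 - 0.3 = 1.2
  expect_equal(lsirm_prob(0.5, 1.0, gamma = 1, distance = 0.3), 0.7685248,
               tolerance = 1e-7)
  # gamma = 0 removes the latent space entirely
  expect_equal(lsirm_prob(0.4, -1.1, w = c(9, 9), z = c(-3, 0), gamma = 0),
               plogis(0.4 - 1.1))
  expect_error(lsirm_prob(0, 0, distance = 1, gamma = -1), "gamma")
  # strictly within (0, 1) and decreasing in distance
  p <- lsirm_prob(2, 2, distance = c(0, 1, 5, 50))
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) < 0))
})

test_that("joint log-likelihood sums Bernoulli terms over observed cells only", {
  Y <- matrix(c(1, 0, 0, 1), 2, 2)
  z0 <- matrix(0, 2, 2)
  expect_equal(lsirm_loglik(Y, c(0, 0), c(0, 0), z0, z0), -4 * log(2))
  # one observed cell at p = 0.5
  Y1 <- matrix(c(1, NA, NA, NA), 2, 2)
  expect_equal(lsirm_loglik(Y1, c(0, 0), c(0, 0), z0, z0), log(0.5))
  # hand-set parameters against an independent per-cell enumeration
  set.seed(21)
  inst <- random_instance(N = 2, J = 2, miss = 0)
  ll_oracle <- 0
  for (p in 1:2) for (j in 1:2) {
    d <- sqrt(sum((inst$W[j, ] - inst$Z[p, ])^2))
    pr <- plogis(inst$theta[p] + inst$beta[j] - d)
    ll_oracle <- ll_oracle +
      inst$Y[p, j] * log(pr) + (1 - inst$Y[p, j]) * log(1 - pr)
  }
  expect_equal(lsirm_loglik(inst$Y, inst$theta, inst$beta, inst$Z, inst$W),
               ll_oracle, tolerance = 1e-12)
})

test_that("likelihood is invariant under rotation, translation, and theta-beta transfer", {
  set.seed(31)
  for (i in 1:8) {
    inst <- random_instance(N = 7, J = 6, D = 2, miss = 0.15)
    ll <- lsirm_loglik(inst$Y, inst$theta, inst$beta, inst$Z, inst$W)
    Q <- random_orthogonal(2)
    expect_equal(lsirm_loglik(inst$Y, inst$theta, inst$beta,
                              inst$Z %*% Q, inst$W %*% Q), ll,
                 tolerance = 1e-10)
    shift <- rnorm(2)
    expect_equal(lsirm_loglik(inst$Y, inst$theta, inst$beta,
                              sweep(inst$Z, 2, shift, "+"),
                              sweep(inst$W, 2, shift, "+")), ll,
                 tolerance = 1e-10)
    cc <- rnorm(1)
    expect_equal(lsirm_loglik(inst$Y, inst$theta + cc, inst$beta - cc,
                              inst$Z, inst$W), ll, tolerance = 1e-10)
  }
})

test_that("penalized log-likelihood reduces correctly at its boundaries", {
  set.seed(41)
  inst <- random_instance()
  expect_identical(
    lsirm_penalized_loglik(inst$Y, inst$theta, inst$beta, inst$Z, inst$W, 0),
    lsirm_loglik(inst$Y, inst$theta, inst$beta, inst$Z, inst$W))
  z0 <- matrix(0, 6, 2); w0 <- matrix(0, 5, 2)
  expect_equal(lsirm_penalized_loglik(inst$Y, rep(0, 6), rep(0, 5), z0, w0, 1),
               lsirm_loglik(inst$Y, rep(0, 6), rep(0, 5), z0, w0))
  # empty-data limit: only the penalty remains
  Y_empty <- matrix(NA_real_, 1, 1)
  expect_equal(
    lsirm_penalized_loglik(Y_empty, 1, 1, matrix(0, 1, 1), matrix(0, 1, 1), 1),
    -1.0)
  expect_error(lsirm_penalized_loglik(inst$Y, inst$theta, inst$beta,
                                      inst$Z, inst$W, -0.1), "lambda")
})

test_that("analytic gradients match central finite differences", {
  set.seed(51)
  for (i in 1:20) {
    N <- sample(4:8, 1); J <- sample(3:7, 1); D <- sample(1:3, 1)
    lam <- sample(c(0, 0.5, 1), 1)
    inst <- random_instance(N, J, D, miss = 0.1)
    g <- lsirm_gradients(inst$Y, inst$theta, inst$beta, inst$Z, inst$W, lam)
    pack <- c(inst$theta, inst$beta, as.numeric(inst$Z), as.numeric(inst$W))
    f <- function(par) {
      th <- par[1:N]; be <- par[N + 1:J]
      Z <- matrix(par[N + J + 1:(N * D)], N, D)
      W <- matrix(par[N + J + N * D + 1:(J * D)], J, D)
      lsirm_penalized_loglik(inst$Y, th, be, Z, W, lam)
    }
    num <- numeric_gradient(f, pack)
    ana <- c(g$theta, g$beta, as.numeric(g$Z), as.numeric(g$W))
    expect_lt(max(abs(ana - num) / (abs(num) + 1e-6)), 1e-5)
  }
})

test_that("gradients vanish for balanced data at zero and shift exactly with lambda", {
  # two persons x two items, each row/column one 0 and one 1
  Y <- matrix(c(1, 0, 0, 1), 2, 2)
  g <- lsirm_gradients(Y, c(0, 0), c(0, 0), matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(g$theta, c(0, 0))
  expect_equal(g$beta, c(0, 0))
  set.seed(61)
  inst <- random_instance()
  g0 <- lsirm_gradients(inst$Y, inst$theta, inst$beta, inst$Z, inst$W, 0)
  g1 <- lsirm_gradients(inst$Y, inst$theta, inst$beta, inst$Z, inst$W, 0.8)
  expect_equal(g1$theta, g0$theta - 0.8 * inst$theta, tolerance = 1e-12)
  expect_equal(g1$W, g0$W - 0.8 * inst$W, tolerance = 1e-12)
})

test_that("zero person-item distance uses the zero subgradient", {
  Y <- matrix(1, 1, 1)
  g <- lsirm_gradients(Y, 0, 0, matrix(c(1, 1), 1), matrix(c(1, 1), 1))
  expect_equal(as.numeric(g$Z), c(0, 0))
  expect_false(anyNA(g$W))
})
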