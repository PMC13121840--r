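test_that("cell-wise folds partition the observed cells with the remainder rule", {
  # 2x2 fully observed, 4 folds of one cell each
  f <- make_folds(matrix(c(1, 0, 0, 1), 2, 2), K = 4, seed = 1)
  expect_equal(sort(tabulate(f$fold, 4)), rep(1, 4))
  # 5 observed cells, K = 2: sizes (3, 2) forced by the remainder rule
  Y5 <- matrix(c(1, 0, 1, NA, 1, 0), 2, 3)
  f5 <- make_folds(Y5, K = 2, seed = 2)
  expect_equal(tabulate(f5$fold, 2), c(3, 2))
  # never assigns missing cells; every observed cell exactly once
  expect_equal(nrow(f5), 5)
  expect_false(any(f5$person == 2 & f5$item == 2))
  expect_equal(nrow(dplyr::distinct(f5[, c("person", "item")])), 5)
  # deterministic under seed
  expect_identical(make_folds(Y5, K = 2, seed = 7), make_folds(Y5, K = 2, seed = 7))
  expect_error(make_folds(matrix(1, 1, 2), K = 5), "exceeds")
})

test_that("fold partitions cover larger matrices exactly once", {
  set.seed(171)
  Y <- matrix(rbinom(300, 1, 0.5), 20, 15)
  Y[sample(300, 40)] <- NA
  f <- make_folds(Y, K = 10, seed = 3)
  expect_equal(nrow(f), sum(!is.na(Y)))
  sizes <- tabulate(f$fold, 10)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(diff(sizes) <= 0))  # remainder goes to the first folds
  # reconstructing the mask covers all observed cells
  covered <- matrix(FALSE, 20, 15)
  covered[cbind(f$person, f$item)] <- TRUE
  expect_identical(covered, !is.na(Y))
})

test_that("classification error counts misclassifications with ties to one", {
  expect_equal(uce(c(1, 0, 1), c(0.9, 0.2, 0.4)), 1)
  expect_equal(uce(c(1, 0), c(0.8, 0.1)), 0)
  expect_equal(uce(0, 0.5), 1)  # tie at 0.5 classifies as 1
  expect_equal(uce(1, 0.5), 0)
})

test_that("ROC error is fold size times one minus the midrank AUC", {
  expect_equal(ure(c(1, 0), c(0.9, 0.1)), 0)
  # constant predictions, both classes present: midrank AUC = 0.5
  expect_equal(ure(c(1, 0, 1, 0), rep(0.3, 4)), 2)
  # all-pairs enumeration oracle on random data with ties
  set.seed(181)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p <- round(runif(40), 1)  # coarse grid forces ties
    pos <- p[y == 1]; neg <- p[y == 0]
    conc <- 0
    for (a in pos) for (b in neg) conc <- conc + (a > b) + 0.5 * (a == b)
    auc_oracle <- conc / (length(pos) * length(neg))
    expect_equal(ure(y, p), 40 * (1 - auc_oracle), tolerance = 1e-12)
  }
  expect_warning(out <- ure(c(1, 1), c(0.2, 0.9)), "single class")
  expect_equal(out, 1)  # n * (1 - 0.5)
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(191)
  y <- rbinom(60, 1, 0.4)
  p <- round(runif(60), 1)
  auc_ind <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                            direction = "<")))
  expect_equal(1 - ure(y, p) / 60, auc_ind, tolerance = 1e-12)
})

test_that("residual sum of squares behaves as stated", {
  expect_equal(rss(c(1, 0), c(1, 0)), 0)
  expect_equal(rss(rep(1, 8), rep(0.5, 8)), 2)
  expect_equal(rss(c(1, 0), c(0.9, 0.3)), 0.10)
})

test_that("fold predictions are plain logistic evaluations, rotation-invariant", {
  set.seed(201)
  inst <- random_instance(N = 3, J = 3, miss = 0)
  fit <- quiet_fit(inst$Y, dim = 2, seed = 1, control = lsirm_control(max_iter = 5))
  cells <- cbind(c(1, 2, 3), c(3, 1, 2))
  pr <- predict(fit, cells = cells)
  for (k in 1:3) {
    d <- sqrt(sum((fit$W[cells[k, 2], ] - fit$Z[cells[k, 1], ])^2))
    expect_equal(pr$.fitted[k],
                 plogis(fit$theta[cells[k, 1]] + fit$beta[cells[k, 2]] - d),
                 tolerance = 1e-12)
  }
  # a common rotation of the configuration leaves predictions unchanged
  Q <- random_orthogonal(2)
  fit2 <- fit
  fit2$Z <- fit$Z %*% Q
  fit2$W <- fit$W %*% Q
  expect_equal(predict(fit2, cells = cells)$.fitted, pr$.fitted,
               tolerance = 1e-10)
})

test_that("cross-validation bookkeeping sums fold metrics and reuses one partition", {
  set.seed(211)
  Y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  cv <- quiet_cv(Y, dims = 1, K = 2, seed = 5,
                 control = lsirm_control(max_iter = 10))
  expect_equal(nrow(cv$metrics), 2)
  expect_equal(cv$totals$rss, sum(cv$metrics$rss))
  expect_equal(cv$totals$uce, sum(cv$metrics$uce))
  expect_equal(sum(cv$metrics$n), 16)
  cv2 <- quiet_cv(Y, dims = 1, K = 2, seed = 5,
                  control = lsirm_control(max_iter = 10))
  expect_identical(cv$metrics, cv2$metrics)
  expect_identical(cv$folds, cv2$folds)
})

test_that("selection takes the argmin per metric with ties toward smaller D", {
  sim <- simulate_lsirm(n_persons = 80, n_items = 12, seed = 221)
  cv <- quiet_cv(sim$data, dims = 1:2, K = 3, seed = 6,
                 control = lsirm_control(max_iter = 25))
  for (m in c("uce", "ure", "rss")) {
    sel <- cv$selected$dim[cv$selected$metric == m]
    expect_equal(sel, cv$totals$dim[which.min(cv$totals[[m]])])
  }
  td <- tidy(cv)
  sel_of <- cv$selected$dim[match(td$metric, cv$selected$metric)]
  expect_identical(td$selected, td$dim == sel_of)
})

test_that("selection errors on latent-space data go to larger, not smaller, dimensions", {
  # D = 2 truth; with the strong latent space and the normal-prior penalty
  # the held-out error never prefers D = 1
  wrong_small <- 0
  for (r in 1:2) {
    sim <- simulate_lsirm(n_persons = 500, n_items = 24, seed = 230 + r)
    cv <- quiet_cv(sim$data, dims = 1:3, K = 10, seed = 240 + r)
    wrong_small <- wrong_small + sum(cv$selected$dim < 2)
  }
  expect_equal(wrong_small, 0)
})

test_that("a model with no latent structure is identified as low-dimensional", {
  # Rasch data: held-out error should not favor extra dimensions
  set.seed(251)
  th <- rnorm(150); be <- runif(12, -1.5, 1.5)
  Y <- matrix(rbinom(150 * 12, 1, plogis(outer(th, be, "+"))), 150, 12)
  cv <- quiet_cv(Y, dims = c(1, 3), K = 5, seed = 7,
                 control = lsirm_control(max_iter = 300))
  expect_equal(cv$selected$dim[cv$selected$metric == "rss"], 1)
})
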