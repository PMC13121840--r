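test_that("default norm bounds follow the dimension-plus-one recipe", {
  expect_equal(default_constraints(1)$C_item, 5 * sqrt(2), tolerance = 1e-10)
  expect_equal(default_constraints(2)$C_person, 2 * sqrt(3), tolerance = 1e-10)
  # implied uniform-ball per-coordinate variance C^2/(D+3) exceeds the unit
  # normal-prior variance for both defaults at D = 1, 2, 3
  for (D in 1:3) {
    dc <- default_constraints(D)
    expect_gt(dc$C_person^2 / (D + 3), 1)
    expect_gt(dc$C_item^2 / (D + 3), 1)
  }
})

test_that("ball projection is idempotent, feasible, and identity inside", {
  expect_equal(project_to_ball(c(0.5, 0.5), 1), c(0.5, 0.5))
  expect_equal(project_to_ball(c(3, 4), 1), c(0.6, 0.8))
  expect_equal(project_to_ball(c(0, 0), 2), c(0, 0))
  set.seed(101)
  for (i in 1:10) {
    v <- rnorm(4) * 5
    C <- runif(1, 0.1, 3)
    pv <- project_to_ball(v, C)
    expect_lte(sqrt(sum(pv^2)), C + 1e-12)
    expect_equal(project_to_ball(pv, C), pv, tolerance = 1e-12)
  }
})

test_that("fits are reproducible under a seed and differ across seeds", {
  sim <- simulate_lsirm(n_persons = 60, n_items = 12, seed = 1)
  ctl <- lsirm_control(max_iter = 60)
  f1 <- quiet_fit(sim$data, dim = 2, seed = 5, control = ctl)
  f2 <- quiet_fit(sim$data, dim = 2, seed = 5, control = ctl)
  f3 <- quiet_fit(sim$data, dim = 2, seed = 6, control = ctl)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$trace, f2$trace)
  expect_false(identical(f1$theta, f3$theta))
  fc1 <- quiet_fit(sim$data, dim = 2, method = "cjml", seed = 5, control = ctl)
  fc2 <- quiet_fit(sim$data, dim = 2, method = "cjml", seed = 5, control = ctl)
  expect_identical(fc1$W, fc2$W)
})

test_that("objective traces ascend monotonically for both estimators", {
  sim <- simulate_lsirm(n_persons = 120, n_items = 16, seed = 2)
  for (m in c("pjml", "cjml")) {
    fit <- quiet_fit(sim$data, dim = 2, method = m, seed = 3,
                     control = lsirm_control(max_iter = 150))
    expect_false(is.unsorted(fit$trace))
    expect_equal(fit$objective, fit$trace[length(fit$trace)])
  }
})

test_that("the echelon zero pattern is enforced throughout fitting", {
  sim <- simulate_lsirm(n_persons = 80, n_items = 12, dim = 3, seed = 4)
  fit <- quiet_fit(sim$data, dim = 3, seed = 5,
                   control = lsirm_control(max_iter = 40))
  expect_identical(fit$W[1, 2:3], c(0, 0))
  expect_identical(fit$W[2, 3], 0)
  expect_true(all(diag(fit$W[1:3, ]) >= 0))
})

test_that("an overwhelming penalty drives every parameter to zero", {
  sim <- simulate_lsirm(n_persons = 50, n_items = 10, seed = 6)
  fit <- quiet_fit(sim$data, dim = 2, lambda = 1e6, seed = 7)
  expect_lt(max(abs(c(fit$theta, fit$beta, fit$Z, fit$W))), 1e-2)
})

test_that("the penalty keeps an all-ones response matrix from diverging", {
  Y <- matrix(1, 30, 8)
  fit <- quiet_fit(Y, dim = 2, lambda = 1, seed = 8)
  expect_true(is.finite(fit$objective))
  expect_false(is.unsorted(fit$trace))
  expect_true(all(is.finite(c(fit$theta, fit$beta, fit$Z, fit$W))))
})

test_that("constrained fits respect every norm bound", {
  sim <- simulate_lsirm(n_persons = 100, n_items = 12, seed = 9)
  dc <- default_constraints(2)
  fit <- quiet_fit(sim$data, dim = 2, method = "cjml", seed = 10)
  person_norms <- sqrt(fit$theta^2 + rowSums(fit$Z^2))
  item_norms <- sqrt(fit$beta^2 + rowSums(fit$W^2))
  expect_true(all(person_norms <= dc$C_person + 1e-8))
  expect_true(all(item_norms <= dc$C_item + 1e-8))
})

test_that("inactive constraints leave the constrained trajectory unchanged", {
  sim <- simulate_lsirm(n_persons = 60, n_items = 10, seed = 11)
  ctl <- lsirm_control(max_iter = 25, rel_tol = 1e-12)
  fa <- quiet_fit(sim$data, dim = 2, method = "cjml",
                  C_person = 1e6, C_item = 1e6, seed = 12, control = ctl)
  fb <- quiet_fit(sim$data, dim = 2, method = "cjml",
                  C_person = 1e7, C_item = 1e7, seed = 12, control = ctl)
  expect_identical(fa$trace, fb$trace)
  expect_identical(fa$W, fb$W)
  expect_identical(fa$theta, fb$theta)
})

test_that("empty rows and columns are rejected before optimization", {
  Y <- matrix(c(1, NA, 0, NA), 2, 2)  # row 2 fully missing
  expect_error(fit_lsirm(Y, dim = 1), "Row 2")
  Y2 <- cbind(c(1, 0, 1), NA)
  expect_error(fit_lsirm(Y2, dim = 1), "Column 2")
})

test_that("parameter recovery on simulated data reaches the attainable floors", {
  sim <- simulate_lsirm(n_persons = 1000, n_items = 48, seed = 13)
  fit <- quiet_fit(sim$data, dim = 2, seed = 14)
  expect_gt(cor(fit$theta, sim$truth$theta), 0.75)
  d_true <- as.matrix(dist(rbind(sim$truth$Z, sim$truth$W)))[1:1000, 1000 + 1:48]
  d_fit <- as.matrix(dist(rbind(fit$Z, fit$W)))[1:1000, 1000 + 1:48]
  expect_gt(cor(as.numeric(d_true), as.numeric(d_fit)), 0.45)
  expect_gt(cor(fit$beta, sim$truth$beta), 0.9)
})

test_that("penalized and constrained estimates agree closely after alignment", {
  sim <- simulate_lsirm(n_persons = 1000, n_items = 48, gamma = 1.7, seed = 42)
  fp <- quiet_fit(sim$data, dim = 2, seed = 1)
  fc <- quiet_fit(sim$data, dim = 2, method = "cjml", seed = 1)
  al <- align_to_reference(fc$W, fc$Z, W_ref = fp$W)
  expect_gt(cor(fp$theta, fc$theta), 0.9)
  expect_gt(cor(fp$beta, fc$beta), 0.9)
  expect_gt(cor(as.numeric(fp$W), as.numeric(al$W)), 0.9)
  # the constrained estimates are more spread out (no shrinkage)
  expect_gt(sd(fc$theta), sd(fp$theta))
})

test_that("the distance weight is absorbed into the coordinate scale", {
  # the uniform-ball constraints are scale-neutral, so the constrained
  # estimator shows the absorption cleanly; the regression slope of aligned
  # estimates on the truth measures the absorbed scale without the upward
  # bias that estimation noise adds to a standard-deviation ratio
  for (g in c(1, 1.7)) {
    sim <- simulate_lsirm(n_persons = 2000, n_items = 96, gamma = g, seed = 17)
    fit <- quiet_fit(sim$data, dim = 2, method = "cjml", seed = 18)
    rot <- echelon_rotate(sim$truth$W, sim$truth$Z)
    al <- align_to_reference(fit$W, fit$Z, W_ref = rot$W)
    slope <- sum(al$W[, 1] * rot$W[, 1]) / sum(rot$W[, 1]^2)
    expect_lt(abs(slope - g) / g, 0.2)
  }
})
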