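test_that("sse_loss matches hand-computed residual sums", {
  m <- slope_model()
  ds0 <- generate_synthetic(m, 2, times = c(1, 2, 3), sigma = 0)
  expect_lt(sse_loss(m, ds0, 2), 1e-12)
  # single point: prediction 2 vs datum 3
  ds1 <- new_dataset(1, 3)
  expect_equal(sse_loss(m, ds1, 2), 1)
  # two points with residuals (1, -2)
  ds2 <- new_dataset(c(1, 2), c(2 + 1, 4 - 2))
  expect_equal(sse_loss(m, ds2, 2), 5)
})

test_that("least squares recovers a linear model exactly", {
  m <- line_model()
  ds <- generate_synthetic(m, c(1, 2), times = c(0, 1, 2), sigma = 0)
  fit <- fit_least_squares(m, ds, c(0.3, 0.7))
  expect_equal(unname(fit$theta_hat), c(1, 2), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$loss, sse_loss(m, ds, fit$theta_hat),
               tolerance = 1e-9)
})

test_that("LV parameters are recovered from noiseless data", {
  lv <- zoo_model("lv")
  ds <- generate_synthetic(lv, lv$theta, seq(0, 20, length.out = 25),
                           sigma = 0)
  fit <- fit_least_squares(lv, ds, 1.3 * lv$theta)
  expect_lt(max(abs(fit$theta_hat - lv$theta) / lv$theta), 1e-3)
})

test_that("an empty dataset is rejected", {
  expect_error(new_dataset(numeric(0), matrix(0, 0, 1)), "at least one")
})

test_that("regularized fit with no null directions equals plain least squares", {
  m <- line_model()
  ds <- generate_synthetic(m, c(1, 2), times = c(0, 1, 2), sigma = 0.1,
                           seed = 4)
  f1 <- fit_least_squares(m, ds, c(0.5, 0.5))
  f2 <- fit_regularized(m, ds, theta_star = c(0.5, 0.5),
                        Unull = matrix(0, 2, 0), lambda = 1,
                        theta0 = c(0.5, 0.5))
  expect_equal(f2$theta_hat, f1$theta_hat, tolerance = 1e-9)
  expect_false(f2$regularized)
  expect_equal(f2$lambda, 0)
})

test_that("regularized refit satisfies the penalized normal equations", {
  # h = (theta1 + theta2) t: rank-1 sensitivity, null direction (1,-1)/sqrt(2)
  m <- sum_slope_model()
  tt <- c(1, 2, 3)
  theta_star <- c(1.2, 1.8)
  ds <- generate_synthetic(m, c(1, 2), times = tt, sigma = 0)
  S <- sensitivity_matrix(m, theta_star, tt)
  ed <- eigendecompose_fim(fim(S), eps_eig = 1e-10)
  expect_equal(ncol(ed$Unull), 1L)
  lambda <- 1
  fit <- fit_regularized(m, ds, theta_star, ed$Unull, lambda = lambda)
  # linearized oracle: (lambda U U^T + S^T S) theta = S^T b + lambda U U^T theta*
  b <- as.vector(t(ds$observations)) -
    as.vector(t(eval_observable(m, theta_star, tt))) +
    S$values %*% theta_star
  lhs <- (lambda * tcrossprod(ed$Unull) + crossprod(S$values)) %*%
    fit$theta_hat
  rhs <- crossprod(S$values, b) +
    lambda * tcrossprod(ed$Unull) %*% theta_star
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  # reported objective decomposes into loss + penalty
  pen <- lambda * sum((t(ed$Unull) %*% (fit$theta_hat - theta_star))^2)
  expect_equal(fit$objective, fit$loss + pen, tolerance = 1e-9)
  expect_error(fit_regularized(m, ds, theta_star,
                               matrix(c(1, 1), 2, 1), lambda = 1),
               "orthonormal")
})

test_that("regularization renders the polynomial fixture fully profiled-identifiable", {
  p <- zoo_model("polynomial")
  ds <- generate_synthetic(p, c(1, 1, 1), times = c(1, 2, 3), sigma = 0)
  S <- sensitivity_matrix(p, c(1, 1, 1), c(1, 2, 3))
  ed <- eigendecompose_fim(fim(S), eps_eig = 1e-4)
  fit <- fit_regularized(p, ds, c(1, 1, 1), ed$Unull, lambda = 1)
  for (i in 1:3) {
    pc <- profile_likelihood(p, ds, fit$theta_hat, i,
                             Unull = ed$Unull, lambda = 1)
    expect_equal(pc$classification, "identifiable")
  }
})

test_that("regularized FIM has the factored-form spectrum", {
  expect_equal(regularized_fim(diag(2), matrix(0, 2, 0), 0), diag(2))
  # single column of squared norm 5 in a k = 2 problem
  S <- matrix(c(1, 2, 0, 0), 2, 2)
  ed <- eigendecompose_fim(fim(S), eps_eig = 1e-10)
  Freg <- regularized_fim(S, ed$Unull, lambda = 1)
  expect_equal(sort(eigen(Freg, symmetric = TRUE)$values), c(1, 5),
               tolerance = 1e-10)

  set.seed(31)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    Sm <- random_sens_matrix(10, k, n_dependent = sample(1:2, 1))
    ed <- eigendecompose_fim(fim(Sm), eps_eig = 1e-8)
    lambda <- runif(1, 0.5, 2)
    Freg <- regularized_fim(Sm, ed$Unull, lambda)
    got <- sort(eigen(Freg, symmetric = TRUE, only.values = TRUE)$values)
    want <- sort(c(ed$eigenvalues[seq_len(ed$r)],
                   rep(lambda, k - ed$r)))
    expect_equal(got, want, tolerance = 1e-8 * (1 + max(want)))
    # full rank: smallest eigenvalue at least min(lambda, smallest retained)
    expect_gte(min(got),
               min(lambda, min(ed$eigenvalues[seq_len(ed$r)])) - 1e-9)
  }
})

test_that("regularized refit does not increase the penalized objective", {
  p <- zoo_model("polynomial")
  ds <- generate_synthetic(p, c(1, 1, 1), times = c(1, 2, 3), sigma = 0.2,
                           seed = 9)
  theta0 <- c(1.4, 0.7, 1.5)
  S <- sensitivity_matrix(p, theta0, c(1, 2, 3))
  ed <- eigendecompose_fim(fim(S), eps_eig = 1e-4)
  obj0 <- sse_loss(p, ds, theta0) +
    1 * sum((t(ed$Unull) %*% (theta0 - theta0))^2)
  fit <- fit_regularized(p, ds, theta0, ed$Unull, lambda = 1)
  expect_lte(fit$objective, obj0 + 1e-12)
})
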