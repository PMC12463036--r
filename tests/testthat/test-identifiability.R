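test_that("fim is the symmetrized Gram matrix of the sensitivities", {
  expect_equal(fim(diag(2)), diag(2))
  expect_equal(fim(matrix(c(1, 1, 0, 1), 2, 2)),
               matrix(c(2, 1, 1, 1), 2, 2))
  set.seed(7)
  for (rep in 1:5) {
    S <- matrix(rnorm(30), 6, 5)
    F <- fim(S)
    ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
    expect_identical(F, t(F))
  }
})

test_that("eigendecomposition splits the spectrum at the threshold", {
  ed <- eigendecompose_fim(diag(c(4, 1, 0)), eps_eig = 1e-4)
  expect_equal(ed$eigenvalues, c(4, 1, 0))
  expect_equal(ed$r, 2)
  expect_equal(abs(ed$Unull), matrix(c(0, 0, 1), 3, 1), tolerance = 1e-12)

  set.seed(11)
  A <- matrix(rnorm(36), 6, 6)
  F <- crossprod(A)
  ed6 <- eigendecompose_fim(F, eps_eig = 0)
  recon <- ed6$eigenvectors %*% diag(ed6$eigenvalues) %*%
    t(ed6$eigenvectors)
  expect_lt(max(abs(recon - F)), 1e-8 * (1 + max(ed6$eigenvalues)))
  expect_lt(max(abs(crossprod(ed6$eigenvectors) - diag(6))), 1e-10)
  expect_true(all(diff(ed6$eigenvalues) <= 1e-12))
  # sign convention: largest-magnitude component positive
  for (j in 1:6)
    expect_gt(ed6$eigenvectors[which.max(abs(ed6$eigenvectors[, j])), j], 0)
  expect_error(eigendecompose_fim(matrix(c(1, 2, 0, 1), 2, 2)),
               "symmetric")
})

test_that("polynomial data at the cubic roots yields exactly one null eigenvalue", {
  p <- zoo_model("polynomial")
  S <- sensitivity_matrix(p, c(1, 1, 1), c(1, 2, 3))
  ed <- eigendecompose_fim(fim(S), eps_eig = 1e-4, p$param_names)
  expect_equal(sum(ed$eigenvalues <= 1e-10), 1L)
  expect_equal(ed$r, 2L)
})

test_that("coordinate metric detects orthogonal and dependent columns", {
  r1 <- coordinate_metric(diag(2))
  expect_equal(unname(r1$metric), c(1, 1))
  expect_true(all(r1$flags))
  r2 <- coordinate_metric(matrix(1, 2, 2))
  expect_equal(unname(r2$metric), c(0, 0), tolerance = 1e-12)
  expect_false(any(r2$flags))
  expect_error(coordinate_metric(matrix(1, 3, 1)), "2 parameters")
})

test_that("coordinate metric is bounded by the column norm", {
  set.seed(3)
  for (rep in 1:20) {
    S <- random_sens_matrix(sample(3:12, 1), sample(2:6, 1),
                            sample(0:2, 1))
    m <- coordinate_metric(S)$metric
    expect_true(all(m >= 0))
    # the projection residual cannot exceed the column it came from
    expect_true(all(m <= sqrt(colSums(S^2)) + 1e-12))
  }
})

test_that("profile of a scalar linear model is a strictly convex parabola", {
  m <- slope_model()
  ds <- generate_synthetic(m, 2, times = c(1, 2, 3), sigma = 0)
  pc <- profile_likelihood(m, ds, 2, 1)
  expect_equal(pc$classification, "identifiable")
  expect_equal(pc$pl_values[which.min(abs(pc$grid - 2))], 0,
               tolerance = 1e-9)
  d2 <- diff(diff(pc$pl_values))
  expect_true(all(d2 > 0))
})

test_that("profile of the invisible cubic coefficient is flat", {
  p <- zoo_model("polynomial")
  ds <- generate_synthetic(p, c(1, 1, 1), times = c(1, 2, 3), sigma = 0)
  pc <- profile_likelihood(p, ds, c(1, 1, 1), 3)
  expect_equal(pc$classification, "flat")
  expect_lt(max(pc$pl_values) - min(pc$pl_values),
            1e-6 * (1 + min(pc$pl_values)))
  # while the visible quadratic coefficient profiles as identifiable
  pc2 <- profile_likelihood(p, ds, c(1, 1, 1), 2)
  expect_equal(pc2$classification, "identifiable")
})

test_that("contribution index is the clipped eigenvalue ratio", {
  expect_equal(contribution_index(diag(3)), 1)
  expect_equal(contribution_index(diag(c(4, 1))), 0.25)
  expect_equal(contribution_index(matrix(1, 2, 2)), 0)
  for (nm in c("polynomial", "hill")) {
    m <- zoo_model(nm)
    S <- sensitivity_matrix(m, m$theta, m$protocol$times)
    xi <- contribution_index(fim(S))
    expect_gte(xi, 0)
    expect_lte(xi, 1)
  }
})

test_that("structural rank test separates full and deficient models", {
  p <- zoo_model("polynomial")
  rt <- structural_rank_test(p, c(1, 1, 1), n_grid = 50)
  expect_equal(rt$rank, 3L)
  expect_true(rt$full_rank)

  rt2 <- structural_rank_test(sum_slope_model(), c(1, 2), n_grid = 30)
  expect_equal(rt2$rank, 1L)
  expect_false(rt2$full_rank)

  h <- zoo_model("hill")
  rt3 <- structural_rank_test(h, h$theta, n_grid = 50)
  expect_true(rt3$full_rank)

  expect_error(structural_rank_test(p, c(1, 1, 1), n_grid = 2), "n_grid")
})

test_that("appending rows never decreases any FIM eigenvalue", {
  set.seed(19)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    S <- matrix(rnorm(8 * k), 8, k)
    extra <- matrix(rnorm(3 * k), 3, k)
    ev1 <- eigen(fim(S), symmetric = TRUE, only.values = TRUE)$values
    ev2 <- eigen(fim(rbind(S, extra)), symmetric = TRUE,
                 only.values = TRUE)$values
    expect_true(all(ev2 >= ev1 - 1e-10 * max(ev2)))
  }
})

test_that("feeding a null direction back as data raises the contribution index", {
  set.seed(23)
  for (rep in 1:10) {
    S <- cbind(matrix(rnorm(12), 6, 2), 0)  # third column identically zero
    S[, 3] <- S[, 1] * 0
    F <- fim(S)
    xi0 <- contribution_index(F)
    u <- eigendecompose_fim(F, eps_eig = 1e-10)$Unull[, 1]
    S2 <- rbind(S, 2 * u)
    xi1 <- contribution_index(fim(S2))
    expect_gte(xi1, xi0)
  }
})

test_that("dead relu neurons are flagged non-identifiable, tanh neurons are not", {
  # neuron 2 has pre-activation w1*t + b1 <= -1 on [0, 1]: it never fires,
  # so its input weight, bias and output weight drop out of the loss
  relu <- zoo_model("nn1", M_neurons = 2, activation = "relu")
  theta <- c(w1 = c(1, -1), b1 = c(0.5, -1), w2 = c(1, 1), b2 = 0)
  tt <- seq(0, 1, length.out = 11)
  cm <- coordinate_metric(sensitivity_matrix(relu, theta, tt))
  dead <- c("w1_2", "b1_2", "w2_2")
  expect_true(all(cm$metric[dead] <= 1e-10))
  # the live neuron is affine on all of [0, 1], so only a slope and an
  # intercept are determined: FIM rank 2 out of 7
  S <- sensitivity_matrix(relu, theta, tt)
  ed <- eigendecompose_fim(fim(S), eps_eig = 1e-8)
  expect_equal(ed$r, 2L)

  # with tanh every neuron responds somewhere on the interval
  tanh_net <- zoo_model("nn1", M_neurons = 2, activation = "tanh")
  theta2 <- c(0.8, -1.1, 0.2, 0.4, 1.2, -0.7, 0.1)
  cm2 <- coordinate_metric(sensitivity_matrix(tanh_net, theta2, tt))
  expect_true(all(cm2$metric > 0))
})
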