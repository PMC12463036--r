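test_that("decoupled Lotka-Volterra reduces to independent exponentials", {
  lv1 <- model_spec("lv_decoupled", "ode", c("a", "b", "d", "g"), c(0, 5),
    rhs = function(t, s, th) c(th[1] * s[1] - th[2] * s[1] * s[2],
                               th[3] * s[1] * s[2] - th[4] * s[2]),
    init = function(th) c(1, 1), state_names = c("x", "y"))
  st <- solve_states(lv1, c(0.5, 0, 0, 0.3), 2)
  expect_equal(unname(st[1, 1]), exp(1.0), tolerance = 1e-6)
  expect_equal(unname(st[1, 2]), exp(-0.6), tolerance = 1e-6)
})

test_that("SEIR conserves total population along trajectories", {
  seir <- zoo_model("seir", observables = c("S", "E", "I", "R"))
  tr <- solve_states(seir, seir$theta, seq(0, 100, by = 1))
  expect_lt(max(abs(rowSums(tr) - 1)), 1e-8)
})

test_that("SEIR with zero incubation decouples I to linear decay", {
  seir <- zoo_model("seir")
  st <- solve_states(seir, c(beta = 0.6, sigma = 0, gamma = 0.2), 5)
  expect_equal(unname(st[1, "I"]), 0.01 * exp(-1), tolerance = 1e-6)
})

test_that("Michaelis-Menten conserves enzyme and substrate totals", {
  mm <- zoo_model("mm", observables = c("S", "E", "ES", "P"))
  tr <- solve_states(mm, mm$theta, seq(0, 60, by = 1))
  expect_lt(max(abs(tr[, "E"] + tr[, "ES"] - 1)), 1e-8)
  expect_lt(max(abs(tr[, "S"] + tr[, "ES"] + tr[, "P"] - 10)), 1e-8)
})

test_that("Hill observable is bounded in [0, Vmax] and hits 1/2 at x = Kd", {
  h <- zoo_model("hill")
  expect_equal(as.numeric(eval_observable(h, c(1, 1, 1), 1)), 0.5)
  for (n in c(1, 2, 4)) {
    x <- seq(0, 4, length.out = 50)
    vals <- eval_observable(h, c(2, 1.3, n), x)
    expect_true(all(vals >= 0 & vals <= 2 + 1e-12))
    expect_equal(as.numeric(eval_observable(h, c(2, 1.3, n), 1.3)), 1,
                 tolerance = 1e-12)
  }
})

test_that("polynomial cubic term vanishes at its roots", {
  p <- zoo_model("polynomial")
  expect_equal(as.numeric(eval_observable(p, c(1, 1, 1), 2)), 7)
  expect_equal(as.numeric(eval_observable(p, c(1, 1, 5), c(1, 2, 3))),
               as.numeric(eval_observable(p, c(1, 1, -5), c(1, 2, 3))))
})

test_that("nn_forward follows the documented flattening and activations", {
  # one relu neuron clips a negative pre-activation
  expect_equal(nn_forward(c(1, 0, 1, 0), -1, "relu", 1), 0)
  # tanh(0) = 0 so only the output bias survives
  expect_equal(nn_forward(c(1, 0, 2, 0.5), 0, "tanh", 1), 0.5)
  # symmetric output weights cancel identical neurons for every input
  w <- c(1.3, 1.3, 0.2, 0.2, 1, -1, 0)
  expect_equal(nn_forward(w, seq(-2, 2, by = 0.5), "tanh", 2),
               rep(0, 9))
  # zero network is identically zero through the model interface
  nn <- zoo_model("nn1", M_neurons = 3)
  expect_equal(as.numeric(eval_observable(nn, rep(0, 10), c(0, 0.5, 1))),
               rep(0, 3))
  expect_error(nn_forward(c(1, 2), 0, "relu", 1), "length")
})

test_that("observable evaluation equals h composed with the state solve", {
  for (nm in c("lv", "mm", "seir")) {
    m <- zoo_model(nm)
    tt <- seq(m$t_domain[1], m$t_domain[2], length.out = 7)
    st <- solve_states(m, m$theta, tt)
    obs <- eval_observable(m, m$theta, tt)
    expect_equal(unname(obs), unname(st[, m$obs_idx, drop = FALSE]))
  }
})

test_that("halving tolerances barely moves the zoo trajectories", {
  for (nm in c("lv", "mm", "seir")) {
    m <- zoo_model(nm)
    tt <- seq(m$t_domain[1], m$t_domain[2], length.out = 9)
    a <- solve_states(m, m$theta, tt, rtol = 1e-8, atol = 1e-10)
    b <- solve_states(m, m$theta, tt, rtol = 5e-9, atol = 5e-11)
    expect_lt(max(abs(a - b)) / max(abs(a)), 10 * 1e-8)
  }
})

test_that("Lotka-Volterra stays positive from a positive start", {
  lv <- zoo_model("lv")
  tr <- solve_states(lv, lv$theta, seq(0, 20, length.out = 200))
  expect_true(all(tr > 0))
})

test_that("times outside the model domain and bad theta are rejected", {
  lv <- zoo_model("lv")
  expect_error(solve_states(lv, lv$theta, 25), "t_domain")
  expect_error(solve_states(lv, c(1, 2), 5), "length")
  expect_error(solve_states(zoo_model("hill"), c(1, 1, 1), 1),
               "ode")
})
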