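# Small hand-built models used across the suite (zoo models are exercised
# separately via zoo_model()).

# scalar exponential decay: x' = -theta * x, x(0) = 1
decay_model <- function() {
  model_spec(
    name = "decay", kind = "ode", param_names = "theta",
    t_domain = c(0, 10),
    rhs = function(t, s, th) -th[1] * s[1],
    init = function(th) 1,
    state_names = "x"
  )
}

# scalar exponential growth: x' = theta * x, x(0) = 1
growth_model <- function() {
  model_spec(
    name = "growth", kind = "ode", param_names = "theta",
    t_domain = c(0, 5),
    rhs = function(t, s, th) th[1] * s[1],
    init = function(th) 1,
    state_names = "x"
  )
}

# h(t) = theta1 + theta2 * t (closed form, linear in parameters)
line_model <- function() {
  model_spec(
    name = "line", kind = "closed_form", param_names = c("a", "b"),
    t_domain = c(0, 10),
    fn = function(times, theta) theta[1] + theta[2] * times
  )
}

# h(t) = (theta1 + theta2) * t: rank-1 sensitivity, never identifiable
sum_slope_model <- function() {
  model_spec(
    name = "sum_slope", kind = "closed_form", param_names = c("a", "b"),
    t_domain = c(0, 10),
    fn = function(times, theta) (theta[1] + theta[2]) * times
  )
}

# h(t) = theta1 * t (scalar linear model)
slope_model <- function() {
  model_spec(
    name = "slope", kind = "closed_form", param_names = "a",
    t_domain = c(0, 10),
    fn = function(times, theta) theta[1] * times
  )
}

# random sensitivity matrix with optionally planted rank deficiencies:
# some columns are forced into the span of the others
random_sens_matrix <- function(nrow, k, n_dependent = 0) {
  S <- matrix(stats::rnorm(nrow * k), nrow, k)
  if (n_dependent > 0) {
    dep <- sample(k, n_dependent)
    indep <- setdiff(seq_len(k), dep)
    for (j in dep) {
      if (length(indep) == 0) {
        S[, j] <- 0
      } else {
        w <- stats::rnorm(length(indep))
        S[, j] <- S[, indep, drop = FALSE] %*% w
      }
    }
  }
  S
}

# independent residual oracle: QR-based least-squares residual of column i
# of S against the remaining columns
qr_residual_norm <- function(S, i) {
  A <- S[, -i, drop = FALSE]
  qrA <- qr(A)
  r <- qr.resid(qrA, S[, i])
  sqrt(sum(r^2))
}
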