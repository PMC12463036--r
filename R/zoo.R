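#' Built-in model zoo
#'
#' Constructs one of the packaged worked models with documented default
#' parameters, observable selections and a data-collection protocol
#' (`$protocol`: default measurement times, noise level and eigenvalue
#' threshold used by the packaged configs).
#'
#' Available models:
#' \describe{
#'   \item{polynomial}{Closed form \eqn{h(t;\theta) = \theta_1 + \theta_2 t^2
#'     + \theta_3 (t-1)(t-2)(t-3) + 2}, k = 3, t in \[0, 4\]. With data only
#'     at t = 1, 2, 3 the cubic coefficient is invisible: its sensitivity
#'     column vanishes, making it the canonical non-identifiability fixture.}
#'   \item{hill}{Saturating dose-response \eqn{V_{max} x^n / (x^n + K_d^n)}
#'     with \eqn{\theta = (V_{max}, K_d, n)}; the independent variable is
#'     ligand concentration, treated uniformly as "time" in all interfaces.
#'     Defaults Vmax = 1, Kd = 1, n = 4 on x in \[0, 4\]; the packaged
#'     protocol samples baseline and plateau (x = 0.1, 0.2, 3, 3.5, 4), which
#'     leaves the cooperativity n practically non-identifiable.}
#'   \item{nn1}{Single-hidden-layer scalar network (see [nn_forward()]) with
#'     `M_neurons` units and k = 3*M_neurons + 1 parameters, t in \[0, 1\].}
#'   \item{lv}{Lotka-Volterra predator-prey ODE: \eqn{\dot x = \alpha x -
#'     \beta x y}, \eqn{\dot y = \delta x y - \gamma y}. Defaults
#'     (0.55, 0.028, 0.024, 0.84), x0 = 30, y0 = 4, t in \[0, 20\], both
#'     states observed.}
#'   \item{mm}{Michaelis-Menten enzyme kinetics with states (S, E, ES, P) and
#'     rates (k1, km1, k2): binding, unbinding, catalysis. Defaults
#'     (1, 0.5, 0.3), S0 = 10, E0 = 1, t in \[0, 60\]. Observable cases:
#'     `observables = c("S", "P")` (case 1, default) or `"P"` (case 2).}
#'   \item{seir}{SEIR epidemic compartments as fractions with rates
#'     \eqn{(\beta, \sigma, \gamma)} = transmission, incubation, recovery.
#'     Defaults (0.6, 0.2, 0.15), I0 = 0.01, t in \[0, 100\]; default
#'     observable is the infected fraction I.}
#' }
#'
#' @param name One of `"polynomial"`, `"hill"`, `"nn1"`, `"lv"`, `"mm"`,
#'   `"seir"`.
#' @param observables For ODE models, character vector of state names (or
#'   integer indices) to observe; defaults per model as documented above.
#' @param M_neurons,activation For `nn1`: hidden-layer width and activation.
#' @return A `model_spec` with a `$protocol` list attached.
#' @export
zoo_model <- function(name, observables = NULL, M_neurons = 5,
                      activation = c("tanh", "relu")) {
  switch(name,
    polynomial = zoo_polynomial(),
    hill = zoo_hill(),
    nn1 = zoo_nn1(M_neurons, match.arg(activation)),
    lv = zoo_lv(observables),
    mm = zoo_mm(observables),
    seir = zoo_seir(observables),
    stop("unknown zoo model '", name, "'")
  )
}

zoo_polynomial <- function() {
  m <- model_spec(
    name = "polynomial", kind = "closed_form",
    param_names = c("theta1", "theta2", "theta3"),
    t_domain = c(0, 4),
    fn = function(times, theta)
      theta[1] + theta[2] * times^2 +
        theta[3] * (times - 1) * (times - 2) * (times - 3) + 2,
    obs_names = "h", theta = c(1, 1, 1)
  )
  m$protocol <- list(times = c(1, 2, 3), sigma = 0, eps_eig = 1e-4)
  m
}

zoo_hill <- function() {
  m <- model_spec(
    name = "hill", kind = "closed_form",
    param_names = c("Vmax", "Kd", "n"),
    t_domain = c(0, 4),
    fn = function(times, theta) {
      xn <- times^theta[3]
      theta[1] * xn / (xn + theta[2]^theta[3])
    },
    obs_names = "h", theta = c(Vmax = 1, Kd = 1, n = 4)
  )
  m$protocol <- list(times = c(0.1, 0.2, 3, 3.5, 4), sigma = 0,
                     eps_eig = 1e-4)
  m
}

zoo_nn1 <- function(M_neurons, activation) {
  M <- as.integer(M_neurons)
  pn <- c(paste0("w1_", seq_len(M)), paste0("b1_", seq_len(M)),
          paste0("w2_", seq_len(M)), "b2")
  m <- model_spec(
    name = "nn1", kind = "closed_form", param_names = pn,
    t_domain = c(0, 1),
    fn = function(times, theta)
      nn_forward(theta, times, activation = activation, M_neurons = M),
    obs_names = "h", theta = rep(0, 3L * M + 1L)
  )
  m$M_neurons <- M
  m$activation <- activation
  m$protocol <- list(times = seq(0, 1, length.out = 21), sigma = 0,
                     eps_eig = 1e-4)
  m
}

resolve_obs <- function(observables, state_names, default) {
  if (is.null(observables)) observables <- default
  if (is.character(observables)) {
    idx <- match(observables, state_names)
    if (any(is.na(idx)))
      stop("unknown observable(s): ",
           paste(observables[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(observables)
}

zoo_lv <- function(observables = NULL) {
  sn <- c("x", "y")
  idx <- resolve_obs(observables, sn, sn)
  m <- model_spec(
    name = "lv", kind = "ode",
    param_names = c("alpha", "beta", "delta", "gamma"),
    t_domain = c(0, 20),
    rhs = function(t, state, theta) {
      x <- state[1]; y <- state[2]
      c(theta[1] * x - theta[2] * x * y,
        theta[3] * x * y - theta[4] * y)
    },
    init = function(theta) c(30, 4),
    rhs_jac = function(t, state, theta) {
      x <- state[1]; y <- state[2]
      list(state = matrix(c(theta[1] - theta[2] * y, theta[3] * y,
                            -theta[2] * x, theta[3] * x - theta[4]),
                          2, 2),
           theta = matrix(c(x, 0, -x * y, 0, 0, x * y, 0, -y), 2, 4))
    },
    obs_idx = idx, state_names = sn,
    theta = c(alpha = 0.55, beta = 0.028, delta = 0.024, gamma = 0.84)
  )
  m$protocol <- list(times = seq(0, 20, length.out = 25), sigma = NULL,
                     eps_eig = 1e-6)
  m
}

zoo_mm <- function(observables = NULL) {
  sn <- c("S", "E", "ES", "P")
  idx <- resolve_obs(observables, sn, c("S", "P"))
  m <- model_spec(
    name = "mm", kind = "ode",
    param_names = c("k1", "km1", "k2"),
    t_domain = c(0, 60),
    rhs = function(t, state, theta) {
      S <- state[1]; E <- state[2]; ES <- state[3]
      v_bind <- theta[1] * E * S
      v_unbind <- theta[2] * ES
      v_cat <- theta[3] * ES
      c(-v_bind + v_unbind,
        -v_bind + v_unbind + v_cat,
        v_bind - v_unbind - v_cat,
        v_cat)
    },
    init = function(theta) c(10, 1, 0, 0),
    rhs_jac = function(t, state, theta) {
      S <- state[1]; E <- state[2]; ES <- state[3]
      k1 <- theta[1]; km1 <- theta[2]; k2 <- theta[3]
      Jy <- rbind(c(-k1 * E, -k1 * S, km1, 0),
                  c(-k1 * E, -k1 * S, km1 + k2, 0),
                  c(k1 * E, k1 * S, -(km1 + k2), 0),
                  c(0, 0, k2, 0))
      Jp <- rbind(c(-E * S, ES, 0),
                  c(-E * S, ES, ES),
                  c(E * S, -ES, -ES),
                  c(0, 0, ES))
      list(state = Jy, theta = Jp)
    },
    obs_idx = idx, state_names = sn,
    theta = c(k1 = 1, km1 = 0.5, k2 = 0.3)
  )
  m$protocol <- list(times = seq(0, 60, length.out = 25), sigma = NULL,
                     eps_eig = 1e-6)
  m
}

zoo_seir <- function(observables = NULL) {
  sn <- c("S", "E", "I", "R")
  idx <- resolve_obs(observables, sn, "I")
  m <- model_spec(
    name = "seir", kind = "ode",
    param_names = c("beta", "sigma", "gamma"),
    t_domain = c(0, 100),
    rhs = function(t, state, theta) {
      S <- state[1]; E <- state[2]; I <- state[3]
      inf <- theta[1] * S * I
      c(-inf, inf - theta[2] * E, theta[2] * E - theta[3] * I,
        theta[3] * I)
    },
    init = function(theta) c(0.99, 0, 0.01, 0),
    rhs_jac = function(t, state, theta) {
      S <- state[1]; E <- state[2]; I <- state[3]
      b <- theta[1]; s <- theta[2]; g <- theta[3]
      Jy <- rbind(c(-b * I, 0, -b * S, 0),
                  c(b * I, -s, b * S, 0),
                  c(0, s, -g, 0),
                  c(0, 0, g, 0))
      Jp <- rbind(c(-S * I, 0, 0),
                  c(S * I, -E, 0),
                  c(0, E, -I),
                  c(0, 0, I))
      list(state = Jy, theta = Jp)
    },
    obs_idx = idx, state_names = sn,
    theta = c(beta = 0.6, sigma = 0.2, gamma = 0.15)
  )
  m$protocol <- list(times = seq(0, 100, length.out = 25), sigma = NULL,
                     eps_eig = 1e-6)
  m
}

#' Default noise level for a synthetic protocol
#'
#' Returns a per-observable standard deviation equal to 5% of each
#' observable's trajectory range over the given times, the package's
#' documented substitute when a protocol does not fix sigma.
#'
#' @inheritParams solve_states
#' @param frac Fraction of the trajectory range, default 0.05.
#' @return Length-L numeric vector of standard deviations.
#' @export
default_sigma <- function(model, theta = model$theta, times = NULL,
                          frac = 0.05) {
  if (is.null(times)) times <- model$protocol$times
  obs <- eval_observable(model, theta, times)
  frac * (apply(obs, 2, max) - apply(obs, 2, min))
}
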