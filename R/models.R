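#' Define a dynamic model for identifiability analysis
#'
#' A `model_spec` is the object every analysis in the package consumes. It
#' describes either a closed-form observable \eqn{h(t, \theta)} or an ODE
#' system \eqn{\dot\varphi = f(\varphi, \theta)} together with an observable
#' map \eqn{h(\varphi)} that selects or transforms the measurable quantities.
#'
#' @param name Identifier for the model.
#' @param kind Either `"closed_form"` or `"ode"`.
#' @param param_names Character vector of k unique parameter names.
#' @param t_domain Closed interval of admissible times, length-2 numeric.
#' @param fn For closed-form models: `function(times, theta)` returning an
#'   N x L matrix (or length-N vector when L = 1) of observables.
#' @param rhs For ODE models: `function(t, state, theta)` returning the
#'   length-M state derivative.
#' @param init For ODE models: `function(theta)` returning the length-M
#'   initial state at the left end of `t_domain` (may depend on theta).
#' @param obs For ODE models: `function(state)` mapping a length-M state to a
#'   length-L observation vector. Defaults to the identity.
#' @param obs_idx Optional integer vector of state indices; when supplied it
#'   defines `obs` as a plain state selection (and enables exact observable
#'   Jacobians in the sensitivity code).
#' @param state_names Optional character names for the M states (ODE only).
#' @param obs_names Optional character names for the L observables.
#' @param theta Default parameter vector (used by the model zoo; optional).
#' @param rhs_jac Optional analytic Jacobians: `function(t, state, theta)`
#'   returning a list with elements `state` (M x M) and `theta` (M x k).
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, kind = c("closed_form", "ode"), param_names,
                       t_domain, fn = NULL, rhs = NULL, init = NULL,
                       obs = NULL, obs_idx = NULL, state_names = NULL,
                       obs_names = NULL, theta = NULL, rhs_jac = NULL) {
  kind <- match.arg(kind)
  param_names <- as.character(param_names)
  if (anyDuplicated(param_names)) stop("param_names must be unique")
  if (length(t_domain) != 2L || !is.numeric(t_domain) || diff(t_domain) <= 0)
    stop("t_domain must be an increasing length-2 numeric interval")

  if (kind == "closed_form") {
    if (!is.function(fn)) stop("closed_form models require fn(times, theta)")
    state_dim <- 1L
  } else {
    if (!is.function(rhs) || !is.function(init))
      stop("ode models require rhs(t, state, theta) and init(theta)")
    state_dim <- length(init(if (is.null(theta))
      rep(1, length(param_names)) else theta))
    if (!is.null(obs_idx)) {
      obs_idx <- as.integer(obs_idx)
      if (any(obs_idx < 1L | obs_idx > state_dim))
        stop("obs_idx out of range for state dimension ", state_dim)
      obs <- local({
        idx <- obs_idx
        function(state) state[idx]
      })
    }
    if (is.null(obs)) {
      obs <- identity
      obs_idx <- seq_len(state_dim)
    }
  }

  m <- structure(list(
    name = name, kind = kind, k = length(param_names),
    param_names = param_names, state_dim = state_dim,
    t_domain = as.numeric(t_domain), fn = fn, rhs = rhs, init = init,
    obs = obs, obs_idx = obs_idx, state_names = state_names,
    obs_names = obs_names, theta = theta, rhs_jac = rhs_jac
  ), class = "model_spec")
  m$L <- obs_dim(m)
  if (is.null(m$obs_names)) {
    m$obs_names <- if (!is.null(obs_idx) && !is.null(state_names))
      state_names[obs_idx] else paste0("obs", seq_len(m$L))
  }
  m
}

# Observable dimension, probed once at construction.
obs_dim <- function(model) {
  theta <- model$theta %||% rep(1, model$k)
  if (model$kind == "closed_form") {
    out <- model$fn(model$t_domain[1], theta)
    length(as.numeric(out))
  } else {
    length(model$obs(model$init(theta)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_theta <- function(model, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != model$k)
    stop(sprintf("theta has length %d; model '%s' expects %d",
                 length(theta), model$name, model$k))
  if (any(!is.finite(theta))) stop("theta contains non-finite values")
  theta
}

check_times <- function(model, times) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("times must contain at least one value")
  if (any(!is.finite(times))) stop("times contains non-finite values")
  lo <- model$t_domain[1] - 1e-12
  hi <- model$t_domain[2] + 1e-12
  if (any(times < lo | times > hi))
    stop(sprintf("times outside t_domain [%g, %g] for model '%s'",
                 model$t_domain[1], model$t_domain[2], model$name))
  times
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec '%s'> kind=%s, k=%d, M=%d, L=%d, t in [%g, %g]\n",
              x$name, x$kind, x$k, x$state_dim, x$L,
              x$t_domain[1], x$t_domain[2]))
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  if (!is.null(x$theta))
    cat("  default theta:", paste(signif(x$theta, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Integrate the state trajectory of an ODE model
#'
#' Solves \eqn{\dot\varphi = f(\varphi, \theta)} from the left end of the
#' model's time domain with an adaptive stiff-capable integrator
#' (\code{deSolve::ode}, method \code{"lsoda"}) and returns the states at the
#' requested times.
#'
#' @param model A `model_spec` of kind `"ode"`.
#' @param theta Parameter vector of length k.
#' @param times Sorted numeric vector of output times within `t_domain`.
#' @param rtol,atol Relative and absolute integration tolerances. Defaults
#'   are tight (1e-8, 1e-10) because sensitivities are differenced downstream.
#' @return A length(times) x M matrix of states; columns named after states
#'   when the model declares `state_names`.
#' @export
solve_states <- function(model, theta, times, rtol = 1e-8, atol = 1e-10) {
  if (model$kind != "ode") stop("solve_states requires an ode model")
  theta <- check_theta(model, theta)
  times <- check_times(model, times)
  y0 <- model$init(theta)
  t0 <- model$t_domain[1]
  tt <- sort(unique(c(t0, times)))
  if (length(tt) == 1L) {   # only the initial time requested: no integration
    out <- matrix(rep(y0, each = length(times)), nrow = length(times))
    if (!is.null(model$state_names)) colnames(out) <- model$state_names
    return(out)
  }
  f <- function(t, y, p) list(model$rhs(t, y, p))
  sol <- deSolve::ode(y = y0, times = tt, func = f, parms = theta,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- unclass(sol)
  if (nrow(sol) < length(tt) || any(!is.finite(sol[, -1, drop = FALSE]))) {
    bad <- if (nrow(sol) < length(tt)) tt[nrow(sol) + 1L] else
      tt[which(apply(!is.finite(sol[, -1, drop = FALSE]), 1, any))[1]]
    stop(sprintf("integration of model '%s' failed near t = %g",
                 model$name, bad))
  }
  out <- sol[match(times, tt), -1, drop = FALSE]
  out <- matrix(out, nrow = length(times), ncol = model$state_dim)
  if (!is.null(model$state_names)) colnames(out) <- model$state_names
  out
}

#' Evaluate the observable trajectory h(phi(t, theta))
#'
#' For closed-form models the observable function is evaluated directly; for
#' ODE models the states are integrated first and the observable map applied
#' row-wise.
#'
#' @inheritParams solve_states
#' @return An N x L matrix of observables with columns named per the model.
#' @export
eval_observable <- function(model, theta, times, rtol = 1e-8, atol = 1e-10) {
  theta <- check_theta(model, theta)
  times <- check_times(model, times)
  if (model$kind == "closed_form") {
    out <- model$fn(times, theta)
    out <- matrix(as.numeric(out), nrow = length(times), ncol = model$L)
  } else {
    states <- solve_states(model, theta, times, rtol = rtol, atol = atol)
    out <- t(apply(states, 1L, model$obs))
    out <- matrix(out, nrow = length(times), ncol = model$L)
  }
  if (any(!is.finite(out)))
    stop(sprintf("non-finite observable output from model '%s'", model$name))
  colnames(out) <- model$obs_names
  out
}

#' Forward pass of a single-hidden-layer scalar network
#'
#' Computes \eqn{\sum_m w^{(2)}_m\,\mathrm{act}(w^{(1)}_m t + b^{(1)}_m) +
#' b^{(2)}} for a scalar input. The weight vector is flat with the
#' documented order: the M input weights, then the M input biases, then the
#' M output weights, then the single output bias (length 3M + 1).
#'
#' @param weights Numeric vector of length `3 * M_neurons + 1`.
#' @param t Numeric input (vectorized).
#' @param activation `"relu"` or `"tanh"`.
#' @param M_neurons Number of hidden units.
#' @return Numeric vector the length of `t`.
#' @export
nn_forward <- function(weights, t, activation = c("tanh", "relu"),
                       M_neurons) {
  activation <- match.arg(activation)
  M <- as.integer(M_neurons)
  if (length(weights) != 3L * M + 1L)
    stop(sprintf("weights must have length %d (3*M_neurons + 1), got %d",
                 3L * M + 1L, length(weights)))
  w1 <- weights[seq_len(M)]
  b1 <- weights[M + seq_len(M)]
  w2 <- weights[2L * M + seq_len(M)]
  b2 <- weights[3L * M + 1L]
  act <- if (activation == "relu") function(z) pmax(z, 0) else tanh
  pre <- outer(t, w1) + rep(b1, each = length(t))  # |t| x M
  drop(act(pre) %*% w2) + b2
}
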