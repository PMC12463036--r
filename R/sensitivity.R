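#' Generalized sensitivity matrix of the observables
#'
#' Stacks the partial derivatives of every observable with respect to every
#' parameter over the measurement times into one (N*L) x k matrix. The block
#' order is the package-wide convention: N time blocks, each an L x k block
#' whose (l, i) entry is \eqn{\partial h_l(\varphi(t_n, \theta)) /
#' \partial\theta_i}. The Fisher Information Matrix is the Gram matrix of
#' this stacking (see [fim()]).
#'
#' @inheritParams solve_states
#' @param method `"finite_difference"` (central differences on the observable
#'   trajectory), `"forward_ode"` (forward sensitivity equations, ODE models
#'   only), or `"auto"` (forward_ode for ODE models, finite differences
#'   otherwise).
#' @param step_rel Relative finite-difference step; the per-parameter step is
#'   `step_rel * max(1, abs(theta_i))`.
#' @return An object of class `sensitivity_matrix` with elements `values`
#'   (the (N*L) x k matrix), `times`, `param_names`, `obs_names`, `L`.
#' @export
sensitivity_matrix <- function(model, theta, times,
                               method = c("auto", "finite_difference",
                                          "forward_ode"),
                               step_rel = 1e-6, rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  theta <- check_theta(model, theta)
  times <- check_times(model, times)
  if (method == "auto")
    method <- if (model$kind == "ode") "forward_ode" else "finite_difference"
  if (method == "forward_ode" && model$kind != "ode")
    stop("method 'forward_ode' requires an ode model")

  N <- length(times); L <- model$L; k <- model$k
  S <- matrix(0, nrow = N * L, ncol = k)

  if (method == "finite_difference") {
    # differencing amplifies trajectory error by 1/(2h): integrate the
    # perturbed trajectories much tighter than the step for ODE models
    rtol_fd <- if (model$kind == "ode") min(rtol, 1e-11) else rtol
    atol_fd <- if (model$kind == "ode") min(atol, 1e-13) else atol
    for (i in seq_len(k)) {
      h <- step_rel * max(1, abs(theta[i]))
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      dp <- eval_observable(model, tp, times, rtol = rtol_fd, atol = atol_fd)
      dm <- eval_observable(model, tm, times, rtol = rtol_fd, atol = atol_fd)
      col <- as.vector(t((dp - dm) / (2 * h)))
      if (any(!is.finite(col))) {
        bad <- times[ceiling(which(!is.finite(col))[1] / L)]
        stop(sprintf(
          "non-finite sensitivity for parameter '%s' near t = %g",
          model$param_names[i], bad))
      }
      S[, i] <- col
    }
  } else {
    fs <- forward_sensitivity_odes(model, theta, times,
                                   rtol = rtol, atol = atol)
    for (n in seq_len(N)) {
      Zn <- fs$sens[n, , , drop = TRUE]
      Zn <- matrix(Zn, nrow = model$state_dim, ncol = k)
      dh <- obs_state_jacobian(model, fs$states[n, ])
      block <- dh %*% Zn
      if (any(!is.finite(block))) {
        bad <- model$param_names[
          which(apply(!is.finite(block), 2, any))[1]]
        stop(sprintf(
          "non-finite sensitivity for parameter '%s' near t = %g",
          bad, times[n]))
      }
      S[(n - 1L) * L + seq_len(L), ] <- block
    }
  }
  colnames(S) <- model$param_names
  structure(list(values = S, times = times,
                 param_names = model$param_names,
                 obs_names = model$obs_names, L = L),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix> %d x %d (%d times x %d observables)\n",
              nrow(x$values), ncol(x$values), length(x$times), x$L))
  invisible(x)
}

# L x M Jacobian of the observable map at one state; exact for index
# selections, central differences otherwise.
obs_state_jacobian <- function(model, state) {
  M <- model$state_dim; L <- model$L
  if (!is.null(model$obs_idx)) {
    J <- matrix(0, L, M)
    J[cbind(seq_len(L), model$obs_idx)] <- 1
    return(J)
  }
  J <- matrix(0, L, M)
  for (m in seq_len(M)) {
    h <- 1e-7 * max(1, abs(state[m]))
    sp <- state; sp[m] <- sp[m] + h
    sm <- state; sm[m] <- sm[m] - h
    J[, m] <- (model$obs(sp) - model$obs(sm)) / (2 * h)
  }
  J
}

#' Forward sensitivity equations for an ODE model
#'
#' Integrates the augmented system \eqn{\dot Z = J_f(\varphi, \theta) Z +
#' \partial f / \partial\theta} alongside the states, with
#' \eqn{Z(0) = \partial\varphi_0 / \partial\theta}. Jacobians of `f` are
#' formed by central differences (step `1e-7 * max(1, |value|)`) unless the
#' model registers analytic Jacobians in `rhs_jac`.
#'
#' @inheritParams solve_states
#' @return A list with `times`, `states` (N x M) and `sens`
#'   (N x M x k array); `sens[n, m, i]` is
#'   \eqn{\partial\varphi_m(t_n) / \partial\theta_i}.
#' @export
forward_sensitivity_odes <- function(model, theta, times,
                                     rtol = 1e-8, atol = 1e-10) {
  if (model$kind != "ode") stop("forward_sensitivity_odes requires an ode model")
  theta <- check_theta(model, theta)
  times <- check_times(model, times)
  M <- model$state_dim; k <- model$k

  jac <- function(t, state) {
    if (!is.null(model$rhs_jac)) return(model$rhs_jac(t, state, theta))
    Jy <- matrix(0, M, M)
    for (m in seq_len(M)) {
      h <- 1e-7 * max(1, abs(state[m]))
      sp <- state; sp[m] <- sp[m] + h
      sm <- state; sm[m] <- sm[m] - h
      Jy[, m] <- (model$rhs(t, sp, theta) - model$rhs(t, sm, theta)) / (2 * h)
    }
    Jp <- matrix(0, M, k)
    for (i in seq_len(k)) {
      h <- 1e-7 * max(1, abs(theta[i]))
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      Jp[, i] <- (model$rhs(t, state, tp) - model$rhs(t, state, tm)) / (2 * h)
    }
    list(state = Jy, theta = Jp)
  }

  # Z(0) = d(initial state)/d(theta), central differences; exactly zero for
  # theta-independent initial states.
  Z0 <- matrix(0, M, k)
  for (i in seq_len(k)) {
    h <- 1e-7 * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    Z0[, i] <- (model$init(tp) - model$init(tm)) / (2 * h)
  }

  aug <- function(t, y, p) {
    phi <- y[seq_len(M)]
    Z <- matrix(y[-seq_len(M)], M, k)
    J <- jac(t, phi)
    dZ <- J$state %*% Z + J$theta
    list(c(model$rhs(t, phi, p), as.vector(dZ)))
  }

  t0 <- model$t_domain[1]
  tt <- sort(unique(c(t0, times)))
  if (length(tt) == 1L) {   # only the initial time: state and Z(0) directly
    states <- matrix(rep(model$init(theta), each = length(times)),
                     nrow = length(times))
    if (!is.null(model$state_names)) colnames(states) <- model$state_names
    sens <- array(rep(as.vector(Z0), each = length(times)),
                  dim = c(length(times), M, k))
    return(list(times = times, states = states, sens = sens))
  }
  sol <- deSolve::ode(y = c(model$init(theta), as.vector(Z0)), times = tt,
                      func = aug, parms = theta, method = "lsoda",
                      rtol = rtol, atol = atol)
  sol <- unclass(sol)
  if (nrow(sol) < length(tt) || any(!is.finite(sol[, -1, drop = FALSE]))) {
    bad <- if (nrow(sol) < length(tt)) tt[nrow(sol) + 1L] else
      tt[which(apply(!is.finite(sol[, -1, drop = FALSE]), 1, any))[1]]
    stop(sprintf("sensitivity integration of model '%s' failed near t = %g",
                 model$name, bad))
  }
  rows <- match(times, tt)
  states <- matrix(sol[rows, 1L + seq_len(M)], nrow = length(times))
  if (!is.null(model$state_names)) colnames(states) <- model$state_names
  sens <- array(sol[rows, -(seq_len(M + 1L)), drop = FALSE],
                dim = c(length(times), M, k))
  list(times = times, states = states, sens = sens)
}
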