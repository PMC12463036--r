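#' Sum-of-squares loss of a model against a dataset
#'
#' The least-squares objective \eqn{\sum_{i=1}^N \|h(\varphi(t_i, \theta)) -
#' \hat h_i\|_2^2} with unit noise weight.
#'
#' @param model A `model_spec`.
#' @param dataset A dataset (see [generate_synthetic()], [read_dataset()]).
#' @param theta Parameter vector.
#' @return Non-negative scalar.
#' @export
sse_loss <- function(model, dataset, theta) {
  check_dataset_model(dataset, model)
  pred <- eval_observable(model, theta, dataset$times)
  sum((pred - dataset$observations)^2)
}

check_dataset_model <- function(dataset, model) {
  if (!inherits(dataset, "identifim_dataset"))
    stop("dataset must be an identifim_dataset")
  if (ncol(dataset$observations) != model$L)
    stop(sprintf("dataset has %d observable columns; model '%s' expects %d",
                 ncol(dataset$observations), model$name, model$L))
  invisible(TRUE)
}

# Residual vector in the package block order (time blocks of L observables)
# and its Jacobian from the sensitivity module.
fit_residuals <- function(model, dataset, theta)
  as.vector(t(eval_observable(model, theta, dataset$times))) -
    as.vector(t(dataset$observations))

#' Least-squares parameter estimation
#'
#' Minimizes [sse_loss()] with a trust-region Levenberg-Marquardt solver
#' (\code{minpack.lm::nls.lm}) using the analytic/forward-sensitivity
#' Jacobian from [sensitivity_matrix()]. Optional seeded multi-start
#' perturbs the initial guess multiplicatively (log-uniform in
#' \[2/3, 3/2\]) and keeps the best converged solution.
#'
#' @param model A `model_spec`.
#' @param dataset A dataset; must be non-empty.
#' @param theta0 Initial parameter vector.
#' @param bounds Optional list with `lower` and/or `upper` box bounds.
#' @param seed Integer seed controlling multi-start draws.
#' @param n_starts Number of starts (1 = just `theta0`).
#' @param max_iter Iteration cap per start.
#' @return An object of class `fit_result`: `theta_hat`, `loss`,
#'   `objective` (equals `loss` here), `n_iterations`, `converged`,
#'   `gradient_norm`, `regularized = FALSE`, `lambda = 0`.
#' @export
fit_least_squares <- function(model, dataset, theta0, bounds = NULL,
                              seed = 1L, n_starts = 1L, max_iter = 500L) {
  check_dataset_model(dataset, model)
  if (length(dataset$times) == 0L) stop("dataset is empty")
  theta0 <- check_theta(model, theta0)
  starts <- list(theta0)
  if (n_starts > 1L) {
    extra <- withr::with_seed(seed, lapply(seq_len(n_starts - 1L), function(j)
      theta0 * exp(stats::runif(length(theta0), log(2 / 3), log(3 / 2)))))
    starts <- c(starts, extra)
  }
  run_lm_fit(model, dataset, starts, bounds, max_iter,
             penalty = NULL)
}

#' Regularized (MAP) refit restricted to the non-identifiable subspace
#'
#' Minimizes the least-squares loss plus the penalty
#' \eqn{\lambda \|U_{null}^T \theta - U_{null}^T \theta^*\|_2^2}, which
#' pins the non-identifiable parameter combinations at their current values
#' while leaving identifiable directions free. The penalty corresponds to a
#' Gaussian prior of variance \eqn{\tau^2 = 1/(2\lambda)} on the null-space
#' coordinates, and is implemented as \eqn{\sqrt\lambda\,U_{null}^T(\theta -
#' \theta^*)} appended as extra residual rows so the same least-squares
#' machinery applies. The refit FIM is full rank by construction (see
#' [regularized_fim()]).
#'
#' @inheritParams fit_least_squares
#' @param theta_star Anchor parameter vector (the current estimate).
#' @param Unull k x (k - r) matrix with orthonormal columns spanning the
#'   non-identifiable subspace (from [eigendecompose_fim()]); may have zero
#'   columns, in which case the fit reduces to [fit_least_squares()].
#' @param lambda Positive penalty weight (default 1).
#' @param theta0 Starting point; defaults to `theta_star`.
#' @return A `fit_result` with `regularized = TRUE`, the `lambda` used,
#'   `Unull_used`, `loss` (data term only) and `objective` (loss + penalty).
#' @export
fit_regularized <- function(model, dataset, theta_star, Unull, lambda = 1,
                            theta0 = theta_star, bounds = NULL,
                            max_iter = 500L) {
  check_dataset_model(dataset, model)
  theta_star <- check_theta(model, theta_star)
  Unull <- as.matrix(Unull)
  if (nrow(Unull) != model$k)
    stop("Unull must have k rows")
  if (ncol(Unull) > 0) {
    G <- crossprod(Unull)
    if (max(abs(G - diag(ncol(Unull)))) > 1e-8)
      stop("Unull columns are not orthonormal within 1e-8")
    if (lambda <= 0) stop("lambda must be positive")
  }
  penalty <- if (ncol(Unull) > 0)
    list(Unull = Unull, lambda = lambda, theta_star = theta_star) else NULL
  res <- run_lm_fit(model, dataset, list(check_theta(model, theta0)),
                    bounds, max_iter, penalty = penalty)
  res$regularized <- ncol(Unull) > 0
  res$lambda <- if (ncol(Unull) > 0) lambda else 0
  res$Unull_used <- Unull
  res
}

run_lm_fit <- function(model, dataset, starts, bounds, max_iter, penalty) {
  k <- model$k
  lower <- rep(-Inf, k); upper <- rep(Inf, k)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower <- rep_len(bounds$lower, k)
    if (!is.null(bounds$upper)) upper <- rep_len(bounds$upper, k)
  }
  fn <- function(th) {
    r <- fit_residuals(model, dataset, th)
    if (!is.null(penalty))
      r <- c(r, sqrt(penalty$lambda) *
               drop(t(penalty$Unull) %*% (th - penalty$theta_star)))
    r
  }
  jac <- function(th) {
    J <- sensitivity_matrix(model, th, dataset$times, method = "auto")$values
    if (!is.null(penalty))
      J <- rbind(J, sqrt(penalty$lambda) * t(penalty$Unull))
    J
  }
  best <- NULL
  failures <- character(0)
  for (th0 in starts) {
    fitj <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = fn, jac = jac,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter)),
      error = function(e) e)
    if (inherits(fitj, "error")) {
      failures <- c(failures, conditionMessage(fitj))
      next
    }
    obj <- sum(fn(fitj$par)^2)
    if (is.null(best) || obj < best$objective) {
      grad <- drop(2 * t(jac(fitj$par)) %*% fn(fitj$par))
      best <- list(
        theta_hat = stats::setNames(fitj$par, model$param_names),
        loss = sse_loss(model, dataset, fitj$par),
        objective = obj,
        n_iterations = fitj$niter,
        converged = fitj$info %in% 1:4,
        gradient_norm = max(abs(grad)),
        message = fitj$message)
    }
  }
  if (is.null(best))
    stop("all optimization starts failed: ",
         paste(unique(failures), collapse = "; "))
  best$regularized <- FALSE
  best$lambda <- 0
  best$Unull_used <- NULL
  class(best) <- "fit_result"
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result>%s loss=%.6g, converged=%s (%d iterations)\n",
              if (x$regularized) sprintf(" regularized (lambda=%g)", x$lambda)
              else "", x$loss, x$converged, x$n_iterations))
  print(signif(x$theta_hat, 6))
  invisible(x)
}

#' FIM of the regularized objective
#'
#' Returns \eqn{\lambda U_{null} U_{null}^T + S^T S}. When `Unull` comes from
#' the eigendecomposition of \eqn{S^T S} itself, the result is
#' block-diagonal in that eigenbasis: its spectrum is the retained
#' eigenvalues together with \eqn{\lambda} repeated k - r times, hence full
#' rank for any positive \eqn{\lambda}.
#'
#' @param S A `sensitivity_matrix` or numeric matrix.
#' @param Unull k x (k - r) orthonormal-column matrix (may be empty).
#' @param lambda Non-negative penalty weight.
#' @return Symmetric PSD k x k matrix.
#' @export
regularized_fim <- function(S, Unull, lambda) {
  V <- if (inherits(S, "sensitivity_matrix")) S$values else as.matrix(S)
  Unull <- as.matrix(Unull)
  if (ncol(Unull) > 0 && nrow(Unull) != ncol(V))
    stop("Unull must have as many rows as S has columns")
  F <- fim(V)
  if (ncol(Unull) > 0 && lambda != 0)
    F <- F + lambda * tcrossprod(Unull)
  (F + t(F)) / 2
}
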