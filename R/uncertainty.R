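#' Parameter covariance restricted to the non-identifiable subspace
#'
#' Returns \eqn{\tau^2 U_{null} U_{null}^T}, the covariance of an isotropic
#' Gaussian perturbation of scale \eqn{\tau} confined to the non-identifiable
#' eigendirections. Its rank is k - r and its trace is
#' \eqn{(k - r)\,\tau^2}.
#'
#' @param Unull k x (k - r) matrix with orthonormal columns (may have zero
#'   columns, giving the zero matrix).
#' @param tau Positive perturbation scale.
#' @return Symmetric PSD k x k matrix.
#' @export
nullspace_covariance <- function(Unull, tau) {
  Unull <- as.matrix(Unull)
  if (tau <= 0) stop("tau must be positive")
  k <- nrow(Unull)
  if (ncol(Unull) == 0L) return(matrix(0, k, k))
  G <- crossprod(Unull)
  if (max(abs(G - diag(ncol(Unull)))) > 1e-8)
    stop("Unull columns are not orthonormal within 1e-8")
  tau^2 * tcrossprod(Unull)
}

#' Predictive variance of the observables under parameter uncertainty
#'
#' First-order propagation of a parameter covariance into observable space:
#' \eqn{Var(h_l(t)) = \nabla_\theta h_l\,C\,\nabla_\theta h_l^T} per
#' observable and evaluation time, with gradients from
#' [sensitivity_matrix()].
#'
#' @inheritParams sensitivity_matrix
#' @param cov Symmetric PSD k x k parameter covariance.
#' @return N x L matrix of non-negative variances.
#' @export
predictive_variance <- function(model, theta, cov, times, method = "auto") {
  cov <- as.matrix(cov)
  if (nrow(cov) != model$k || ncol(cov) != model$k)
    stop("cov must be k x k")
  S <- sensitivity_matrix(model, theta, times, method = method)
  v <- rowSums((S$values %*% cov) * S$values)
  v <- pmax(v, 0)   # clip round-off negatives
  matrix(v, nrow = length(times), ncol = model$L, byrow = TRUE,
         dimnames = list(NULL, model$obs_names))
}

#' Normal-theory confidence band from mean and variance
#'
#' \eqn{mean \pm z_{\alpha/2} \sqrt{variance}} with z the standard-normal
#' upper \eqn{\alpha/2} quantile.
#'
#' @param mean,variance Conformable numeric matrices.
#' @param alpha Coverage complement in (0, 1); 0.05 gives a 95% band.
#' @return List with `lower` and `upper` matrices.
#' @export
confidence_band <- function(mean, variance, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  hw <- z * sqrt(variance)
  list(lower = mean - hw, upper = mean + hw)
}

#' Analytic null-space uncertainty band
#'
#' Perturbs parameters only along the non-identifiable eigendirections
#' (\eqn{\hat\theta = \tilde\theta + U_{null}\,\epsilon},
#' \eqn{\epsilon \sim N(0, \tau^2 I)}) and propagates that covariance to a
#' pointwise confidence band on every observable. By construction the loss
#' is unaffected to first order, so for linear-in-parameter models the band
#' collapses to zero width at the data times.
#'
#' @inheritParams sensitivity_matrix
#' @param Unull Non-identifiable eigenvector block from
#'   [eigendecompose_fim()].
#' @param tau Null-space perturbation scale. Default
#'   `0.1 * max(1, norm(theta)) / sqrt(k)`.
#' @param times Evaluation grid; defaults to 200 uniform points over the
#'   model's time domain plus `data_times`.
#' @param data_times Optional data times merged into the default grid so the
#'   zero-width property is directly observable.
#' @param alpha Coverage complement, default 0.05.
#' @return An object of class `uncertainty_band`: `times`, `mean`,
#'   `variance`, `lower`, `upper`, `alpha`, `tau`, `method = "analytic"`.
#' @export
uncertainty_band <- function(model, theta, Unull,
                             tau = 0.1 * max(1, sqrt(sum(theta^2))) /
                               sqrt(model$k),
                             times = NULL, data_times = NULL, alpha = 0.05) {
  theta <- check_theta(model, theta)
  if (is.null(times))
    times <- sort(unique(c(
      seq(model$t_domain[1], model$t_domain[2], length.out = 200),
      data_times)))
  cov <- nullspace_covariance(Unull, tau)
  mean <- eval_observable(model, theta, times)
  variance <- predictive_variance(model, theta, cov, times)
  band <- confidence_band(mean, variance, alpha)
  structure(list(times = times, mean = mean, variance = variance,
                 lower = band$lower, upper = band$upper, alpha = alpha,
                 tau = tau, method = "analytic"),
            class = "uncertainty_band")
}

#' Monte-Carlo null-space uncertainty band
#'
#' Draws seeded Gaussian perturbations in the non-identifiable subspace,
#' evaluates the model at each perturbed parameter vector, and returns the
#' pointwise empirical \eqn{(\alpha/2, 1 - \alpha/2)} quantile band. Draws
#' whose model evaluation fails are dropped with a warning; more than 10%
#' failures is an error.
#'
#' @inheritParams uncertainty_band
#' @param n_samples Number of draws, at least 100.
#' @param seed Integer seed; bands are bitwise reproducible.
#' @return An `uncertainty_band` with `method = "monte_carlo"`.
#' @export
monte_carlo_band <- function(model, theta, Unull, tau, n_samples = 1000L,
                             seed = 1L, alpha = 0.05, times = NULL,
                             data_times = NULL) {
  theta <- check_theta(model, theta)
  if (n_samples < 100L) stop("n_samples must be at least 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (tau < 0) stop("tau must be non-negative")
  Unull <- as.matrix(Unull)
  if (is.null(times))
    times <- sort(unique(c(
      seq(model$t_domain[1], model$t_domain[2], length.out = 200),
      data_times)))
  mean <- eval_observable(model, theta, times)
  p <- ncol(Unull)
  if (p == 0L || tau == 0) {
    return(structure(list(times = times, mean = mean,
                          variance = matrix(0, nrow(mean), ncol(mean)),
                          lower = mean, upper = mean, alpha = alpha,
                          tau = tau, method = "monte_carlo"),
                     class = "uncertainty_band"))
  }
  eps <- withr::with_seed(seed,
    matrix(stats::rnorm(p * n_samples, sd = tau), nrow = p))
  draws <- vector("list", n_samples)
  n_fail <- 0L
  for (j in seq_len(n_samples)) {
    th <- theta + drop(Unull %*% eps[, j])
    draws[[j]] <- tryCatch(eval_observable(model, th, times),
                           error = function(e) NULL)
    if (is.null(draws[[j]])) n_fail <- n_fail + 1L
  }
  if (n_fail > 0.1 * n_samples)
    stop(sprintf("monte_carlo_band: %d of %d draws failed", n_fail,
                 n_samples))
  if (n_fail > 0L)
    warning(sprintf("monte_carlo_band: dropped %d failed draws", n_fail))
  draws <- draws[!vapply(draws, is.null, logical(1))]
  arr <- simplify2array(draws)           # N x L x n_ok
  lower <- apply(arr, c(1, 2), stats::quantile, probs = alpha / 2)
  upper <- apply(arr, c(1, 2), stats::quantile, probs = 1 - alpha / 2)
  variance <- apply(arr, c(1, 2), stats::var)
  structure(list(times = times, mean = mean, variance = variance,
                 lower = lower, upper = upper, alpha = alpha, tau = tau,
                 method = "monte_carlo"),
            class = "uncertainty_band")
}

#' @export
print.uncertainty_band <- function(x, ...) {
  cat(sprintf(
    "<uncertainty_band> %s, %d times, alpha=%g, tau=%g, max width=%.4g\n",
    x$method, length(x$times), x$alpha, x$tau, max(x$upper - x$lower)))
  invisible(x)
}

#' Write an uncertainty band as CSV for plotting
#'
#' One row per evaluation time; per observable, columns `<name>_mean`,
#' `<name>_lower`, `<name>_upper`.
#'
#' @param band An `uncertainty_band`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band <- function(band, path) {
  nm <- colnames(band$mean) %||% paste0("obs", seq_len(ncol(band$mean)))
  df <- data.frame(time = band$times)
  for (l in seq_along(nm)) {
    df[[paste0(nm[l], "_mean")]] <- band$mean[, l]
    df[[paste0(nm[l], "_lower")]] <- band$lower[, l]
    df[[paste0(nm[l], "_upper")]] <- band$upper[, l]
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
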