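#' Fisher Information Matrix from a sensitivity matrix
#'
#' Computes \eqn{F(\theta^*) = s(\theta^*)^T s(\theta^*)}, symmetrized as
#' `(F + t(F)) / 2` to kill round-off asymmetry. As a Gram matrix it is
#' positive semidefinite; its null space spans the non-identifiable
#' parameter combinations.
#'
#' @param S A `sensitivity_matrix` or a plain numeric matrix.
#' @return A k x k symmetric matrix.
#' @export
fim <- function(S) {
  V <- if (inherits(S, "sensitivity_matrix")) S$values else as.matrix(S)
  if (any(!is.finite(V))) stop("sensitivity matrix contains non-finite values")
  F <- crossprod(V)
  (F + t(F)) / 2
}

#' Thresholded eigendecomposition of the FIM
#'
#' Performs the full eigendecomposition \eqn{F = U \Sigma U^T}, sorts
#' eigenvalues non-increasing, clips small negative round-off to zero, and
#' splits the eigenvector basis at the threshold `eps_eig`: the first r
#' columns `Ur` (eigenvalue > eps_eig) span the practically identifiable
#' parameter combinations \eqn{U_r^T \theta}, the remaining k - r columns
#' `Unull` span the non-identifiable ones. Eigenvector signs are fixed by
#' making each vector's largest-magnitude component positive (ties broken by
#' lowest index) so heatmaps are reproducible.
#'
#' @param F Symmetric k x k matrix (checked within 1e-8 relative).
#' @param eps_eig Non-negative eigenvalue threshold. The packaged configs
#'   mirror context-dependent choices: 1e-4 for the polynomial and Hill
#'   fixtures, 1e-6 for the ODE zoo.
#' @param param_names Optional parameter names for reporting.
#' @return An object of class `fim_analysis`: `F`, `eigenvalues`,
#'   `eigenvectors` (U), `eps_eig`, `r`, `Ur`, `Unull`, `param_names`,
#'   `near_degenerate` (flags for eigenvalue gaps below 1e-8 relative).
#' @export
eigendecompose_fim <- function(F, eps_eig = 1e-6, param_names = NULL) {
  F <- as.matrix(F)
  if (eps_eig < 0) stop("eps_eig must be non-negative")
  scale <- max(abs(F), 1e-300)
  if (max(abs(F - t(F))) > 1e-8 * scale)
    stop("F is not symmetric within tolerance")
  F <- (F + t(F)) / 2
  e <- eigen(F, symmetric = TRUE)
  ev <- pmax(e$values, 0)            # already non-increasing from eigen()
  U <- e$vectors
  for (j in seq_len(ncol(U))) {
    piv <- which.max(abs(U[, j]))
    if (U[piv, j] < 0) U[, j] <- -U[, j]
  }
  k <- length(ev)
  r <- sum(ev > eps_eig)
  gaps <- if (k > 1) abs(diff(ev)) <= 1e-8 * max(ev, 1e-300) else logical(0)
  if (!is.null(param_names)) rownames(U) <- param_names
  structure(list(
    F = F, eigenvalues = ev, eigenvectors = U, eps_eig = eps_eig, r = r,
    Ur = U[, seq_len(r), drop = FALSE],
    Unull = U[, r + seq_len(k - r), drop = FALSE],
    param_names = param_names, near_degenerate = gaps
  ), class = "fim_analysis")
}

#' @export
print.fim_analysis <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("<fim_analysis> k=%d, r=%d identifiable directions (eps_eig=%g)\n",
              k, x$r, x$eps_eig))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

# Minimum-norm least-squares solve via SVD with relative rank cutoff.
pinv_solve <- function(A, b, tol_rank = 1e-10) {
  if (ncol(A) == 0L) return(numeric(0))
  sv <- svd(A)
  keep <- sv$d > tol_rank * max(sv$d, 1e-300)
  if (!any(keep)) return(rep(0, ncol(A)))
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

#' Per-coordinate identifiability metric
#'
#' For each parameter i, projects its sensitivity column \eqn{s_i} onto the
#' range of the remaining columns A (the pseudoinverse projection
#' \eqn{A A^\dagger s_i}) and reports the infinity norm of the residual
#' \eqn{\|(I - A A^\dagger) s_i\|_\infty}. A parameter is coordinate
#' non-identifiable exactly when its column lies in the span of the others,
#' i.e. when the metric is zero; lower values indicate weaker
#' identifiability. A is formed by deleting column i, which has the same
#' range as the column-permutation construction it abbreviates.
#'
#' @param S A `sensitivity_matrix` or numeric matrix with k >= 2 columns.
#' @param tol_rank Relative singular-value cutoff for the pseudoinverse.
#' @param tol_coord Threshold below which a parameter is flagged
#'   non-identifiable; defaults to `1e-8 * max(column norms of S)`.
#' @return An object of class `coordinate_report`: `metric` (length-k,
#'   non-negative), `flags` (TRUE = identifiable), `tol_coord`,
#'   `param_names`.
#' @export
coordinate_metric <- function(S, tol_rank = 1e-10, tol_coord = NULL) {
  V <- if (inherits(S, "sensitivity_matrix")) S$values else as.matrix(S)
  pn <- if (inherits(S, "sensitivity_matrix")) S$param_names else colnames(V)
  k <- ncol(V)
  if (k < 2L) stop("coordinate_metric requires at least 2 parameters")
  if (any(!is.finite(V))) stop("sensitivity matrix contains non-finite values")
  metric <- numeric(k)
  for (i in seq_len(k)) {
    A <- V[, -i, drop = FALSE]
    xhat <- pinv_solve(A, V[, i], tol_rank = tol_rank)
    metric[i] <- max(abs(V[, i] - A %*% xhat))
  }
  if (is.null(tol_coord))
    tol_coord <- 1e-8 * max(sqrt(colSums(V^2)), 1e-300)
  names(metric) <- pn
  structure(list(metric = metric, flags = metric > tol_coord,
                 tol_coord = tol_coord, param_names = pn),
            class = "coordinate_report")
}

#' @export
print.coordinate_report <- function(x, ...) {
  cat("<coordinate_report>\n")
  df <- data.frame(parameter = x$param_names %||% seq_along(x$metric),
                   metric = signif(x$metric, 5),
                   identifiable = x$flags)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Profile likelihood of one parameter
#'
#' Traces the least-squares loss minimized over all parameters except
#' coordinate i, as that coordinate varies over a grid around its estimate.
#' A locally unique minimum signals coordinate identifiability; a flat
#' profile signals non-identifiability. Each grid solve is warm-started from
#' the previous grid point's optimum. With `Unull` and `lambda` supplied the
#' profiled objective is the regularized one (loss plus
#' \eqn{\lambda \|U_{null}^T(\theta - \theta^*)\|_2^2}).
#'
#' @param model A `model_spec`.
#' @param dataset A dataset from [generate_synthetic()] or [read_dataset()].
#' @param theta_star Parameter vector around which to profile (ideally a
#'   fitted optimum; not enforced).
#' @param i Parameter index to profile.
#' @param half_width_fraction Half-width of the grid as a fraction of
#'   `theta_star[i]` (default 0.5, i.e. +/- 50%).
#' @param n_points Number of grid points (default 21).
#' @param tol_flat Relative flatness tolerance: the profile is classified
#'   `"flat"` when `max(pl) - min(pl) <= tol_flat * (1 + min(pl))`.
#' @param Unull,lambda Optional regularization (orthonormal-column matrix
#'   and penalty weight) applied around `theta_star`.
#' @param bounds Optional list with `lower`/`upper` vectors for the free
#'   parameters.
#' @return An object of class `profile_curve`: `param_index`, `grid`,
#'   `pl_values`, `converged`, `classification` (`"identifiable"` or
#'   `"flat"`).
#' @export
profile_likelihood <- function(model, dataset, theta_star, i,
                               half_width_fraction = 0.5, n_points = 21,
                               tol_flat = 1e-6, Unull = NULL, lambda = 0,
                               bounds = NULL) {
  theta_star <- check_theta(model, theta_star)
  k <- model$k
  if (i < 1L || i > k) stop("parameter index out of range")
  hw <- half_width_fraction * max(abs(theta_star[i]), 1)
  grid <- seq(theta_star[i] - hw, theta_star[i] + hw, length.out = n_points)

  free <- setdiff(seq_len(k), i)
  lower <- rep(-Inf, k); upper <- rep(Inf, k)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower <- rep_len(bounds$lower, k)
    if (!is.null(bounds$upper)) upper <- rep_len(bounds$upper, k)
  }
  obs_vec <- as.vector(t(dataset$observations))

  resid_fun <- function(th_free, val) {
    th <- theta_star; th[i] <- val; th[free] <- th_free
    pred <- as.vector(t(eval_observable(model, th, dataset$times)))
    r <- pred - obs_vec
    if (!is.null(Unull) && ncol(Unull) > 0 && lambda > 0)
      r <- c(r, sqrt(lambda) * drop(t(Unull) %*% (th - theta_star)))
    r
  }

  pl <- rep(NA_real_, n_points)
  converged <- logical(n_points)
  # profile outward from the grid point nearest theta_star[i] so warm starts
  # stay in the right basin
  start_idx <- which.min(abs(grid - theta_star[i]))
  order_idx <- order(abs(seq_len(n_points) - start_idx),
                     seq_len(n_points))
  warm <- list()
  for (j in order_idx) {
    prev <- if (j == start_idx) theta_star[free] else {
      nb <- if (j > start_idx) j - 1L else j + 1L
      warm[[as.character(nb)]] %||% theta_star[free]
    }
    if (length(free) == 0L) {
      pl[j] <- sum(resid_fun(numeric(0), grid[j])^2)
      converged[j] <- TRUE
      next
    }
    fitj <- tryCatch(
      minpack.lm::nls.lm(par = prev, fn = resid_fun, val = grid[j],
                         lower = lower[free], upper = upper[free],
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fitj)) {
      converged[j] <- FALSE
      warm[[as.character(j)]] <- prev
    } else {
      pl[j] <- sum(resid_fun(fitj$par, grid[j])^2)
      converged[j] <- fitj$info %in% 1:4
      warm[[as.character(j)]] <- fitj$par
    }
  }
  if (mean(!converged) > 0.5)
    stop("profile likelihood: more than half of the grid solves failed")

  ok <- is.finite(pl)
  rng <- max(pl[ok]) - min(pl[ok])
  flat <- rng <= tol_flat * (1 + min(pl[ok]))
  structure(list(param_index = i,
                 param_name = model$param_names[i],
                 grid = grid, pl_values = pl, converged = converged,
                 tol_flat = tol_flat,
                 classification = if (flat) "flat" else "identifiable"),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve> parameter %s: %s (range %.3g)\n",
              x$param_name %||% x$param_index, x$classification,
              max(x$pl_values, na.rm = TRUE) - min(x$pl_values, na.rm = TRUE)))
  invisible(x)
}

#' Contribution index of a dataset
#'
#' The ratio \eqn{\xi = \sigma_{min} / \sigma_{max}} of the smallest to
#' largest FIM eigenvalue (clipped at zero), a scalar in \[0, 1\] summarizing
#' how thoroughly a dataset pins down all parameter directions. Returns 0
#' for a singular FIM.
#'
#' @param F Symmetric PSD k x k matrix.
#' @return A number in \[0, 1\].
#' @export
contribution_index <- function(F) {
  ev <- pmax(eigen(as.matrix(F), symmetric = TRUE, only.values = TRUE)$values, 0)
  smax <- max(ev); smin <- min(ev)
  if (smax == 0 || smin < 1e-300) return(0)
  smin / smax
}

#' Structural-identifiability rank test
#'
#' Builds the sensitivity matrix on a dense uniform time grid over the
#' model's domain and reports its numerical column rank (singular values
#' above `1e-10` of the largest). Full column rank on a sufficiently rich
#' grid indicates structural identifiability: structural analysis is the
#' limiting case of practical analysis as the dataset grows dense.
#'
#' @inheritParams sensitivity_matrix
#' @param n_grid Number of uniform grid points; `n_grid * L` must be >= k.
#' @return A list with `rank`, `full_rank`, `singular_values`, `n_grid`.
#' @export
structural_rank_test <- function(model, theta = model$theta, n_grid = 50,
                                 method = "auto") {
  theta <- check_theta(model, theta)
  if (n_grid * model$L < model$k)
    stop("n_grid * L must be at least k for a rank test")
  grid <- seq(model$t_domain[1], model$t_domain[2], length.out = n_grid)
  S <- sensitivity_matrix(model, theta, grid, method = method)
  d <- svd(S$values, nu = 0, nv = 0)$d
  rank <- sum(d > 1e-10 * max(d, 1e-300))
  list(rank = rank, full_rank = rank == model$k, singular_values = d,
       n_grid = n_grid)
}
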