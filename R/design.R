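#' Information score of a candidate measurement time
#'
#' Computes the L x k sensitivity block \eqn{\tilde S(t)} at a candidate
#' time and returns \eqn{d(t) = \mathrm{diag}(U_{null}^T \tilde S^T \tilde S
#' U_{null})}: the squared norms of \eqn{\tilde S u} over the current
#' non-identifiable directions u. An entry above tolerance means the
#' candidate injects information into that direction.
#'
#' @inheritParams sensitivity_matrix
#' @param t Single candidate time.
#' @param Unull Current non-identifiable eigenvector block; must have at
#'   least one column.
#' @return Non-negative numeric vector of length k - r.
#' @export
candidate_score <- function(model, theta, t, Unull, method = "auto") {
  Unull <- as.matrix(Unull)
  if (ncol(Unull) == 0L)
    stop("candidate_score: no non-identifiable directions to score")
  B <- sensitivity_matrix(model, theta, t, method = method)$values
  colSums((B %*% Unull)^2)
}

#' Greedy optimal selection of measurement times
#'
#' Iteratively augments a measurement-time set until the FIM built from it
#' attains full numerical rank (all k eigenvalues above `eps_eig`). At each
#' iteration every grid candidate not yet selected is scored by
#' [candidate_score()] against the current non-identifiable directions; the
#' winner is the candidate activating the most directions (entries of d(t)
#' above `tol_design`), ties broken by the largest total score, then by the
#' smallest time. Candidate search is a deterministic grid search, so
#' permuting the candidate grid cannot change the selected set.
#'
#' @inheritParams sensitivity_matrix
#' @param initial_times Starting time set (size q >= 1); if `NULL`, one
#'   point is drawn from the grid with `seed`.
#' @param candidate_grid Candidate times within the model's domain; default
#'   201 uniform points over `t_domain`.
#' @param eps_eig Eigenvalue threshold defining numerical rank.
#' @param M_max Cap on the total number of selected times.
#' @param seed Seed for the random initial point when `initial_times` is
#'   `NULL`.
#' @param tol_design Score tolerance for "nonzero" contributions; default
#'   `1e-10 * (1 + largest current eigenvalue)`, recomputed per iteration.
#' @return An object of class `design_result`: final `times`, `added_times`,
#'   per-iteration records (`iterations`: candidate chosen, score vector,
#'   rank before/after, spectrum), `success`, `eps_eig`, `m`, `q`, `M_max`,
#'   `final_eigenvalues`.
#' @export
optimal_design <- function(model, theta = model$theta, initial_times = NULL,
                           candidate_grid = NULL, eps_eig = 1e-6,
                           M_max = 50L, seed = 1L, tol_design = NULL,
                           method = "auto") {
  theta <- check_theta(model, theta)
  if (is.null(candidate_grid))
    candidate_grid <- seq(model$t_domain[1], model$t_domain[2],
                          length.out = 201)
  candidate_grid <- sort(unique(check_times(model, candidate_grid)))
  if (is.null(initial_times)) {
    initial_times <- withr::with_seed(seed,
      sample(candidate_grid, 1L))
  }
  initial_times <- sort(check_times(model, initial_times))
  q <- length(initial_times)
  k <- model$k

  # one sensitivity pass over everything; blocks are theta-fixed
  all_times <- sort(unique(c(initial_times, candidate_grid)))
  Sall <- sensitivity_matrix(model, theta, all_times, method = method)
  L <- Sall$L
  block_of <- function(t) {
    n <- match(t, all_times)
    Sall$values[(n - 1L) * L + seq_len(L), , drop = FALSE]
  }

  in_set <- function(t, set) any(abs(set - t) < 1e-12)
  Tset <- initial_times
  F <- Reduce(`+`, lapply(Tset, function(t) crossprod(block_of(t))),
              accumulate = FALSE)
  F <- (F + t(F)) / 2
  iterations <- list()
  m <- q
  repeat {
    ed <- eigendecompose_fim(F, eps_eig = eps_eig,
                             param_names = model$param_names)
    r <- ed$r
    if (r == k) {
      success <- TRUE
      break
    }
    if (m >= M_max) {
      success <- FALSE
      break
    }
    tol <- tol_design %||% (1e-10 * (1 + max(ed$eigenvalues)))
    pool <- candidate_grid[!vapply(candidate_grid, in_set, logical(1),
                                   set = Tset)]
    if (length(pool) == 0L) {
      success <- FALSE
      break
    }
    scores <- lapply(pool, function(t)
      colSums((block_of(t) %*% ed$Unull)^2))
    counts <- vapply(scores, function(d) sum(d > tol), integer(1))
    sums <- vapply(scores, sum, numeric(1))
    if (max(counts) == 0L) {
      success <- FALSE
      attr(success, "diagnostic") <-
        "no candidate contributes to any null direction; the model may be structurally non-identifiable on this grid"
      break
    }
    best <- which(counts == max(counts))
    best <- best[sums[best] == max(sums[best])]
    best <- best[which.min(pool[best])]
    t_new <- pool[best]
    F_new <- F + crossprod(block_of(t_new))
    F_new <- (F_new + t(F_new)) / 2
    ed_new <- eigendecompose_fim(F_new, eps_eig = eps_eig)
    iterations[[length(iterations) + 1L]] <- list(
      chosen = t_new, score = scores[[best]], rank_before = r,
      rank_after = ed_new$r, spectrum = ed_new$eigenvalues)
    Tset <- sort(c(Tset, t_new))
    F <- F_new
    m <- m + 1L
  }
  structure(list(
    times = Tset, added_times = setdiff(Tset, initial_times),
    iterations = iterations,
    success = as.logical(success),
    diagnostic = attr(success, "diagnostic"),
    eps_eig = eps_eig, m = m, q = q, M_max = M_max,
    final_eigenvalues = eigendecompose_fim(F, eps_eig)$eigenvalues
  ), class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf(
    "<design_result> %s: %d initial + %d added times (eps_eig=%g)\n",
    if (x$success) "full rank reached" else "did not reach full rank",
    x$q, length(x$added_times), x$eps_eig))
  if (length(x$added_times))
    cat("  added:", paste(signif(x$added_times, 6), collapse = ", "), "\n")
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}
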