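#' Construct a time-series dataset
#'
#' @param times Length-N numeric vector, sorted non-decreasing.
#' @param observations N x L numeric matrix (or length-N vector for L = 1).
#' @param observable_names Optional length-L character vector.
#' @param meta Optional provenance list (model, theta, sigma, seed for
#'   synthetic data).
#' @return An object of class `identifim_dataset`.
#' @export
new_dataset <- function(times, observations, observable_names = NULL,
                        meta = list()) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("a dataset needs at least one time point")
  obs <- as.matrix(observations)
  if (!is.numeric(obs)) stop("observations must be numeric")
  if (nrow(obs) != length(times))
    stop("observations must have one row per time point")
  if (any(!is.finite(times)) || any(!is.finite(obs)))
    stop("dataset contains non-finite values")
  if (is.unsorted(times)) {
    warning("times were not sorted; reordering dataset")
    o <- order(times)
    times <- times[o]
    obs <- obs[o, , drop = FALSE]
  }
  if (is.null(observable_names))
    observable_names <- colnames(obs) %||% paste0("obs", seq_len(ncol(obs)))
  colnames(obs) <- observable_names
  structure(list(times = times, observations = obs,
                 observable_names = observable_names, meta = meta),
            class = "identifim_dataset")
}

#' @export
print.identifim_dataset <- function(x, ...) {
  cat(sprintf("<identifim_dataset> N=%d times, L=%d observables (%s)\n",
              length(x$times), ncol(x$observations),
              paste(x$observable_names, collapse = ", ")))
  if (!is.null(x$meta$model))
    cat(sprintf("  synthetic from model '%s' (sigma=%s, seed=%s)\n",
                x$meta$model, paste(x$meta$sigma, collapse = "/"),
                x$meta$seed %||% "NA"))
  invisible(x)
}

#' Generate synthetic observations with additive Gaussian noise
#'
#' Evaluates the model observables at the given times and adds independent
#' homoscedastic Gaussian noise per observable:
#' \eqn{\hat h_i = h(\varphi(t_i, \theta)) + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, \sigma^2)}. A per-observable `sigma` vector is
#' supported because observable scales can differ (e.g. prey vs predator
#' counts).
#'
#' @inheritParams solve_states
#' @param sigma Scalar or length-L vector of noise standard deviations
#'   (>= 0).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return An `identifim_dataset` whose `meta` records model name, theta,
#'   sigma and seed.
#' @export
generate_synthetic <- function(model, theta = model$theta,
                               times = model$protocol$times, sigma = 0,
                               seed = 1L) {
  theta <- check_theta(model, theta)
  clean <- eval_observable(model, theta, times)
  sigma <- rep_len(as.numeric(sigma), ncol(clean))
  if (any(sigma < 0)) stop("sigma must be non-negative")
  noise <- withr::with_seed(seed, matrix(
    stats::rnorm(length(clean), sd = rep(sigma, each = nrow(clean))),
    nrow = nrow(clean)))
  new_dataset(times, clean + noise,
              observable_names = model$obs_names,
              meta = list(model = model$name, theta = theta, sigma = sigma,
                          seed = seed))
}

#' Read a dataset from a delimited text file
#'
#' Expects a header row with a time column first, then L observable columns.
#' The delimiter is autodetected among comma, tab and semicolon; the decimal
#' mark is always the point (locale-independent). Times are sorted on read
#' with a warning if reordering occurred.
#'
#' @param path File path.
#' @return An `identifim_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty dataset file: ", path)
  seps <- c("," = ",", "\t" = "\t", ";" = ";")
  counts <- vapply(seps, function(s)
    length(strsplit(first, s, fixed = TRUE)[[1]]), integer(1))
  sep <- seps[[which.max(counts)]]
  header <- strsplit(first, sep, fixed = TRUE)[[1]]
  if (!any(is.na(suppressWarnings(as.numeric(header)))))
    stop("dataset file lacks a header row: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          check.names = FALSE)
  if (ncol(df) < 2L)
    stop("dataset file needs a time column plus at least one observable")
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("dataset file contains non-numeric cells")
  new_dataset(df[[1]], as.matrix(df[, -1, drop = FALSE]),
              observable_names = names(df)[-1],
              meta = list(path = path))
}

#' Write a dataset to a delimited text file
#'
#' @param dataset An `identifim_dataset`.
#' @param path Output path.
#' @param sep Delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, sep = ",") {
  if (!inherits(dataset, "identifim_dataset"))
    stop("dataset must be an identifim_dataset")
  df <- data.frame(time = dataset$times, dataset$observations,
                   check.names = FALSE)
  names(df) <- c("time", dataset$observable_names)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

as_report_entry <- function(x) {
  if (inherits(x, "fim_analysis")) {
    list(type = "fim_analysis",
         eigenvalues = as.numeric(x$eigenvalues),
         eigenvectors = unname(x$eigenvectors),
         r = x$r, eps_eig = x$eps_eig,
         contribution_index = contribution_index(x$F),
         param_names = x$param_names)
  } else if (inherits(x, "coordinate_report")) {
    list(type = "coordinate_report", metric = unname(x$metric),
         flags = unname(x$flags), tol_coord = x$tol_coord,
         param_names = x$param_names)
  } else if (inherits(x, "fit_result")) {
    list(type = "fit_result", theta_hat = unname(x$theta_hat),
         param_names = names(x$theta_hat), loss = x$loss,
         objective = x$objective, converged = x$converged,
         n_iterations = x$n_iterations, regularized = x$regularized,
         lambda = x$lambda,
         Unull_dim = if (is.null(x$Unull_used)) c(0L, 0L)
                     else dim(x$Unull_used))
  } else if (inherits(x, "design_result")) {
    list(type = "design_result", times = x$times,
         added_times = x$added_times, success = x$success,
         eps_eig = x$eps_eig, m = x$m, q = x$q, M_max = x$M_max,
         n_iterations = length(x$iterations),
         final_eigenvalues = x$final_eigenvalues)
  } else if (inherits(x, "profile_curve")) {
    list(type = "profile_curve", param_index = x$param_index,
         param_name = x$param_name, grid = x$grid,
         pl_values = x$pl_values, classification = x$classification)
  } else x
}

#' Write a structured JSON analysis report
#'
#' Serializes any mix of package analysis objects (FIM analyses, coordinate
#' reports, fit results, design results, profile curves) plus plain values
#' into a versioned JSON document.
#'
#' @param objects Named list of analysis objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(objects, path) {
  if (is.null(names(objects)) || any(names(objects) == ""))
    stop("write_report requires a fully named list")
  body <- c(list(schema_version = "1.0"),
            lapply(objects, as_report_entry))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a JSON analysis report
#' @param path Report path.
#' @return The parsed report list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
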