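#' Read and resolve a YAML run configuration
#'
#' A run config drives the command-line workflow. Recognized keys:
#' `model` (zoo name), `theta` (numeric vector; defaults to the zoo
#' default), `observables`, `times` (explicit list) or `t_grid`
#' (`{from, to, n_points}`), `noise_sigma` (scalar, vector, or `"auto"` for 5% of
#' each observable's range), `seed`, `eps_eig`, `lambda`, `tau`, `alpha`,
#' `dataset` (path to a CSV; overrides synthetic generation), `outdir`,
#' `M_neurons`, `activation`, and a `design` block
#' (`initial_times`, `grid: {from, to, n}`, `M_max`).
#'
#' @param path Path to a YAML file.
#' @return A list with the resolved config, the constructed `model` and the
#'   resolved `times`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  resolve_config(cfg, dir = dirname(path))
}

resolve_config <- function(cfg, dir = ".") {
  problems <- character(0)
  if (is.null(cfg$model)) problems <- c(problems, "missing key 'model'")
  if (length(problems)) stop(paste(problems, collapse = "; "))

  model <- zoo_model(cfg$model,
                     observables = unlist(cfg$observables) %||% NULL,
                     M_neurons = cfg$M_neurons %||% 5,
                     activation = cfg$activation %||% "tanh")
  theta <- as.numeric(unlist(cfg$theta) %||% model$theta)
  if (length(theta) != model$k)
    stop(sprintf("config theta has length %d; model '%s' expects %d",
                 length(theta), model$name, model$k))

  times <- if (!is.null(cfg$times)) as.numeric(unlist(cfg$times))
    else if (!is.null(cfg$t_grid))
      seq(cfg$t_grid$from, cfg$t_grid$to, length.out = cfg$t_grid$n_points)
    else model$protocol$times

  sigma <- cfg$noise_sigma %||% model$protocol$sigma %||% "auto"
  if (identical(sigma, "auto"))
    sigma <- default_sigma(model, theta, times)
  sigma <- as.numeric(unlist(sigma))

  list(model = model, theta = theta, times = times, sigma = sigma,
       seed = as.integer(cfg$seed %||% 1L),
       eps_eig = as.numeric(cfg$eps_eig %||% model$protocol$eps_eig %||%
                              1e-6),
       lambda = as.numeric(cfg$lambda %||% 1),
       tau = if (is.null(cfg$tau)) NULL else as.numeric(cfg$tau),
       alpha = as.numeric(cfg$alpha %||% 0.05),
       dataset = if (is.null(cfg$dataset)) NULL else
         file.path(dir, cfg$dataset),
       outdir = cfg$outdir %||% ".",
       design = cfg$design %||% list(),
       raw = cfg)
}

#' Path to a packaged example configuration
#'
#' @param name Config base name, e.g. `"polynomial"`, `"hill"`, `"lv"`,
#'   `"mm_case1"`, `"mm_case2"`, `"seir"`. With no argument, lists the
#'   available names.
#' @return A file path, or a character vector of names.
#' @export
packaged_config <- function(name = NULL) {
  dir <- system.file("extdata", "configs", package = "identifim")
  if (is.null(name))
    return(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
  p <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(p)) stop("no packaged config named '", name, "'")
  p
}
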