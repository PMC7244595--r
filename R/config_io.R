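#' Write an Anderson model (and optional grid) to a YAML config
#'
#' Numbers are serialized with 17 significant digits, so a
#' write-read-write cycle is bit-exact.
#'
#' @param model an `anderson_model`
#' @param path output file path
#' @param grid optional `tau_grid` stored alongside the model
#' @return `path`, invisibly
#' @export
write_model_config <- function(model, path, grid = NULL) {
  stopifnot(inherits(model, "anderson_model"))
  cfg <- list(
    model = list(U = model$U, J = model$J, mu = model$mu,
                 n_target = model$n_target),
    host = list(energies = model$host_energies,
                labels = model$host_labels),
    impurity = list(energies = model$impurity_energies,
                    labels = model$orbital_labels),
    hybridization = apply(model$hybridization, 1, as.numeric,
                          simplify = FALSE))
  if (!is.null(grid))
    cfg$grid <- list(beta = grid$beta, L = grid$L)
  # serialize numbers as %.17g strings: doubles round-trip exactly and
  # the YAML emitter's own precision cap never truncates them
  cfg <- rapply(cfg, function(x)
    if (is.double(x)) sprintf("%.17g", x) else x, how = "replace")
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' Read an Anderson model config written by [write_model_config()]
#'
#' @param path YAML config path
#' @return list with `model` (an `anderson_model`) and `grid` (a
#'   `tau_grid` or NULL)
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  n_host <- length(cfg$host$energies)
  n_orb <- length(cfg$impurity$energies)
  hyb <- if (n_host > 0)
    do.call(rbind, lapply(cfg$hybridization, as.numeric))
  else matrix(0, 0, n_orb)
  model <- anderson_model(
    host_energies = as.numeric(cfg$host$energies %||% numeric(0)),
    impurity_energies = as.numeric(cfg$impurity$energies),
    hybridization = hyb,
    U = as.numeric(cfg$model$U), J = as.numeric(cfg$model$J %||% 0),
    mu = as.numeric(cfg$model$mu %||% 0),
    n_target = if (!is.null(cfg$model$n_target))
      as.numeric(cfg$model$n_target),
    host_labels = cfg$host$labels,
    orbital_labels = cfg$impurity$labels)
  grid <- if (!is.null(cfg$grid))
    tau_grid(beta = as.numeric(cfg$grid$beta), L = as.integer(cfg$grid$L))
  list(model = model, grid = grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
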