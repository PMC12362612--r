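# Run configuration files (YAML/JSON) and plain-text result writers.

#' Read a run configuration (YAML or JSON)
#'
#' The schema has five optional blocks: \code{model} (a registry name, see
#' [build_model()]), \code{params} (keys matching [kinetic_params()]
#' fields), \code{controller} (keys matching [controller_config()]
#' arguments), \code{scan} (\code{parameter}, \code{grid}) and
#' \code{simulation} (\code{n}, \code{t_end}, \code{omega}, \code{seed}).
#' Unknown keys anywhere are an error.
#'
#' @param path file path; the extension selects the parser (.yaml/.yml or
#'   .json).
#' @return A validated list with class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config extension: .", ext, call. = FALSE))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  check_keys(cfg, c("model", "params", "controller", "scan", "simulation",
                    "output"), "config")
  if (!is.null(cfg$params))
    check_keys(cfg$params, names(formals(kinetic_params)), "params")
  if (!is.null(cfg$controller))
    check_keys(cfg$controller, names(formals(controller_config)),
               "controller")
  if (!is.null(cfg$scan))
    check_keys(cfg$scan, c("parameter", "grid", "vary"), "scan")
  if (!is.null(cfg$simulation))
    check_keys(cfg$simulation, c("n", "t_end", "omega", "seed", "x0"),
               "simulation")
  class(cfg) <- "run_config"
  cfg
}

#' Build a model spec from a registry name
#'
#' Registry: \code{toggle}, \code{controlled_toggle},
#' \code{toggle_selfactivation}, \code{toggle_selfactivation_double},
#' \code{mutual_activation}, \code{controlled_mutual_activation},
#' \code{controlled_tristable}. Controlled models take the controller
#' wiring from \code{config} (defaults: negative feedback for the toggle,
#' inhibition for mutual activation, double inhibition for the tristable
#' network).
#'
#' @param model registry name.
#' @param params a [kinetic_params()] object.
#' @param config optional [controller_config()] (or a list of two for the
#'   tristable network).
#' @return A [model_spec()].
#' @export
build_model <- function(model, params = kinetic_params(), config = NULL) {
  switch(model,
    toggle = make_toggle(params),
    controlled_toggle = make_controlled_toggle(
      params, if (is.null(config)) negative_feedback_config() else config),
    toggle_selfactivation = make_toggle_selfactivation(params),
    toggle_selfactivation_double =
      make_toggle_selfactivation(params, double = TRUE),
    mutual_activation = {
      p <- params; p$beta <- 0
      make_controlled_mutual_activation(p)
    },
    controlled_mutual_activation = {
      if (is.null(config)) make_controlled_mutual_activation(params)
      else make_controlled_mutual_activation(params, config)
    },
    controlled_tristable = {
      cfgs <- if (is.null(config)) tristable_inhibition_configs() else config
      make_controlled_tristable(params, cfgs$y1, cfgs$y2)
    },
    stop("unknown model: ", model, call. = FALSE))
}

config_to_params <- function(cfg) {
  do.call(kinetic_params, as.list(cfg$params %||% list()))
}

config_to_controller <- function(cfg) {
  if (is.null(cfg$controller)) NULL
  else do.call(controller_config, as.list(cfg$controller))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as CSV with a JSON metadata sidecar
#'
#' @param traj a trajectory from [simulate_ode()] or [simulate_ssa()].
#' @param path CSV output path; metadata (kind, omega, seed) goes to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(kind = traj$kind, omega = traj$omega, seed = traj$seed,
               n_points = length(traj$times), t_end = max(traj$times))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an equilibrium set as CSV plus a JSON summary of counts
#'
#' @param eqset an equilibrium set from [find_equilibria()].
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return The CSV data frame, invisibly.
#' @export
write_equilibria <- function(eqset, csv_path = NULL, json_path = NULL) {
  df <- do.call(rbind, lapply(eqset$equilibria, function(e) {
    out <- as.data.frame(t(e$location))
    names(out) <- eqset$species
    out$label <- e$label
    out
  }))
  if (is.null(df))
    df <- data.frame(matrix(numeric(0), 0, length(eqset$species),
                            dimnames = list(NULL, eqset$species)))
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    cnt <- count_equilibria(eqset)
    jsonlite::write_json(list(model = eqset$model,
                              counts = as.list(cnt),
                              n_equilibria = length(eqset$equilibria)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}

#' Serialize a fate distribution (JSON) and its per-run labels (CSV)
#'
#' @param fd a [fate_distribution()].
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @return \code{fd}, invisibly.
#' @export
write_fate <- function(fd, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n = fd$n, omega = fd$omega, t_end = fd$t_end,
      fractions = stats::setNames(as.list(fd$fractions),
                                  fd$fraction_labels),
      histogram = fd$histogram),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(data.frame(run = seq_along(fd$labels),
                                fate = fd$labels),
                     csv_path, row.names = FALSE)
  invisible(fd)
}
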