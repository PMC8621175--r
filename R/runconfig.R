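.runconfig_keys <- c("cell", "confinement", "fillers", "topology",
                     "interaction", "schedule", "ensemble", "scenario",
                     "descriptor", "seed", "output")

#' Read, validate and write structured run configurations
#'
#' Run configurations are YAML files with the sections `cell`,
#' `confinement`, `fillers`, `topology`, `interaction`, `schedule`,
#' `ensemble`, `scenario`, `descriptor`, `seed` and `output`.  Unknown keys
#' are rejected.  The parsed object carries constructed specification
#' objects ready for [run_mc()], [run_scenario()] and [cce_norms()], and
#' round-trips losslessly through [write_run_config()].
#'
#' @param path YAML file path.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
  structure(list(raw = raw,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)),
            class = "run_config")
}

#' @param config A `run_config` (or the raw list).
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  raw <- if (inherits(config, "run_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @param raw A raw configuration list.
#' @rdname read_run_config
#' @export
validate_run_config <- function(raw) {
  unknown <- setdiff(names(raw), .runconfig_keys)
  if (length(unknown)) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$interaction)) {
    ik <- setdiff(names(raw$interaction),
                  names(formals(interaction_spec)))
    if (length(ik)) stop("unknown interaction key(s): ", paste(ik, collapse = ", "))
  }
  if (!is.null(raw$schedule)) {
    sk <- setdiff(names(raw$schedule), names(formals(move_schedule)))
    if (length(sk)) stop("unknown schedule key(s): ", paste(sk, collapse = ", "))
  }
  if (!is.null(raw$ensemble)) {
    ek <- setdiff(names(raw$ensemble), names(formals(ensemble_spec)))
    if (length(ek)) stop("unknown ensemble key(s): ", paste(ek, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> sections:", paste(names(x$raw), collapse = ", "), "\n")
  invisible(x)
}

# ---- constructors from the raw list ---------------------------------

rc_confinement <- function(raw) {
  cf <- raw$confinement
  if (is.null(cf) || identical(cf$type, "none")) return(conf_none())
  switch(cf$type,
    walls = conf_walls(unlist(cf$dims)),
    cylinder = conf_cylinder(cf$axis %||% 3L, cf$ends %||% "open"),
    sphere = conf_sphere(),
    stop("unknown confinement type '", cf$type, "'"))
}

rc_cell <- function(raw) {
  if (is.null(raw$cell$lengths)) stop("run config needs cell: lengths")
  sim_cell(unlist(raw$cell$lengths), rc_confinement(raw))
}

rc_fillers <- function(raw) {
  lapply(raw$fillers, function(f) {
    if (f$kind == "sphere") filler_sphere(unlist(f$center), f$diameter)
    else filler_cylinder(f$axis, unlist(f$anchor), f$diameter)
  })
}

rc_interaction <- function(raw) {
  do.call(interaction_spec, raw$interaction %||% list())
}

rc_schedule <- function(raw) {
  sc <- raw$schedule %||% list()
  if (!is.null(sc$probs)) sc$probs <- unlist(sc$probs)
  do.call(move_schedule, sc)
}

rc_ensemble <- function(raw) {
  do.call(ensemble_spec, raw$ensemble %||% list())
}

rc_scenario <- function(raw) {
  sc <- raw$scenario %||% list()
  if (!is.null(raw$seed)) sc$seed <- as.integer(raw$seed)
  if (!is.null(sc$confinement)) {
    sc$confinement <- rc_confinement(list(confinement = sc$confinement))
  }
  do.call(scenario_spec, sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
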