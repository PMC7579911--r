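# Problem serialization: OCP definitions to/from a structured YAML or JSON
# config dialect, so users can define pathway models in plain text and the
# built-in benchmarks can be exported, modified and re-loaded.

problem_to_list <- function(problem) {
  hz <- problem$horizon
  list(
    name = problem$name,
    states = as.list(problem$states),
    controls = as.list(problem$controls),
    params = as.list(problem$params),
    rhs = as.list(stats::setNames(unname(problem$rhs_text), problem$states)),
    x0 = as.numeric(problem$x0),
    horizon = c(list(t0 = hz$t0, tf_mode = hz$tf_mode),
                if (hz$tf_mode == "fixed") list(tf = hz$tf)
                else list(tf_bounds = hz$tf_bounds)),
    objectives = lapply(problem$objectives, function(ob)
      Filter(Negate(is.null),
             list(mayer = ob$mayer_text, lagrange = ob$lagrange_text,
                  sense = ob$sense, name = ob$name))),
    path_constraints = lapply(problem$path_constraints, function(pc)
      list(expr = pc$expr_text, bound = pc$bound, dir = pc$dir,
           label = pc$label)),
    point_constraints = lapply(problem$point_constraints, function(pc)
      list(expr = pc$expr_text, time = pc$time, bound = pc$bound,
           rel = pc$rel, label = pc$label)),
    control_bounds = list(lower = problem$control_bounds$lower,
                          upper = problem$control_bounds$upper))
}

list_to_problem <- function(x) {
  ocp_problem(
    name = x$name %||% "ocp",
    states = unlist(x$states), controls = unlist(x$controls),
    params = unlist(x$params) %||% numeric(0),
    rhs = x$rhs,
    x0 = as.numeric(unlist(x$x0)),
    horizon = if (identical(x$horizon$tf_mode, "free"))
      time_horizon(t0 = x$horizon$t0,
                   tf_bounds = as.numeric(unlist(x$horizon$tf_bounds)))
    else time_horizon(t0 = x$horizon$t0, tf = x$horizon$tf),
    objectives = lapply(x$objectives, function(ob)
      objective_functional(mayer = ob$mayer, lagrange = ob$lagrange,
                           sense = ob$sense %||% "min", name = ob$name)),
    path_constraints = lapply(x$path_constraints, function(pc)
      path_constraint(pc$expr, bound = pc$bound, dir = pc$dir,
                      label = pc$label)),
    point_constraints = lapply(x$point_constraints, function(pc)
      point_constraint(pc$expr, time = pc$time, bound = pc$bound,
                       rel = pc$rel, label = pc$label)),
    control_bounds = list(lower = as.numeric(unlist(x$control_bounds$lower)),
                          upper = as.numeric(unlist(x$control_bounds$upper))))
}

#' Write an OCP definition to a config file
#'
#' @param problem an \code{ocp_problem}.
#' @param path output file; format by extension (.yaml/.yml or .json).
#' @export
write_ocp <- function(problem, path) {
  x <- problem_to_list(problem)
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(x, path, precision = 15L)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  else stop("unsupported config extension (use .yaml or .json): ", path)
  invisible(path)
}

#' Load an OCP definition from a config file
#'
#' @param path a .yaml/.yml or .json problem definition, with state/control
#'   names, rhs expression strings, numeric vectors and constraint blocks.
#' @return an \code{ocp_problem}.
#' @export
load_ocp <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else if (grepl("\\.json$", path))
         jsonlite::read_json(path, simplifyVector = FALSE)
       else stop("unsupported config extension (use .yaml or .json): ", path)
  list_to_problem(x)
}
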