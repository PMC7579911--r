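# Built-in benchmark problems.
#
# Three kinetic pathway case studies (a three-step linear pathway, the
# central carbon metabolism of S. cerevisiae during diauxic shift, and the
# central carbon metabolism of B. subtilis under substrate shifts) plus two
# analytic fixtures used to validate the solvers.

#' Three-step linear pathway (minimum transition time vs intermediate burden)
#'
#' A substrate S1 (held constant: its stoichiometric row is zero, substrate
#' in abundance) is converted to a product S4 through intermediates S2, S3 by
#' three enzymatic steps with mass-action kinetics v_i = k_i * S_i * e_i. The
#' time-varying enzyme concentrations e1..e3 are the controls, limited by a
#' shared capacity e1+e2+e3 <= E_T. Objectives: minimize the transition time
#' tf (free) needed to reach the product target S4(tf) = product_target, and
#' minimize the accumulated intermediates integral( S2 + S3 ) dt.
#'
#' Control bounds default to [0, E_T] and the free final time is searched in
#' \code{tf_bounds}; neither is part of the published model and both are
#' documented package defaults.
#'
#' @param overrides named list overriding any of \code{E_T}, \code{k} (length
#'   3), \code{product_target}, \code{S1_0}, \code{tf_bounds}.
#' @return an \code{ocp_problem}.
#' @export
build_lpn3b <- function(overrides = list()) {
  p <- build_linear_pathway(n_steps = 3)
  if (length(overrides)) p <- apply_pathway_overrides(3, overrides)
  p$name <- "LPN3B"
  p
}

apply_pathway_overrides <- function(n_steps, ov) {
  args <- list(n_steps = n_steps)
  for (nm in names(ov)) args[[nm]] <- ov[[nm]]
  do.call(build_linear_pathway, args)
}

#' Generalized n-step linear activation pathway
#'
#' Scalability fixture generalizing the three-step pathway to n mass-action
#' steps; \code{build_linear_pathway(3)} is field-by-field identical to
#' \code{\link{build_lpn3b}}.
#'
#' @param n_steps number of enzymatic steps (>= 1).
#' @param k rate constants, recycled to length \code{n_steps}.
#' @param E_T total enzyme capacity.
#' @param product_target required final product concentration.
#' @param S1_0 substrate concentration (constant over time).
#' @param tf_bounds search interval for the free final time.
#' @return an \code{ocp_problem}.
#' @export
build_linear_pathway <- function(n_steps = 3, k = 1, E_T = 1,
                                 product_target = 0.9, S1_0 = 1,
                                 tf_bounds = c(0.5, 10)) {
  stopifnot(n_steps >= 1)
  k <- rep_len(k, n_steps)
  states <- paste0("S", seq_len(n_steps + 1))
  controls <- paste0("e", seq_len(n_steps))
  params <- stats::setNames(k, paste0("k", seq_len(n_steps)))
  # v_i = k_i * S_i * e_i ; S1 constant, dS_{i+1} = v_i - v_{i+1}
  v <- sprintf("k%d * S%d * e%d", seq_len(n_steps), seq_len(n_steps),
               seq_len(n_steps))
  rhs <- c("0", vapply(seq_len(n_steps), function(i)
    if (i < n_steps) paste0(v[i], " - ", v[i + 1]) else v[i], ""))
  names(rhs) <- states
  intermediates <- states[-c(1L, n_steps + 1L)]
  j2_integrand <- if (length(intermediates))
    paste(intermediates, collapse = " + ") else "0"
  ocp_problem(
    name = if (n_steps == 3) "LPN3B" else sprintf("linear_pathway_%d", n_steps),
    states = states, controls = controls,
    rhs = as.list(rhs),
    x0 = c(S1_0, rep(0, n_steps)),
    params = params,
    horizon = time_horizon(t0 = 0, tf_bounds = tf_bounds),
    objectives = list(
      objective_functional(mayer = "tf", sense = "min", name = "transition_time"),
      objective_functional(lagrange = j2_integrand, sense = "min",
                           name = "intermediate_accumulation")),
    path_constraints = list(
      path_constraint(paste(controls, collapse = " + "), bound = E_T,
                      dir = "<=", label = "enzyme_capacity")),
    point_constraints = list(
      point_constraint(states[n_steps + 1], time = "tf",
                       bound = product_target, rel = "==",
                       label = "product_target")),
    control_bounds = list(lower = 0, upper = E_T))
}

#' Yeast central carbon metabolism during diauxic shift
#'
#' Mass-action kinetic model of S. cerevisiae central carbon metabolism
#' (glucose, triose phosphates, pyruvate, ethanol as X1..X4, plus
#' NADH/ATP/NAD/ADP) during glucose depletion. The cell reroutes flux from
#' glycolysis to aerobic ethanol utilization through six time-varying enzyme
#' concentrations e1..e6 (controls). Objectives: maximize the survival time
#' tf and maximize -integral(sum e_i) dt (i.e. minimize protein investment).
#' Survival requires NADH >= NADH_c and ATP >= ATP_c as path constraints, and
#' the enzyme pool is limited by e1+...+e6 <= E_T with E_T = 11.5. Reactions
#' u7 = 3*ATP and u8 = 0.1*NADH are uncontrolled drains.
#'
#' The critical values default to \code{atp_c = 0.3}, \code{nadh_c = 0.1}.
#' These are PLACEHOLDER inputs: the published model states the constraints
#' but the critical values are not printed with it, so any result depending
#' on them is conditional on these inputs.
#'
#' @param atp_c critical ATP concentration (placeholder default 0.3).
#' @param nadh_c critical NADH concentration (placeholder default 0.1).
#' @param E_T total enzyme capacity (11.5).
#' @param overrides named list overriding \code{x0} or \code{tf_bounds}.
#' @return an \code{ocp_problem}.
#' @export
build_sc <- function(atp_c = 0.3, nadh_c = 0.1, E_T = 11.5,
                     overrides = list()) {
  stopifnot(atp_c > 0, nadh_c > 0)
  states <- c("X1", "X2", "X3", "X4", "NADH", "ATP", "NAD", "ADP")
  controls <- paste0("e", 1:6)
  # stoichiometric matrix, rows = states, columns = reactions u1..u8
  N <- matrix(c(
    -1,  0,  0,  0,  0,  0,  0,  0,
     2, -1,  0,  0,  0,  0,  0,  0,
     0,  1, -1,  1, -1,  0,  0,  0,
     0,  0,  1, -1,  0,  0,  0,  0,
     0,  1, -1,  1,  4, -1,  0, -1,
    -2,  2,  0,  0,  0,  3, -1,  0,
     0, -1,  1, -1, -4,  1,  0,  1,
     2, -2,  0,  0,  0, -3,  1,  0), nrow = 8, byrow = TRUE)
  u <- c("e1 * X1 * ATP",
         "e2 * X2 * NAD * ADP",
         "e3 * X3 * NADH",
         "e4 * X4 * NAD",
         "e5 * X3 * NAD",
         "e6 * NADH * ADP",
         "3 * ATP",
         "0.1 * NADH")
  rhs <- stoich_rhs(N, u)
  names(rhs) <- states
  x0 <- c(1, 1, 1, 10, 0.7, 0.8, 0.3, 0.2)
  tf_bounds <- c(0.2, 8)
  if (!is.null(overrides$x0)) x0 <- overrides$x0
  if (!is.null(overrides$tf_bounds)) tf_bounds <- overrides$tf_bounds
  ocp_problem(
    name = "SC", states = states, controls = controls,
    rhs = as.list(rhs), x0 = x0,
    horizon = time_horizon(t0 = 0, tf_bounds = tf_bounds),
    objectives = list(
      objective_functional(mayer = "tf", sense = "max", name = "survival_time"),
      objective_functional(
        lagrange = paste0("-(", paste(controls, collapse = " + "), ")"),
        sense = "max", name = "negative_protein_investment")),
    path_constraints = list(
      path_constraint(paste(controls, collapse = " + "), bound = E_T,
                      dir = "<=", label = "enzyme_capacity"),
      path_constraint("NADH", bound = nadh_c, dir = ">=", label = "NADH_critical"),
      path_constraint("ATP", bound = atp_c, dir = ">=", label = "ATP_critical")),
    control_bounds = list(lower = 0, upper = E_T))
}

# rhs strings from a stoichiometric matrix and kinetic rate strings.
stoich_rhs <- function(N, u) {
  apply(N, 1, function(row) {
    terms <- character(0)
    for (j in seq_along(u)) {
      if (row[j] == 0) next
      coef <- if (abs(row[j]) == 1) "" else paste0(abs(row[j]), " * ")
      term <- paste0(coef, "(", u[j], ")")
      terms <- c(terms, if (row[j] > 0) paste0(" + ", term)
                 else paste0(" - ", term))
    }
    if (!length(terms)) return("0")
    out <- paste(terms, collapse = "")
    sub("^ \\+ ", "", sub("^ - ", "-", out))
  })
}

#' B. subtilis central carbon metabolism under a substrate shift
#'
#' Simplified kinetic model with 22 states (FBP, PEP, PYR, CIT, MAL, ATP,
#' ADP, thirteen enzymes E1..E13, and the substrates glucose G and malate M).
#' Enzyme synthesis rates a1..a13 are the controls, bounded in
#' [0.0025, 0.125]; enzymes decay with rate constant beta = 0.25. Objectives
#' (both minimized as stated): -integral(ATP) dt (maximize overall ATP) and
#' integral(sum of enzymes) dt (minimize protein investment). Total enzyme
#' capacity: sum of E1..E13 <= 6.5. Two scenarios are supported: "G-M"
#' (growth on glucose, malate added: G = 12, M = 0 at the shift) and "M-G"
#' (the converse). The fixed horizon defaults to tf = 30 time units, a
#' PLACEHOLDER documented package default (not part of the published model).
#'
#' @param scenario "G-M" or "M-G".
#' @param tf fixed final time (placeholder default 30).
#' @param overrides named list overriding \code{E_T}, \code{beta} or
#'   \code{x0}.
#' @return an \code{ocp_problem}.
#' @export
build_bsub <- function(scenario = c("G-M", "M-G"), tf = 30,
                       overrides = list()) {
  if (!is.character(scenario) || !scenario[1] %in% c("G-M", "M-G"))
    stop("invalid scenario: must be 'G-M' or 'M-G'")
  scenario <- scenario[1]
  stopifnot(tf > 0)
  beta <- if (!is.null(overrides$beta)) overrides$beta else 0.25
  E_T <- if (!is.null(overrides$E_T)) overrides$E_T else 6.5
  states <- c("FBP", "PEP", "PYR", "CIT", "MAL", "ATP", "ADP",
              paste0("E", 1:13), "G", "M")
  # internal symbols X1..X22 in the kinetic expressions map onto the states
  X <- states
  controls <- paste0("a", 1:13)
  atp_net <- sprintf("-(%s * %s * %s * %s) + 2 * (%s * %s * %s) + %s * %s * %s + 5 * (%s * %s * %s) - %s * %s * %s - 8 * %s",
                     X[21], X[8], X[2], X[6],  X[10], X[1], X[7],
                     X[12], X[2], X[7],        X[17], X[4], X[7],
                     X[19], X[6], X[5],        X[6])
  rhs <- c(
    sprintf("%s * %s * %s * %s - %s * %s - %s * %s * %s + %s * %s",
            X[21], X[8], X[2], X[6], X[9], X[1], X[10], X[1], X[7], X[11], X[2]),
    sprintf("-(%s * %s * %s * %s) + 2 * (%s * %s * %s) - 2 * (%s * %s) - %s * %s * %s + %s * %s * %s",
            X[21], X[8], X[2], X[6], X[10], X[1], X[7], X[11], X[2],
            X[12], X[2], X[7], X[19], X[6], X[5]),
    sprintf("%s * %s * %s * %s + %s * %s * %s - %s * %s - %s * %s - %s * %s * %s - %s * %s",
            X[21], X[8], X[2], X[6], X[12], X[2], X[7], X[13], X[3],
            X[14], X[3], X[15], X[3], X[5], X[18], X[3]),
    sprintf("%s * %s * %s - %s * %s - %s * %s * %s",
            X[15], X[3], X[5], X[16], X[4], X[17], X[4], X[7]),
    sprintf("3 * (%s * %s) + %s * %s * %s - %s * %s * %s + %s * %s - %s * %s * %s",
            X[22], X[20], X[17], X[4], X[7], X[15], X[3], X[5],
            X[18], X[3], X[19], X[6], X[5]),
    atp_net,
    paste0("-(", atp_net, ")"),
    sprintf("a%d - %s * %s", 1:13, num_lit(beta), X[8:20]),
    sprintf("-(0.01) * %s * %s * %s * %s", X[21], X[8], X[2], X[6]),
    sprintf("-(0.03) * %s * %s", X[22], X[20]))
  names(rhs) <- states
  x0 <- c(1, 0.02, 1, 2, 2, 1, 1, rep(0.1, 13),
          if (scenario == "G-M") c(12, 0) else c(0, 12))
  if (!is.null(overrides$x0)) x0 <- overrides$x0
  ocp_problem(
    name = paste0("BSUB_", scenario),
    states = states, controls = controls,
    rhs = as.list(rhs), x0 = x0,
    horizon = time_horizon(t0 = 0, tf = tf),
    objectives = list(
      objective_functional(lagrange = "-ATP", sense = "min",
                           name = "negative_atp_production"),
      objective_functional(lagrange = paste(paste0("E", 1:13), collapse = " + "),
                           sense = "min", name = "protein_investment")),
    path_constraints = list(
      path_constraint(paste(paste0("E", 1:13), collapse = " + "),
                      bound = E_T, dir = "<=", label = "enzyme_capacity")),
    control_bounds = list(lower = 0.0025, upper = 0.125))
}

#' Linear-quadratic analytic fixture
#'
#' min integral(u^2) dt on [0, 1] with xdot = u, x(0) = 0 and the endpoint
#' equality x(1) = 1. Closed form: u* = 1 everywhere, J* = 1, and the costate
#' is lambda* = -2 under the Hamiltonian convention H = L + lambda * f. Used
#' as the oracle for the collocation transcription and the adjoint
#' extraction.
#'
#' @param u_bound symmetric control bound (the optimum is interior).
#' @return an \code{ocp_problem}.
#' @export
build_lq_toy <- function(u_bound = 5) {
  ocp_problem(
    name = "LQ_TOY", states = "x", controls = "u",
    rhs = list(x = "u"), x0 = 0,
    horizon = time_horizon(t0 = 0, tf = 1),
    objectives = objective_functional(lagrange = "u^2", sense = "min",
                                      name = "control_energy"),
    point_constraints = point_constraint("x", time = "tf", bound = 1,
                                         rel = "==", label = "endpoint"),
    control_bounds = list(lower = -u_bound, upper = u_bound))
}

#' List the built-in benchmark problems
#'
#' @return data.frame with one row per benchmark: name, states, controls,
#'   objectives, path and point constraint counts, horizon type.
#' @export
list_benchmarks <- function() {
  probs <- list(LPN3B = build_lpn3b(), SC = build_sc(),
                `BSUB_G-M` = build_bsub("G-M"), `BSUB_M-G` = build_bsub("M-G"),
                LQ_TOY = build_lq_toy())
  do.call(rbind, lapply(names(probs), function(nm) {
    p <- probs[[nm]]
    data.frame(name = nm, states = n_states(p), controls = n_controls(p),
               objectives = n_objectives(p),
               path_constraints = length(p$path_constraints),
               point_constraints = length(p$point_constraints),
               horizon = p$horizon$tf_mode)
  }))
}

# Resolve a benchmark by name (used by the config/CLI layer).
get_benchmark <- function(name, ...) {
  switch(name,
         LPN3B = build_lpn3b(...),
         SC = build_sc(...),
         `BSUB_G-M` = build_bsub("G-M", ...),
         `BSUB_M-G` = build_bsub("M-G", ...),
         BSUB = build_bsub("G-M", ...),
         LQ_TOY = build_lq_toy(...),
         stop("unknown benchmark '", name, "'"))
}
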