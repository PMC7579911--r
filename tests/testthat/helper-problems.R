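# Shared fixtures: small analytic problems used across test files.

# scalar exponential decay: xdot = -x, no controls
decay_problem <- function(tf = 1) {
  ocp_problem(
    name = "decay", states = "x", controls = character(0),
    rhs = list(x = "-x"), x0 = 1,
    horizon = time_horizon(0, tf = tf),
    objectives = objective_functional(mayer = "x", sense = "min"),
    control_bounds = list(lower = numeric(0), upper = numeric(0)))
}

# bi-objective analytic toy: xdot = u on [0,1], u in [0,1],
# J1 = int u^2 dt (min), J2 = -x(1) (min). Closed-form Pareto front:
# for target x(1) = c the optimal u is constant c, so J1 = c^2, J2 = -c.
biobjective_toy <- function() {
  ocp_problem(
    name = "bi_toy", states = "x", controls = "u",
    rhs = list(x = "u"), x0 = 0,
    horizon = time_horizon(0, tf = 1),
    objectives = list(
      objective_functional(lagrange = "u^2", sense = "min", name = "effort"),
      objective_functional(mayer = "-x", sense = "min", name = "neg_yield")),
    control_bounds = list(lower = 0, upper = 1))
}

# free-final-time linear test system: xdot = a (constant), used for
# normalization round-trips
free_tf_linear <- function(a = 1) {
  ocp_problem(
    name = "free_linear", states = "x", controls = "u",
    rhs = list(x = paste0(a, " + 0 * u")), x0 = 0,
    horizon = time_horizon(0, tf_bounds = c(0.5, 4)),
    objectives = objective_functional(mayer = "tf", sense = "min"),
    point_constraints = point_constraint("x", time = "tf", bound = 2,
                                         rel = "==", label = "target"),
    control_bounds = list(lower = 0, upper = 1))
}

# simple finite-dimensional NLPs for the optimizer tests
toy_nlp <- function(n, lower, upper, fn, eq = function(y) numeric(0),
                    ineq = function(y) numeric(0)) {
  structure(list(
    n = n, lower = rep_len(lower, n), upper = rep_len(upper, n),
    y0 = (rep_len(lower, n) + rep_len(upper, n)) / 2,
    eval = function(y) list(cost = fn(y), eq = eq(y), ineq = ineq(y),
                            ok = TRUE),
    grad = NULL, hess = NULL, layout = list(),
    eq_names = character(0), ineq_names = character(0), meta = list()),
    class = "dnlp")
}

# settings that keep solver-based tests fast
fast_settings <- function(...) {
  utils::modifyList(list(
    cvp = list(n_elements = 5L, order = 2L),
    search = list(max_evals = 800L,
                  local = list(maxit_outer = 3L, maxit_inner = 12L,
                               factr = 1e7)),
    mesh_intervals = 40L), list(...))
}
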