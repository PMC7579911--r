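# Post-optimality analyses: multiplicity ensembles, constraint sweeps and
# multiplier-based sensitivity ranking.

test_that("ensemble membership applies the relative cost threshold", {
  # threshold arithmetic on a synthetic cost vector: cutoff best*(1+0.005)
  costs <- c(10.00, 10.03, 10.20, 11.0)
  cutoff <- min(costs) + 0.005 * abs(min(costs))
  expect_equal(which(costs <= cutoff), c(1, 2))
})

test_that("a convex problem yields a tight ensemble", {
  p <- biobjective_toy()
  ens <- multiplicity_ensemble(p, strategy = "collocation", n_runs = 3,
                               seed = 1, objective = 2,
                               settings = fast_settings(mesh_intervals = 20L))
  expect_gte(ens$n_members, 2)
  # unique optimum (u = 1): near-zero envelopes
  w <- max(ens$control_envelopes$u$max - ens$control_envelopes$u$min)
  expect_lt(w, 1e-3)
  # envelopes bracket every member everywhere
  for (m in ens$members) {
    tau <- (m$traj$times - m$traj$times[1]) /
      diff(range(m$traj$times))
    v <- stats::approx(tau, m$traj$controls[, 1],
                       xout = ens$control_envelopes$u$tau)$y
    expect_true(all(v >= ens$control_envelopes$u$min - 1e-8))
    expect_true(all(v <= ens$control_envelopes$u$max + 1e-8))
  }
})

test_that("compensating controls show wide envelopes at tight cost spread", {
  # u1 and u2 enter only as u1 + u2: any split with the right sum is optimal
  p <- ocp_problem(
    name = "degenerate", states = "x", controls = c("u1", "u2"),
    rhs = list(x = "u1 + u2"), x0 = 0,
    horizon = time_horizon(0, tf = 1),
    objectives = objective_functional(lagrange = "(u1 + u2 - 1)^2"),
    control_bounds = list(lower = 0, upper = 1))
  ens <- multiplicity_ensemble(p, strategy = "multistart_collocation",
                               n_runs = 4, seed = 2,
                               settings = fast_settings(mesh_intervals = 15L,
                                                        n_starts = 2L))
  costs <- ens$costs
  expect_lt(diff(range(costs)), 1e-4)
  # individual controls spread while their sum stays pinned near 1
  w1 <- max(ens$control_envelopes$u1$max - ens$control_envelopes$u1$min)
  sum_med <- ens$control_envelopes$u1$median + ens$control_envelopes$u2$median
  expect_gt(w1, 0.2)
  expect_lt(max(abs(sum_med - 1)), 0.05)
})

test_that("constraint sweeps expose monotone relaxation", {
  # effort objective with endpoint x(1) >= target: raising the target can
  # only increase the optimal effort (tightening never helps)
  p <- ocp_problem(
    name = "sweep_toy", states = "x", controls = "u",
    rhs = list(x = "u"), x0 = 0, horizon = time_horizon(0, tf = 1),
    objectives = objective_functional(lagrange = "u^2"),
    point_constraints = point_constraint("x", time = "tf", bound = 0.5,
                                         rel = ">=", label = "yield_floor"),
    control_bounds = list(lower = 0, upper = 2))
  sw <- constraint_sweep(p, "yield_floor", values = c(0.3, 0.6, 0.9),
                         strategy = "collocation", seed = 1,
                         settings = fast_settings(mesh_intervals = 20L))
  expect_true(all(sw$summary$feasible))
  expect_true(all(diff(sw$summary$cost) >= -1e-6))
  # closed form: minimal effort for target c is c^2
  expect_equal(sw$summary$cost, c(0.3, 0.6, 0.9)^2, tolerance = 1e-3)
  # a single sweep value equal to the default matches a plain solve
  sw1 <- constraint_sweep(p, "yield_floor", values = 0.5,
                          strategy = "collocation", seed = 1,
                          settings = fast_settings(mesh_intervals = 20L))
  plain <- solve_ocp(p, "collocation", seed = 1,
                     settings = fast_settings(mesh_intervals = 20L))
  expect_equal(sw1$summary$cost, plain$cost, tolerance = 1e-6)
  expect_error(constraint_sweep(p, "yield_floor", numeric(0)),
               "nothing to sweep")
  expect_error(constraint_sweep(p, "no_such", 1), "no constraint labelled")
})

test_that("sensitivity ranking puts inactive constraints last and estimates
          first-order cost changes", {
  # LQ toy with a dummy inactive path constraint
  p <- ocp_problem(
    name = "lq_sens", states = "x", controls = "u",
    rhs = list(x = "u"), x0 = 0, horizon = time_horizon(0, tf = 1),
    objectives = objective_functional(lagrange = "u^2"),
    path_constraints = path_constraint("u", bound = 4, dir = "<=",
                                       label = "dummy"),
    point_constraints = point_constraint("x", time = "tf", bound = 1,
                                         rel = "==", label = "endpoint"),
    control_bounds = list(lower = -5, upper = 5))
  sol <- solve_ocp(p, "collocation", seed = 1,
                   settings = fast_settings(mesh_intervals = 40L))
  rep <- sensitivity_report(sol)
  expect_equal(rep$constraint[nrow(rep)], "dummy")
  expect_lt(rep$sensitivity[rep$constraint == "dummy"], 1e-8)
  expect_gt(rep$sensitivity[rep$constraint == "endpoint"], 0.1)
  # first-order check: perturbing the endpoint by delta changes the optimal
  # cost by about multiplier * delta (J(c) = c^2 so dJ/dc = 2 at c = 1)
  mult <- sol$mult$point_eq[1]
  delta <- 0.05
  p2 <- p
  p2$point_constraints[[1]]$bound <- 1 + delta
  sol2 <- solve_ocp(dynenz:::compile_problem(p2), "collocation", seed = 1,
                    settings = fast_settings(mesh_intervals = 40L))
  dJ <- sol2$cost - sol$cost
  expect_lt(abs(dJ - abs(mult) * delta) / abs(dJ), 0.2)
})
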