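# Problem data model, vector-field evaluation, canonical transformations,
# simulation, objective evaluation and constraint checking.

test_that("evaluate_rhs reproduces hand-computed pathway derivatives", {
  p <- build_lpn3b()
  expect_equal(unname(evaluate_rhs(p, 0, c(1, 0, 0, 0), c(1, 0, 0))),
               c(0, 1, 0, 0))
  sc <- build_sc()
  expect_equal(unname(evaluate_rhs(sc, 0, sc$x0, rep(0, 6))),
               c(0, 0, 0, 0, -0.07, -2.4, 0.07, 2.4), tolerance = 1e-12)
  bs <- build_bsub("G-M")
  f <- evaluate_rhs(bs, 0, bs$x0, rep(0, 13))
  expect_equal(unname(f[8]), -0.25 * 0.1)
})

test_that("evaluate_rhs validates shapes and finiteness", {
  p <- build_lpn3b()
  expect_error(evaluate_rhs(p, 0, c(1, 0), c(1, 0, 0)), "shape error")
  expect_error(evaluate_rhs(p, 0, c(1, 0, 0, 0), c(1, 0)), "shape error")
  bad <- ocp_problem(states = "x", controls = "u", rhs = list(x = "1 / x"),
                     x0 = 1, horizon = time_horizon(0, tf = 1),
                     objectives = objective_functional(mayer = "x"),
                     control_bounds = list(lower = 0, upper = 1))
  expect_error(evaluate_rhs(bad, 0, 0, 0.5), "model evaluation error.*x")
})

test_that("expression grammar rejects unresolved symbols and foreign calls", {
  expect_error(
    ocp_problem(states = "x", controls = "u", rhs = list(x = "u + z"),
                x0 = 0, horizon = time_horizon(0, tf = 1),
                objectives = objective_functional(mayer = "x"),
                control_bounds = list(lower = 0, upper = 1)),
    "does not resolve")
  expect_error(parse_model_expr("system('ls')", c("x")), "outside the supported grammar")
})

test_that("augment_lagrange turns integral terms into quadrature states", {
  # J = int u dt with u = 0.5 on [0,1] -> quadrature state ends at 0.5
  p <- ocp_problem(states = "x", controls = "u", rhs = list(x = "0 * u"),
                   x0 = 0, horizon = time_horizon(0, tf = 1),
                   objectives = objective_functional(lagrange = "u"),
                   control_bounds = list(lower = 0, upper = 1))
  pa <- augment_lagrange(p)
  expect_equal(pa$states, c("x", "qJ1"))
  tr <- simulate_ocp(pa, function(t) 0.5)
  expect_equal(unname(tr$states[nrow(tr$states), "qJ1"]), 0.5,
               tolerance = 1e-8)
  expect_equal(unname(evaluate_objectives(pa, tr)), 0.5, tolerance = 1e-8)
  # pure-Mayer problem returned unchanged
  pm <- decay_problem()
  expect_identical(augment_lagrange(pm), pm)
  # LPN3B objective 2 becomes one extra state with rhs S2 + S3
  pl <- augment_lagrange(build_lpn3b())
  expect_true("qJ2" %in% pl$states)
  expect_equal(gsub(" ", "", pl$rhs_text[["qJ2"]]), "S2+S3")
})

test_that("augment_lagrange preserves objective values for arbitrary controls", {
  p <- biobjective_toy()
  pa <- augment_lagrange(p)
  set.seed(42)
  for (k in 1:5) {
    w <- runif(3)
    ufn <- function(t) w[1] + w[2] * t + w[3] * t^2
    tr_raw <- simulate_ocp(p, ufn, n_out = 1501)
    tr_aug <- simulate_ocp(pa, ufn, n_out = 1501)
    expect_equal(evaluate_objectives(p, tr_raw),
                 evaluate_objectives(pa, tr_aug), tolerance = 1e-6)
  }
})

test_that("normalize_time maps a free horizon onto [0,1] with tf as parameter", {
  p <- free_tf_linear(a = 1)
  pn <- normalize_time(p)
  expect_equal(pn$horizon$tf_mode, "fixed")
  expect_equal(pn$horizon$tf, 1)
  expect_equal(pn$decision_params$tf, c(0.5, 4))
  tr <- simulate_ocp(pn, function(t) 0, dp = c(tf = 2))
  # xdot = 1 at tf = 2: x(tau) = 2 tau, so x(1) = 2
  expect_equal(unname(tr$states[nrow(tr$states), "x"]), 2, tolerance = 1e-8)
  expect_error(normalize_time(pn), "not free-time")
  # the tf objective of the pathway benchmark maps to the tf parameter
  pl <- prepare_problem(build_lpn3b())
  expect_equal(pl$objectives[[1]]$mayer_text, "tf")
  expect_true("tf" %in% names(pl$decision_params))
})

test_that("normalized simulation round-trips against the raw horizon", {
  # linear system xdot = -x + u with constant control, fixed tf = T,
  # versus the normalized problem at dp tf = T
  praw <- ocp_problem(states = "x", controls = "u", rhs = list(x = "-x + u"),
                      x0 = 1, horizon = time_horizon(0, tf = 1.7),
                      objectives = objective_functional(mayer = "x"),
                      control_bounds = list(lower = 0, upper = 2))
  pfree <- ocp_problem(states = "x", controls = "u", rhs = list(x = "-x + u"),
                       x0 = 1, horizon = time_horizon(0, tf_bounds = c(0.1, 5)),
                       objectives = objective_functional(mayer = "x"),
                       control_bounds = list(lower = 0, upper = 2))
  pn <- normalize_time(pfree)
  tr_raw <- simulate_ocp(praw, function(t) 0.8, rtol = 1e-10, atol = 1e-10)
  tr_nrm <- simulate_ocp(pn, function(t) 0.8, rtol = 1e-10, atol = 1e-10,
                         dp = c(tf = 1.7))
  expect_equal(tr_raw$states[nrow(tr_raw$states), "x"],
               tr_nrm$states[nrow(tr_nrm$states), "x"], tolerance = 1e-8)
})

test_that("simulate_ocp matches closed forms and respects tolerances", {
  p <- decay_problem()
  tr <- simulate_ocp(p)
  expect_equal(unname(tr$states[nrow(tr$states), "x"]), exp(-1),
               tolerance = 1e-6)
  expect_equal(tr$times[1], 0)
  expect_equal(tr$times[length(tr$times)], 1)
  # zero rhs: trajectory constant at x0
  pz <- ocp_problem(states = "x", controls = character(0),
                    rhs = list(x = "0"), x0 = 3,
                    horizon = time_horizon(0, tf = 2),
                    objectives = objective_functional(mayer = "x"),
                    control_bounds = list(lower = numeric(0),
                                          upper = numeric(0)))
  trz <- simulate_ocp(pz)
  expect_true(all(trz$states[, "x"] == 3))
})

test_that("conserved moiety pairs stay constant under random admissible controls", {
  sc <- prepare_problem(build_sc())
  bs <- prepare_problem(build_bsub("G-M", tf = 10))
  set.seed(7)
  for (k in 1:3) {
    e <- runif(6, 0, 1.9)   # sum < E_T
    tr <- simulate_ocp(sc, function(t) e, dp = c(tf = 1.5))
    expect_lt(max(abs(tr$states[, "NADH"] + tr$states[, "NAD"] - 1)), 1e-6)
    expect_lt(max(abs(tr$states[, "ATP"] + tr$states[, "ADP"] - 1)), 1e-6)
    a <- runif(13, 0.0025, 0.125)
    trb <- simulate_ocp(bs, function(t) a)
    expect_lt(max(abs(trb$states[, "ATP"] + trb$states[, "ADP"] - 2)), 1e-6)
  }
})

test_that("evaluate_objectives integrates Lagrange terms by trapezoid rule", {
  # stored cubic integrand: J = int (t^3 - 2 t^2 + 3) dt on [0, 2]
  p <- ocp_problem(states = "x", controls = character(0),
                   rhs = list(x = "0"), x0 = 0,
                   horizon = time_horizon(0, tf = 2),
                   objectives = objective_functional(
                     lagrange = "t^3 - 2 * t^2 + 3"),
                   control_bounds = list(lower = numeric(0),
                                         upper = numeric(0)))
  tr <- simulate_ocp(p, n_out = 200)
  analytic <- 2^4 / 4 - 2 * 2^3 / 3 + 3 * 2
  expect_equal(unname(evaluate_objectives(p, tr)), analytic, tolerance = 1e-4)
  # LPN3B objective vector is [tf, integral of intermediates]
  pl <- build_lpn3b()
  cl <- prepare_problem(pl)
  tr2 <- simulate_ocp(cl, function(t) c(0.5, 0.3, 0.2), dp = c(tf = 2))
  J <- evaluate_objectives(cl, tr2)
  expect_equal(unname(J[1]), 2)
  expect_gt(J[2], 0)
})

test_that("check_constraints reports violations, worst times and activity", {
  p <- prepare_problem(build_lpn3b())
  tr <- simulate_ocp(p, function(t) c(0.5, 0.3, 0.2), dp = c(tf = 2))
  cc <- check_constraints(p, tr)
  cap <- cc[cc$label == "enzyme_capacity", ]
  expect_equal(cap$violation, 0)
  expect_true(cap$active)  # sum = 1 everywhere
  tr2 <- simulate_ocp(p, function(t) c(0.2, 0.2, 0.1), dp = c(tf = 2))
  cc2 <- check_constraints(p, tr2)
  expect_false(cc2[cc2$label == "enzyme_capacity", "active"])
  expect_equal(cc2[cc2$label == "enzyme_capacity", "violation"], 0)
  # endpoint miss is reported with its size
  pt <- cc2[cc2$label == "product_target", ]
  s4 <- unname(tr2$states[nrow(tr2$states), "S4"])
  expect_equal(pt$violation, abs(s4 - 0.9), tolerance = 1e-12)
})
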