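# Control vector parameterization: piecewise-polynomial controls, the
# reduced NLP, and mesh refinement.

test_that("build_control reproduces piecewise constant and linear profiles", {
  p <- prepare_problem(biobjective_toy())
  # rho = 1, M = 1: constant control
  par1 <- control_parameterization(p, n_elements = 1, order = 1)
  u1 <- build_control(par1, 0.5)
  expect_equal(unname(u1(0)), 0.5)
  expect_equal(unname(u1(0.77)), 0.5)
  # rho = 2, M = 1 on [0,1]: element values 0.2 / 0.8
  par2 <- control_parameterization(p, n_elements = 2, order = 1)
  u2 <- build_control(par2, c(0.2, 0.8))
  expect_equal(unname(u2(0.25)), 0.2)
  expect_equal(unname(u2(0.75)), 0.8)
  expect_equal(unname(u2(0.5)), 0.8)   # right-continuous at the boundary
  # M = 2: linear blend, endpoint values (0, 1) -> midpoint 0.5
  par3 <- control_parameterization(p, n_elements = 1, order = 2)
  u3 <- build_control(par3, c(0, 1))
  expect_equal(unname(u3(0.5)), 0.5)
  expect_error(u3(1.5), "out of horizon")
})

test_that("transcription dimensions follow the coefficient counting rule", {
  p <- prepare_problem(build_lpn3b())
  # 3 controls x 5 elements x order 2 + tf = 31 (fixed-length elements)
  par <- control_parameterization(p, n_elements = 5, order = 2)
  nlp <- transcribe_cvp(p, par)
  expect_equal(nlp$n, 31)
  # variable-length adds one width per element
  parv <- control_parameterization(p, n_elements = 5, order = 2,
                                   variable_length = TRUE)
  expect_equal(transcribe_cvp(p, parv)$n, 36)
})

test_that("zero enzyme coefficients leave the product target unmet by 0.9", {
  p <- prepare_problem(build_lpn3b())
  par <- control_parameterization(p, n_elements = 5, order = 2)
  nlp <- transcribe_cvp(p, par)
  e <- nlp$eval(c(rep(0, par$n_coef), 3))
  expect_equal(e$eq, -0.9, tolerance = 1e-8)  # S4(tf) - 0.9 with no flux
})

test_that("the CVP cost is definitionally the simulated Mayer value", {
  p <- prepare_problem(biobjective_toy())
  par <- control_parameterization(p, n_elements = 4, order = 2)
  nlp <- transcribe_cvp(p, par, objective = 1)
  b <- par$boundaries
  samp <- sort(unique(c(b, (b[-1] + b[-length(b)]) / 2)))
  set.seed(11)
  for (k in 1:3) {
    w <- runif(par$n_coef)
    e <- nlp$eval(w)
    ctrl <- build_control(par, w)
    # same output grid as the transcription so the IVP solve is identical
    tr <- simulate_ocp(p, ctrl, n_out = 2, sample_times = samp)
    expect_equal(e$cost, unname(evaluate_objectives(p, tr)[1]),
                 tolerance = 1e-9)
  }
})

test_that("refine_mesh preserves the represented control exactly", {
  p <- prepare_problem(build_lpn3b())
  par <- control_parameterization(p, n_elements = 5, order = 2)
  set.seed(3)
  w <- runif(par$n_coef)
  ref <- refine_mesh(par, w, factor = 2)
  expect_equal(ref$par$n_elements, 10)
  u_old <- build_control(par, w)
  u_new <- build_control(ref$par, ref$w)
  tg <- seq(0, 1, length.out = 401)
  expect_lt(max(abs(u_old(tg) - u_new(tg))), 1e-7)
  expect_error(refine_mesh(par, w, factor = 1), "invalid factor")
  # refined coefficients give the same cost
  nlp_old <- transcribe_cvp(p, par)
  nlp_new <- transcribe_cvp(p, ref$par)
  y_old <- c(w, 2.5); y_new <- c(ref$w, 2.5)
  expect_equal(nlp_old$eval(y_old)$cost, nlp_new$eval(y_new)$cost,
               tolerance = 1e-6)
})

test_that("single-element piecewise-constant CVP reduces to a static parameter", {
  # min over constant u of J1 = int u^2 dt subject to nothing: grid search
  # over the lone coefficient agrees with the transcribed cost
  p <- prepare_problem(ocp_problem(
    states = "x", controls = "u", rhs = list(x = "u"), x0 = 0,
    horizon = time_horizon(0, tf = 1),
    objectives = objective_functional(lagrange = "(u - 0.37)^2"),
    control_bounds = list(lower = 0, upper = 1)))
  par <- control_parameterization(p, n_elements = 1, order = 1)
  nlp <- transcribe_cvp(p, par)
  grid <- seq(0, 1, by = 0.01)
  costs <- vapply(grid, function(w) nlp$eval(w)$cost, 0)
  expect_equal(grid[which.min(costs)], 0.37, tolerance = 1e-3 + 0.01)
  res <- local_solve(nlp, y0 = 0.9)
  expect_equal(res$y, 0.37, tolerance = 1e-3)
})
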