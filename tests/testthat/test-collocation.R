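# Trapezoidal transcription, symbolic derivative assembly, the collocation
# solve with multiplier extraction, warm starting, and adjoint estimates.

test_that("trapezoidal defects encode the implicit update", {
  # xdot = -x, x0 = 1, one step h = 0.1: defect zero at x1 = 0.95/1.05
  p <- decay_problem(tf = 0.1)
  pa <- augment_lagrange(p)
  mesh <- collocation_mesh(pa, 1)
  nlp <- transcribe_trapezoidal(pa, mesh)
  x1 <- 0.95 / 1.05
  e <- nlp$eval(c(1, x1, 0, 0))   # states x then quadrature qJ? (pure Mayer here)
  expect_lt(max(abs(e$eq)), 1e-12)
  # and nonzero away from the recursion
  e2 <- nlp$eval(c(1, 0.9, 0, 0))
  expect_gt(max(abs(e2$eq)), 1e-4)
})

test_that("states satisfying the recursion give zero defect residuals", {
  p <- prepare_problem(build_lpn3b())
  mesh <- collocation_mesh(p, 25)
  nlp <- transcribe_trapezoidal(p, mesh)
  lay <- nlp$layout
  # build a decision vector by running the trapezoidal recursion forward
  set.seed(5)
  y <- nlp$y0
  y[lay$dpind] <- 2
  for (j in seq_len(lay$nu)) y[lay$uind(j)] <- runif(1, 0, 0.33)
  X <- matrix(0, lay$Np, lay$ns)
  X[1, ] <- unname(p$x0)
  U <- vapply(seq_len(lay$nu), function(j) y[lay$uind(j)], numeric(lay$Np))
  rhsv <- dynenz:::make_rhs_fn_vec(p)
  h <- mesh$h
  for (i in seq_len(lay$Np - 1)) {
    # implicit trapezoidal step solved by fixed-point iteration
    xi <- X[i, ]
    fi <- rhsv(matrix(xi, 1), U[i, , drop = FALSE], c(tf = 2), mesh$nodes[i])
    xn <- xi + h[i] * as.numeric(fi)
    for (it in 1:60) {
      fn <- rhsv(matrix(xn, 1), U[i + 1, , drop = FALSE], c(tf = 2),
                 mesh$nodes[i + 1])
      xn <- xi + h[i] / 2 * (as.numeric(fi) + as.numeric(fn))
    }
    X[i + 1, ] <- xn
  }
  for (s in seq_len(lay$ns)) y[lay$xind(s)] <- X[, s]
  e <- nlp$eval(y)
  expect_lt(max(abs(e$eq[seq_len((lay$Np - 1) * lay$ns)])), 1e-10)
})

test_that("decision dimensions follow the node counting rule", {
  p <- prepare_problem(build_lpn3b())   # 4 states + 1 quadrature, 3 controls
  mesh <- collocation_mesh(p, 40)
  nlp <- transcribe_trapezoidal(p, mesh)
  expect_equal(nlp$n, 41 * 5 + 41 * 3 + 1)
})

test_that("assembled derivatives match finite differences", {
  # quadratic control cost: gradient of the trapezoidal quadrature of u^2
  lq <- prepare_problem(build_lq_toy())
  mesh <- collocation_mesh(lq, 10)
  nlp <- transcribe_trapezoidal(lq, mesh)
  set.seed(8)
  y <- pmin(pmax(runif(nlp$n, -1, 1), nlp$lower), nlp$upper)
  gr <- nlp$grad(y)
  hstep <- 1e-6
  for (k in sample(nlp$n, 8)) {
    yp <- y; yp[k] <- y[k] + hstep
    ym <- y; ym[k] <- y[k] - hstep
    expect_equal(gr$cost[k],
                 (nlp$eval(yp)$cost - nlp$eval(ym)$cost) / (2 * hstep),
                 tolerance = 1e-6)
    expect_equal(as.numeric(gr$jac_eq[, k]),
                 (nlp$eval(yp)$eq - nlp$eval(ym)$eq) / (2 * hstep),
                 tolerance = 1e-5)
  }
  # the LQ defect rows are linear, so a wide-step difference is already exact
  k <- 2L
  yw <- y; yw[k] <- y[k] + 0.3
  fd_wide <- (nlp$eval(yw)$eq - nlp$eval(y)$eq) / 0.3
  expect_equal(as.numeric(gr$jac_eq[, k]), fd_wide, tolerance = 1e-9)
})

test_that("random pathway Jacobians agree with central differences", {
  p <- prepare_problem(build_lpn3b())
  mesh <- collocation_mesh(p, 7)
  nlp <- transcribe_trapezoidal(p, mesh)
  set.seed(21)
  y <- pmin(pmax(runif(nlp$n, 0, 1), nlp$lower), nlp$upper)
  gr <- nlp$grad(y)
  hstep <- 1e-6
  ks <- sample(nlp$n, 10)
  for (k in ks) {
    yp <- y; yp[k] <- y[k] + hstep
    ym <- y; ym[k] <- y[k] - hstep
    fd_eq <- (nlp$eval(yp)$eq - nlp$eval(ym)$eq) / (2 * hstep)
    fd_in <- (nlp$eval(yp)$ineq - nlp$eval(ym)$ineq) / (2 * hstep)
    expect_lt(max(abs(as.numeric(gr$jac_eq[, k]) - fd_eq)), 1e-5)
    expect_lt(max(abs(as.numeric(gr$jac_ineq[, k]) - fd_in)), 1e-5)
  }
})

test_that("the Hessian of the Lagrangian matches finite differences", {
  p <- prepare_problem(build_lpn3b())
  mesh <- collocation_mesh(p, 5)
  nlp <- transcribe_trapezoidal(p, mesh)
  set.seed(31)
  y <- pmin(pmax(runif(nlp$n, 0.1, 0.9), nlp$lower), nlp$upper)
  nu <- runif(length(nlp$eq_names), -1, 1)
  mu <- runif(length(nlp$ineq_names), 0, 1)
  H <- as.matrix(nlp$hess(y, 1, nu, mu))
  expect_equal(H, t(H))
  lagr <- function(yy) {
    e <- nlp$eval(yy)
    e$cost + sum(nu * e$eq) + sum(mu * e$ineq)
  }
  hh <- 1e-4
  ks <- sample(nlp$n, 5)
  for (a in ks) for (b in ks) {
    f <- function(s1, s2) {
      yy <- y; yy[a] <- yy[a] + s1 * hh; yy[b] <- yy[b] + s2 * hh
      lagr(yy)
    }
    fd <- (f(1, 1) - f(1, -1) - f(-1, 1) + f(-1, -1)) / (4 * hh^2)
    expect_equal(H[a, b], fd, tolerance = 1e-4)
  }
})

test_that("the linear-quadratic oracle is solved to its closed form", {
  lq <- prepare_problem(build_lq_toy())
  mesh <- collocation_mesh(lq, 100)
  nlp <- transcribe_trapezoidal(lq, mesh)
  sol <- solve_collocation(nlp)
  expect_true(sol$feasible)
  expect_equal(sol$cost, 1, tolerance = 1e-4)
  expect_lt(max(abs(sol$traj$controls - 1)), 1e-3)
  adj <- extract_adjoints(sol$mult, mesh)
  expect_lt(max(abs(adj$lambda[, "x"] + 2)), 1e-2)
  # a feasible KKT guess is returned essentially unchanged
  sol2 <- solve_collocation(nlp, guess = sol$result$y)
  expect_equal(sol2$cost, sol$cost, tolerance = 1e-8)
})

test_that("adjoint estimation error shrinks under mesh refinement", {
  lq <- prepare_problem(build_lq_toy())
  errs <- vapply(c(10, 20, 40), function(nn) {
    mesh <- collocation_mesh(lq, nn)
    sol <- solve_collocation(transcribe_trapezoidal(lq, mesh))
    adj <- extract_adjoints(sol$mult, mesh)
    max(abs(adj$lambda[, "x"] + 2))
  }, 0)
  # first-order or better once past discretization noise
  expect_lt(errs[3], errs[1] + 1e-12)
  expect_lt(errs[3], 1e-2)
})

test_that("warm starts interpolate trajectories onto the mesh", {
  p <- prepare_problem(build_lpn3b())
  mesh <- collocation_mesh(p, 20)
  nlp <- transcribe_trapezoidal(p, mesh)
  tr <- simulate_ocp(p, function(t) c(0.4, 0.3, 0.3), dp = c(tf = 2),
                     n_out = 41)   # mesh nodes are a subset of this grid
  fake_sol <- list(traj = tr, dp = c(tf = 2))
  y <- warm_start_from(fake_sol, nlp)
  lay <- nlp$layout
  expect_equal(y[lay$xind(1)], unname(tr$states[seq(1, 41, by = 2), "S1"]))
  expect_true(all(y[lay$uind(1)] == 0.4))
  expect_equal(unname(y[lay$dpind]), 2)
  # dimension mismatch is detected
  lq <- prepare_problem(build_lq_toy())
  nlq <- transcribe_trapezoidal(lq, collocation_mesh(lq, 5))
  expect_error(warm_start_from(fake_sol, nlq), "problem mismatch")
})

test_that("inactive path constraints carry zero multipliers", {
  # LQ toy with a dummy never-active path constraint u <= 4
  p <- ocp_problem(
    name = "lq_dummy", states = "x", controls = "u",
    rhs = list(x = "u"), x0 = 0, horizon = time_horizon(0, tf = 1),
    objectives = objective_functional(lagrange = "u^2"),
    path_constraints = path_constraint("u", bound = 4, dir = "<=",
                                       label = "dummy"),
    point_constraints = point_constraint("x", time = "tf", bound = 1,
                                         rel = "==", label = "endpoint"),
    control_bounds = list(lower = -5, upper = 5))
  pa <- prepare_problem(p)
  mesh <- collocation_mesh(pa, 40)
  sol <- solve_collocation(transcribe_trapezoidal(pa, mesh))
  expect_true(sol$feasible)
  adj <- extract_adjoints(sol$mult, mesh)
  expect_lt(max(abs(adj$mu[, "dummy"])), 1e-8)
  expect_equal(unname(adj$sensitivity["dummy"]), 0, tolerance = 1e-8)
})
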