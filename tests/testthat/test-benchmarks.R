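# Benchmark factories: dimensions, printed parameter values, structural
# conservation properties, the n-step generalization and the config
# round-trip.

test_that("the three pathway models have the published dimensions", {
  p <- build_lpn3b()
  expect_equal(length(p$states), 4)
  expect_equal(length(p$controls), 3)
  expect_equal(length(p$objectives), 2)
  expect_equal(length(p$path_constraints), 1)
  expect_equal(length(p$point_constraints), 1)
  sc <- build_sc()
  expect_equal(length(sc$states), 8)
  expect_equal(length(sc$controls), 6)
  expect_equal(length(sc$objectives), 2)
  expect_equal(length(sc$path_constraints), 3)
  expect_equal(sc$path_constraints[[1]]$bound, 11.5)
  bs <- build_bsub("G-M")
  expect_equal(length(bs$states), 22)
  expect_equal(length(bs$controls), 13)
  expect_equal(bs$path_constraints[[1]]$bound, 6.5)
  expect_equal(bs$control_bounds$lower, rep(0.0025, 13))
  expect_equal(bs$control_bounds$upper, rep(0.125, 13))
  lq <- build_lq_toy()
  expect_equal(length(lq$states), 1)
  expect_equal(length(lq$point_constraints), 1)
  bm <- list_benchmarks()
  expect_equal(nrow(bm), 5)
})

test_that("substrate abundance fixes S1 under any control", {
  p <- prepare_problem(build_lpn3b())
  set.seed(2)
  for (k in 1:3) {
    e <- runif(3, 0, 0.33)
    tr <- simulate_ocp(p, function(t) e, dp = c(tf = 3))
    expect_true(all(abs(tr$states[, "S1"] - 1) < 1e-10))
  }
})

test_that("scenario initial conditions and enzyme decay match the model", {
  g <- build_bsub("G-M")
  expect_equal(unname(g$x0[c("G", "M")]), c(12, 0))
  m <- build_bsub("M-G")
  expect_equal(unname(m$x0[c("G", "M")]), c(0, 12))
  expect_error(build_bsub("X-Y"), "invalid scenario")
  # with zero synthesis every enzyme decays as 0.1 exp(-0.25 t); reachable
  # only with a = 0 below the printed lower bound, so integrate the rhs
  # directly as a structural check
  f <- evaluate_rhs(g, 0, g$x0, rep(0, 13))
  expect_equal(unname(f[8:20]), rep(-0.025, 13))
  # ATP+ADP conservation is structural: f7 = -f6
  set.seed(9)
  x <- abs(rnorm(22)); a <- runif(13, 0.0025, 0.125)
  fr <- evaluate_rhs(g, 0, x, a)
  expect_equal(unname(fr["ADP"]), -unname(fr["ATP"]), tolerance = 1e-12)
})

test_that("the n-step pathway generalizes and reduces to the 3-step model", {
  p3 <- build_linear_pathway(3)
  ref <- build_lpn3b()
  expect_equal(p3$rhs_text, ref$rhs_text)
  expect_equal(p3$x0, ref$x0)
  expect_equal(p3$params, ref$params)
  expect_equal(p3$control_bounds, ref$control_bounds)
  expect_equal(p3$objectives[[2]]$lagrange_text,
               ref$objectives[[2]]$lagrange_text)
  # n = 1: product ODE is S2dot = E_T = 1 at full capacity, so the minimum
  # transition time to S2 = 0.9 is exactly 0.9
  p1 <- build_linear_pathway(1)
  sol <- solve_ocp(p1, "collocation", objective = 1, seed = 1,
                   settings = fast_settings(mesh_intervals = 30L))
  expect_true(sol$feasible)
  expect_equal(unname(sol$objectives[1]), 0.9, tolerance = 1e-3)
})

test_that("LQ fixture admits its closed form", {
  lq <- prepare_problem(build_lq_toy())
  tr <- simulate_ocp(lq, function(t) 1)
  expect_equal(unname(tr$states[nrow(tr$states), "x"]), 1, tolerance = 1e-8)
  expect_equal(unname(evaluate_objectives(lq, tr)), 1, tolerance = 1e-8)
})

test_that("problems round-trip through the config dialect", {
  dir <- withr::local_tempdir()
  for (prob in list(build_lpn3b(), build_sc(), build_bsub("M-G"))) {
    fj <- file.path(dir, paste0(prob$name, ".json"))
    write_ocp(prob, fj)
    back <- load_ocp(fj)
    expect_equal(back$rhs_text, prob$rhs_text)
    expect_equal(back$x0, prob$x0)
    expect_equal(back$params, prob$params)
    expect_equal(back$horizon, prob$horizon)
    expect_equal(length(back$path_constraints), length(prob$path_constraints))
    expect_equal(vapply(back$objectives, `[[`, "", "sense"),
                 vapply(prob$objectives, `[[`, "", "sense"))
    # identical dynamics after the round trip
    set.seed(1)
    x <- abs(rnorm(length(prob$states))); u <- runif(length(prob$controls))
    expect_equal(evaluate_rhs(back, 0, x, u), evaluate_rhs(prob, 0, x, u))
  }
  # YAML variant
  fy <- file.path(dir, "sc.yaml")
  write_ocp(build_sc(), fy)
  backy <- load_ocp(fy)
  expect_equal(backy$x0, build_sc()$x0)
})

test_that("benchmark overrides change the intended parameter only", {
  p <- build_lpn3b(overrides = list(E_T = 2, product_target = 0.5))
  expect_equal(p$path_constraints[[1]]$bound, 2)
  expect_equal(p$point_constraints[[1]]$bound, 0.5)
  expect_equal(p$x0, build_lpn3b()$x0)
  sc <- build_sc(atp_c = 0.4)
  lab <- vapply(sc$path_constraints, `[[`, "", "label")
  expect_equal(sc$path_constraints[[which(lab == "ATP_critical")]]$bound, 0.4)
})
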