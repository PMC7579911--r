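# Dominance filtering, knee identification, anchors and the
# epsilon-constraint sweep on the analytic bi-objective toy.

test_that("filter_dominated keeps exactly the non-dominated points", {
  pts <- rbind(c(1, 3), c(2, 2), c(3, 1), c(2.5, 2.5))
  out <- filter_dominated(pts)
  expect_equal(attr(out, "indices"), 1:3)
  # single point kept; empty input gives empty output
  expect_equal(nrow(filter_dominated(rbind(c(1, 1)))), 1)
  expect_equal(nrow(filter_dominated(matrix(numeric(0), 0, 2))), 0)
})

test_that("filter_dominated agrees with the brute-force pairwise oracle", {
  set.seed(17)
  for (k in 1:5) {
    n <- sample(20:200, 1)
    pts <- matrix(stats::runif(2 * n), n, 2)
    keep <- attr(filter_dominated(pts), "indices")
    oracle <- vapply(seq_len(n), function(q) {
      !any(vapply(seq_len(n), function(p)
        p != q && all(pts[p, ] <= pts[q, ]) && any(pts[p, ] < pts[q, ]),
        TRUE))
    }, TRUE)
    expect_equal(keep, which(oracle))
  }
})

test_that("knee_point maximizes normalized distance to the anchor chord", {
  J <- rbind(c(0, 1), c(0.2, 0.3), c(1, 0))
  expect_equal(knee_point(J), 2L)
  # scaling one objective by 1000 does not change the knee
  J2 <- J %*% diag(c(1, 1000))
  expect_equal(knee_point(J2), 2L)
  # colinear front: first interior point, flagged flat
  J3 <- rbind(c(0, 1), c(0.3, 0.7), c(0.6, 0.4), c(1, 0))
  k3 <- knee_point(J3)
  expect_equal(as.integer(k3), 2L)
  expect_true(isTRUE(attr(k3, "flat")))
  expect_error(knee_point(J[1:2, ]), "no interior point")
})

test_that("anchors of the bi-objective toy match the closed form", {
  # J1 = int u^2 (min): u = 0, (J1, J2) = (0, 0)
  # J2 = -x(1) (min): u = 1, (J1, J2) = (1, -1)
  p <- biobjective_toy()
  a1 <- solve_anchor(p, 1, strategy = "collocation", seed = 1,
                     settings = fast_settings())
  expect_true(a1$feasible)
  expect_equal(unname(a1$objectives), c(0, 0), tolerance = 1e-3)
  a2 <- solve_anchor(p, 2, strategy = "collocation", seed = 1,
                     settings = fast_settings())
  expect_true(a2$feasible)
  expect_equal(unname(a2$objectives), c(1, -1), tolerance = 1e-3)
})

test_that("the epsilon-constraint sweep traces the closed-form toy front", {
  # front: J1 = c^2, J2 = -c for c in [0, 1]
  p <- biobjective_toy()
  front <- epsilon_constraint_sweep(p, primary_index = 1, n_points = 5,
                                    strategy = "collocation", seed = 1,
                                    settings = fast_settings())
  J <- front$objectives
  expect_equal(nrow(J), 5)
  cvals <- -J[, 2]
  expect_equal(unname(J[, 1]), cvals^2, tolerance = 2e-3)
  expect_equal(sort(cvals), seq(0, 1, length.out = 5), tolerance = 2e-3)
  # 2-D monotonicity: sorted by J1, J2 non-increasing
  expect_true(all(diff(J[order(J[, 1]), 2]) <= 1e-9))
  # anchors bound the front on their own objectives
  expect_lte(min(J[, 1]), J[front$anchors[1], 1] + 1e-9)
  # n_points = 2 returns exactly the anchors
  f2 <- epsilon_constraint_sweep(p, primary_index = 1, n_points = 2,
                                 strategy = "collocation", seed = 1,
                                 settings = fast_settings())
  expect_equal(nrow(f2$objectives), 2)
  expect_equal(sort(f2$anchors), 1:2)
})

test_that("single-objective problems bypass the epsilon machinery", {
  p <- prepare_problem(build_lq_toy())
  expect_error(epsilon_constraint_sweep(build_lq_toy(), n_points = 3),
               "at least two objectives")
})
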