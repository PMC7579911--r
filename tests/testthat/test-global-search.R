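# Scatter search, multistart and the augmented-Lagrangian local solver on
# closed-form finite-dimensional problems.

test_that("scatter search finds convex and multimodal 1-D optima", {
  n1 <- toy_nlp(1, -10, 10, function(y) (y - 3)^2)
  r <- scatter_search(n1, list(seed = 1, max_evals = 400))
  expect_equal(r$y_best, 3, tolerance = 1e-4)
  # multimodal (Rastrigin form): global minimum 0 at y = 0
  n2 <- toy_nlp(1, -5.12, 5.12,
                function(y) y^2 + 10 * (1 - cos(2 * pi * y)))
  hits <- 0
  for (s in 1:5) {
    r2 <- scatter_search(n2, list(seed = s, max_evals = 2500))
    if (abs(r2$y_best) < 1e-3) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("identical seed and settings reproduce the result exactly", {
  n2 <- toy_nlp(2, c(-5.12, -5.12), c(5.12, 5.12),
                function(y) sum(y^2 + 10 * (1 - cos(2 * pi * y))))
  ra <- scatter_search(n2, list(seed = 7, max_evals = 700))
  rb <- scatter_search(n2, list(seed = 7, max_evals = 700))
  expect_identical(ra$y_best, rb$y_best)
  expect_identical(ra$history, rb$history)
  expect_identical(ra$cost, rb$cost)
  expect_error(scatter_search(n2, list(max_evals = 0)),
               "no evaluations allowed")
})

test_that("the best-cost trace is monotone non-increasing", {
  n2 <- toy_nlp(3, -4, 4, function(y) sum((y - c(1, -2, 0.5))^2) +
                  0.3 * sin(10 * y[1]))
  r <- scatter_search(n2, list(seed = 5, max_evals = 900))
  expect_true(all(diff(r$history[, "best_cost"]) <= 1e-12))
  rm <- multistart(n2, n_starts = 4, seed = 2)
  expect_true(all(diff(rm$history[, "best_cost"]) <= 1e-12))
})

test_that("local_solve reaches KKT points of constrained quadratics", {
  # min y1^2 + y2^2 s.t. y1 + y2 = 1 -> (0.5, 0.5), multiplier -1
  n3 <- toy_nlp(2, -5, 5, function(y) sum(y^2), eq = function(y) sum(y) - 1)
  r3 <- local_solve(n3, c(0, 0))
  expect_equal(r3$y, c(0.5, 0.5), tolerance = 1e-4)
  expect_true(r3$feasible)
  expect_equal(r3$nu_eq, -1, tolerance = 1e-2)
  # starting at the optimum returns the same point (within solver tolerance)
  r4 <- local_solve(n3, c(0.5, 0.5))
  expect_equal(r4$y, c(0.5, 0.5), tolerance = 1e-4)
})

test_that("local_solve matches closed-form KKT solutions of random convex QPs", {
  # min 0.5 y'Qy + q'y  s.t.  a'y = b: KKT system solved directly as oracle
  set.seed(99)
  for (k in 1:4) {
    n <- sample(2:5, 1)
    A <- matrix(rnorm(n * n), n)
    Q <- crossprod(A) + diag(n)
    q <- rnorm(n)
    a <- rnorm(n); b <- rnorm(1)
    K <- rbind(cbind(Q, a), c(a, 0))
    sol <- solve(K, c(-q, b))
    y_star <- sol[1:n]
    if (max(abs(y_star)) > 4) next   # keep the optimum inside the box
    nlp <- toy_nlp(n, -5, 5,
                   function(y) 0.5 * sum(y * (Q %*% y)) + sum(q * y),
                   eq = function(y) sum(a * y) - b)
    r <- local_solve(nlp, rep(0, n),
                     control = list(feas_tol = 1e-9, opt_tol = 1e-9,
                                    fd_central = TRUE, factr = 10))
    expect_lt(max(abs(r$y - y_star)), 1e-6)
  }
})

test_that("multistart retains both basins of a double well", {
  # f(y) = (y^2 - 1)^2 has minima at -1 and +1
  nw <- toy_nlp(1, -2, 2, function(y) (y^2 - 1)^2)
  r <- multistart(nw, n_starts = 12, seed = 4)
  ends <- vapply(r$ensemble, function(e) e$y, 0)
  expect_true(any(abs(ends - 1) < 1e-3))
  expect_true(any(abs(ends + 1) < 1e-3))
  expect_equal(r$cost, 0, tolerance = 1e-6)
  # convex case: all starts coincide
  nc <- toy_nlp(2, -3, 3, function(y) sum((y - 0.3)^2))
  rc <- multistart(nc, n_starts = 5, seed = 1)
  ends2 <- t(vapply(rc$ensemble, function(e) e$y, numeric(2)))
  expect_lt(max(apply(ends2, 2, stats::sd)), 1e-3)
})

test_that("feasibility-first comparison prefers feasible points", {
  # infeasible low-cost trap: constraint y >= 2 with cost y^2
  nf <- toy_nlp(1, -5, 5, function(y) y^2, ineq = function(y) 2 - y)
  r <- scatter_search(nf, list(seed = 3, max_evals = 500))
  expect_true(r$feasible)
  expect_equal(r$y_best, 2, tolerance = 1e-3)
})
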