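# Simultaneous (complete discretization) transcription.
#
# States and controls are both discretized on a mesh; the ODE is imposed
# through trapezoidal defect constraints
#   x_{i+1} - x_i - (h_i/2) (f_i + f_{i+1}) = 0
# (the two-stage Runge-Kutta scheme with beta = (1/2, 1/2)). Controls are
# node values with piecewise-linear interpolation between nodes. Cost
# gradient, constraint Jacobian (sparse) and Hessian of the Lagrangian are
# assembled from symbolic derivatives of the model expressions. The NLP
# multipliers of the converged solve estimate the continuous adjoints.

#' Collocation mesh
#'
#' @param problem canonical \code{ocp_problem} (fixed horizon).
#' @param n_intervals number of mesh intervals rho (rho + 1 nodes).
#' @param nodes explicit increasing node vector spanning the horizon
#'   (overrides \code{n_intervals}).
#' @return an object of class \code{ocp_mesh}.
#' @export
collocation_mesh <- function(problem, n_intervals = 100, nodes = NULL) {
  t0 <- problem$horizon$t0; tfv <- problem$horizon$tf
  if (is.null(nodes)) nodes <- seq(t0, tfv, length.out = n_intervals + 1)
  if (abs(nodes[1] - t0) > 1e-12 || abs(nodes[length(nodes)] - tfv) > 1e-12)
    stop("mesh error: nodes must span the horizon")
  h <- diff(nodes)
  if (any(h <= 0)) stop("mesh error: nodes must be strictly increasing")
  structure(list(nodes = nodes, h = h), class = "ocp_mesh")
}

# Symbolic partials of every rhs/constraint/objective expression with respect
# to states, controls and decision parameters. NULL entries are structural
# zeros.
symbolic_partials <- function(prob) {
  vars <- c(prob$states, prob$controls, names(prob$decision_params))
  dfd <- lapply(prob$rhs, function(ex)
    lapply(stats::setNames(vars, vars), function(v) expr_deriv(ex, v)))
  dfd
}

#' Transcribe an OCP with the trapezoidal collocation scheme
#'
#' @param problem canonical \code{ocp_problem} (pure Mayer, fixed horizon).
#' @param mesh an \code{\link{collocation_mesh}}.
#' @param objective index of the objective to minimize (scalarized with its
#'   declared sense).
#' @param derivatives attach analytic derivative callbacks (default TRUE).
#' @return a discretized NLP (class \code{dnlp}) whose decision vector is all
#'   node states, all node controls and the free decision parameters.
#' @export
transcribe_trapezoidal <- function(problem, mesh, objective = 1L,
                                   derivatives = TRUE) {
  if (any(vapply(problem$objectives, function(o) !is.null(o$lagrange_text), TRUE)))
    stop("problem must be augmented to pure Mayer first (augment_lagrange)")
  if (problem$horizon$tf_mode != "fixed")
    stop("problem must have a fixed (possibly normalized) horizon")
  ns <- n_states(problem); nu <- n_controls(problem)
  nodes <- mesh$nodes; h <- mesh$h
  Np <- length(nodes); N <- Np - 1L
  dpn <- names(problem$decision_params); ndp <- length(dpn)
  n <- (ns + nu) * Np + ndp
  xind <- function(s) ((s - 1L) * Np + 1L):(s * Np)
  uind <- function(j) (ns * Np + (j - 1L) * Np + 1L):(ns * Np + j * Np)
  dpind <- if (ndp) ((ns + nu) * Np + 1L):n else integer(0)
  layout <- list(Np = Np, ns = ns, nu = nu, xind = xind, uind = uind,
                 dpind = dpind, dpn = dpn,
                 states = problem$states, controls = problem$controls)

  lower <- c(rep(-Inf, ns * Np),
             rep(problem$control_bounds$lower, each = Np),
             vapply(problem$decision_params, `[[`, 0, 1L))
  upper <- c(rep(Inf, ns * Np),
             rep(problem$control_bounds$upper, each = Np),
             vapply(problem$decision_params, `[[`, 0, 2L))

  ob <- problem$objectives[[objective]]
  sgn <- if (ob$sense == "max") -1 else 1
  rhs_vec <- make_rhs_fn_vec(problem)

  pt_eq <- Filter(function(p) p$rel == "==", problem$point_constraints)
  pt_in <- Filter(function(p) p$rel != "==", problem$point_constraints)
  pc_node <- function(pc) if (identical(pc$time, "t0")) 1L
    else if (identical(pc$time, "tf")) Np
    else which.min(abs(nodes - pc$time))
  npath <- length(problem$path_constraints)
  eq_names <- c(sprintf("defect_%s_%d", rep(problem$states, each = N),
                        rep(seq_len(N), ns)),
                sprintf("init_%s", problem$states),
                vapply(pt_eq, `[[`, "", "label"))
  ineq_names <- c(unlist(lapply(problem$path_constraints, function(p)
                    sprintf("%s@n%d", p$label, seq_len(Np)))),
                  vapply(pt_in, `[[`, "", "label"))

  unpack <- function(y) {
    X <- matrix(y[seq_len(ns * Np)], Np, ns)
    U <- if (nu) matrix(y[ns * Np + seq_len(nu * Np)], Np, nu)
         else matrix(0, Np, 0)
    dp <- if (ndp) stats::setNames(y[dpind], dpn) else NULL
    list(X = X, U = U, dp = dp)
  }

  eval_fn <- function(y) {
    z <- unpack(y)
    Fm <- rhs_vec(z$X, z$U, z$dp, nodes)
    defect <- z$X[-1L, , drop = FALSE] - z$X[-Np, , drop = FALSE] -
      (h / 2) * (Fm[-1L, , drop = FALSE] + Fm[-Np, , drop = FALSE])
    eq <- c(as.numeric(defect), z$X[1L, ] - unname(problem$x0))
    b_all <- make_bindings(problem, x = z$X, u = z$U, dp = z$dp, t = nodes,
                           tf = if ("tf" %in% dpn) z$dp[["tf"]]
                                else problem$horizon$tf)
    for (pc in pt_eq) {
      i <- pc_node(pc)
      bi <- make_bindings(problem, x = z$X[i, ], u = z$U[i, ], dp = z$dp,
                          t = nodes[i],
                          tf = if ("tf" %in% dpn) z$dp[["tf"]]
                               else problem$horizon$tf)
      eq <- c(eq, as.numeric(eval_model_expr(pc$expr, bi)) - pc$bound)
    }
    ineq <- numeric(0)
    for (pc in problem$path_constraints) {
      val <- rep_len(as.numeric(eval_model_expr(pc$expr, b_all)), Np)
      ineq <- c(ineq, if (pc$dir == "<=") val - pc$bound else pc$bound - val)
    }
    for (pc in pt_in) {
      i <- pc_node(pc)
      bi <- make_bindings(problem, x = z$X[i, ], u = z$U[i, ], dp = z$dp,
                          t = nodes[i],
                          tf = if ("tf" %in% dpn) z$dp[["tf"]]
                               else problem$horizon$tf)
      v <- as.numeric(eval_model_expr(pc$expr, bi))
      ineq <- c(ineq, if (pc$rel == "<=") v - pc$bound else pc$bound - v)
    }
    bf <- make_bindings(problem, x = z$X[Np, ], u = z$U[Np, ], dp = z$dp,
                        t = nodes[Np],
                        tf = if ("tf" %in% dpn) z$dp[["tf"]]
                             else problem$horizon$tf)
    cost <- sgn * as.numeric(eval_model_expr(ob$mayer, bf))
    list(cost = cost, eq = eq, ineq = ineq, ok = TRUE)
  }

  # default initial guess: constant states at x0, mid-bound controls,
  # mid-bound decision parameters
  umid <- (pmax(problem$control_bounds$lower, -1e3) +
           pmin(problem$control_bounds$upper, 1e3)) / 2
  y0 <- c(rep(unname(problem$x0), each = Np),
          rep(umid, each = Np),
          vapply(problem$decision_params, mean, 0))

  nlp <- structure(list(
    n = n, lower = lower, upper = upper, y0 = y0,
    eval = eval_fn, grad = NULL, hess = NULL,
    layout = layout, eq_names = eq_names, ineq_names = ineq_names,
    meta = list(kind = "collocation", problem = problem, mesh = mesh,
                objective = objective, sgn = sgn,
                n_defect = N * ns, n_init = ns, n_pt_eq = length(pt_eq),
                npath = npath, n_pt_in = length(pt_in))
  ), class = "dnlp")
  if (derivatives) {
    d <- assemble_derivatives(problem, mesh, objective = objective)
    nlp$grad <- d$grad
    nlp$grad_lag <- d$grad_lag
    nlp$hess <- d$hess
    nlp$jacobian <- d$jacobian
  }
  nlp
}

#' Assemble analytic derivative callbacks for a trapezoidal transcription
#'
#' Generates, by symbolic differentiation of the model expressions, the exact
#' cost gradient, the sparse constraint Jacobian (equalities and inequalities
#' separately, with a fixed sparsity pattern) and the Hessian of the
#' Lagrangian \code{sigma * F + nu' c_eq + mu' c_ineq} (dense; intended for
#' verification and moderate mesh sizes).
#'
#' @param problem canonical \code{ocp_problem}.
#' @param mesh an \code{\link{collocation_mesh}}.
#' @param objective objective index.
#' @return list with functions \code{grad(y)} (list: cost, jac_eq, jac_ineq),
#'   \code{jacobian(y)} (single sparse matrix, equality rows first) and
#'   \code{hess(y, sigma, nu_eq, mu_in)}.
#' @export
assemble_derivatives <- function(problem, mesh, objective = 1L) {
  ns <- n_states(problem); nu <- n_controls(problem)
  nodes <- mesh$nodes; h <- mesh$h
  Np <- length(nodes); N <- Np - 1L
  dpn <- names(problem$decision_params); ndp <- length(dpn)
  n <- (ns + nu) * Np + ndp
  xcol <- function(s, i) (s - 1L) * Np + i
  ucol <- function(j, i) ns * Np + (j - 1L) * Np + i
  dpcol <- function(d) (ns + nu) * Np + d
  ob <- problem$objectives[[objective]]
  sgn <- if (ob$sense == "max") -1 else 1
  vars_x <- problem$states; vars_u <- problem$controls

  dfdx <- lapply(problem$rhs, function(ex)
    lapply(stats::setNames(vars_x, vars_x), function(v) expr_deriv(ex, v)))
  dfdu <- lapply(problem$rhs, function(ex)
    lapply(stats::setNames(vars_u, vars_u), function(v) expr_deriv(ex, v)))
  dfdp <- lapply(problem$rhs, function(ex)
    lapply(stats::setNames(dpn, dpn), function(v) expr_deriv(ex, v)))

  pt_eq <- Filter(function(p) p$rel == "==", problem$point_constraints)
  pt_in <- Filter(function(p) p$rel != "==", problem$point_constraints)
  pc_node <- function(pc) if (identical(pc$time, "t0")) 1L
    else if (identical(pc$time, "tf")) Np
    else which.min(abs(nodes - pc$time))
  defect_row <- function(s, i) (s - 1L) * N + i   # i = interval index

  unpack <- function(y) {
    X <- matrix(y[seq_len(ns * Np)], Np, ns)
    U <- if (nu) matrix(y[ns * Np + seq_len(nu * Np)], Np, nu)
         else matrix(0, Np, 0)
    dp <- if (ndp) stats::setNames(y[(ns + nu) * Np + seq_len(ndp)], dpn)
          else NULL
    list(X = X, U = U, dp = dp)
  }
  bind_all <- function(z) make_bindings(problem, x = z$X, u = z$U, dp = z$dp,
                                        t = nodes,
                                        tf = if ("tf" %in% dpn) z$dp[["tf"]]
                                             else problem$horizon$tf)

  # ---- equality Jacobian pattern (triplets; values recomputed per call) ----
  iv <- seq_len(N)
  plan_eq <- list()   # each: rows, cols, value(...) closure
  for (s in seq_len(ns)) {
    plan_eq[[length(plan_eq) + 1L]] <- list(
      rows = defect_row(s, iv), cols = xcol(s, iv), const = rep(-1, N))
    plan_eq[[length(plan_eq) + 1L]] <- list(
      rows = defect_row(s, iv), cols = xcol(s, iv + 1L), const = rep(1, N))
  }
  # nonlinear parts: -h/2 * partial at left and right node of each interval
  dyn_eq <- list()    # each: rows, cols, expr, node ("L" or "R")
  add_dyn <- function(s, dex, colfun) {
    dyn_eq[[length(dyn_eq) + 1L]] <<- list(
      rows = defect_row(s, iv), cols = colfun(iv), expr = dex, side = "L")
    dyn_eq[[length(dyn_eq) + 1L]] <<- list(
      rows = defect_row(s, iv), cols = colfun(iv + 1L), expr = dex, side = "R")
  }
  for (s in seq_len(ns)) {
    for (s2 in seq_len(ns)) {
      dex <- dfdx[[s]][[s2]]
      if (!is.null(dex)) add_dyn(s, dex, function(i) xcol(s2, i))
    }
    for (j in seq_len(nu)) {
      dex <- dfdu[[s]][[j]]
      if (!is.null(dex)) add_dyn(s, dex, function(i) ucol(j, i))
    }
    for (d in seq_len(ndp)) {
      dex <- dfdp[[s]][[d]]
      if (!is.null(dex)) add_dyn(s, dex, function(i) rep(dpcol(d), length(i)))
    }
  }
  # initial conditions
  init_rows <- N * ns + seq_len(ns)
  init_cols <- vapply(seq_len(ns), function(s) xcol(s, 1L), 0L)
  # point equality constraints
  pt_eq_plan <- lapply(seq_along(pt_eq), function(k) {
    pc <- pt_eq[[k]]
    i <- pc_node(pc)
    dd <- c(lapply(stats::setNames(vars_x, vars_x), function(v)
              expr_deriv(pc$expr, v)),
            lapply(stats::setNames(vars_u, vars_u), function(v)
              expr_deriv(pc$expr, v)),
            lapply(stats::setNames(dpn, dpn), function(v)
              expr_deriv(pc$expr, v)))
    cols <- c(vapply(seq_len(ns), function(s) xcol(s, i), 0L),
              if (nu) vapply(seq_len(nu), function(j) ucol(j, i), 0L),
              if (ndp) vapply(seq_len(ndp), dpcol, 0L))
    keep <- !vapply(dd, is.null, TRUE)
    list(row = N * ns + ns + k, node = i, cols = cols[keep], dd = dd[keep])
  })
  n_eq <- N * ns + ns + length(pt_eq)

  # ---- inequality Jacobian pattern ----
  npath <- length(problem$path_constraints)
  path_plan <- lapply(seq_along(problem$path_constraints), function(k) {
    pc <- problem$path_constraints[[k]]
    sgn_pc <- if (pc$dir == "<=") 1 else -1
    dd <- c(lapply(stats::setNames(vars_x, vars_x), function(v)
              expr_deriv(pc$expr, v)),
            lapply(stats::setNames(vars_u, vars_u), function(v)
              expr_deriv(pc$expr, v)),
            lapply(stats::setNames(dpn, dpn), function(v)
              expr_deriv(pc$expr, v)))
    colfun <- c(lapply(seq_len(ns), function(s) function(i) xcol(s, i)),
                lapply(seq_len(nu), function(j) function(i) ucol(j, i)),
                lapply(seq_len(ndp), function(d) function(i)
                  rep(dpcol(d), length(i))))
    keep <- !vapply(dd, is.null, TRUE)
    list(rows0 = (k - 1L) * Np, sgn = sgn_pc, dd = dd[keep],
         colfun = colfun[keep])
  })
  pt_in_plan <- lapply(seq_along(pt_in), function(k) {
    pc <- pt_in[[k]]
    i <- pc_node(pc)
    sgn_pc <- if (pc$rel == "<=") 1 else -1
    dd <- c(lapply(stats::setNames(vars_x, vars_x), function(v)
              expr_deriv(pc$expr, v)),
            lapply(stats::setNames(vars_u, vars_u), function(v)
              expr_deriv(pc$expr, v)),
            lapply(stats::setNames(dpn, dpn), function(v)
              expr_deriv(pc$expr, v)))
    cols <- c(vapply(seq_len(ns), function(s) xcol(s, i), 0L),
              if (nu) vapply(seq_len(nu), function(j) ucol(j, i), 0L),
              if (ndp) vapply(seq_len(ndp), dpcol, 0L))
    keep <- !vapply(dd, is.null, TRUE)
    list(row = npath * Np + k, node = i, sgn = sgn_pc,
         cols = cols[keep], dd = dd[keep])
  })
  n_in <- npath * Np + length(pt_in)

  # ---- cost gradient pattern ----
  dmayer <- c(lapply(stats::setNames(vars_x, vars_x), function(v)
                expr_deriv(ob$mayer, v)),
              lapply(stats::setNames(dpn, dpn), function(v)
                expr_deriv(ob$mayer, v)))
  mayer_cols <- c(vapply(seq_len(ns), function(s) xcol(s, Np), 0L),
                  if (ndp) vapply(seq_len(ndp), dpcol, 0L))
  keep_m <- !vapply(dmayer, is.null, TRUE)
  dmayer <- dmayer[keep_m]; mayer_cols <- mayer_cols[keep_m]

  eval_dex <- function(dex, b, Np) {
    if (is.numeric(dex)) rep_len(dex, Np)
    else rep_len(as.numeric(eval_model_expr(dex, b)), Np)
  }

  # static sparsity patterns: row/col index vectors are fixed, only the value
  # vectors change between calls
  eq_ii <- c(unlist(lapply(plan_eq, `[[`, "rows")),
             unlist(lapply(dyn_eq, `[[`, "rows")),
             init_rows,
             unlist(lapply(pt_eq_plan, function(pl)
               rep(pl$row, length(pl$cols)))))
  eq_jj <- c(unlist(lapply(plan_eq, `[[`, "cols")),
             unlist(lapply(dyn_eq, `[[`, "cols")),
             init_cols,
             unlist(lapply(pt_eq_plan, `[[`, "cols")))
  eq_const <- unlist(lapply(plan_eq, `[[`, "const"))
  in_ii <- c(unlist(lapply(path_plan, function(pl)
               rep(pl$rows0 + seq_len(Np), length(pl$dd)))),
             unlist(lapply(pt_in_plan, function(pl)
               rep(pl$row, length(pl$cols)))))
  in_jj <- c(unlist(lapply(path_plan, function(pl)
               unlist(lapply(pl$colfun, function(f) f(seq_len(Np)))))),
             unlist(lapply(pt_in_plan, `[[`, "cols")))

  jac_pair <- function(y) {
    z <- unpack(y)
    b <- bind_all(z)
    dyn_vals <- lapply(dyn_eq, function(pl) {
      v <- eval_dex(pl$expr, b, Np)
      if (pl$side == "L") -(h / 2) * v[iv] else -(h / 2) * v[iv + 1L]
    })
    pt_vals <- lapply(pt_eq_plan, function(pl)
      vapply(pl$dd, function(dd) eval_dex(dd, b, Np)[pl$node], 0))
    xx_eq <- c(eq_const, unlist(dyn_vals), rep(1, ns), unlist(pt_vals))
    jac_eq <- Matrix::sparseMatrix(i = eq_ii, j = eq_jj, x = xx_eq,
                                   dims = c(n_eq, n))
    path_vals <- lapply(path_plan, function(pl)
      unlist(lapply(pl$dd, function(dd) pl$sgn * eval_dex(dd, b, Np))))
    ptin_vals <- lapply(pt_in_plan, function(pl)
      vapply(pl$dd, function(dd) pl$sgn * eval_dex(dd, b, Np)[pl$node], 0))
    xx_in <- c(unlist(path_vals), unlist(ptin_vals))
    jac_in <- if (length(in_ii))
      Matrix::sparseMatrix(i = in_ii, j = in_jj, x = xx_in, dims = c(n_in, n))
      else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n_in, n))
    list(jac_eq = jac_eq, jac_ineq = jac_in)
  }

  grad_fn <- function(y) {
    z <- unpack(y)
    b <- bind_all(z)
    g <- numeric(n)
    for (k in seq_along(dmayer))
      g[mayer_cols[k]] <- g[mayer_cols[k]] +
        sgn * eval_dex(dmayer[[k]], b, Np)[Np]
    jp <- jac_pair(y)
    list(cost = g, jac_eq = jp$jac_eq, jac_ineq = jp$jac_ineq)
  }

  # fast gradient of F + w_eq' c + w_in' g without sparse-matrix assembly:
  # precomputed scatter orders turn the J' w products into cumsum-diff
  # accumulations over the static triplet patterns
  make_jtv <- function(jjv) {
    o <- order(jjv)
    jo <- jjv[o]
    ends <- c(which(diff(jo) != 0L), length(jo))
    cols <- jo[ends]
    function(vals, g) {
      cs <- cumsum(vals[o])
      sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
      g[cols] <- g[cols] + sums
      g
    }
  }
  jtv_eq <- make_jtv(eq_jj)
  jtv_in <- if (length(in_jj)) make_jtv(in_jj) else NULL

  grad_lag_fn <- function(y, w_eq, w_in) {
    z <- unpack(y)
    b <- bind_all(z)
    g <- numeric(n)
    for (k in seq_along(dmayer))
      g[mayer_cols[k]] <- g[mayer_cols[k]] +
        sgn * eval_dex(dmayer[[k]], b, Np)[Np]
    dyn_vals <- lapply(dyn_eq, function(pl) {
      v <- eval_dex(pl$expr, b, Np)
      if (pl$side == "L") -(h / 2) * v[iv] else -(h / 2) * v[iv + 1L]
    })
    pt_vals <- lapply(pt_eq_plan, function(pl)
      vapply(pl$dd, function(dd) eval_dex(dd, b, Np)[pl$node], 0))
    xx_eq <- c(eq_const, unlist(dyn_vals), rep(1, ns), unlist(pt_vals))
    g <- jtv_eq(xx_eq * w_eq[eq_ii], g)
    if (!is.null(jtv_in) && length(w_in)) {
      path_vals <- lapply(path_plan, function(pl)
        unlist(lapply(pl$dd, function(dd) pl$sgn * eval_dex(dd, b, Np))))
      ptin_vals <- lapply(pt_in_plan, function(pl)
        vapply(pl$dd, function(dd) pl$sgn * eval_dex(dd, b, Np)[pl$node], 0))
      xx_in <- c(unlist(path_vals), unlist(ptin_vals))
      g <- jtv_in(xx_in * w_in[in_ii], g)
    }
    g
  }

  # ---- Hessian of the Lagrangian (sparse, symmetric) ----
  vars_all <- c(vars_x, vars_u, dpn)
  colfun_all <- c(lapply(seq_len(ns), function(s) function(i) xcol(s, i)),
                  lapply(seq_len(nu), function(j) function(i) ucol(j, i)),
                  lapply(seq_len(ndp), function(d) function(i)
                    rep(dpcol(d), length(i))))
  d2_of <- function(ex) {
    out <- list()
    for (a in seq_along(vars_all)) {
      da <- expr_deriv(ex, vars_all[a])
      if (is.null(da)) next
      for (bv in a:length(vars_all)) {
        dab <- expr_deriv(da, vars_all[bv])
        if (is.null(dab)) next
        out[[length(out) + 1L]] <- list(a = a, b = bv, expr = dab)
      }
    }
    out
  }
  d2f <- lapply(problem$rhs, d2_of)
  d2mayer <- d2_of(ob$mayer)
  d2path <- lapply(problem$path_constraints, function(pc) d2_of(pc$expr))
  d2pt <- lapply(c(pt_eq, pt_in), function(pc) d2_of(pc$expr))

  hess_fn <- function(y, sigma = 1, nu_eq = rep(0, n_eq),
                      mu_in = rep(0, n_in)) {
    z <- unpack(y)
    b <- bind_all(z)
    iv_all <- seq_len(Np)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    addH <- function(r, c, v) {
      keep <- v != 0
      if (!any(keep)) return(invisible())
      r <- r[keep]; c <- c[keep]; v <- v[keep]
      off <- r != c
      ii <<- c(ii, r, c[off]); jj <<- c(jj, c, r[off]); xx <<- c(xx, v, v[off])
    }
    # node weights on f_s from the defect multipliers
    numat <- matrix(nu_eq[seq_len(N * ns)], N, ns)
    W <- matrix(0, Np, ns)
    W[1L, ] <- -(h[1L] / 2) * numat[1L, ]
    W[Np, ] <- -(h[N] / 2) * numat[N, ]
    if (Np > 2L)
      W[2L:N, ] <- -(h[2L:N] / 2) * numat[2L:N, , drop = FALSE] -
                    (h[1L:(N - 1L)] / 2) * numat[1L:(N - 1L), , drop = FALSE]
    for (s in seq_len(ns)) {
      for (term in d2f[[s]]) {
        v <- eval_dex(term$expr, b, Np)
        addH(colfun_all[[term$a]](iv_all), colfun_all[[term$b]](iv_all),
             W[, s] * v)
      }
    }
    for (term in d2mayer) {
      v <- eval_dex(term$expr, b, Np)[Np]
      addH(colfun_all[[term$a]](Np), colfun_all[[term$b]](Np), sigma * sgn * v)
    }
    for (k in seq_along(d2path)) {
      pc <- problem$path_constraints[[k]]
      sgn_pc <- if (pc$dir == "<=") 1 else -1
      mus <- mu_in[(k - 1L) * Np + seq_len(Np)]
      for (term in d2path[[k]]) {
        v <- eval_dex(term$expr, b, Np)
        addH(colfun_all[[term$a]](iv_all), colfun_all[[term$b]](iv_all),
             sgn_pc * mus * v)
      }
    }
    all_pt <- c(pt_eq, pt_in)
    for (k in seq_along(all_pt)) {
      pc <- all_pt[[k]]
      i <- pc_node(pc)
      m <- if (k <= length(pt_eq)) nu_eq[N * ns + ns + k]
           else {
             sgn_pc <- if (pc$rel == "<=") 1 else -1
             sgn_pc * mu_in[npath * Np + (k - length(pt_eq))]
           }
      if (m == 0) next
      for (term in d2pt[[k]]) {
        v <- eval_dex(term$expr, b, Np)[i]
        addH(colfun_all[[term$a]](i), colfun_all[[term$b]](i), m * v)
      }
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  }

  jacobian_fn <- function(y) {
    jp <- jac_pair(y)
    rbind(jp$jac_eq, jp$jac_ineq)
  }

  list(grad = grad_fn, grad_lag = grad_lag_fn, jacobian = jacobian_fn,
       hess = hess_fn, n_eq = n_eq, n_in = n_in)
}

#' Solve a collocation NLP
#'
#' Runs the augmented-Lagrangian local solver from a supplied guess (clipped
#' to bounds with a warning if outside) at tight feasibility (the collocation
#' constraints are exact algebra, so 1e-8 feasibility is cheap) and returns
#' the reassembled trajectories plus the full multiplier set.
#'
#' @param nlp a collocation \code{dnlp} from
#'   \code{\link{transcribe_trapezoidal}}.
#' @param guess decision vector (e.g. from \code{\link{warm_start_from}});
#'   defaults to \code{nlp$y0}.
#' @param control control overrides for \code{\link{local_solve}}.
#' @return list with \code{result} (the local-solve result), \code{traj}
#'   (node trajectory), \code{mult} (a \code{multiplier_set}), \code{cost}
#'   and \code{feasible}.
#' @export
solve_collocation <- function(nlp, guess = NULL, control = list()) {
  stopifnot(identical(nlp$meta$kind, "collocation"))
  if (!is.null(guess)) {
    clipped <- pmin(pmax(guess, nlp$lower), nlp$upper)
    if (max(abs(clipped - guess)) > 1e-10)
      warning("guess outside bounds; clipped")
    guess <- clipped
  }
  ctl <- utils::modifyList(
    list(feas_tol = 1e-6, opt_tol = 1e-7, maxit_outer = 20L,
         maxit_inner = 400L, rho0 = 100, factr = 1e3,
         kkt_refine = TRUE, kkt_feas_tol = 1e-9, kkt_steps = 10L),
    control)
  res <- local_solve(nlp, y0 = guess,
                     control = ctl[setdiff(names(ctl),
                                           c("kkt_refine", "kkt_feas_tol",
                                             "kkt_steps"))])
  if (isTRUE(ctl$kkt_refine) && !is.null(nlp$hess))
    res <- kkt_refine(nlp, res, feas_tol = ctl$kkt_feas_tol,
                      max_steps = ctl$kkt_steps)
  collocation_solution(nlp, res)
}

# Newton active-set refinement of an approximate KKT point: with the active
# inequalities and bounds pinned as equalities, each step solves the SQP
# equality-QP system [H J'; J 0] [dy; lambda+] = [-grad F; -c] built from the
# analytic sparse Hessian of the Lagrangian and constraint Jacobian. This
# sharpens both the iterate and the multipliers (hence the adjoint estimates)
# to near machine precision when the active set is stable.
kkt_refine <- function(nlp, res, feas_tol = 1e-9, opt_tol = 1e-7,
                       max_steps = 12L, act_tol = 1e-6) {
  y <- res$y; nu <- res$nu_eq; mu <- res$mu_in
  n <- nlp$n
  lower <- nlp$lower; upper <- nlp$upper
  best <- res; best_kkt <- Inf
  # working-set bookkeeping: bounds/inequalities released on a wrong-sign
  # multiplier stay out for the next step (classic active-set update)
  drop_in <- integer(0); drop_lo <- integer(0); drop_hi <- integer(0)
  bound_mult <- rep(0, n)
  for (step in seq_len(max_steps)) {
    e <- nlp$eval(y); gr <- nlp$grad(y)
    n_in <- length(e$ineq)
    act_in <- setdiff(which(e$ineq > -act_tol | mu > 1e-8), drop_in)
    at_lo <- setdiff(which(is.finite(lower) &
                             y - lower <= act_tol * (1 + abs(lower))),
                     drop_lo)
    at_hi <- setdiff(setdiff(which(is.finite(upper) &
                                     upper - y <= act_tol * (1 + abs(upper))),
                             at_lo), drop_hi)
    nb <- length(at_lo) + length(at_hi)
    Jb <- Matrix::sparseMatrix(i = seq_len(nb), j = c(at_lo, at_hi),
                               x = rep(1, nb), dims = c(nb, n))
    J <- rbind(gr$jac_eq, gr$jac_ineq[act_in, , drop = FALSE], Jb)
    cvec <- c(e$eq, e$ineq[act_in],
              y[at_lo] - lower[at_lo], y[at_hi] - upper[at_hi])
    m <- nrow(J)
    H <- nlp$hess(y, 1, nu, mu)
    lam_cur <- c(nu, mu[act_in], bound_mult[c(at_lo, at_hi)])
    gl <- gr$cost + as.numeric(Matrix::crossprod(J, lam_cur))
    kkt_res <- max(max(abs(cvec), 0), max(abs(gl)))
    viol <- max(0, abs(e$eq), e$ineq)
    if (viol <= feas_tol && kkt_res < best_kkt &&
        (!length(act_in) || all(mu[act_in] >= -1e-8))) {
      best_kkt <- kkt_res
      mu_full <- rep(0, n_in); mu_full[act_in] <- pmax(mu[act_in], 0)
      best <- utils::modifyList(res, list(
        y = y, cost = e$cost, eq = e$eq, ineq = e$ineq,
        nu_eq = nu, mu_in = mu_full, feasible = TRUE, viol = viol,
        converged = TRUE))
    }
    if (kkt_res <= opt_tol * (1 + abs(e$cost)) && viol <= feas_tol) break
    K <- rbind(cbind(H, Matrix::t(J)),
               cbind(J, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0), dims = c(m, m))))
    rhsv <- c(-gr$cost, -cvec)
    sol <- tryCatch(Matrix::solve(K, rhsv), error = function(err) NULL)
    if (is.null(sol)) {
      K <- K + Matrix::Diagonal(n + m, c(rep(1e-8, n), rep(-1e-10, m)))
      sol <- tryCatch(Matrix::solve(K, rhsv), error = function(err) NULL)
      if (is.null(sol)) break
    }
    sol <- as.numeric(sol)
    dy <- sol[seq_len(n)]
    lam <- sol[n + seq_len(m)]
    y <- pmin(pmax(y + dy, lower), upper)
    nu <- lam[seq_along(nu)]
    lam_in <- lam[length(nu) + seq_along(act_in)]
    lam_b <- lam[length(nu) + length(act_in) + seq_len(nb)]
    lam_lo <- lam_b[seq_along(at_lo)]
    lam_hi <- lam_b[length(at_lo) + seq_along(at_hi)]
    # release wrong-sign members of the working set: inequality and upper
    # bound multipliers must be >= 0, lower-bound row multipliers <= 0
    drop_in <- act_in[lam_in < -1e-8]
    drop_lo <- at_lo[lam_lo > 1e-8]
    drop_hi <- at_hi[lam_hi < -1e-8]
    mu <- rep(0, n_in)
    if (length(act_in)) mu[act_in] <- pmax(lam_in, 0)
    bound_mult <- rep(0, n)
    bound_mult[at_lo] <- lam_lo
    bound_mult[at_hi] <- lam_hi
  }
  best
}

# Reassemble trajectory and multipliers from a local-solve result.
collocation_solution <- function(nlp, res) {
  problem <- nlp$meta$problem
  mesh <- nlp$meta$mesh
  lay <- nlp$layout
  Np <- lay$Np; ns <- lay$ns; nu <- lay$nu
  N <- Np - 1L
  X <- matrix(res$y[seq_len(ns * Np)], Np, ns,
              dimnames = list(NULL, lay$states))
  U <- if (nu) matrix(res$y[ns * Np + seq_len(nu * Np)], Np, nu,
                      dimnames = list(NULL, lay$controls))
       else matrix(0, Np, 0)
  dp <- if (length(lay$dpind))
    stats::setNames(res$y[lay$dpind], lay$dpn) else NULL
  traj <- structure(list(times = mesh$nodes, states = X, controls = U,
                         tf = if (isTRUE(problem$meta$normalized)) dp[["tf"]]
                              else problem$horizon$tf,
                         dp = dp),
                    class = "ocp_trajectory")
  npath <- nlp$meta$npath
  defect <- matrix(res$nu_eq[seq_len(N * ns)], N, ns,
                   dimnames = list(NULL, lay$states))
  init_m <- res$nu_eq[N * ns + seq_len(ns)]
  pt_eq_m <- if (nlp$meta$n_pt_eq)
    res$nu_eq[N * ns + ns + seq_len(nlp$meta$n_pt_eq)] else numeric(0)
  path_m <- if (npath)
    matrix(res$mu_in[seq_len(npath * Np)], Np, npath,
           dimnames = list(NULL, vapply(problem$path_constraints, `[[`, "",
                                        "label")))
    else matrix(0, Np, 0)
  pt_in_m <- if (nlp$meta$n_pt_in)
    res$mu_in[npath * Np + seq_len(nlp$meta$n_pt_in)] else numeric(0)
  # bound multipliers from the stationarity residual
  bound_mult <- rep(0, nlp$n)
  if (!is.null(nlp$grad)) {
    gr <- nlp$grad(res$y)
    r <- gr$cost +
      as.numeric(Matrix::crossprod(gr$jac_eq, res$nu_eq)) +
      as.numeric(Matrix::crossprod(gr$jac_ineq, res$mu_in))
    at_lo <- res$y - nlp$lower <= 1e-7 * (1 + abs(nlp$lower))
    at_hi <- nlp$upper - res$y <= 1e-7 * (1 + abs(nlp$upper))
    bound_mult[at_lo] <- r[at_lo]
    bound_mult[at_hi] <- -r[at_hi]
  }
  mult <- structure(list(defect = defect, init = init_m,
                         point_eq = pt_eq_m, path = path_m,
                         point_in = pt_in_m, bound = bound_mult,
                         converged = res$converged && res$feasible),
                    class = "multiplier_set")
  list(result = res, traj = traj, mult = mult, cost = res$cost,
       feasible = res$feasible, nlp = nlp)
}

#' Interpolate a phase-1 solution onto a collocation mesh
#'
#' Linearly interpolates the CVP solution's states and controls onto the mesh
#' nodes, carries the decision parameters (tf), and clips into bounds,
#' yielding a warm-start decision vector for \code{\link{solve_collocation}}.
#'
#' @param cvp_sol a list with an \code{ocp_trajectory} in \code{$traj} and
#'   optional \code{$dp} (an \code{ocp_solution} works).
#' @param nlp the collocation \code{dnlp} to warm start.
#' @return decision vector of length \code{nlp$n}.
#' @export
warm_start_from <- function(cvp_sol, nlp) {
  stopifnot(identical(nlp$meta$kind, "collocation"))
  traj <- cvp_sol$traj
  lay <- nlp$layout
  if (ncol(traj$states) != lay$ns || ncol(traj$controls) != lay$nu)
    stop("problem mismatch: trajectory dimensions do not match the transcription")
  nodes <- nlp$meta$mesh$nodes
  y <- numeric(nlp$n)
  for (s in seq_len(lay$ns))
    y[lay$xind(s)] <- stats::approx(traj$times, traj$states[, s],
                                    xout = nodes, rule = 2)$y
  for (j in seq_len(lay$nu))
    y[lay$uind(j)] <- stats::approx(traj$times, traj$controls[, j],
                                    xout = nodes, rule = 2)$y
  if (length(lay$dpind)) {
    dp <- if (!is.null(traj$dp)) traj$dp else cvp_sol$dp
    if (is.null(dp) || !all(lay$dpn %in% names(dp)))
      stop("problem mismatch: missing decision parameters for warm start")
    y[lay$dpind] <- dp[lay$dpn]
  }
  pmin(pmax(y, nlp$lower), nlp$upper)
}

#' Estimate continuous adjoints from collocation multipliers
#'
#' Under the Lagrangian convention \code{F + nu' c} with defects
#' \code{x_{i+1} - x_i - (h_i/2)(f_i + f_{i+1})}, the defect multipliers
#' estimate \code{-lambda(t)} of the Hamiltonian convention
#' \code{H = L + lambda' f} (so the linear-quadratic oracle has
#' \code{lambda = -2}). Path-constraint node multipliers scale to the
#' continuous multiplier density \code{mu(t)} by the trapezoidal quadrature
#' weights; their plain sum approximates the integral of \code{mu}, reported
#' as a per-constraint scalar sensitivity.
#'
#' @param mult a \code{multiplier_set} from \code{\link{solve_collocation}}.
#' @param mesh the \code{\link{collocation_mesh}} of the solve.
#' @return list with \code{times}, \code{lambda} (nodes x states), \code{mu}
#'   (nodes x path constraints), and \code{sensitivity} (named integral of mu
#'   per path constraint).
#' @export
extract_adjoints <- function(mult, mesh) {
  if (!isTRUE(mult$converged))
    warning("unreliable multipliers: solve did not fully converge")
  nodes <- mesh$nodes; h <- mesh$h
  Np <- length(nodes); N <- Np - 1L
  ns <- ncol(mult$defect)
  lambda <- matrix(0, Np, ns, dimnames = list(NULL, colnames(mult$defect)))
  lambda[1L, ] <- -mult$defect[1L, ]
  lambda[Np, ] <- -mult$defect[N, ]
  if (Np > 2L)
    lambda[2L:N, ] <- -(mult$defect[1L:(N - 1L), , drop = FALSE] +
                        mult$defect[2L:N, , drop = FALSE]) / 2
  wq <- c(h[1L] / 2, if (Np > 2L) (h[-N] + h[-1L]) / 2, h[N] / 2)
  mu <- sweep(mult$path, 1L, wq, `/`)
  sens <- colSums(mult$path)
  list(times = nodes, lambda = lambda, mu = mu, sensitivity = sens)
}
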