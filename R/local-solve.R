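# Gradient-based constrained local solver.
#
# Bound-constrained augmented Lagrangian: equality constraints c(y) = 0 and
# inequalities g(y) <= 0 are folded into
#   phi(y) = F(y) + nu' c + (rho/2)||c||^2
#            + 1/(2 rho) * sum( max(0, mu + rho g)^2 - mu^2 )
# minimized over the box bounds with L-BFGS-B; the classical first-order
# multiplier updates nu <- nu + rho c, mu <- max(0, mu + rho g) converge to
# the KKT multipliers, which downstream modules reuse as discrete adjoint
# estimates. Analytic derivative callbacks are used when the NLP provides
# them; otherwise forward differences with step fd_step * (1 + |y|).

local_control_defaults <- function(n) {
  list(feas_tol = 1e-5, opt_tol = 1e-6,
       maxit_outer = 25L, maxit_inner = 200L,
       rho0 = 10, rho_max = 1e7, rho_grow = 10,
       # forward differences must step over the IVP integration noise
       # (~1e-7 relative): 1e-4 balances noise against truncation error
       fd_step = 1e-4, fd_central = FALSE, factr = 1e3,
       trace = 0L)
}

#' Local constrained solve of a discretized NLP
#'
#' @param nlp a discretized NLP (class \code{dnlp}).
#' @param y0 starting point (clipped to bounds); defaults to \code{nlp$y0}.
#' @param control list overriding solver settings: \code{feas_tol},
#'   \code{opt_tol}, \code{maxit_outer}, \code{maxit_inner}, \code{rho0},
#'   \code{fd_step}.
#' @return list with \code{y}, \code{cost}, \code{eq}, \code{ineq},
#'   \code{nu_eq}, \code{mu_in} (Lagrange multiplier estimates),
#'   \code{feasible}, \code{viol}, \code{converged}, \code{message},
#'   \code{evals}.
#' @export
local_solve <- function(nlp, y0 = NULL, control = list()) {
  ctl <- utils::modifyList(local_control_defaults(nlp$n), control)
  lower <- nlp$lower; upper <- nlp$upper
  y <- if (is.null(y0)) nlp$y0 else y0
  y <- pmin(pmax(y, lower), upper)
  evals <- 0L
  ev <- function(y) { evals <<- evals + 1L; nlp$eval(y) }

  e0 <- ev(y)
  n_eq <- length(e0$eq); n_in <- length(e0$ineq)
  # multiplier warm starts (continuation along constraint sweeps)
  nu <- if (!is.null(ctl$nu0) && length(ctl$nu0) == n_eq) ctl$nu0
        else rep(0, n_eq)
  mu <- if (!is.null(ctl$mu0) && length(ctl$mu0) == n_in) pmax(ctl$mu0, 0)
        else rep(0, n_in)
  rho <- ctl$rho0
  viol_of <- function(e) max(0, abs(e$eq), e$ineq)
  viol_prev <- viol_of(e0)

  phi <- function(y) {
    e <- ev(y)
    v <- e$cost
    if (n_eq) v <- v + sum(nu * e$eq) + 0.5 * rho * sum(e$eq^2)
    if (n_in) {
      m <- pmax(0, mu + rho * e$ineq)
      v <- v + sum(m^2 - mu^2) / (2 * rho)
    }
    if (!is.finite(v)) v <- 1e12
    v
  }
  gphi <- if (!is.null(nlp$grad_lag)) {
    function(y) {
      e <- ev(y)
      nlp$grad_lag(y,
                   if (n_eq) nu + rho * e$eq else numeric(0),
                   if (n_in) pmax(0, mu + rho * e$ineq) else numeric(0))
    }
  } else if (!is.null(nlp$grad)) {
    function(y) {
      e <- ev(y); gr <- nlp$grad(y)
      g <- gr$cost
      if (n_eq) g <- g + as.numeric(Matrix::crossprod(gr$jac_eq, nu + rho * e$eq))
      if (n_in) g <- g + as.numeric(Matrix::crossprod(gr$jac_ineq,
                                                      pmax(0, mu + rho * e$ineq)))
      g
    }
  } else {
    function(y) {
      h <- ctl$fd_step * (1 + abs(y))
      g <- numeric(length(y))
      if (ctl$fd_central) {
        for (i in seq_along(y)) {
          hi <- min(h[i], (upper[i] - y[i]), (y[i] - lower[i]))
          if (hi <= 0) hi <- h[i]
          yp <- y; yp[i] <- min(y[i] + hi, upper[i])
          ym <- y; ym[i] <- max(y[i] - hi, lower[i])
          g[i] <- (phi(yp) - phi(ym)) / (yp[i] - ym[i])
        }
      } else {
        f0 <- phi(y)
        # keep perturbed points inside bounds
        for (i in seq_along(y)) {
          hi <- h[i]
          if (y[i] + hi > upper[i]) hi <- -hi
          yp <- y; yp[i] <- y[i] + hi
          g[i] <- (phi(yp) - f0) / hi
        }
      }
      g
    }
  }

  best <- list(y = y, e = e0, viol = viol_prev)
  converged <- FALSE; msg <- "max outer iterations"
  for (it in seq_len(ctl$maxit_outer)) {
    opt <- tryCatch(
      stats::optim(y, fn = phi, gr = gphi, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = ctl$maxit_inner, factr = ctl$factr)),
      error = function(e) NULL)
    if (!is.null(opt)) y <- opt$par
    e <- ev(y)
    viol <- viol_of(e)
    # track best (feasibility-first, then cost)
    if ((viol <= ctl$feas_tol && (best$viol > ctl$feas_tol ||
                                  e$cost < best$e$cost)) ||
        (viol > ctl$feas_tol && best$viol > ctl$feas_tol && viol < best$viol))
      best <- list(y = y, e = e, viol = viol)
    # first-order multiplier updates
    if (n_eq) nu <- nu + rho * e$eq
    if (n_in) mu <- pmax(0, mu + rho * e$ineq)
    if (viol <= ctl$feas_tol) {
      # declare convergence when feasible and the iterate has stopped moving
      if (it > 1 && abs(e$cost - cost_prev) <=
          ctl$opt_tol * (1 + abs(e$cost)) && viol_prev <= ctl$feas_tol) {
        converged <- TRUE; msg <- "converged"; break
      }
    } else if (viol > ctl$feas_tol && viol > 0.25 * viol_prev) {
      # penalty escalation only while genuinely infeasible; runaway rho
      # destroys both conditioning and the multiplier estimates
      rho <- min(rho * ctl$rho_grow, ctl$rho_max)
    }
    cost_prev <- e$cost
    viol_prev <- viol
  }
  e <- ev(best$y)
  list(y = best$y, cost = e$cost, eq = e$eq, ineq = e$ineq,
       nu_eq = nu, mu_in = mu,
       feasible = best$viol <= ctl$feas_tol, viol = best$viol,
       converged = converged,
       message = if (converged) msg else paste0("max-iter (", msg, ")"),
       evals = evals)
}
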