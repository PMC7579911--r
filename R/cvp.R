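# Control vector parameterization (sequential transcription).
#
# The horizon is split into rho elements; within element i each control j is
# a Lagrange polynomial of order M_j (1 = piecewise constant, 2 = piecewise
# linear) in the normalized element time tau = (t - t_{i-1})/(t_i - t_{i-1}).
# The polynomial coefficients w (plus, optionally, the element widths and any
# free decision parameters such as tf) are the decision variables of a
# reduced NLP whose every evaluation embeds one IVP solve.

#' Control parameterization for CVP
#'
#' @param problem canonical \code{ocp_problem} (fixed horizon) whose controls
#'   are parameterized.
#' @param n_elements number of mesh elements rho.
#' @param order polynomial order per control (scalar or vector; 1 = piecewise
#'   constant, 2 = piecewise linear; higher orders are not supported).
#' @param variable_length should the element widths be decision variables?
#'   Minimum element width is \code{min_width_frac} of the horizon.
#' @param boundaries optional element boundaries (length rho + 1, spanning
#'   the horizon); defaults to uniform.
#' @param min_width_frac minimum element width as a fraction of the horizon.
#' @return an object of class \code{cvp_parameterization}.
#' @export
control_parameterization <- function(problem, n_elements = 10, order = 2,
                                     variable_length = FALSE,
                                     boundaries = NULL,
                                     min_width_frac = 1e-3) {
  nu <- n_controls(problem)
  stopifnot(nu > 0, n_elements >= 1)
  order <- rep_len(as.integer(order), nu)
  if (!all(order %in% 1:2))
    stop("only piecewise-constant (1) or piecewise-linear (2) control orders are supported")
  t0 <- problem$horizon$t0; tfv <- problem$horizon$tf
  if (is.null(boundaries))
    boundaries <- seq(t0, tfv, length.out = n_elements + 1)
  stopifnot(length(boundaries) == n_elements + 1,
            all(diff(boundaries) > 0),
            isTRUE(all.equal(boundaries[1], t0)),
            isTRUE(all.equal(boundaries[n_elements + 1], tfv)))
  lower <- rep(problem$control_bounds$lower, times = n_elements * order)
  upper <- rep(problem$control_bounds$upper, times = n_elements * order)
  # coefficient layout: control-major, then element, then node
  idx <- split(seq_len(sum(n_elements * order)),
               rep(seq_len(nu), times = n_elements * order))
  # per-element coordinate groups across controls (sparse-corner sampling in
  # the global search: extreme points of shared-capacity feasible sets have
  # one active control per element)
  groups <- lapply(seq_len(n_elements), function(i)
    lapply(seq_len(nu), function(j)
      idx[[j]][(i - 1L) * order[j] + seq_len(order[j])]))
  structure(list(
    n_elements = n_elements, order = order,
    boundaries = boundaries, t0 = t0, tf = tfv,
    control_names = problem$controls,
    coef_lower = lower, coef_upper = upper,
    coef_index = idx,
    coef_groups = groups,
    n_coef = sum(n_elements * order),
    variable_length = variable_length,
    min_width = min_width_frac * (tfv - t0)
  ), class = "cvp_parameterization")
}

#' Build the piecewise-polynomial control function
#'
#' @param par a \code{cvp_parameterization}.
#' @param w coefficient vector (length \code{par$n_coef}).
#' @param boundaries optional element boundaries overriding the stored ones
#'   (used with variable-length elements).
#' @return function(t): control vector at scalar t (named), or a
#'   length(t) x n_controls matrix for vector t. Right-continuous at element
#'   boundaries.
#' @export
build_control <- function(par, w, boundaries = NULL) {
  stopifnot(length(w) == par$n_coef)
  b <- if (is.null(boundaries)) par$boundaries else boundaries
  rho <- par$n_elements
  nu <- length(par$control_names)
  # left/right node coefficient matrices (rho x nu); piecewise-constant
  # controls get equal endpoints so one linear-blend expression serves both
  W1 <- matrix(0, rho, nu); W2 <- matrix(0, rho, nu)
  for (j in seq_len(nu)) {
    wj <- w[par$coef_index[[j]]]
    if (par$order[j] == 1L) {
      W1[, j] <- wj; W2[, j] <- wj
    } else {
      M <- matrix(wj, nrow = rho, ncol = 2L, byrow = TRUE)
      W1[, j] <- M[, 1L]; W2[, j] <- M[, 2L]
    }
  }
  names_u <- par$control_names
  t0 <- b[1]; tfv <- b[rho + 1]
  hb <- diff(b)
  f <- function(t) {
    if (length(t) == 1L) {
      if (t < t0 - 1e-12 || t > tfv + 1e-12)
        stop("out of horizon: control requested at t = ", signif(t, 6))
      i <- sum(b <= t)   # right-continuous element lookup
      if (i < 1L) i <- 1L else if (i > rho) i <- rho
      tau <- (t - b[i]) / hb[i]
      return(W1[i, ] * (1 - tau) + W2[i, ] * tau)
    }
    if (any(t < t0 - 1e-12) || any(t > tfv + 1e-12))
      stop("out of horizon: control requested outside [",
           signif(t0, 6), ", ", signif(tfv, 6), "]")
    i <- findInterval(t, b, rightmost.closed = TRUE)
    i[i < 1L] <- 1L; i[i > rho] <- rho
    tau <- (t - b[i]) / hb[i]
    vals <- W1[i, , drop = FALSE] * (1 - tau) + W2[i, , drop = FALSE] * tau
    colnames(vals) <- names_u
    vals
  }
  attr(f, "vectorized") <- TRUE
  f
}

#' Transcribe an OCP by control vector parameterization
#'
#' Produces a reduced NLP whose decision vector is the control-coefficient
#' vector w, optionally the element widths, and the free decision parameters
#' (tf of a normalized problem). Each NLP evaluation performs exactly one IVP
#' solve shared by the cost and all constraints. Path constraints are sampled
#' at element boundaries and midpoints.
#'
#' @param problem canonical \code{ocp_problem} (pure Mayer, fixed horizon:
#'   run \code{prepare_problem} first).
#' @param par a \code{cvp_parameterization}.
#' @param objective index of the objective to optimize (scalarized with its
#'   declared sense: the NLP always minimizes).
#' @param rtol,atol IVP tolerances.
#' @return a discretized NLP (class \code{dnlp}).
#' @export
transcribe_cvp <- function(problem, par, objective = 1L,
                           rtol = 1e-7, atol = 1e-7) {
  if (any(vapply(problem$objectives, function(o) !is.null(o$lagrange_text), TRUE)))
    stop("problem must be augmented to pure Mayer first (augment_lagrange)")
  if (problem$horizon$tf_mode != "fixed")
    stop("problem must have a fixed (possibly normalized) horizon")
  ob <- problem$objectives[[objective]]
  sgn <- if (ob$sense == "max") -1 else 1
  rho <- par$n_elements
  nu <- n_controls(problem)
  t0 <- par$t0; tfv <- par$tf; H <- tfv - t0
  dpn <- names(problem$decision_params)
  nw <- par$n_coef
  nwid <- if (par$variable_length) rho else 0L
  ndp <- length(dpn)
  n <- nw + nwid + ndp
  layout <- list(w = seq_len(nw),
                 widths = if (nwid) nw + seq_len(nwid) else integer(0),
                 dp = if (ndp) nw + nwid + seq_len(ndp) else integer(0))
  lower <- c(par$coef_lower,
             rep(par$min_width, nwid),
             vapply(problem$decision_params, `[[`, 0, 1L))
  upper <- c(par$coef_upper,
             rep(H, nwid),
             vapply(problem$decision_params, `[[`, 0, 2L))
  rhs_fn <- make_rhs_fn(problem)
  prob_fast <- problem
  attr(prob_fast, "rhs_fn") <- rhs_fn

  eq_names <- c(if (nwid) "element_widths_sum",
                vapply(Filter(function(p) p$rel == "==",
                              problem$point_constraints), `[[`, "", "label"))
  pt_eq <- Filter(function(p) p$rel == "==", problem$point_constraints)
  pt_in <- Filter(function(p) p$rel != "==", problem$point_constraints)
  npath <- length(problem$path_constraints)
  n_samp <- 2L * rho + 1L
  ineq_names <- c(
    unlist(lapply(problem$path_constraints, function(p)
      sprintf("%s@s%d", p$label, seq_len(n_samp)))),
    vapply(pt_in, `[[`, "", "label"))

  fail_count <- new.env(parent = emptyenv())
  fail_count$failed <- 0L; fail_count$total <- 0L

  eval_fn <- function(y) {
    w <- y[layout$w]
    boundaries <- if (nwid) {
      wid <- y[layout$widths]
      t0 + c(0, cumsum(wid))
    } else par$boundaries
    dp <- if (ndp) stats::setNames(y[layout$dp], dpn) else NULL
    ctrl <- build_control(par, w, boundaries = if (nwid) {
      bsc <- boundaries
      # widths need not sum exactly to H mid-iteration; rescale so the
      # control is defined on the full horizon (the equality constraint
      # drives the sum to H at the solution)
      t0 + (bsc - t0) * H / max(bsc[rho + 1] - t0, .Machine$double.eps)
    } else NULL)
    bline <- if (nwid) t0 + (boundaries - t0) * H /
      max(boundaries[rho + 1] - t0, .Machine$double.eps) else boundaries
    mids <- (bline[-1] + bline[-(rho + 1)]) / 2
    samp <- sort(c(bline, mids))   # fixed length: stable constraint layout
    fail_count$total <- fail_count$total + 1L
    traj <- tryCatch(
      simulate_ocp(prob_fast, ctrl, rtol = rtol, atol = atol, dp = dp,
                   n_out = 2, sample_times = samp),
      error = function(e) e)
    if (inherits(traj, "error")) {
      fail_count$failed <- fail_count$failed + 1L
      if (fail_count$total > 20L &&
          fail_count$failed > 0.5 * fail_count$total)
        stop("integration failed in more than half of the NLP evaluations; ",
             "aborting (last failure: ", conditionMessage(traj), ")")
      nin <- npath * n_samp + length(pt_in)
      return(list(cost = 1e8, eq = rep(1, length(eq_names)),
                  ineq = rep(1, nin), ok = FALSE))
    }
    nlast <- length(traj$times)
    bf <- make_bindings(problem, x = traj$states[nlast, ], dp = dp,
                        t = traj$times[nlast], tf = traj$tf)
    cost <- sgn * as.numeric(eval_model_expr(ob$mayer, bf))
    b_all <- make_bindings(problem, x = traj$states, u = traj$controls,
                           dp = dp, t = traj$times, tf = traj$tf)
    si <- vapply(samp, function(s) which.min(abs(traj$times - s)), 0L)
    ineq <- numeric(0)
    for (pc in problem$path_constraints) {
      val <- rep_len(as.numeric(eval_model_expr(pc$expr, b_all)), nlast)[si]
      g <- if (pc$dir == "<=") val - pc$bound else pc$bound - val
      ineq <- c(ineq, g)
    }
    eq <- if (nwid) sum(y[layout$widths]) - H else numeric(0)
    for (pc in pt_eq) eq <- c(eq, point_value(problem, pc, traj, dp) - pc$bound)
    for (pc in pt_in) {
      v <- point_value(problem, pc, traj, dp)
      ineq <- c(ineq, if (pc$rel == "<=") v - pc$bound else pc$bound - v)
    }
    list(cost = cost, eq = eq, ineq = ineq, ok = TRUE, traj = traj)
  }

  y0 <- c(pmin(pmax((par$coef_lower + pmin(par$coef_upper, 1e6)) / 2,
                    par$coef_lower), par$coef_upper),
          rep(H / rho, nwid),
          vapply(problem$decision_params, function(bb) mean(bb), 0))
  structure(list(
    n = n, lower = lower, upper = upper, y0 = y0,
    eval = eval_fn, grad = NULL, hess = NULL,
    layout = layout, eq_names = eq_names, ineq_names = ineq_names,
    meta = list(kind = "cvp", problem = problem, par = par,
                objective = objective, sgn = sgn, rtol = rtol, atol = atol)
  ), class = "dnlp")
}

point_value <- function(problem, pc, traj, dp) {
  idx <- if (identical(pc$time, "t0")) 1L
    else if (identical(pc$time, "tf")) length(traj$times)
    else which.min(abs(traj$times - pc$time))
  b <- make_bindings(problem, x = traj$states[idx, ], u = traj$controls[idx, ],
                     dp = dp, t = traj$times[idx], tf = traj$tf)
  as.numeric(eval_model_expr(pc$expr, b))
}

#' Event-horizon CVP transcription for transition/survival problems
#'
#' Exact reformulation of two free-final-time problem families whose
#' objective is the final time itself:
#' \itemize{
#'   \item \strong{transition} (minimize tf subject to an endpoint equality
#'     \code{expr(tf) = bound} with \code{expr} monotone along trajectories,
#'     e.g. a product target): the realized final time is the first crossing
#'     of the target, found by integrating with root detection, and the
#'     endpoint equality holds by construction;
#'   \item \strong{survival} (maximize tf subject to state path constraints,
#'     e.g. critical metabolite levels): the realized final time is the
#'     first violation of any state-dependent path constraint, so those
#'     constraints hold on the whole realized horizon by construction.
#' }
#' Controls are parameterized in real time on \code{[t0, tf_max]} with
#' variable-length elements (constant extrapolation past the last element
#' boundary); the decision vector is coefficients plus element widths, with
#' box bounds only — the endpoint equality and the tf variable both
#' disappear, which makes the reduced problem far better conditioned for
#' stochastic search than the generic normalized transcription.
#'
#' @param problem augmented (pure-Mayer) \code{ocp_problem} with a free
#'   final time whose selected objective is \code{tf}.
#' @param n_elements number of control elements.
#' @param order polynomial order per control (1 or 2).
#' @param objective index of the tf objective.
#' @param rtol,atol IVP tolerances.
#' @param min_width_frac minimum element width as a fraction of tf_max.
#' @return a discretized NLP (class \code{dnlp}) with
#'   \code{meta$kind = "cvp_event"}.
#' @export
transcribe_cvp_event <- function(problem, n_elements = 5L, order = 2L,
                                 objective = 1L, rtol = 1e-7, atol = 1e-7,
                                 min_width_frac = 1e-3) {
  if (problem$horizon$tf_mode != "free")
    stop("event transcription needs a free final time")
  ob <- problem$objectives[[objective]]
  if (any(vapply(problem$objectives, function(o) !is.null(o$lagrange_text),
                 TRUE)))
    stop("problem must be augmented to pure Mayer first (augment_lagrange)")
  t0 <- problem$horizon$t0
  tf_lo <- problem$horizon$tf_bounds[1]; tf_max <- problem$horizon$tf_bounds[2]
  pt_eq <- Filter(function(p) p$rel == "==", problem$point_constraints)
  pt_in <- Filter(function(p) p$rel != "==", problem$point_constraints)
  # transition mode pins tf at the (unique) crossing of the endpoint target,
  # so it admits any Mayer objective; survival mode pins tf at the first
  # path-constraint violation, which is only optimal when the objective is
  # to maximize tf itself
  mode <- if (length(pt_eq) == 1L) "transition" else "survival"
  if (mode == "survival" &&
      !(identical(ob$mayer_text, "tf") && ob$sense == "max"))
    stop("survival mode needs maximize-tf as the selected objective")
  if (mode == "transition" && length(pt_eq) != 1L)
    stop("transition mode needs exactly one endpoint equality")
  sgn <- if (ob$sense == "max") -1 else 1
  # state-dependent path constraints become roots in survival mode;
  # control-only ones (e.g. total enzyme capacity) are sampled as usual
  state_dep <- vapply(problem$path_constraints, function(pc)
    any(expr_symbols(pc$expr) %in% problem$states), TRUE)
  roots <- if (mode == "transition") pt_eq else
    problem$path_constraints[state_dep]
  sampled <- if (mode == "transition") problem$path_constraints else
    problem$path_constraints[!state_dep]
  if (mode == "survival" && !length(roots))
    stop("survival mode needs at least one state-dependent path constraint")

  # fixed-shape parameterization over [t0, tf_max]; element widths are
  # separate decision variables (no sum constraint: the control extends
  # past the last boundary by constant extrapolation)
  fixed_prob <- problem
  fixed_prob$horizon <- time_horizon(t0, tf = tf_max)
  fixed_prob$decision_params <- list()
  fixed_prob <- compile_problem(fixed_prob)
  par <- control_parameterization(fixed_prob, n_elements = n_elements,
                                  order = order,
                                  min_width_frac = min_width_frac)
  rho <- n_elements
  nw <- par$n_coef
  n <- nw + rho
  layout <- list(w = seq_len(nw), widths = nw + seq_len(rho), dp = integer(0))
  lower <- c(par$coef_lower, rep(par$min_width, rho))
  upper <- c(par$coef_upper, rep(tf_max - t0, rho))
  rhs_fn <- make_rhs_fn(fixed_prob)
  nsamp <- 2L * rho + 1L
  eq_names <- if (mode == "transition") pt_eq[[1]]$label else character(0)
  ineq_names <- c(unlist(lapply(sampled, function(p)
                    sprintf("%s@s%d", p$label, seq_len(nsamp)))),
                  vapply(pt_in, `[[`, "", "label"),
                  "tf_lower_bound")
  # root function: slack of each root constraint (crosses zero at the event)
  root_exprs <- lapply(roots, function(pc) {
    if (!is.null(pc$dir)) {   # path constraint
      if (pc$dir == "<=") call("-", pc$bound, pc$expr)
      else call("-", pc$expr, pc$bound)
    } else call("-", pc$expr, pc$bound)   # endpoint target crossing
  })
  states <- problem$states
  root_fn <- make_root_fn(fixed_prob, root_exprs)

  eval_fn <- function(y) {
    w <- y[layout$w]
    wid <- y[layout$widths]
    b <- t0 + c(0, cumsum(wid))
    b_end <- b[rho + 1L]
    base_ctrl <- build_control(par, w, boundaries = {
      bb <- b
      # parameterization boundaries must span [t0, tf_max]
      if (b_end < tf_max) bb[rho + 1L] <- tf_max
      bb / 1
    })
    ctrl <- function(t) base_ctrl(pmin(t, tf_max))
    attr(ctrl, "vectorized") <- TRUE
    # fixed-length sample vector (duplicates allowed) so the constraint
    # vector has a stable layout across evaluations
    samp <- sort(pmin(c(b, (b[-1] + b[-(rho + 1)]) / 2), tf_max))
    times <- sort(unique(c(samp, seq(t0, tf_max, length.out = 31L))))
    out <- tryCatch(suppressWarnings(
      deSolve::lsodar(y = unname(problem$x0), times = times, func = rhs_fn,
                      parms = list(u_fn = ctrl, dp = NULL),
                      rtol = rtol, atol = atol, rootfunc = root_fn,
                      tcrit = tf_max)),
      error = function(e) e)
    if (inherits(out, "error") || any(!is.finite(out[, -1L]))) {
      return(list(cost = 1e8, eq = rep(1, length(eq_names)),
                  ineq = rep(1, length(ineq_names)), ok = FALSE))
    }
    troot <- attr(out, "troot")
    Tr <- if (length(troot)) troot[1] else out[nrow(out), 1L]
    Xend <- out[nrow(out), -1L]
    reached <- length(troot) > 0
    be <- make_bindings(problem, x = Xend, u = NULL, t = Tr, tf = Tr)
    cost <- sgn * as.numeric(eval_model_expr(ob$mayer, be))
    tsim <- out[, 1L]
    Xs <- out[, -1L, drop = FALSE]; colnames(Xs) <- states
    U <- control_matrix(ctrl, tsim, length(problem$controls),
                        problem$controls)
    bnd <- make_bindings(problem, x = Xs, u = U, t = tsim, tf = Tr)
    eq <- numeric(0)
    if (mode == "transition") {
      # target reached -> equality satisfied by construction; otherwise the
      # terminal shortfall is the violation driving the search
      pc <- pt_eq[[1]]
      eq <- if (reached) 0 else {
        be <- make_bindings(problem, x = Xend, u = U[nrow(U), ], t = Tr,
                            tf = Tr)
        as.numeric(eval_model_expr(pc$expr, be)) - pc$bound
      }
    }
    ineq <- numeric(0)
    keep <- tsim <= Tr + 1e-12
    si <- vapply(samp, function(s) which.min(abs(tsim - min(s, Tr))), 0L)
    for (pc in sampled) {
      val <- rep_len(as.numeric(eval_model_expr(pc$expr, bnd)),
                     length(tsim))[si]
      ineq <- c(ineq, if (pc$dir == "<=") val - pc$bound else pc$bound - val)
    }
    for (pc in pt_in) {
      be <- make_bindings(problem, x = Xend, u = U[nrow(U), ], t = Tr,
                          tf = Tr)
      v <- as.numeric(eval_model_expr(pc$expr, be))
      ineq <- c(ineq, if (pc$rel == "<=") v - pc$bound else pc$bound - v)
    }
    ineq <- c(ineq, tf_lo - Tr)   # realized horizon at least tf lower bound
    keep <- keep & !duplicated(tsim)
    traj <- structure(list(times = tsim[keep],
                           states = Xs[keep, , drop = FALSE],
                           controls = U[keep, , drop = FALSE],
                           tf = Tr, dp = c(tf = Tr)),
                      class = "ocp_trajectory")
    list(cost = cost, eq = eq, ineq = ineq, ok = TRUE, traj = traj, T = Tr)
  }

  tf_mid <- (tf_lo + tf_max) / 2
  y0 <- c(pmin(pmax((par$coef_lower + pmin(par$coef_upper, 1e6)) / 2,
                    par$coef_lower), par$coef_upper),
          rep(tf_mid / rho, rho))
  structure(list(
    n = n, lower = lower, upper = upper, y0 = y0,
    eval = eval_fn, grad = NULL, hess = NULL,
    layout = layout, eq_names = eq_names, ineq_names = ineq_names,
    meta = list(kind = "cvp_event", problem = problem, par = par,
                mode = mode, objective = objective, tf_max = tf_max,
                rtol = rtol, atol = atol)
  ), class = "dnlp")
}

#' Refine a CVP mesh, preserving the represented control
#'
#' Splits each element into \code{factor} children; new coefficients are the
#' old control evaluated at the new nodes, so the represented control
#' function is unchanged.
#'
#' @param par a \code{cvp_parameterization}.
#' @param sol a solve result on \code{par} (uses \code{sol$y}) or a plain
#'   coefficient vector w.
#' @param factor integer >= 2 split factor.
#' @return list with the refined parameterization \code{par} and the carried
#'   coefficient vector \code{w}.
#' @export
refine_mesh <- function(par, sol, factor = 2L) {
  if (factor < 2) stop("invalid factor: must be >= 2")
  w_old <- if (is.list(sol)) sol$y[seq_len(par$n_coef)] else sol
  boundaries_old <- if (is.list(sol) && !is.null(sol$boundaries))
    sol$boundaries else par$boundaries
  ufn <- build_control(par, w_old, boundaries = boundaries_old)
  bnew <- unique(sort(unlist(lapply(seq_len(par$n_elements), function(i)
    seq(boundaries_old[i], boundaries_old[i + 1], length.out = factor + 1)))))
  rho_new <- length(bnew) - 1L
  par_new <- par
  par_new$n_elements <- rho_new
  par_new$boundaries <- bnew
  nu <- length(par$control_names)
  par_new$coef_lower <- rep(vapply(seq_len(nu), function(j)
    par$coef_lower[par$coef_index[[j]][1]], 0), times = rho_new * par$order)
  par_new$coef_upper <- rep(vapply(seq_len(nu), function(j)
    par$coef_upper[par$coef_index[[j]][1]], 0), times = rho_new * par$order)
  par_new$coef_index <- split(seq_len(sum(rho_new * par$order)),
                              rep(seq_len(nu), times = rho_new * par$order))
  par_new$n_coef <- sum(rho_new * par$order)
  # evaluate the old control at the new nodes (element starts for M=1;
  # both endpoints for M=2, approaching interior boundaries from the left)
  w_new <- numeric(par_new$n_coef)
  eps <- 1e-9 * (par$tf - par$t0)
  for (j in seq_len(nu)) {
    vals <- numeric(0)
    for (i in seq_len(rho_new)) {
      if (par$order[j] == 1L) {
        tt <- bnew[i]
        vals <- c(vals, ufn(tt)[j])
      } else {
        t_left <- bnew[i]
        t_right <- max(bnew[i], bnew[i + 1] - eps)  # left limit at boundary
        vals <- c(vals, ufn(t_left)[j], ufn(t_right)[j])
      }
    }
    w_new[par_new$coef_index[[j]]] <- vals
  }
  list(par = par_new, w = w_new)
}
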