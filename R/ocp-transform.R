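# Canonical problem transformations.
#
# Both transcriptions work on a canonical form: every Lagrange integrand is
# reduced to a quadrature state (pure-Mayer objectives), and a free final
# time is removed by rescaling time onto [0, 1] with tf promoted to a static
# decision parameter multiplying the vector field.

#' Reduce Lagrange objective terms to quadrature states
#'
#' Each objective with an integral term gets an extra state \code{qJ<k>} with
#' zero initial value whose right-hand side is the integrand; the objective
#' becomes pure Mayer on that state. Objective values are unchanged for any
#' trajectory.
#'
#' @param problem an \code{ocp_problem}.
#' @return an equivalent pure-Mayer \code{ocp_problem}.
#' @export
augment_lagrange <- function(problem) {
  has_lag <- vapply(problem$objectives, function(o) !is.null(o$lagrange_text), TRUE)
  if (!any(has_lag)) return(problem)
  prob <- problem
  for (k in which(has_lag)) {
    qname <- sprintf("qJ%d", k)
    if (qname %in% c(prob$states, prob$controls, names(prob$params)))
      stop("name clash with quadrature state ", qname)
    prob$states <- c(prob$states, qname)
    prob$rhs_text <- c(prob$rhs_text, stats::setNames(
      prob$objectives[[k]]$lagrange_text, qname))
    prob$x0 <- c(prob$x0, stats::setNames(0, qname))
    ob <- prob$objectives[[k]]
    ob$mayer_text <- if (is.null(ob$mayer_text)) qname
      else paste0("(", ob$mayer_text, ") + ", qname)
    ob$lagrange_text <- NULL
    prob$objectives[[k]] <- ob
    prob$meta$quadrature <- c(prob$meta$quadrature, qname)
  }
  prob <- compile_problem(prob)
  validate_ocp(prob)
  prob
}

#' Normalize a free-final-time problem onto a fixed unit horizon
#'
#' Rescales time to tau in [0, 1]; the vector field becomes tf * f and tf is
#' added as a static decision parameter bounded by the original tf bounds.
#' An objective that is just \code{tf} maps to that parameter.
#'
#' @param problem an \code{ocp_problem} with a free final time.
#' @return a fixed-horizon \code{ocp_problem} on [0, 1].
#' @export
normalize_time <- function(problem) {
  if (problem$horizon$tf_mode != "free")
    stop("not free-time: normalize_time needs a free final time")
  prob <- problem
  t0 <- prob$horizon$t0
  # original t inside rhs becomes t0 + tf * tau, then the whole field scales
  # by tf (chain rule of t = t0 + tf * tau with tau the new clock).
  prob$rhs_text <- vapply(prob$rhs_text, function(txt) {
    ex <- str2lang(txt)
    ex <- expr_substitute(ex, list(t = str2lang(sprintf("(%s + tf * t)", num_lit(t0)))))
    paste0("tf * (", deparse1(ex), ")")
  }, "")
  names(prob$rhs_text) <- prob$states
  prob$decision_params <- c(prob$decision_params,
                            list(tf = prob$horizon$tf_bounds))
  prob$horizon <- time_horizon(t0 = 0, tf = 1)
  prob$meta$normalized <- TRUE
  prob$meta$t0_orig <- t0
  prob <- compile_problem(prob)
  validate_ocp(prob)
  prob
}

# Canonical form used by every solver: pure Mayer, fixed horizon.
prepare_problem <- function(problem) {
  prob <- augment_lagrange(problem)
  if (prob$horizon$tf_mode == "free") prob <- normalize_time(prob)
  prob
}

# Map a canonical (possibly normalized) trajectory clock back to model time.
real_times <- function(prob, times, dp = NULL) {
  if (isTRUE(prob$meta$normalized)) {
    tfv <- dp[["tf"]]
    prob$meta$t0_orig + tfv * times
  } else times
}
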