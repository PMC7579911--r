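# Hybrid stochastic-deterministic global search.
#
# A scatter-search metaheuristic in the spirit of enhanced scatter search:
# a space-filling diverse set seeds a small reference set maintained by
# quality and diversity; reference members are pairwise recombined (line
# recombination extended beyond the segment, with a go-beyond intensification
# step), and promising members are periodically polished with the
# gradient-based local solver. Constraint handling is feasibility-first: a
# feasible point always beats an infeasible one; among infeasible points a
# quadratic penalty decides. All randomness comes from one generator seeded
# per call, so identical seed + settings give identical results.

search_settings_defaults <- function(n) {
  list(seed = 1L,
       max_evals = 5000L,
       ref_set_size = max(6L, min(12L, 2L * ceiling(sqrt(n)))),
       diverse_set_size = max(20L, min(10L * n, 100L)),
       local_solver_freq = 10L,
       penalty_weight = 1e4,
       feas_tol = 1e-5,
       local = list(),        # control for in-loop polishes
       local_final = NULL)    # control for the final polish (defaults: local)
}

# Latin-hypercube style space-filling sample in [lower, upper]: one point per
# stratum per dimension, strata randomly permuted.
lhs_sample <- function(m, lower, upper) {
  n <- length(lower)
  pts <- vapply(seq_len(n), function(i) {
    (sample.int(m) - stats::runif(m)) / m
  }, numeric(m))
  if (m == 1L) pts <- matrix(pts, nrow = 1L)
  sweep(sweep(pts, 2L, upper - lower, `*`), 2L, lower, `+`)
}

# Penalized score and feasibility-first comparison key.
score_point <- function(e, penalty_weight, feas_tol) {
  viol2 <- sum(e$eq^2) + sum(pmax(0, e$ineq)^2)
  feas <- sqrt(viol2) <= feas_tol
  list(cost = e$cost, pen = e$cost + penalty_weight * viol2, feasible = feas,
       viol = sqrt(viol2))
}

# TRUE if a beats b.
better_than <- function(a, b) {
  if (a$feasible != b$feasible) return(a$feasible)
  if (a$feasible) a$cost < b$cost else a$pen < b$pen
}

#' Scatter-search global optimization of a discretized NLP
#'
#' @param nlp a discretized NLP (class \code{dnlp}) with finite bounds.
#' @param settings list overriding \code{seed}, \code{max_evals},
#'   \code{ref_set_size}, \code{diverse_set_size}, \code{local_solver_freq}
#'   (polish every k accepted improvements), \code{penalty_weight},
#'   \code{feas_tol}, \code{local} (control list for the polish), and
#'   optionally \code{init_points} (matrix of rows injected into the diverse
#'   set, e.g. a warm start).
#' @return a solve result: list with \code{y_best}, \code{cost},
#'   \code{feasible}, \code{viol}, \code{history} (eval count vs best cost),
#'   \code{ensemble} (local-solve endpoints), \code{evals}, \code{seed}.
#' @export
scatter_search <- function(nlp, settings = list()) {
  st <- utils::modifyList(search_settings_defaults(nlp$n), settings)
  if (st$max_evals <= 0) stop("no evaluations allowed: max_evals must be positive")
  if (any(!is.finite(nlp$lower)) || any(!is.finite(nlp$upper)))
    stop("scatter_search needs finite bounds on every decision variable")
  if (st$ref_set_size < 4L) st$ref_set_size <- 4L
  set.seed(st$seed)
  n <- nlp$n; lower <- nlp$lower; upper <- nlp$upper
  span <- pmax(upper - lower, .Machine$double.eps)

  evals <- 0L
  history <- list()
  ensemble <- list()
  best <- NULL
  ev <- function(y) {
    evals <<- evals + 1L
    e <- nlp$eval(y)
    s <- score_point(e, st$penalty_weight, st$feas_tol)
    s$y <- y
    if (is.null(best) || better_than(s, best)) {
      best <<- s
      history[[length(history) + 1L]] <<- c(evals, s$cost, s$viol)
    }
    s
  }

  # diverse set: space-filling interior samples plus a fraction of corner
  # samples (each coordinate at one of its bounds) — bang-bang-like control
  # structures live at such corners and interior sampling alone finds them
  # slowly
  groups <- nlp$meta$par$coef_groups
  m_corner <- ceiling(st$diverse_set_size / 4)
  m_sparse <- if (!is.null(groups)) ceiling(st$diverse_set_size / 4) else 0L
  P <- lhs_sample(st$diverse_set_size - m_corner, lower, upper)
  corners <- matrix(0, m_corner, n)
  for (k in seq_len(m_corner)) {
    pk <- stats::runif(1, 0.1, 0.9)
    corners[k, ] <- ifelse(stats::runif(n) < pk, upper, lower)
  }
  # the two extreme corners always participate (all controls off / at max)
  P <- rbind(P, corners, lower, upper)
  if (m_sparse) {
    # sparse corners aligned with the control-element structure: in each
    # element exactly one control sits at its upper bound, the rest at the
    # lower — the extreme points of shared-capacity feasible sets. When the
    # pattern count is small they are enumerated outright (paired with the
    # default guess for all non-coefficient coordinates); otherwise sampled.
    apply_pattern <- function(y, picks) {
      for (i in seq_along(groups)) {
        g <- groups[[i]]
        for (j in seq_along(g))
          y[g[[j]]] <- if (j == picks[i]) upper[g[[j]]] else lower[g[[j]]]
      }
      y
    }
    nu_g <- length(groups[[1]])
    npat <- nu_g^length(groups)
    # enumeration pays off for cold starts; warm-started (continuation)
    # solves already know their basin
    Psp <- if (npat <= 300 && is.null(st$init_points)) {
      pats <- as.matrix(expand.grid(rep(list(seq_len(nu_g)),
                                        length(groups))))
      t(apply(pats, 1L, function(pk) apply_pattern(nlp$y0, pk)))
    } else {
      {
        M <- matrix(0, m_sparse, n)
        for (k in seq_len(m_sparse))
          M[k, ] <- apply_pattern(lhs_sample(1L, lower, upper)[1L, ],
                                  sample.int(nu_g, length(groups),
                                             replace = TRUE))
        M
      }
    }
    P <- rbind(P, Psp)
  }
  if (!is.null(st$init_points)) {
    ip <- st$init_points
    if (is.numeric(ip) && is.null(dim(ip))) ip <- matrix(ip, nrow = 1L)
    ip <- pmin(pmax(ip, matrix(lower, nrow(ip), n, byrow = TRUE)),
               matrix(upper, nrow(ip), n, byrow = TRUE))
    P <- rbind(ip, P)
  }
  pts <- apply(P, 1L, ev, simplify = FALSE)

  # reference set: half quality, half diversity (max-min scaled distance)
  b <- min(st$ref_set_size, length(pts))
  ord <- order(!vapply(pts, `[[`, TRUE, "feasible"),
               vapply(pts, function(s) if (s$feasible) s$cost else s$pen, 0))
  nq <- ceiling(b / 2)
  ref <- pts[ord[seq_len(nq)]]
  rest <- pts[setdiff(seq_along(pts), ord[seq_len(nq)])]
  while (length(ref) < b && length(rest)) {
    refY <- t(vapply(ref, `[[`, numeric(n), "y")) / rep(span, each = length(ref))
    dmin <- vapply(rest, function(s) {
      d <- sweep(refY, 2L, s$y / span)
      min(rowSums(d^2))
    }, 0)
    k <- which.max(dmin)
    ref <- c(ref, rest[k]); rest <- rest[-k]
  }

  improvements <- 0L
  polished <- rep(FALSE, length(ref))
  init_polished <- FALSE
  worst_idx <- function() {
    o <- order(!vapply(ref, `[[`, TRUE, "feasible"),
               vapply(ref, function(s) if (s$feasible) s$cost else s$pen, 0))
    o[length(o)]
  }

  last_polish_y <- NULL
  best_mult <- NULL
  run_polish <- function(from, final = FALSE, warm_mult = NULL) {
    ctl <- if (final && !is.null(st$local_final)) st$local_final else st$local
    if (!is.null(warm_mult))
      ctl <- utils::modifyList(ctl, list(nu0 = warm_mult$nu,
                                         mu0 = warm_mult$mu))
    res <- local_solve(nlp, y0 = from$y,
                       control = utils::modifyList(
                         list(feas_tol = st$feas_tol), ctl))
    if (final) last_polish_y <<- res$y
    evals <<- evals + res$evals
    s <- score_point(list(cost = res$cost, eq = res$eq, ineq = res$ineq),
                     st$penalty_weight, st$feas_tol)
    s$y <- res$y
    ensemble[[length(ensemble) + 1L]] <<- list(y = res$y, cost = res$cost,
                                               feasible = res$feasible,
                                               viol = res$viol)
    if (better_than(s, best)) {
      best <<- s
      best_mult <<- list(nu = res$nu_eq, mu = res$mu_in)
      history[[length(history) + 1L]] <<- c(evals, s$cost, s$viol)
    }
    s
  }

  # a supplied warm start is polished immediately with the final-polish
  # budget: in continuation settings (epsilon sweeps) it is near-feasible
  # with a good cost, but feasibility-first ranking would otherwise leave it
  # unpolished behind mediocre feasible points
  if (!is.null(st$init_points) && !isFALSE(st$polish_init)) {
    s0 <- list(y = pmin(pmax(as.numeric(st$init_points[1, ]), lower), upper))
    run_polish(s0, final = TRUE, warm_mult = st$warm_mult)
    init_polished <- TRUE
  }

  while (evals < st$max_evals) {
    progressed <- FALSE
    for (i in seq_along(ref)) {
      for (j in seq_along(ref)) {
        if (i >= j) next
        if (evals >= st$max_evals) break
        xi <- ref[[i]]$y; xj <- ref[[j]]$y
        lam <- stats::runif(n, -0.3, 1.3)
        child <- pmin(pmax(xi + lam * (xj - xi), lower), upper)
        s <- ev(child)
        # go-beyond: keep stepping while the child improves on both parents
        steps <- 0L
        while (better_than(s, ref[[i]]) && better_than(s, ref[[j]]) &&
               steps < 3L && evals < st$max_evals) {
          dirv <- s$y - xi
          child2 <- pmin(pmax(s$y + dirv, lower), upper)
          s2 <- ev(child2)
          if (!better_than(s2, s)) break
          s <- s2; steps <- steps + 1L
        }
        wi <- worst_idx()
        if (better_than(s, ref[[wi]])) {
          dmin <- min(vapply(ref, function(r)
            sum(((r$y - s$y) / span)^2), 0))
          if (dmin > 1e-12) {
            ref[[wi]] <- s
            polished[wi] <- FALSE
            improvements <- improvements + 1L
            progressed <- TRUE
            if (improvements %% st$local_solver_freq == 0L &&
                evals < st$max_evals) {
              bi <- order(!vapply(ref, `[[`, TRUE, "feasible"),
                          vapply(ref, function(r)
                            if (r$feasible) r$cost else r$pen, 0))
              k <- bi[which(!polished[bi])[1]]
              if (!is.na(k)) { ref[[k]] <- run_polish(ref[[k]]); polished[k] <- TRUE }
            }
          }
        }
      }
      if (evals >= st$max_evals) break
    }
    if (!progressed && evals < st$max_evals) {
      # stagnation: refresh the worst half of the reference set
      o <- order(!vapply(ref, `[[`, TRUE, "feasible"),
                 vapply(ref, function(s) if (s$feasible) s$cost else s$pen, 0))
      drop <- o[(nq + 1):length(o)]
      Pn <- lhs_sample(length(drop), lower, upper)
      for (k in seq_along(drop)) {
        if (evals >= st$max_evals) break
        ref[[drop[k]]] <- ev(Pn[k, ])
        polished[drop[k]] <- FALSE
      }
    }
  }
  # final polish from the incumbent (unless it is already the freshly
  # polished warm start)
  if (is.null(last_polish_y) || !identical(best$y, last_polish_y))
    run_polish(best, final = TRUE)

  hist_mat <- do.call(rbind, history)
  colnames(hist_mat) <- c("evals", "best_cost", "viol")
  list(y_best = best$y, cost = best$cost, feasible = best$feasible,
       viol = best$viol, history = hist_mat, mult = best_mult,
       ensemble = ensemble, evals = evals, seed = st$seed, settings = st)
}

#' Multistart local optimization
#'
#' Space-filling start points, one local solve each; the full ensemble of
#' endpoints is retained for solution-multiplicity analysis.
#'
#' @param nlp a discretized NLP.
#' @param n_starts number of starts (>= 1).
#' @param seed RNG seed.
#' @param control control list for \code{\link{local_solve}}.
#' @param init_points optional matrix of starts used before random ones.
#' @return a solve result as in \code{\link{scatter_search}}.
#' @export
multistart <- function(nlp, n_starts = 10L, seed = 1L, control = list(),
                       init_points = NULL) {
  stopifnot(n_starts >= 1)
  if (any(!is.finite(nlp$lower)) || any(!is.finite(nlp$upper)))
    stop("multistart needs finite bounds on every decision variable")
  set.seed(seed)
  P <- lhs_sample(n_starts, nlp$lower, nlp$upper)
  if (!is.null(init_points)) {
    ip <- init_points
    if (is.null(dim(ip))) ip <- matrix(ip, nrow = 1L)
    P <- rbind(ip, P)[seq_len(max(n_starts, nrow(ip))), , drop = FALSE]
  }
  evals <- 0L
  ensemble <- list()
  best <- NULL; best_res <- NULL
  history <- list()
  for (k in seq_len(nrow(P))) {
    res <- local_solve(nlp, y0 = P[k, ], control = control)
    evals <- evals + res$evals
    ensemble[[k]] <- list(y = res$y, cost = res$cost, feasible = res$feasible,
                          viol = res$viol)
    s <- list(cost = res$cost, feasible = res$feasible,
              pen = res$cost + 1e4 * res$viol^2, viol = res$viol)
    if (is.null(best) || better_than(s, best)) {
      best <- s; best_res <- res
      history[[length(history) + 1L]] <- c(evals, res$cost, res$viol)
    }
  }
  if (is.null(best_res) || (!best_res$feasible && all(!vapply(ensemble, `[[`, TRUE, "feasible"))))
    warning("all starts ended infeasible; returning least-infeasible point")
  hist_mat <- do.call(rbind, history)
  colnames(hist_mat) <- c("evals", "best_cost", "viol")
  list(y_best = best_res$y, cost = best_res$cost, feasible = best_res$feasible,
       viol = best_res$viol, history = hist_mat, ensemble = ensemble,
       evals = evals, seed = seed,
       nu_eq = best_res$nu_eq, mu_in = best_res$mu_in)
}
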