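#' Coupled population-Nash fixed point
#'
#' Finds the coexistence equilibrium of the slow population dynamics under
#' equilibrium behavior: biomasses \eqn{(N_c^*, N_p^*) > 0} at which both
#' per-capita growth rates vanish when evaluated at the mean-field Nash
#' equilibrium for those biomasses. The outer problem is a damped Newton
#' iteration on \eqn{(\log N_c, \log N_p)} with a finite-difference Jacobian;
#' every inner game solve is warm-started from the previous one.
#'
#' Because the consumer payoff is linear in its strategy, the consumer's
#' within-support fitness level equals its per-capita growth rate, so at a
#' converged coexistence equilibrium `lambda_c` is zero: the ideal free
#' distribution with zero fitness.
#'
#' @param params,env,grid model parameters, environment profiles, grid.
#' @param init optional starting biomasses, a [population_state()] or numeric
#'   `c(N_c, N_p)`.
#' @param tol tolerance on `max(|f_c|, |f_p|)` (month^-1), default 1e-10.
#' @param nash_tol tolerance for the inner game solves (default `tol/10`,
#'   floored at 1e-12).
#' @param max_iter outer Newton iteration budget.
#' @param box log10 search box for the biomasses (g m^-3).
#' @param pinned_strategies optional [strategy_pair()]: if supplied, behavior
#'   is frozen at these densities (no game solve) and the classical
#'   fixed-coefficient system is solved instead — the constant-behavior
#'   variant when given [uniform_strategies()].
#' @return an object of class `equilibrium_result`: `state`, `nash`
#'   (a `nash_solution`, or `NULL` when behavior is pinned), `growth_residuals`
#'   (named `c(f_c, f_p)`), `converged`, `iterations`.
#' @export
solve_coexistence_equilibrium <- function(params, env, grid, init = NULL,
                                          tol = 1e-10, nash_tol = NULL,
                                          max_iter = 100L,
                                          box = c(-6, 4),
                                          pinned_strategies = NULL) {
  if (is.null(nash_tol)) nash_tol <- max(tol / 10, 1e-12)
  if (is.null(init)) init <- c(0.5, 0.05)
  if (inherits(init, "population_state")) init <- c(init$N_c, init$N_p)
  stopifnot(length(init) == 2, all(init > 0))
  u <- log(init)
  lo <- box[1] * log(10); hi <- box[2] * log(10)

  warm <- NULL
  rates_at <- function(u) {
    st <- population_state(exp(u[1]), exp(u[2]))
    if (is.null(pinned_strategies)) {
      sol <- solve_nash(st, params, env, grid, init = warm, tol = nash_tol)
      warm <<- sol
      sigma <- sol$strategies
    } else {
      sol <- NULL
      sigma <- pinned_strategies
    }
    list(f = percap_growth_rates(st, sigma, params, env, grid),
         state = st, nash = sol)
  }

  cur <- rates_at(u)
  iters <- 0L

  # damped Newton sweep; returns TRUE if it made progress to tolerance
  newton_phase <- function(budget) {
    for (it in seq_len(budget)) {
      iters <<- iters + 1L
      if (max(abs(cur$f)) <= tol) return(TRUE)
      # forward-difference Jacobian in log space
      hstep <- 1e-7
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        up <- u; up[j] <- up[j] + hstep
        J[, j] <- (rates_at(up)$f - cur$f) / hstep
      }
      du <- tryCatch(solve(J, -cur$f), error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) {
        du <- -cur$f * 0.1  # gradient-free nudge if the Jacobian degenerates
      }
      # keep steps inside the box and bounded
      du <- pmax(pmin(du, 2), -2)
      t_step <- 1
      base <- max(abs(cur$f))
      ok <- FALSE
      for (ls in 1:30) {
        u_try <- pmax(pmin(u + t_step * du, hi), lo)
        cand <- tryCatch(rates_at(u_try), error = function(e) NULL)
        if (!is.null(cand) && all(is.finite(cand$f)) &&
            max(abs(cand$f)) < base * (1 - 1e-4 * t_step)) {
          ok <- TRUE
          break
        }
        t_step <- t_step / 2
      }
      if (!ok) return(FALSE)
      u <<- u_try; cur <<- cand
    }
    max(abs(cur$f)) <= tol
  }

  # pseudo-time fallback: the coexistence point of the behavioral system is
  # attracting in practice, so following N_i <- N_i exp(h f_i) with an
  # adaptive step pulls a stalled iterate into Newton's basin
  relax_phase <- function(budget) {
    h <- 0.5 / max(max(abs(cur$f)), 1e-3)
    for (it in seq_len(budget)) {
      r <- max(abs(cur$f))
      if (r <= 1e-2 || r <= tol) return(TRUE)
      du <- pmax(pmin(h * cur$f, 0.5), -0.5)
      u_try <- pmax(pmin(u + du, hi), lo)
      cand <- tryCatch(rates_at(u_try), error = function(e) NULL)
      if (is.null(cand) || any(!is.finite(cand$f))) return(FALSE)
      if (max(abs(cand$f)) < r) h <- h * 1.3 else h <- h / 2
      u <<- u_try; cur <<- cand
    }
    TRUE
  }

  for (phase in 1:4) {
    if (newton_phase(if (phase == 1) max_iter else 40L)) break
    if (!relax_phase(150L)) break
  }

  converged <- max(abs(cur$f)) <= tol
  if (!converged && (exp(u[1]) <= exp(lo) * 1.01 || exp(u[2]) <= exp(lo) * 1.01)) {
    stop(sprintf(
      paste0("no coexistence fixed point found inside the search box: ",
             "iterate at N_c = %.3e, N_p = %.3e with residuals ",
             "f_c = %.3e, f_p = %.3e (a boundary equilibrium is likely)"),
      exp(u[1]), exp(u[2]), cur$f[1], cur$f[2]), call. = FALSE)
  }
  structure(
    list(state = cur$state, nash = cur$nash,
         growth_residuals = cur$f, converged = converged, iterations = iters),
    class = "equilibrium_result"
  )
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf(
    "equilibrium_result: N_c* = %.8g, N_p* = %.8g (f_c %.2e, f_p %.2e, %s)\n",
    x$state$N_c, x$state$N_p, x$growth_residuals[1], x$growth_residuals[2],
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Multi-start agreement check for the coexistence equilibrium
#'
#' Runs [solve_coexistence_equilibrium()] from several random starting
#' biomasses and reports the maximum pairwise distance between the solutions
#' — a falsifiable numerical echo of the uniqueness of the coexistence fixed
#' point.
#'
#' @param params,env,grid as elsewhere.
#' @param n_starts number of restarts.
#' @param seed RNG seed for the starting points.
#' @param tol inner tolerance passed through.
#' @return list with `result` (the first solution), `states` (matrix of
#'   `n_starts` rows), and `max_pairwise` (largest absolute difference in
#'   either biomass across restarts).
#' @export
equilibrium_multistart <- function(params, env, grid, n_starts = 5,
                                   seed = 1234, tol = 1e-10) {
  set.seed(seed)
  starts <- matrix(10^stats::runif(2 * n_starts, -2, 1), ncol = 2)
  sols <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    sols[[i]] <- solve_coexistence_equilibrium(params, env, grid,
                                               init = starts[i, ], tol = tol)
  }
  states <- t(vapply(sols, function(s) c(s$state$N_c, s$state$N_p), numeric(2)))
  colnames(states) <- c("N_c", "N_p")
  max_pairwise <- max(apply(states, 2, function(col) diff(range(col))))
  list(result = sols[[1]], states = states, max_pairwise = max_pairwise)
}

#' Sweep a model parameter and track the equilibrium
#'
#' Re-solves the coexistence equilibrium along a sequence of values of `K`
#' (carrying capacity) or `c` (predator competition), warm-starting each solve
#' from the previous equilibrium (continuation). Individual failures are
#' flagged and the sweep continues.
#'
#' @param params base [model_parameters()]; the swept field is overwritten.
#' @param grid a [habitat_grid()].
#' @param which `"K"` or `"c"`.
#' @param values ascending nonnegative parameter values.
#' @param tol equilibrium tolerance.
#' @return an object of class `sweep_result`: list with `parameter`, `values`,
#'   `N_c`, `N_p` (vectors), `converged` (logical vector), `strategies_c`,
#'   `strategies_p` (n_nodes x length(values) matrices, NA columns on
#'   failure), and `grid`.
#' @export
sweep_parameter <- function(params, grid, which = c("K", "c"), values,
                            tol = 1e-10) {
  which <- match.arg(which)
  stopifnot(is.numeric(values), length(values) >= 1, all(values >= 0),
            !is.unsorted(values))
  nv <- length(values)
  n <- grid$n_nodes
  N_c <- N_p <- rep(NA_real_, nv)
  conv <- rep(FALSE, nv)
  Sc <- Sp <- matrix(NA_real_, n, nv)
  init <- NULL
  for (i in seq_len(nv)) {
    ov <- stats::setNames(list(values[i]), which)
    p_i <- do.call(model_parameters,
                   c(as.list(unclass(params))[setdiff(names(unclass(params)),
                                                      c("beta_c", which))],
                     ov))
    env_i <- environment_profiles(p_i, grid)
    res <- tryCatch(
      solve_coexistence_equilibrium(p_i, env_i, grid, init = init, tol = tol),
      error = function(e) NULL)
    if (!is.null(res)) {
      N_c[i] <- res$state$N_c
      N_p[i] <- res$state$N_p
      conv[i] <- res$converged
      Sc[, i] <- res$nash$strategies$sigma_c
      Sp[, i] <- res$nash$strategies$sigma_p
      init <- c(res$state$N_c, res$state$N_p)
    }
  }
  structure(
    list(parameter = which, values = values, N_c = N_c, N_p = N_p,
         converged = conv, strategies_c = Sc, strategies_p = Sp, grid = grid),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result over %s: %d values in [%g, %g], %d converged\n",
              x$parameter, length(x$values), min(x$values), max(x$values),
              sum(x$converged)))
  invisible(x)
}

#' Export a sweep to CSV
#'
#' Writes a tidy table (value, N_c, N_p, converged) and optionally a wide
#' strategy table (rows = depth, one column per parameter value).
#'
#' @param sweep a `sweep_result`.
#' @param path tidy CSV path.
#' @param strategies_path optional path prefix for the two wide strategy CSVs
#'   (suffixes `_sigma_c.csv`, `_sigma_p.csv`).
#' @return invisibly, the written paths.
#' @export
sweep_to_csv <- function(sweep, path, strategies_path = NULL) {
  df <- data.frame(value = sweep$values, N_c = sweep$N_c, N_p = sweep$N_p,
                   converged = sweep$converged)
  names(df)[1] <- sweep$parameter
  utils::write.csv(df, path, row.names = FALSE)
  written <- list(tidy = path)
  if (!is.null(strategies_path)) {
    for (sp in c("sigma_c", "sigma_p")) {
      m <- if (sp == "sigma_c") sweep$strategies_c else sweep$strategies_p
      wide <- data.frame(depth = sweep$grid$depths, m)
      names(wide)[-1] <- paste0(sweep$parameter, "_", sweep$values)
      f <- paste0(strategies_path, "_", sp, ".csv")
      utils::write.csv(wide, f, row.names = FALSE)
      written[[sp]] <- f
    }
  }
  invisible(written)
}
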