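#' One forward-Euler step of the population dynamics
#'
#' \eqn{N_i \leftarrow \max(0, N_i (1 + h f_i))} with the per-capita rates
#' evaluated at the supplied strategies. Clamping at zero is recorded in the
#' `"clamped"` attribute.
#'
#' @param state a [population_state()].
#' @param sigma a [strategy_pair()] (mean-field strategies for this instant).
#' @param params,env,grid as elsewhere.
#' @param h time step in months (> 0).
#' @return the next [population_state()].
#' @export
step_euler <- function(state, sigma, params, env, grid, h) {
  stopifnot(h > 0)
  f <- percap_growth_rates(state, sigma, params, env, grid)
  nc <- state$N_c * (1 + h * f[["f_c"]])
  np <- state$N_p * (1 + h * f[["f_p"]])
  out <- population_state(max(0, nc), max(0, np))
  attr(out, "clamped") <- (nc < 0) || (np < 0)
  out
}

#' Simulate the slow population dynamics
#'
#' Forward-Euler integration of \eqn{\dot N_i = N_i f_i}. In `"optimal"` mode
#' the instantaneous game is re-solved at every step (warm-started from the
#' previous step, exploiting the smooth transients); in `"constant"` mode both
#' strategies are pinned to the uniform density, recovering the classical
#' Rosenzweig-MacArthur system with spatially averaged coefficients.
#'
#' @param params,env,grid as elsewhere.
#' @param initial starting [population_state()].
#' @param t_end horizon in months.
#' @param h Euler step in months (default 0.01).
#' @param behavior_mode `"optimal"` or `"constant"`.
#' @param snapshot_stride store the strategy pair every this many steps
#'   (optimal mode only); 0 disables snapshots.
#' @param nash_tol tolerance for the per-step game solves.
#' @return an object of class `trajectory`: `times`, `N_c`, `N_p`,
#'   `behavior_mode`, and (optional) `snapshots` — a list with `times`,
#'   `sigma_c`, `sigma_p` matrices (n_nodes x n_snapshots).
#' @export
simulate_population <- function(params, env, grid, initial, t_end, h = 0.01,
                                behavior_mode = c("optimal", "constant"),
                                snapshot_stride = 10L, nash_tol = 1e-9) {
  behavior_mode <- match.arg(behavior_mode)
  stopifnot(t_end > 0, h > 0)
  n_steps <- ceiling(t_end / h)
  times <- seq(0, by = h, length.out = n_steps + 1)
  N_c <- N_p <- numeric(n_steps + 1)
  N_c[1] <- initial$N_c
  N_p[1] <- initial$N_p

  uniform <- uniform_strategies(grid)
  take_snaps <- behavior_mode == "optimal" && snapshot_stride > 0
  snaps <- if (take_snaps) {
    idx <- seq(1, n_steps + 1, by = snapshot_stride)
    list(times = times[idx], idx = idx,
         sigma_c = matrix(NA_real_, grid$n_nodes, length(idx)),
         sigma_p = matrix(NA_real_, grid$n_nodes, length(idx)),
         pos = 1L)
  } else NULL

  state <- initial
  warm <- NULL
  for (k in seq_len(n_steps + 1)) {
    if (behavior_mode == "optimal") {
      sol <- tryCatch(
        solve_nash(state, params, env, grid, init = warm, tol = nash_tol),
        error = function(e) e)
      if (inherits(sol, "error")) {
        warning(sprintf("game solve failed at t = %.4f: %s; returning partial trajectory",
                        times[k], conditionMessage(sol)), call. = FALSE)
        keep <- seq_len(k - 1)
        return(structure(list(times = times[keep], N_c = N_c[keep],
                              N_p = N_p[keep], behavior_mode = behavior_mode,
                              snapshots = snaps, complete = FALSE),
                         class = "trajectory"))
      }
      warm <- sol
      sigma <- sol$strategies
    } else {
      sigma <- uniform
    }
    if (take_snaps && snaps$pos <= length(snaps$idx) &&
        k == snaps$idx[snaps$pos]) {
      snaps$sigma_c[, snaps$pos] <- sigma$sigma_c
      snaps$sigma_p[, snaps$pos] <- sigma$sigma_p
      snaps$pos <- snaps$pos + 1L
    }
    if (k <= n_steps) {
      state <- step_euler(state, sigma, params, env, grid, h)
      N_c[k + 1] <- state$N_c
      N_p[k + 1] <- state$N_p
    }
  }
  if (take_snaps) snaps$pos <- NULL
  structure(list(times = times, N_c = N_c, N_p = N_p,
                 behavior_mode = behavior_mode, snapshots = snaps,
                 complete = TRUE),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory (%s behavior): %d points over [0, %g] months; final N_c = %.6g, N_p = %.6g\n",
    x$behavior_mode, length(x$times), max(x$times),
    x$N_c[length(x$N_c)], x$N_p[length(x$N_p)]))
  invisible(x)
}

#' Constant-behavior (uniform strategies) reduction
#'
#' With both strategies pinned to the uniform density, the spatial model
#' collapses to a planar Rosenzweig-MacArthur system with three quadrature
#' constants: `A = <1/capacity, 1>` (inverse-capacity mean), `b_bar =
#' <beta_p, 1>` (mean clearance, entering the functional response), and `q =
#' <beta_p, 1>` (quadratic competition-loss coefficient at uniform predator
#' density). The reduced rates are
#' \deqn{f_c = \beta_c (1 - N_c A) - F_p N_p \bar b / (F_p + N_c \bar b),
#'   \quad f_p = \varepsilon F_p N_c \bar b / (F_p + N_c \bar b)
#'   - c N_p q - \mu_p.}
#'
#' @param params,env,grid as elsewhere.
#' @return list with constants `A`, `b_bar`, `q` and a function
#'   `rates(N_c, N_p)` returning `c(f_c, f_p)`.
#' @export
constant_behavior_reduction <- function(params, env, grid) {
  one <- rep(1, grid$n_nodes)
  A <- inner_product(1 / env$capacity, one, grid)
  b_bar <- inner_product(env$beta_p, one, grid)
  q <- b_bar
  rates <- function(N_c, N_p) {
    B <- N_c * b_bar
    c(f_c = params$beta_c * (1 - N_c * A) -
        params$F_p * N_p * b_bar / (params$F_p + B),
      f_p = params$eps * params$F_p * B / (params$F_p + B) -
        params$c * N_p * q - params$mu_p)
  }
  list(A = A, b_bar = b_bar, q = q, rates = rates)
}

#' Oscillation amplitude by quarters of a time series
#'
#' Splits a population time series into `n_segments` equal windows and
#' reports the peak-to-peak amplitude of each — the in-code diagnostic used
#' for the limit-cycle vs. damping contrast between constant and optimal
#' behavior.
#'
#' @param traj a `trajectory`.
#' @param species `"N_c"` or `"N_p"`.
#' @param n_segments number of windows (default 4).
#' @return numeric vector of peak-to-peak amplitudes, one per window.
#' @export
oscillation_amplitudes <- function(traj, species = "N_c", n_segments = 4) {
  x <- traj[[species]]
  n <- length(x)
  bounds <- floor(seq(1, n + 1, length.out = n_segments + 1))
  vapply(seq_len(n_segments), function(i) {
    seg <- x[bounds[i]:(bounds[i + 1] - 1)]
    diff(range(seg))
  }, numeric(1))
}

#' Export a trajectory to CSV
#'
#' @param traj a `trajectory`.
#' @param path CSV path for the time series (time, N_c, N_p).
#' @param snapshots_path optional prefix for wide strategy-snapshot CSVs
#'   (depth x time; suffixes `_sigma_c.csv`, `_sigma_p.csv`).
#' @param grid required when writing snapshots.
#' @return invisibly, the written paths.
#' @export
trajectory_to_csv <- function(traj, path, snapshots_path = NULL, grid = NULL) {
  utils::write.csv(data.frame(time = traj$times, N_c = traj$N_c, N_p = traj$N_p),
                   path, row.names = FALSE)
  written <- list(series = path)
  if (!is.null(snapshots_path) && !is.null(traj$snapshots)) {
    stopifnot(!is.null(grid))
    for (sp in c("sigma_c", "sigma_p")) {
      m <- traj$snapshots[[sp]]
      wide <- data.frame(depth = grid$depths, m)
      names(wide)[-1] <- paste0("t_", traj$snapshots$times)
      f <- paste0(snapshots_path, "_", sp, ".csv")
      utils::write.csv(wide, f, row.names = FALSE)
      written[[sp]] <- f
    }
  }
  invisible(written)
}
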