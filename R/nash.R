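#' @name nash_solver
#' @title Mean-field Nash equilibrium of the instantaneous habitat game
#'
#' @description
#' At fixed population sizes, each individual picks the depth distribution
#' maximizing its instantaneous fitness against the mean-field distributions
#' of both species. The first-order (Karush-Kuhn-Tucker) conditions for the
#' symmetric mean-field equilibrium are, per species \eqn{i}:
#' \deqn{g_i - \lambda_i + \nu_i = 0, \quad \nu_i \ge 0, \quad \sigma_i \ge 0,
#'   \quad \langle \sigma_i, \nu_i \rangle = 0, \quad \langle \sigma_i, 1
#'   \rangle = 1}
#' where \eqn{g_i} is the strategy gradient of the individual payoff evaluated
#' at the mean field, \eqn{\lambda_i} the multiplier of the normalization
#' constraint and \eqn{\nu_i} the nonnegative slack. Within the occupied
#' habitat fitness is flat at \eqn{\lambda_i}; elsewhere it is no higher: the
#' simple ideal free distribution.
#'
#' The discretized system is solved as a square semismooth root problem, with
#' the nodewise complementarity between \eqn{\sigma_{ij}} and
#' \eqn{s_{ij} = \lambda_i - g_{ij}} encoded by the Fischer-Burmeister
#' function \eqn{\psi(a,b) = a + b - \sqrt{a^2+b^2}} and solved by damped
#' Newton iteration.
NULL

# Fischer-Burmeister complementarity function, optionally smoothed
# (Chen-Mangasarian): psi_mu(a, b) = a + b - sqrt(a^2 + b^2 + 2 mu).
# mu = 0 is the exact semismooth function; mu > 0 gives a smooth homotopy
# whose zeros satisfy a, b > 0 with a*b = mu.
fb_psi <- function(a, b, mu = 0) a + b - sqrt(a * a + b * b + 2 * mu)

fb_partials <- function(a, b, mu = 0) {
  r <- sqrt(a * a + b * b + 2 * mu)
  deg <- r < .Machine$double.eps
  r[deg] <- 1
  da <- 1 - a / r
  db <- 1 - b / r
  # at the origin (mu = 0) pick the centered element of the generalized Jacobian
  da[deg] <- 1 - 1 / sqrt(2)
  db[deg] <- 1 - 1 / sqrt(2)
  list(da = da, db = db)
}

# Strategy gradients for both species in one pass.
game_gradients <- function(state, sigma, params, env, grid) {
  B <- encounter_rate(state, sigma, params, env, grid)
  den <- params$F_p + B
  g_c <- params$beta_c * (1 - state$N_c * sigma$sigma_c / env$capacity) -
    params$F_p * env$beta_p * sigma$sigma_p * state$N_p / den
  g_p <- params$eps * params$F_p^2 * state$N_c * env$beta_p * sigma$sigma_c /
    den^2 - params$c * state$N_p * env$beta_p * sigma$sigma_p
  list(g_c = g_c, g_p = g_p, B = B, den = den)
}

# Analytic Jacobian of (g_c, g_p) with respect to (sigma_c, sigma_p):
# each block is diagonal plus a rank-one correction through the mean-field
# encounter rate B.
game_gradient_jacobian <- function(state, sigma, params, env, grid, grads) {
  n <- grid$n_nodes
  w <- grid$weights
  bp <- env$beta_p
  den <- grads$den
  Nc <- state$N_c; Np <- state$N_p
  Fp <- params$F_p; eps <- params$eps; cc <- params$c

  dB_dsc <- Nc * bp * sigma$sigma_p * w   # row vector of dB/dsigma_c
  dB_dsp <- Nc * bp * sigma$sigma_c * w

  u_c <- Fp * Np * bp * sigma$sigma_p / den^2     # dg_c/dB (columnwise factor)
  u_p <- -2 * eps * Fp^2 * Nc * bp * sigma$sigma_c / den^3  # dg_p/dB

  J_cc <- outer(u_c, dB_dsc)
  diag(J_cc) <- diag(J_cc) - params$beta_c * Nc / env$capacity
  J_cp <- outer(u_c, dB_dsp)
  diag(J_cp) <- diag(J_cp) - Fp * Np * bp / den
  J_pc <- outer(u_p, dB_dsc)
  diag(J_pc) <- diag(J_pc) + eps * Fp^2 * Nc * bp / den^2
  J_pp <- outer(u_p, dB_dsp)
  diag(J_pp) <- diag(J_pp) - cc * Np * bp

  list(J_cc = J_cc, J_cp = J_cp, J_pc = J_pc, J_pp = J_pp)
}

new_nash_solution <- function(sigma, lambda_c, lambda_p, nu_c, nu_p,
                              residuals, grid) {
  structure(
    list(strategies = sigma, lambda_c = lambda_c, lambda_p = lambda_p,
         nu_c = nu_c, nu_p = nu_p, residuals = residuals),
    class = "nash_solution"
  )
}

#' @export
print.nash_solution <- function(x, ...) {
  r <- x$residuals
  cat(sprintf(
    paste0("nash_solution: lambda_c = %.6g, lambda_p = %.6g\n",
           "  residuals: stationarity %.2e, complementarity %.2e, ",
           "negativity %.2e, normalization %.2e\n",
           "  %d iterations, converged: %s\n"),
    x$lambda_c, x$lambda_p, r$stationarity_inf_norm, r$complementarity,
    r$negativity, r$normalization, r$iterations, r$converged))
  invisible(x)
}

#' KKT residual report for a candidate Nash solution
#'
#' Evaluates the four first-order residual groups (stationarity,
#' complementary slackness, negativity, normalization) of a candidate
#' solution. Pure function; species with zero biomass are excluded from the
#' accounting because their payoff gradient constrains nothing.
#'
#' @param candidate a `nash_solution` (or a list with `strategies`,
#'   `lambda_c`, `lambda_p`, `nu_c`, `nu_p`).
#' @param state a [population_state()].
#' @param params,env,grid model parameters, environment profiles, grid.
#' @param iterations,converged bookkeeping fields copied into the report.
#' @return a list of class `residual_report` with `stationarity_inf_norm`,
#'   `complementarity`, `negativity`, `normalization`, `iterations`,
#'   `converged`.
#' @export
kkt_residual <- function(candidate, state, params, env, grid,
                         iterations = NA_integer_, converged = NA) {
  sig <- candidate$strategies
  if (length(sig$sigma_c) != grid$n_nodes || length(sig$sigma_p) != grid$n_nodes) {
    stop("candidate strategies do not conform to the grid", call. = FALSE)
  }
  grads <- game_gradients(state, sig, params, env, grid)
  one <- rep(1, grid$n_nodes)

  stat <- 0; comp <- 0; neg <- 0; norm <- 0
  acct <- function(sigma_i, g_i, lambda_i, nu_i) {
    stat <<- max(stat, max(abs(g_i - lambda_i + nu_i)))
    comp <<- max(comp, abs(inner_product(sigma_i, nu_i, grid)))
    neg <<- max(neg, -min(0, min(sigma_i), min(nu_i)))
    norm <<- max(norm, abs(inner_product(sigma_i, one, grid) - 1))
  }
  if (state$N_c > 0) acct(sig$sigma_c, grads$g_c, candidate$lambda_c, candidate$nu_c)
  if (state$N_p > 0) acct(sig$sigma_p, grads$g_p, candidate$lambda_p, candidate$nu_p)

  structure(list(stationarity_inf_norm = stat, complementarity = comp,
                 negativity = neg, normalization = norm,
                 iterations = iterations, converged = converged),
            class = "residual_report")
}

# Assemble the stacked semismooth system F(z) and its Jacobian.
# z = (sigma_c [if alive], lambda_c [if alive], sigma_p [if alive], lambda_p).
nash_system <- function(z, state, params, env, grid, alive_c, alive_p,
                        sigma_fixed, want_jacobian = TRUE, mu = 0) {
  n <- grid$n_nodes
  w <- grid$weights
  idx <- 0
  if (alive_c) { sc <- z[1:n]; lc <- z[n + 1]; idx <- n + 1 } else {
    sc <- sigma_fixed$sigma_c; lc <- 0
  }
  if (alive_p) { sp <- z[(idx + 1):(idx + n)]; lp <- z[idx + n + 1] } else {
    sp <- sigma_fixed$sigma_p; lp <- 0
  }
  sigma <- strategy_pair(sc, sp, grid, check = FALSE)
  grads <- game_gradients(state, sigma, params, env, grid)

  Fv <- numeric(length(z))
  J <- if (want_jacobian) matrix(0, length(z), length(z)) else NULL
  if (want_jacobian) {
    gj <- game_gradient_jacobian(state, sigma, params, env, grid, grads)
  }

  fill_block <- function(offset, sigma_i, lambda_i, g_i, Jg_self, Jg_other,
                         offset_other, alive_other) {
    s <- lambda_i - g_i
    p <- fb_partials(sigma_i, s, mu)
    Fv[offset + 1:n] <<- fb_psi(sigma_i, s, mu)
    Fv[offset + n + 1] <<- sum(w * sigma_i) - 1
    if (want_jacobian) {
      # d psi_j / d sigma_i = da * I - db * dg/dsigma_i ; d psi_j / d lambda = db
      Jblk <- -p$db * Jg_self                 # row scaling of the gradient block
      diag(Jblk) <- diag(Jblk) + p$da
      J[offset + 1:n, offset + 1:n] <<- Jblk
      J[offset + 1:n, offset + n + 1] <<- p$db
      J[offset + n + 1, offset + 1:n] <<- w
      if (alive_other) {
        J[offset + 1:n, offset_other + 1:n] <<- -p$db * Jg_other
      }
    }
  }

  off_c <- 0
  off_p <- if (alive_c) n + 1 else 0
  if (alive_c) {
    fill_block(off_c, sc, lc, grads$g_c,
               if (want_jacobian) gj$J_cc else NULL,
               if (want_jacobian) gj$J_cp else NULL,
               off_p, alive_p)
  }
  if (alive_p) {
    fill_block(off_p, sp, lp, grads$g_p,
               if (want_jacobian) gj$J_pp else NULL,
               if (want_jacobian) gj$J_pc else NULL,
               off_c, alive_c)
  }
  list(F = Fv, J = J, sigma = sigma, grads = grads,
       lambda_c = lc, lambda_p = lp)
}

#' Solve the instantaneous game for the mean-field Nash equilibrium
#'
#' Solves the discretized KKT system for both species simultaneously by a
#' damped semismooth Newton method on the Fischer-Burmeister reformulation.
#' A species with zero biomass has a strategy-independent payoff for the
#' others, so by convention its strategy is pinned to the uniform density and
#' excluded from the system.
#'
#' @param state a [population_state()]; `N_c`, `N_p` >= 0.
#' @param params,env,grid model parameters, environment profiles, grid.
#' @param init optional warm start: a `nash_solution` or a
#'   [strategy_pair()].
#' @param tol convergence tolerance on the infinity norm of all residual
#'   groups (default 1e-9).
#' @param max_iter maximum Newton iterations (default 200).
#' @return a `nash_solution`: strategies, multipliers `lambda_c`, `lambda_p`,
#'   slacks `nu_c`, `nu_p` and a `residual_report` with `converged = TRUE`.
#' @seealso [kkt_residual()], [replicator_solve()], [best_response_consumer()]
#' @export
solve_nash <- function(state, params, env, grid, init = NULL, tol = 1e-9,
                       max_iter = 200L) {
  n <- grid$n_nodes
  w <- grid$weights
  one <- rep(1, n)
  alive_c <- state$N_c > 0
  alive_p <- state$N_p > 0
  uniform <- uniform_strategies(grid)

  finish <- function(sigma, lc, lp, iters, conv) {
    grads <- game_gradients(state, sigma, params, env, grid)
    nu_c <- pmax(0, lc - grads$g_c)
    nu_p <- pmax(0, lp - grads$g_p)
    sol <- new_nash_solution(sigma, lc, lp, nu_c, nu_p, NULL, grid)
    sol$residuals <- kkt_residual(sol, state, params, env, grid,
                                  iterations = iters, converged = conv)
    sol
  }

  if (!alive_c && !alive_p) {
    return(finish(uniform, 0, 0, 0L, TRUE))
  }

  # initial iterate
  init_sigma <- uniform
  if (!is.null(init)) {
    init_sigma <- if (inherits(init, "nash_solution")) init$strategies else init
  }
  make_z <- function(sigma) {
    grads <- game_gradients(state, sigma, params, env, grid)
    z <- numeric(0)
    if (alive_c) z <- c(z, sigma$sigma_c, inner_product(one, grads$g_c, grid))
    if (alive_p) z <- c(z, sigma$sigma_p, inner_product(one, grads$g_p, grid))
    z
  }

  # Damped Newton (Levenberg-Marquardt fallback when the plain step stalls)
  # on the smoothed system at fixed mu.
  run_newton <- function(z0, mu, tol_inner, iter_budget) {
    z <- z0
    sys <- nash_system(z, state, params, env, grid, alive_c, alive_p, uniform,
                       mu = mu)
    merit <- 0.5 * sum(sys$F^2)
    iters <- 0L
    lm <- 0  # Levenberg-Marquardt damping, raised only when Newton stalls
    while (iters < iter_budget) {
      if (max(abs(sys$F)) <= tol_inner) {
        return(list(z = z, sys = sys, iters = iters, converged = TRUE))
      }
      iters <- iters + 1L
      step_of <- function(lm) {
        if (lm == 0) {
          dz <- tryCatch(solve(sys$J, -sys$F), error = function(e) NULL)
          if (!is.null(dz) && all(is.finite(dz))) return(dz)
          lm <- 1e-10
        }
        JtJ <- crossprod(sys$J)
        diag(JtJ) <- diag(JtJ) + lm * (1 + diag(JtJ))
        dz <- tryCatch(solve(JtJ, -crossprod(sys$J, sys$F)),
                       error = function(e) NULL)
        if (is.null(dz) || any(!is.finite(dz))) NULL else as.numeric(dz)
      }
      improved <- FALSE
      repeat {
        dz <- step_of(lm)
        if (!is.null(dz)) {
          # Armijo backtracking on the squared-residual merit
          t_step <- 1
          for (ls in 1:30) {
            z_try <- z + t_step * dz
            sys_try <- nash_system(z_try, state, params, env, grid,
                                   alive_c, alive_p, uniform, mu = mu,
                                   want_jacobian = FALSE)
            merit_try <- 0.5 * sum(sys_try$F^2)
            if (is.finite(merit_try) &&
                merit_try <= merit * (1 - 1e-4 * t_step)) {
              z <- z_try
              sys <- nash_system(z, state, params, env, grid,
                                 alive_c, alive_p, uniform, mu = mu)
              merit <- merit_try
              improved <- TRUE
              lm <- lm / 4
              break
            }
            t_step <- t_step / 2
          }
        }
        if (improved) break
        lm <- if (lm == 0) 1e-8 else lm * 100
        if (lm > 1e8) {
          return(list(z = z, sys = sys, iters = iters, converged = FALSE))
        }
      }
    }
    list(z = z, sys = sys, iters = iters,
         converged = max(abs(sys$F)) <= tol_inner)
  }

  # Try the exact (mu = 0) semismooth solve first; if it stalls, restart
  # through a smoothing homotopy, ending again at the exact system.
  run_homotopy <- function(z0) {
    res <- run_newton(z0, 0, tol_inner = tol, iter_budget = max_iter)
    if (res$converged) return(res)
    total <- res$iters
    z <- z0
    mu <- 1e-2
    while (mu > 1e-14) {
      step <- run_newton(z, mu, tol_inner = max(0.1 * mu, tol),
                         iter_budget = max_iter)
      z <- step$z
      total <- total + step$iters
      mu <- mu / 100
    }
    final <- run_newton(z, 0, tol_inner = tol, iter_budget = max_iter)
    final$iters <- total + final$iters
    if (!final$converged && max(abs(res$sys$F)) < max(abs(final$sys$F))) {
      res$iters <- final$iters
      return(res)
    }
    final
  }

  res <- run_homotopy(make_z(init_sigma))
  if (!res$converged) {
    # deterministic re-initialization: tilt the uniform start toward the
    # current payoff gradient (a crude best-response smoothing)
    grads0 <- game_gradients(state, uniform, params, env, grid)
    tilt <- function(g) {
      s <- exp((g - max(g)) / max(1e-8, stats::sd(g)))
      s / inner_product(s, one, grid)
    }
    sigma2 <- strategy_pair(tilt(grads0$g_c), tilt(grads0$g_p), grid, check = FALSE)
    res2 <- run_homotopy(make_z(sigma2))
    if (res2$converged ||
        max(abs(res2$sys$F)) < max(abs(res$sys$F))) res <- res2
  }

  sol <- finish(res$sys$sigma, res$sys$lambda_c, res$sys$lambda_p,
                res$iters, res$converged)
  if (!res$converged) {
    stop(structure(
      class = c("nash_solver_failure", "error", "condition"),
      list(message = sprintf(
        paste0("Nash solver did not converge in %d iterations ",
               "(residual %.3e > tol %.1e)"),
        res$iters, max(abs(res$sys$F)), tol),
        call = NULL, best = sol)))
  }
  sol
}

#' Consumer best response to fixed mean fields
#'
#' The consumer payoff is linear in the individual strategy, so the best
#' response concentrates all mass on the argmax of the pointwise fitness
#' `g_c`, spread uniformly (as a density) over maximizers tied within
#' `tie_tol`.
#'
#' @param mean_fields a [strategy_pair()] of mean-field strategies.
#' @param state,params,env,grid as elsewhere.
#' @param tie_tol absolute tolerance for counting a node as tied with the max.
#' @return a density vector on the grid.
#' @export
best_response_consumer <- function(mean_fields, state, params, env, grid,
                                   tie_tol = 1e-12) {
  g_c <- consumer_pointwise_fitness(state, mean_fields, params, env, grid)
  tied <- g_c >= max(g_c) - tie_tol
  sigma <- numeric(grid$n_nodes)
  sigma[tied] <- 1 / sum(grid$weights[tied])
  sigma
}

#' Replicator-dynamics oracle for the Nash equilibrium
#'
#' Independent check of [solve_nash()], in two stages. Stage one iterates the
#' (discretized, mean-field) replicator map
#' \eqn{\sigma \leftarrow \sigma (1 + \eta (g - \langle\sigma, g\rangle))}
#' for each living species — with an extragradient half-step to damp the
#' predator-prey rotation of the coupled flow, nonnegativity clipping and
#' renormalization — until the fitness spread is small enough to identify the
#' equilibrium support. Stage two polishes on that support: at fixed
#' multipliers \eqn{(\lambda_c, \lambda_p)} and encounter rate \eqn{B} the
#' two stationarity conditions are *linear* in \eqn{(\sigma_c(x),
#' \sigma_p(x))} at each node, so the densities are eliminated pointwise and
#' the three scalars are solved by a damped finite-difference Newton
#' iteration on the two normalization constraints plus the
#' encounter-rate consistency equation. The support is repaired (nodes with
#' negative eliminated density dropped, nodes with a positive off-support
#' fitness advantage added) until the full first-order conditions hold at
#' `tol`. The payoff gradients are the only ingredient shared with
#' [solve_nash()]; the algebraic path is disjoint.
#'
#' @param state,params,env,grid as elsewhere.
#' @param step nominal stage-one step size (> 0), rescaled by the current
#'   fitness spread.
#' @param max_iters stage-one iteration budget; if the support cannot be
#'   identified and polished within budget the oracle errors (oracle failures
#'   must not pass silently).
#' @param seed if non-`NULL`, the starting densities are jittered
#'   reproducibly.
#' @param tol tolerance on the within-support fitness spread and off-support
#'   advantage of the returned pair (month^-1).
#' @param support_tol density threshold below which a node counts as
#'   unoccupied.
#' @return a [strategy_pair()].
#' @export
replicator_solve <- function(state, params, env, grid, step = 0.2,
                             max_iters = 20000L, seed = NULL, tol = 1e-10,
                             support_tol = 1e-8) {
  stopifnot(step > 0)
  n <- grid$n_nodes
  w <- grid$weights
  one <- rep(1, n)
  alive_c <- state$N_c > 0
  alive_p <- state$N_p > 0

  spread_of <- function(sc, sp) {
    sigma <- strategy_pair(sc, sp, grid, check = FALSE)
    grads <- game_gradients(state, sigma, params, env, grid)
    worst <- 0
    each <- function(sigma_i, g_i) {
      lam <- sum(w * sigma_i * g_i)
      on_sup <- sigma_i > support_tol
      max(max(abs(g_i[on_sup] - lam)), max(g_i - lam))
    }
    if (alive_c) worst <- max(worst, each(sc, grads$g_c))
    if (alive_p) worst <- max(worst, each(sp, grads$g_p))
    worst
  }

  if (!alive_c && !alive_p) return(uniform_strategies(grid))
  if (alive_p && !alive_c) {
    # prey-free predator: with c > 0 the competition-minimizing density is
    # proportional to 1/beta_p; with c = 0 the payoff is flat and the
    # uniform density is (one of the) optima, matching the solver convention.
    sp <- if (params$c > 0) {
      s <- 1 / env$beta_p
      s / sum(w * s)
    } else one
    return(strategy_pair(one, sp, grid, check = FALSE))
  }

  init_density <- function() {
    if (is.null(seed)) return(one)
    s <- 1 + 0.5 * stats::runif(n)
    s / sum(w * s)
  }
  if (!is.null(seed)) set.seed(seed)
  sc <- init_density()
  sp <- if (alive_p) init_density() else one

  # ---- stage one: extragradient-damped replicator iteration ---------------
  advance <- function(sigma_i, dev, eta) {
    s <- pmax(0, sigma_i * (1 + eta * dev))
    s / sum(w * s)
  }
  half_devs <- function(sc_i, sp_i) {
    sigma <- strategy_pair(sc_i, sp_i, grid, check = FALSE)
    grads <- game_gradients(state, sigma, params, env, grid)
    list(dc = grads$g_c - sum(w * sc_i * grads$g_c),
         dp = grads$g_p - sum(w * sp_i * grads$g_p))
  }
  best <- list(sc = sc, sp = sp, spread = spread_of(sc, sp))
  for (it in seq_len(max_iters)) {
    d1 <- half_devs(sc, sp)
    eta_c <- step / (max(abs(d1$dc)) + 1e-15)
    eta_p <- step / (max(abs(d1$dp)) + 1e-15)
    sc_h <- if (alive_c) advance(sc, d1$dc, eta_c) else sc
    sp_h <- if (alive_p) advance(sp, d1$dp, eta_p) else sp
    d2 <- half_devs(sc_h, sp_h)
    if (alive_c) sc <- advance(sc, d2$dc, eta_c)
    if (alive_p) sp <- advance(sp, d2$dp, eta_p)
    if (it %% 25 == 0 || it == max_iters) {
      s <- spread_of(sc, sp)
      if (s < best$spread) best <- list(sc = sc, sp = sp, spread = s)
      if (s <= tol) return(strategy_pair(sc, sp, grid, check = FALSE))
      # support is identifiable long before the spread is tight
      if (s < 1e-2 && it >= 500) break
    }
  }
  sc <- best$sc; sp <- best$sp

  if (!alive_p) {
    # single-species consumer game: sigma_c = cap (beta_c - lambda_c) /
    # (beta_c N_c) on its support; normalization fixes lambda_c.
    S <- sc > support_tol
    for (rep_i in 1:(n + 2)) {
      csum <- sum(w[S] * env$capacity[S])
      lam <- params$beta_c * (1 - state$N_c / csum)
      sig <- numeric(n)
      sig[S] <- env$capacity[S] * (params$beta_c - lam) /
        (params$beta_c * state$N_c)
      if (all(sig >= 0)) {
        g <- params$beta_c * (1 - state$N_c * sig / env$capacity)
        bad <- !S & (g > lam + tol)
        if (!any(bad)) {
          out <- strategy_pair(sig, sp, grid, check = FALSE)
          if (spread_of(sig, sp) <= tol) return(out)
          break
        }
        S[which.max(g - lam)] <- TRUE
      } else {
        S[which.min(sig)] <- FALSE
      }
    }
    stop("replicator oracle: consumer support repair failed", call. = FALSE)
  }

  # ---- stage two: support reduction + 3-scalar Newton polish --------------
  bp <- env$beta_p
  cap <- env$capacity
  Nc <- state$N_c; Np <- state$N_p
  Fp <- params$F_p; epsv <- params$eps; cc <- params$c
  bc <- params$beta_c

  densities_at <- function(th, Sc, Sp) {
    lam_c <- th[1]; lam_p <- th[2]; B <- th[3]
    den <- Fp + B
    sig_c <- numeric(n); sig_p <- numeric(n)
    both <- Sc & Sp
    if (any(both)) {
      # [ a11 a12 ] [sig_c]   [ bc - lam_c ]
      # [ a21 a22 ] [sig_p] = [ -lam_p     ]   (pointwise 2x2)
      a11 <- bc * Nc / cap[both]
      a12 <- rep(Fp * Np / den, sum(both)) * bp[both]
      a21 <- -epsv * Fp^2 * Nc * bp[both] / den^2
      a22 <- cc * Np * bp[both]
      det <- a11 * a22 - a12 * a21
      r1 <- bc - lam_c
      r2 <- -lam_p
      sig_c[both] <- (a22 * r1 - a12 * r2) / det
      sig_p[both] <- (a11 * r2 - a21 * r1) / det
    }
    conly <- Sc & !Sp
    if (any(conly)) {
      sig_c[conly] <- cap[conly] * (bc - lam_c) / (bc * Nc)
    }
    ponly <- Sp & !Sc
    if (any(ponly)) {
      if (cc == 0) return(NULL)  # degenerate; force support repair
      sig_p[ponly] <- lam_p / (cc * Np * bp[ponly])
    }
    list(sig_c = sig_c, sig_p = sig_p)
  }
  # At fixed encounter rate B the eliminated densities are affine in
  # (lambda_c, lambda_p), so the two normalization constraints solve as a
  # 2x2 linear system and the whole polish reduces to one scalar equation
  # F3(B) = N_c <beta_p sigma_c, sigma_p> - B = 0, root-found by a log-scale
  # scan plus bisection. No initialization is needed.
  lambdas_at <- function(B, Sc, Sp) {
    d0 <- densities_at(c(0, 0, B), Sc, Sp)
    dc <- densities_at(c(1, 0, B), Sc, Sp)
    dp <- densities_at(c(0, 1, B), Sc, Sp)
    if (is.null(d0) || is.null(dc) || is.null(dp)) return(NULL)
    M <- matrix(c(sum(w * (dc$sig_c - d0$sig_c)), sum(w * (dc$sig_p - d0$sig_p)),
                  sum(w * (dp$sig_c - d0$sig_c)), sum(w * (dp$sig_p - d0$sig_p))),
                2, 2)
    rhs <- c(1 - sum(w * d0$sig_c), 1 - sum(w * d0$sig_p))
    lam <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(lam) || any(!is.finite(lam))) return(NULL)
    d <- densities_at(c(lam[1], lam[2], B), Sc, Sp)
    list(lam = lam, d = d,
         F3 = Nc * sum(w * bp * d$sig_c * d$sig_p) - B)
  }

  # Validate a candidate root: nonnegative densities, no off-support fitness
  # advantage, small overall spread.
  validate <- function(root, Sc, Sp) {
    d <- root$d
    if (min(d$sig_c) < -1e-10 || min(d$sig_p) < -1e-10) {
      return(list(status = "negative", d = d))
    }
    sig_c <- pmax(0, d$sig_c); sig_p <- pmax(0, d$sig_p)
    pair <- strategy_pair(sig_c, sig_p, grid, check = FALSE)
    grads <- game_gradients(state, pair, params, env, grid)
    adv_c <- grads$g_c - root$lam[1]
    adv_p <- grads$g_p - root$lam[2]
    if (any(!Sc & (adv_c > tol)) || any(!Sp & (adv_p > tol))) {
      return(list(status = "advantage", adv_c = adv_c, adv_p = adv_p))
    }
    if (spread_of(sig_c, sig_p) > max(tol, 1e-9)) {
      return(list(status = "spread"))
    }
    list(status = "ok", pair = pair)
  }

  # All equilibria on a fixed support pair (one per root of F3).
  attempt <- function(Sc, Sp) {
    Bs <- sort(unique(c(0, 10^seq(-8, 4, length.out = 49))))
    f3 <- vapply(Bs, function(B) {
      r <- lambdas_at(B, Sc, Sp)
      if (is.null(r)) NA_real_ else r$F3
    }, numeric(1))
    pairs <- list()
    diag <- list(status = "newton_failed")
    for (i in seq_len(length(Bs) - 1)) {
      if (!is.finite(f3[i]) || !is.finite(f3[i + 1])) next
      if (f3[i] == 0) {
        root <- lambdas_at(Bs[i], Sc, Sp)
      } else if (f3[i] * f3[i + 1] < 0) {
        Bstar <- tryCatch(
          stats::uniroot(function(B) {
            r <- lambdas_at(B, Sc, Sp)
            if (is.null(r)) NA_real_ else r$F3
          }, c(Bs[i], Bs[i + 1]), tol = 1e-15 * max(1, Bs[i + 1]))$root,
          error = function(e) NULL)
        if (is.null(Bstar)) next
        root <- lambdas_at(Bstar, Sc, Sp)
      } else next
      if (is.null(root)) next
      res <- validate(root, Sc, Sp)
      if (res$status == "ok") {
        pairs[[length(pairs) + 1]] <- res$pair
      } else if (diag$status %in% c("newton_failed", "spread")) {
        diag <- res
      }
    }
    if (length(pairs)) list(status = "ok", pairs = pairs) else diag
  }

  nearest_to_stage1 <- function(pairs) {
    d_to_stage1 <- vapply(pairs, function(pr) {
      max(abs(pr$sigma_c - sc), abs(pr$sigma_p - sp))
    }, numeric(1))
    pairs[[which.min(d_to_stage1)]]
  }

  Sc <- sc > support_tol
  Sp <- sp > support_tol
  # without predator competition the predator payoff is proportional to
  # beta_p sigma_c, so predator-occupied nodes must carry consumers
  if (cc == 0) Sc <- Sc | Sp

  for (repair in 1:(2 * n + 4)) {
    res <- attempt(Sc, Sp)
    if (res$status == "ok") return(nearest_to_stage1(res$pairs))
    if (res$status == "advantage") {
      if (any(!Sc & (res$adv_c > tol))) Sc[which.max(res$adv_c * !Sc)] <- TRUE
      if (any(!Sp & (res$adv_p > tol))) Sp[which.max(res$adv_p * !Sp)] <- TRUE
      if (cc == 0) Sc <- Sc | Sp
    } else if (res$status == "negative") {
      if (min(res$d$sig_c) < min(res$d$sig_p)) {
        Sc[which.min(replace(res$d$sig_c, !Sc, Inf))] <- FALSE
      } else {
        Sp[which.min(replace(res$d$sig_p, !Sp, Inf))] <- FALSE
      }
    } else {
      # no usable root: drop the weakest occupied node and retry
      if (sum(Sp) > 1 && (cc == 0 || sum(Sp) >= sum(Sc))) {
        Sp[which.min(replace(sp, !Sp, Inf))] <- FALSE
      } else if (sum(Sc) > 1) {
        Sc[which.min(replace(sc, !Sc, Inf))] <- FALSE
      } else {
        break
      }
    }
  }

  # Exhaustive support enumeration on very coarse grids, where the stage-one
  # iteration can orbit too far out to identify the support reliably. All
  # valid equilibria are collected and the one nearest the stage-one iterate
  # is returned: the oracle selects the equilibrium its own dynamics
  # approaches, so a (rare) non-unique discretized game is resolved
  # dynamically rather than by enumeration order.
  if (n <= 6) {
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    sets <- lapply(seq_len(nrow(combos)), function(i) {
      as.logical(unlist(combos[i, ]))
    })
    sets <- Filter(any, sets)
    found <- list()
    for (Sc_try in sets) {
      for (Sp_try in sets) {
        if (cc == 0 && any(Sp_try & !Sc_try)) next
        res <- attempt(Sc_try, Sp_try)
        if (res$status == "ok") found <- c(found, res$pairs)
      }
    }
    if (length(found)) return(nearest_to_stage1(found))
  }
  stop(sprintf(
    "replicator oracle did not converge (stage-one spread %.3e)", best$spread),
    call. = FALSE)
}

#' Serialize a Nash solution
#'
#' @param sol a `nash_solution`.
#' @param grid the matching grid.
#' @param json_path,csv_path optional output paths; the CSV has columns
#'   depth, sigma_c, sigma_p, g_c, g_p (the spatial-distribution-and-fitness
#'   layout).
#' @param state,params,env needed to recompute the fitness columns for the CSV.
#' @return invisibly, a list of written paths.
#' @export
nash_to_files <- function(sol, grid, json_path = NULL, csv_path = NULL,
                          state = NULL, params = NULL, env = NULL) {
  written <- list()
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(sigma_c = sol$strategies$sigma_c, sigma_p = sol$strategies$sigma_p,
           lambda_c = sol$lambda_c, lambda_p = sol$lambda_p,
           nu_c = sol$nu_c, nu_p = sol$nu_p,
           residuals = unclass(sol$residuals)),
      json_path, auto_unbox = TRUE, digits = NA)
    written$json <- json_path
  }
  if (!is.null(csv_path)) {
    stopifnot(!is.null(state), !is.null(params), !is.null(env))
    grads <- game_gradients(state, sol$strategies, params, env, grid)
    utils::write.csv(
      data.frame(depth = grid$depths,
                 sigma_c = sol$strategies$sigma_c,
                 sigma_p = sol$strategies$sigma_p,
                 g_c = grads$g_c, g_p = grads$g_p),
      csv_path, row.names = FALSE)
    written$csv <- csv_path
  }
  invisible(written)
}
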