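#' @name diagnostics
#' @title Numerical probes of the game's theoretical structure
#'
#' @description
#' Three samplers verify, numerically and falsifiably, the structure the
#' theory predicts: the ideal-free (flat-fitness) geometry of converged
#' equilibria, the evolutionary-stability inequality against random mutant
#' strategies, and strict pseudomonotonicity of the game operator. Probes are
#' samplers, not proofs: a pass is reported as *consistency with* the
#' property, and worst-case margins are logged so regressions are visible.
NULL

new_diagnostic_report <- function(check, pass, margin, n_samples, seed,
                                  details = NULL) {
  structure(list(check = check, pass = pass, margin = margin,
                 n_samples = n_samples, seed = seed, details = details),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("diagnostic [%s]: %s (worst margin %.3e, %d samples%s)\n",
              x$check, if (x$pass) "PASS" else "FAIL", x$margin, x$n_samples,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  invisible(x)
}

#' Ideal-free-distribution check
#'
#' At an ideal free distribution each species' fitness is constant (equal to
#' its multiplier \eqn{\lambda_i}) wherever the species is present, and no
#' higher anywhere else. Passes iff, for every living species,
#' `max |g_i - lambda_i|` over the support and `max (g_i - lambda_i)` off the
#' support are both within `tol`.
#'
#' @param solution a converged `nash_solution`.
#' @param state,params,env,grid as elsewhere.
#' @param tol tolerance (month^-1).
#' @param support_tol density threshold defining the occupied habitat.
#' @return a `diagnostic_report`; `margin` is the worst violation (<= tol on
#'   pass).
#' @export
check_ifd <- function(solution, state, params, env, grid, tol = 1e-8,
                      support_tol = 1e-8) {
  grads <- game_gradients(state, solution$strategies, params, env, grid)
  worst <- 0
  eval_species <- function(sigma_i, g_i, lambda_i) {
    on_sup <- sigma_i > support_tol
    m <- 0
    if (any(on_sup)) m <- max(m, max(abs(g_i[on_sup] - lambda_i)))
    if (any(!on_sup)) m <- max(m, max(0, max(g_i[!on_sup] - lambda_i)))
    m
  }
  if (state$N_c > 0) {
    worst <- max(worst, eval_species(solution$strategies$sigma_c, grads$g_c,
                                     solution$lambda_c))
  }
  if (state$N_p > 0) {
    worst <- max(worst, eval_species(solution$strategies$sigma_p, grads$g_p,
                                     solution$lambda_p))
  }
  new_diagnostic_report("ideal_free_distribution", worst <= tol, worst,
                        n_samples = grid$n_nodes, seed = NULL)
}

# Dirichlet-like jitter of a density restricted to (mostly) the resident's
# support, with optional off-support mass injection.
perturb_density <- function(sigma, grid, magnitude, off_support_frac = 0.2,
                            support_tol = 1e-8) {
  n <- grid$n_nodes
  on_sup <- sigma > support_tol
  jitter <- stats::rexp(n)
  omega <- sigma * (1 + magnitude * (jitter - 1))
  if (any(!on_sup) && stats::runif(1) < off_support_frac) {
    j <- sample(which(!on_sup), 1)
    omega[j] <- omega[j] + magnitude / grid$weights[j]
  }
  omega <- pmax(0, omega)
  omega / sum(grid$weights * omega)
}

#' Evolutionary-stability check against random mutant strategies
#'
#' A strategy profile is evolutionarily stable when slightly perturbed mutant
#' strategies do no better against the resident population. For each random
#' feasible perturbation \eqn{\omega \ne \bar\sigma_i} this checks the
#' variational-inequality form \eqn{\langle -g_i, \omega - \bar\sigma_i\rangle
#' \ge 0}, i.e. no mutant registers a fitness advantage beyond `tol`.
#'
#' @param solution a converged `nash_solution`.
#' @param state,params,env,grid as elsewhere.
#' @param n_perturbations random mutants per species.
#' @param magnitude relative perturbation size (default 1e-3).
#' @param seed RNG seed.
#' @param tol advantage tolerance (month^-1).
#' @return a `diagnostic_report`; `margin` is the largest observed mutant
#'   advantage (should be <= tol).
#' @export
check_ess <- function(solution, state, params, env, grid,
                      n_perturbations = 200, magnitude = 1e-3, seed = 42,
                      tol = 1e-9) {
  set.seed(seed)
  grads <- game_gradients(state, solution$strategies, params, env, grid)
  worst <- -Inf
  species <- list()
  if (state$N_c > 0) species$c <- list(sigma = solution$strategies$sigma_c,
                                       g = grads$g_c)
  if (state$N_p > 0) species$p <- list(sigma = solution$strategies$sigma_p,
                                       g = grads$g_p)
  for (sp in species) {
    for (r in seq_len(n_perturbations)) {
      omega <- perturb_density(sp$sigma, grid, magnitude)
      if (max(abs(omega - sp$sigma)) == 0) next  # omega must differ
      adv <- inner_product(sp$g, omega - sp$sigma, grid)
      worst <- max(worst, adv)
    }
  }
  new_diagnostic_report("evolutionary_stability", worst <= tol, worst,
                        n_samples = n_perturbations * length(species),
                        seed = seed)
}

#' Strict-pseudomonotonicity probe for a game operator
#'
#' Samples pairs \eqn{(x, y)} of feasible points and flags violations of the
#' defining implication \eqn{\langle x-y, T(y)\rangle \ge 0 \Rightarrow
#' \langle x-y, T(x)\rangle > 0}; the pass flag reflects this definitional
#' test. Additionally runs the differential probe: for sampled \eqn{x} and
#' feasible directions \eqn{h} projected onto \eqn{\langle T(x), h\rangle =
#' 0}, it measures \eqn{\langle \nabla T(x) h, h\rangle} by central finite
#' differences. Positive curvature everywhere is *sufficient* for strict
#' pseudomonotonicity but not necessary, so the minimal observed curvature is
#' reported in `details` without gating the pass flag: a negative curvature
#' direction with no pairwise violation means the sufficient condition fails
#' while the property itself remains unrefuted.
#'
#' @param operator function mapping a feasible point (numeric vector) to the
#'   operator value (same length); inner products use `weights`.
#' @param sampler function `(i)` returning the i-th sample point.
#' @param n_pairs number of sampled pairs (and differential tests).
#' @param seed RNG seed.
#' @param weights quadrature weights defining the inner product (defaults to
#'   the Euclidean inner product).
#' @param tangent optional projection onto the admissible directions of the
#'   feasible set (e.g. mean-zero per species on a product of simplices); the
#'   differential test only probes directions that stay feasible, since the
#'   operator is only required to be pseudomonotone on the constraint set.
#' @param tol numerical slack for the premise and conclusion.
#' @param fd_step finite-difference step for the differential test.
#' @return a `diagnostic_report`; `margin` is the minimum observed
#'   \eqn{\langle x-y, T(x)\rangle} over pairs whose premise held (pairwise
#'   test) together with the minimal curvature from the differential test;
#'   `details` carries both separately.
#' @export
pseudomonotonicity_probe <- function(operator, sampler, n_pairs = 100,
                                     seed = 1, weights = NULL, tangent = NULL,
                                     tol = 1e-10, fd_step = 1e-6) {
  stopifnot(n_pairs >= 1)
  set.seed(seed)
  ip <- function(a, b) if (is.null(weights)) sum(a * b) else sum(weights * a * b)

  min_pair_margin <- Inf
  violations <- 0L
  for (i in seq_len(n_pairs)) {
    x <- sampler(2 * i - 1)
    y <- sampler(2 * i)
    if (max(abs(x - y)) == 0) next
    if (ip(x - y, operator(y)) >= -tol) {
      m <- ip(x - y, operator(x))
      min_pair_margin <- min(min_pair_margin, m)
      if (m <= tol) violations <- violations + 1L
    }
  }

  min_curvature <- Inf
  for (i in seq_len(n_pairs)) {
    x <- sampler(2 * n_pairs + i)
    h <- stats::rnorm(length(x))
    if (!is.null(tangent)) h <- tangent(h)
    Tx <- operator(x)
    Tt <- if (is.null(tangent)) Tx else tangent(Tx)
    nT2 <- ip(Tt, Tt)
    if (nT2 > 0) h <- h - ip(Tx, h) / nT2 * Tt  # project onto <T(x), h> = 0
    if (max(abs(h)) == 0) next
    dTh <- (operator(x + fd_step * h) - operator(x - fd_step * h)) / (2 * fd_step)
    curv <- ip(dTh, h)
    min_curvature <- min(min_curvature, curv)
  }

  new_diagnostic_report(
    "strict_pseudomonotonicity", violations == 0L, min_pair_margin,
    n_samples = n_pairs, seed = seed,
    details = list(min_pair_margin = min_pair_margin,
                   min_curvature = min_curvature, violations = violations))
}

#' Game operator -dU for the two-species habitat game
#'
#' Returns the stacked operator `S -> -dU(S)` (negated strategy gradients of
#' both species, evaluated at the mean field) as a plain function of a stacked
#' vector `c(sigma_c, sigma_p)` — the operator whose strict pseudomonotonicity
#' underlies uniqueness of the Nash equilibrium and the evolutionary-stability
#' property.
#'
#' @param state,params,env,grid as elsewhere.
#' @return function from `numeric(2 n)` to `numeric(2 n)`.
#' @export
game_operator <- function(state, params, env, grid) {
  n <- grid$n_nodes
  function(s) {
    sigma <- strategy_pair(s[1:n], s[(n + 1):(2 * n)], grid, check = FALSE)
    grads <- game_gradients(state, sigma, params, env, grid)
    -c(grads$g_c, grads$g_p)
  }
}

#' Random density sampler on a grid
#'
#' Returns a deterministic-by-index sampler of random probability densities
#' (Dirichlet-like: normalized exponentials), for use with
#' [pseudomonotonicity_probe()]. `stacked = TRUE` samples a consumer-predator
#' pair as one stacked vector.
#'
#' @param grid a [habitat_grid()].
#' @param seed base seed; sample `i` uses `seed + i`.
#' @param stacked sample a stacked pair instead of a single density.
#' @return function `(i)` returning a density (or stacked pair of densities).
#' @export
density_sampler <- function(grid, seed = 0, stacked = FALSE) {
  n <- grid$n_nodes
  one <- rep(1, n)
  draw <- function() {
    s <- stats::rexp(n)
    s / inner_product(s, one, grid)
  }
  function(i) {
    set.seed(seed + i)
    if (stacked) c(draw(), draw()) else draw()
  }
}

#' Tangent projection for densities on a grid
#'
#' Returns the projection onto the feasible directions of the (product of)
#' probability simplices: each species block is made mean-zero with respect
#' to the habitat measure, since moving along a density difference must
#' conserve total probability.
#'
#' @param grid a [habitat_grid()].
#' @param stacked if `TRUE`, the vector holds two stacked species blocks.
#' @return function mapping a direction vector to its feasible projection.
#' @export
simplex_tangent <- function(grid, stacked = FALSE) {
  n <- grid$n_nodes
  w <- grid$weights
  center <- function(h) h - sum(w * h)  # weights sum to 1
  if (!stacked) return(center)
  function(h) c(center(h[1:n]), center(h[(n + 1):(2 * n)]))
}

#' Serialize a diagnostic report to JSON
#'
#' @param report a `diagnostic_report`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  x <- unclass(report)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
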