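#' Model parameters for the behaviorally modified Rosenzweig-MacArthur system
#'
#' Returns the default parameterization of the water-column predator-prey
#' model (zooplankton consumers, forage-fish predators) and applies any
#' overrides. Defaults follow Kleiber-law scaling for the rate constants, with
#' masses, scalings and rate values taken from the standard table used with
#' this model:
#'
#' \describe{
#'   \item{m_c = 0.01 g}{consumer mass}
#'   \item{m_p = 10 g}{predator mass}
#'   \item{alpha = 1.25 g^{1/4}/month}{consumption-rate scaling}
#'   \item{b = 27.5 g^{1/4} m^3/month}{clearance-rate scaling}
#'   \item{gamma = 0.2}{respiration-to-max-growth ratio}
#'   \item{K0 = 1e-4 g m^-3}{minimal carrying capacity}
#'   \item{K = 3 g m^-3}{varying carrying capacity (swept in experiments)}
#'   \item{beta0 = 1e-4 m^3/month}{minimal predator clearance}
#'   \item{mu_p = 0.35 month^-1}{predator metabolic rate}
#'   \item{F_p = 7 month^-1}{predator maximal consumption (1/handling time)}
#'   \item{eps = 0.1}{trophic efficiency}
#'   \item{k_light = 0.05 m^-1}{light attenuation}
#'   \item{kappa = 0.1 m^2}{decay scale of predation success}
#'   \item{c = 0}{intraspecific predator competition (dimensionless)}
#' }
#'
#' Derived: `beta_c = b * m_c^0.75` (consumer clearance, depth-independent:
#' olfactory forager). The tabulated `mu_p` and `F_p` are *not* identical to
#' the raw scaling values `gamma * m_p^0.75` and `alpha * m_p^0.75`; the table
#' values are the defaults, but `derive_from_scaling = TRUE` switches to the
#' scaling formulas.
#'
#' @param ... named overrides of any field above (plus `d_coef`, the exponent
#'   coefficient of the predation-success profile `D(x) = exp(-d_coef * x^2)`,
#'   default `k_light * kappa`).
#' @param derive_from_scaling if `TRUE`, set `F_p = alpha * m_p^0.75` and
#'   `mu_p = gamma * m_p^0.75` instead of the tabulated values.
#' @return an object of class `model_params` (named list).
#' @examples
#' p <- model_parameters(K = 40, c = 0)
#' p$beta_c   # 27.5 * 0.01^0.75 ~ 0.8696
#' @export
model_parameters <- function(..., derive_from_scaling = FALSE) {
  defaults <- list(
    m_c = 0.01, m_p = 10, alpha = 1.25, b = 27.5, gamma = 0.2,
    K0 = 1e-4, K = 3, beta0 = 1e-4, mu_p = 0.35, F_p = 7,
    eps = 0.1, k_light = 0.05, kappa = 0.1, c = 0, d_coef = NA_real_
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad <- vapply(overrides, function(v) {
      !is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0
    }, logical(1))
    if (any(bad)) {
      stop("invalid (negative or non-numeric) override for: ",
           paste(names(overrides)[bad], collapse = ", "), call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  p <- defaults
  if (derive_from_scaling) {
    if (!("F_p" %in% names(overrides))) p$F_p <- p$alpha * p$m_p^0.75
    if (!("mu_p" %in% names(overrides))) p$mu_p <- p$gamma * p$m_p^0.75
  }
  if (is.na(p$d_coef)) p$d_coef <- p$k_light * p$kappa
  p$beta_c <- p$b * p$m_c^0.75
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params:\n")
  flds <- unclass(x)
  cat(paste0("  ", names(flds), " = ", vapply(flds, format, character(1))),
      sep = "\n")
  invisible(x)
}

#' Spatial environment profiles on a grid
#'
#' Evaluates the depth-dependent fields of the model: light/resource profile
#' `phi(x) = exp(-k_light * x)`, predation-success profile
#' `D(x) = exp(-d_coef * x^2)` (visual predator, most effective near the
#' surface), total predator clearance `beta_p = b * m_p^0.75 * D + beta0`,
#' and the consumer carrying-capacity profile `capacity = K * phi + K0`.
#'
#' @param params a [model_parameters()] object.
#' @param grid a [habitat_grid()].
#' @return an object of class `env_profiles`: list with vectors `phi`, `D`,
#'   `beta_p`, `capacity` on the grid nodes.
#' @export
environment_profiles <- function(params, grid) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "habitat_grid"))
  x <- grid$depths
  phi <- exp(-params$k_light * x)
  D <- exp(-params$d_coef * x^2)
  beta_p <- params$b * params$m_p^0.75 * D + params$beta0
  capacity <- params$K * phi + params$K0
  structure(list(phi = phi, D = D, beta_p = beta_p, capacity = capacity),
            class = "env_profiles")
}

#' Export environment profiles to CSV
#'
#' @param env an [environment_profiles()] object.
#' @param grid the matching grid.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
env_to_csv <- function(env, grid, path) {
  df <- data.frame(depth = grid$depths, phi = env$phi, D = env$D,
                   beta_p = env$beta_p, capacity = env$capacity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Population state constructor
#'
#' @param N_c consumer biomass (g m^-3), >= 0.
#' @param N_p predator biomass (g m^-3), >= 0.
#' @return list with class `population_state`.
#' @export
population_state <- function(N_c, N_p) {
  stopifnot(is.numeric(N_c), is.numeric(N_p), length(N_c) == 1,
            length(N_p) == 1, N_c >= 0, N_p >= 0)
  structure(list(N_c = N_c, N_p = N_p), class = "population_state")
}

#' Strategy-pair constructor
#'
#' A pair of probability densities on the grid: the mean-field distributions
#' of consumers and predators over depth.
#'
#' @param sigma_c,sigma_p density vectors on the grid.
#' @param grid a [habitat_grid()].
#' @param check validate the densities (tolerance 1e-8)?
#' @return list with class `strategy_pair`.
#' @export
strategy_pair <- function(sigma_c, sigma_p, grid, check = TRUE) {
  stopifnot(length(sigma_c) == grid$n_nodes, length(sigma_p) == grid$n_nodes)
  if (check) {
    for (s in list(sigma_c, sigma_p)) {
      chk <- is_probability_density(s, grid, tol = 1e-8)
      if (!chk$ok) {
        stop(sprintf("not a probability density (min %.3g, mass error %.3g)",
                     chk$min_value, chk$mass_error), call. = FALSE)
      }
    }
  }
  structure(list(sigma_c = sigma_c, sigma_p = sigma_p), class = "strategy_pair")
}

#' Uniform strategy pair (constant behavior)
#'
#' @param grid a [habitat_grid()].
#' @return a [strategy_pair()] with both densities identically 1.
#' @export
uniform_strategies <- function(grid) {
  one <- rep(1, grid$n_nodes)
  strategy_pair(one, one, grid, check = FALSE)
}

# Encounter rate B = N_c <beta_p sigma_c, sigma_p>, the argument of the
# Type II functional response.
encounter_rate <- function(state, sigma, params, env, grid) {
  state$N_c * inner_product(env$beta_p * sigma$sigma_c, sigma$sigma_p, grid)
}

#' Per-capita consumer growth rate
#'
#' Logistic growth against the depth-dependent carrying capacity, averaged
#' over the consumer distribution:
#' \eqn{G_c = \beta_c \langle \bar\sigma_c, 1 - N_c \bar\sigma_c / (K\phi + K_0)\rangle}.
#'
#' @param state a [population_state()].
#' @param sigma a [strategy_pair()] of mean-field strategies.
#' @param params,env,grid model parameters, environment profiles, grid.
#' @return scalar rate (month^-1).
#' @export
consumer_percap_growth <- function(state, sigma, params, env, grid) {
  params$beta_c * inner_product(
    sigma$sigma_c, 1 - state$N_c * sigma$sigma_c / env$capacity, grid)
}

#' Per-capita predator growth rate (Type II functional response)
#'
#' \eqn{G_p = \varepsilon F_p B / (F_p + B)} with encounter rate
#' \eqn{B = N_c \langle \beta_p \bar\sigma_c, \bar\sigma_p\rangle}.
#' Saturates at `eps * F_p`.
#'
#' @inheritParams consumer_percap_growth
#' @return scalar rate (month^-1).
#' @export
predator_percap_growth <- function(state, sigma, params, env, grid) {
  B <- encounter_rate(state, sigma, params, env, grid)
  params$eps * params$F_p * B / (params$F_p + B)
}

#' Per-capita predator mortality
#'
#' Metabolic loss plus quadratic intraspecific competition weighted by the
#' clearance profile:
#' \eqn{M_p = c N_p \langle \bar\sigma_p, \beta_p \bar\sigma_p\rangle + \mu_p}.
#'
#' @inheritParams consumer_percap_growth
#' @return scalar rate (month^-1).
#' @export
predator_percap_mortality <- function(state, sigma, params, env, grid) {
  params$c * state$N_p *
    inner_product(sigma$sigma_p, env$beta_p * sigma$sigma_p, grid) + params$mu_p
}

#' Per-capita consumer mortality
#'
#' Defined by biomass-flux consistency with predator growth:
#' \eqn{M_c = (N_p / (\varepsilon N_c)) G_p}, i.e. prey biomass eaten per unit
#' consumer biomass. Undefined at `N_c = 0`.
#'
#' @inheritParams consumer_percap_growth
#' @return scalar rate (month^-1).
#' @export
consumer_percap_mortality <- function(state, sigma, params, env, grid) {
  if (state$N_c == 0) {
    stop("consumer mortality is undefined at N_c = 0 (extinct consumers)",
         call. = FALSE)
  }
  state$N_p / (params$eps * state$N_c) *
    predator_percap_growth(state, sigma, params, env, grid)
}

#' Per-capita growth rates of both populations
#'
#' `f_c = G_c - M_c`, `f_p = G_p - M_p`; the right-hand side of the slow
#' population dynamics \eqn{\dot N_i = N_i f_i}. The consumer-extinct case
#' `N_c = 0` is handled by taking `M_c = 0` (there is no consumer biomass to
#' lose), in which case also `G_p = 0`.
#'
#' @inheritParams consumer_percap_growth
#' @return named numeric vector `c(f_c = ..., f_p = ...)`.
#' @export
percap_growth_rates <- function(state, sigma, params, env, grid) {
  G_c <- consumer_percap_growth(state, sigma, params, env, grid)
  G_p <- predator_percap_growth(state, sigma, params, env, grid)
  M_p <- predator_percap_mortality(state, sigma, params, env, grid)
  M_c <- if (state$N_c == 0) 0 else
    state$N_p / (params$eps * state$N_c) * G_p
  c(f_c = G_c - M_c, f_p = G_p - M_p)
}

#' Pointwise consumer fitness (strategy gradient)
#'
#' The individual consumer payoff is linear in the individual's own strategy,
#' so its gradient with respect to that strategy is a depth profile that does
#' not depend on the individual's choice: the pointwise fitness
#' \deqn{g_c(x) = \beta_c (1 - N_c \bar\sigma_c(x) / (K\phi(x) + K_0))
#'   - F_p \beta_p(x) \bar\sigma_p(x) N_p / (F_p + B)}
#' with \eqn{B} the mean-field encounter rate. The mean payoff
#' \eqn{\langle \bar\sigma_c, g_c \rangle} equals the per-capita rate `f_c`.
#'
#' @inheritParams consumer_percap_growth
#' @return vector on the grid (month^-1).
#' @export
consumer_pointwise_fitness <- function(state, sigma, params, env, grid) {
  B <- encounter_rate(state, sigma, params, env, grid)
  params$beta_c * (1 - state$N_c * sigma$sigma_c / env$capacity) -
    params$F_p * env$beta_p * sigma$sigma_p * state$N_p / (params$F_p + B)
}

#' Pointwise predator fitness gradient
#'
#' Gradient of the individual predator payoff with respect to the individual
#' strategy, evaluated at the mean field. The Type II response makes the
#' payoff nonlinear in the strategy; the gradient is
#' \deqn{g_p(x) = \varepsilon F_p^2 N_c \beta_p(x) \bar\sigma_c(x) /
#'   (F_p + B)^2 - c N_p \beta_p(x) \bar\sigma_p(x).}
#' The constant metabolic rate has zero gradient and does not appear.
#'
#' @inheritParams consumer_percap_growth
#' @return vector on the grid (month^-1).
#' @export
predator_pointwise_fitness_gradient <- function(state, sigma, params, env, grid) {
  B <- encounter_rate(state, sigma, params, env, grid)
  params$eps * params$F_p^2 * state$N_c * env$beta_p * sigma$sigma_c /
    (params$F_p + B)^2 -
    params$c * state$N_p * env$beta_p * sigma$sigma_p
}

#' Individual payoff functions (for oracle checks)
#'
#' Evaluates the individual consumer and predator payoffs at an *individual*
#' strategy pair, holding the mean-field pair fixed. Used by the
#' finite-difference oracles and the evolutionary-stability diagnostics;
#' the solvers themselves use the analytic gradients.
#'
#' @param ind individual [strategy_pair()] (need not equal the mean field).
#' @param mean_field mean-field [strategy_pair()].
#' @inheritParams consumer_percap_growth
#' @return named vector `c(U_c = ..., U_p = ...)` (month^-1).
#' @export
individual_payoffs <- function(ind, mean_field, state, params, env, grid) {
  B <- encounter_rate(state, mean_field, params, env, grid)
  G_c <- params$beta_c * inner_product(
    ind$sigma_c, 1 - state$N_c * mean_field$sigma_c / env$capacity, grid)
  M_c <- params$F_p * state$N_p *
    inner_product(env$beta_p * ind$sigma_c, mean_field$sigma_p, grid) /
    (params$F_p + B)
  A <- state$N_c * inner_product(env$beta_p * mean_field$sigma_c, ind$sigma_p, grid)
  G_p <- params$eps * params$F_p * A / (params$F_p + A)
  M_p <- params$c * state$N_p *
    inner_product(ind$sigma_p, env$beta_p * mean_field$sigma_p, grid) + params$mu_p
  c(U_c = G_c - M_c, U_p = G_p - M_p)
}
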