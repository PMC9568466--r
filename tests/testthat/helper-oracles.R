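# Shared test oracles, all independent of the package's internal algebra:
# direct weight summation, central finite differences on the discretized
# payoffs, and simple random-input generators.

# plain-R weighted sum, written without inner_product()
direct_sum <- function(w, ...) {
  vals <- list(...)
  acc <- w
  for (v in vals) acc <- acc * v
  sum(acc)
}

random_density <- function(grid) {
  s <- stats::rexp(grid$n_nodes)
  s / sum(grid$weights * s)
}

random_pair <- function(grid) {
  strategy_pair(random_density(grid), random_density(grid), grid, check = FALSE)
}

# central finite difference of the discretized individual payoff with respect
# to one species' individual strategy; divides out the quadrature weight so
# the result is comparable to the analytic (L2) gradient fields
fd_payoff_gradient <- function(species, mean_field, state, params, env, grid,
                               h = 1e-6) {
  n <- grid$n_nodes
  base <- mean_field
  grad <- numeric(n)
  for (j in seq_len(n)) {
    up <- base; dn <- base
    if (species == "c") {
      up$sigma_c[j] <- up$sigma_c[j] + h
      dn$sigma_c[j] <- dn$sigma_c[j] - h
    } else {
      up$sigma_p[j] <- up$sigma_p[j] + h
      dn$sigma_p[j] <- dn$sigma_p[j] - h
    }
    pu <- individual_payoffs(up, mean_field, state, params, env, grid)
    pd <- individual_payoffs(dn, mean_field, state, params, env, grid)
    key <- if (species == "c") "U_c" else "U_p"
    grad[j] <- (pu[[key]] - pd[[key]]) / (2 * h) / grid$weights[j]
  }
  grad
}

# within-support flatness plus off-support advantage of a strategy pair,
# computed from the exported fitness fields only
ifd_spread <- function(sigma, state, params, env, grid, support_tol = 1e-8) {
  g_c <- consumer_pointwise_fitness(state, sigma, params, env, grid)
  g_p <- predator_pointwise_fitness_gradient(state, sigma, params, env, grid)
  w <- grid$weights
  each <- function(s, g) {
    lam <- sum(w * s * g)
    on_sup <- s > support_tol
    max(max(abs(g[on_sup] - lam)), max(g - lam))
  }
  worst <- 0
  if (state$N_c > 0) worst <- max(worst, each(sigma$sigma_c, g_c))
  if (state$N_p > 0) worst <- max(worst, each(sigma$sigma_p, g_p))
  worst
}
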