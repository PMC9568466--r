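params_default <- model_parameters()

test_that("parameter defaults and derivations match the table", {
  expect_equal(params_default$F_p, 7)
  expect_equal(params_default$mu_p, 0.35)
  expect_equal(params_default$eps, 0.1)
  expect_equal(params_default$beta_c, 27.5 * 0.01^0.75)

  p <- model_parameters(K = 40, c = 0)
  expect_equal(p$K, 40)
  expect_equal(p$c, 0)

  # Kleiber-scaling path stays available and overrides win over it
  ps <- model_parameters(derive_from_scaling = TRUE)
  expect_equal(ps$F_p, 1.25 * 10^0.75)
  expect_equal(ps$mu_p, 0.2 * 10^0.75)
  ps2 <- model_parameters(mu_p = 0.5, derive_from_scaling = TRUE)
  expect_equal(ps2$mu_p, 0.5)
})

test_that("parameter validation rejects bad overrides", {
  expect_error(model_parameters(m_c = -1), "m_c")
  expect_error(model_parameters(nonsense = 1), "unknown")
  expect_error(model_parameters(3), "named")
})

test_that("environment profiles have the stated spatial structure", {
  g <- habitat_grid(100, 101)
  env <- environment_profiles(params_default, g)
  expect_equal(env$phi[1], 1)
  expect_equal(env$phi[101], exp(-5))
  expect_true(all(diff(env$phi) < 0))
  expect_equal(env$D[1], 1)
  expect_true(all(env$D > 0 & env$D <= 1))
  expect_gte(min(env$beta_p), params_default$beta0)
  expect_gte(min(env$capacity), params_default$K0)
  # adopted exponent: D(x) = exp(-k_light * kappa * x^2)
  expect_equal(env$D, exp(-0.005 * g$depths^2))
})

test_that("environment profiles export to CSV", {
  g <- habitat_grid(100, 11)
  env <- environment_profiles(params_default, g)
  f <- tempfile(fileext = ".csv")
  env_to_csv(env, g, f)
  df <- utils::read.csv(f)
  expect_named(df, c("depth", "phi", "D", "beta_p", "capacity"))
  expect_equal(df$phi, env$phi, tolerance = 1e-12)
  unlink(f)
})

test_that("per-capita rates reduce correctly in degenerate limits", {
  g <- habitat_grid(100, 31)
  env <- environment_profiles(params_default, g)
  u <- uniform_strategies(g)

  # no consumers: growth is the bare clearance rate, predator growth zero
  st0 <- population_state(0, 1)
  expect_equal(consumer_percap_growth(st0, u, params_default, env, g),
               params_default$beta_c)
  expect_equal(predator_percap_growth(st0, u, params_default, env, g), 0)

  # constant capacity (K = 0): logistic in N_c / K0
  pk0 <- model_parameters(K = 0)
  envk0 <- environment_profiles(pk0, g)
  st <- population_state(5e-5, 0)
  expect_equal(consumer_percap_growth(st, u, pk0, envk0, g),
               pk0$beta_c * (1 - 5e-5 / pk0$K0), tolerance = 1e-12)

  # Type II saturation: huge prey biomass approaches eps * F_p = 0.7
  stv <- population_state(1e12, 1)
  expect_equal(predator_percap_growth(stv, u, params_default, env, g),
               params_default$eps * params_default$F_p, tolerance = 1e-6)

  # mortality limits
  expect_equal(predator_percap_mortality(population_state(1, 0), u,
                                         params_default, env, g), 0.35)
  pc <- model_parameters(c = 0)
  expect_equal(predator_percap_mortality(population_state(1, 1), u, pc, env, g),
               0.35)
  expect_equal(consumer_percap_mortality(population_state(1, 0), u,
                                         params_default, env, g), 0)
  expect_error(consumer_percap_mortality(population_state(0, 1), u,
                                         params_default, env, g), "N_c")
})

test_that("rates match direct weight-summation oracles on a 3-node grid", {
  g <- habitat_grid(100, 3)
  p <- model_parameters(K = 3, c = 1)
  env <- environment_profiles(p, g)
  st <- population_state(1, 1)
  u <- uniform_strategies(g)
  w <- g$weights

  gc_oracle <- p$beta_c * direct_sum(w, 1 - st$N_c / env$capacity)
  expect_equal(consumer_percap_growth(st, u, p, env, g), gc_oracle,
               tolerance = 1e-12)

  B_oracle <- st$N_c * direct_sum(w, env$beta_p)
  gp_oracle <- p$eps * p$F_p * B_oracle / (p$F_p + B_oracle)
  expect_equal(predator_percap_growth(st, u, p, env, g), gp_oracle,
               tolerance = 1e-12)

  mp_oracle <- p$mu_p + st$N_p * direct_sum(w, env$beta_p)
  expect_equal(predator_percap_mortality(st, u, p, env, g), mp_oracle,
               tolerance = 1e-12)

  mc_oracle <- st$N_p / (p$eps * st$N_c) * gp_oracle
  expect_equal(consumer_percap_mortality(st, u, p, env, g), mc_oracle,
               tolerance = 1e-12)
})

test_that("biomass-flux consistency and rate composition hold for random inputs", {
  g <- habitat_grid(100, 31)
  p <- model_parameters(K = 5, c = 0.4)
  env <- environment_profiles(p, g)
  set.seed(11)
  for (i in 1:20) {
    st <- population_state(stats::runif(1, 0.01, 3), stats::runif(1, 0.001, 1))
    sig <- random_pair(g)
    G_p <- predator_percap_growth(st, sig, p, env, g)
    M_c <- consumer_percap_mortality(st, sig, p, env, g)
    expect_equal(p$eps * st$N_c * M_c, st$N_p * G_p, tolerance = 1e-14)
    # saturation bound
    expect_gte(G_p, 0)
    expect_lt(G_p, p$eps * p$F_p)
    # f = G - M componentwise
    f <- percap_growth_rates(st, sig, p, env, g)
    expect_equal(f[["f_c"]],
                 consumer_percap_growth(st, sig, p, env, g) - M_c,
                 tolerance = 1e-14)
    expect_equal(f[["f_p"]],
                 G_p - predator_percap_mortality(st, sig, p, env, g),
                 tolerance = 1e-14)
  }
})

test_that("consumer payoff is linear: mean of the fitness field is f_c", {
  g <- habitat_grid(100, 31)
  p <- model_parameters(K = 3, c = 0.2)
  env <- environment_profiles(p, g)
  set.seed(3)
  for (i in 1:10) {
    st <- population_state(stats::runif(1, 0.05, 2), stats::runif(1, 0.005, 0.5))
    sig <- random_pair(g)
    g_c <- consumer_pointwise_fitness(st, sig, p, env, g)
    f <- percap_growth_rates(st, sig, p, env, g)
    expect_equal(inner_product(sig$sigma_c, g_c, g), f[["f_c"]],
                 tolerance = 1e-12)
  }
  # no predators, no crowding: constant fitness beta_c
  st0 <- population_state(0, 0)
  expect_equal(consumer_pointwise_fitness(st0, uniform_strategies(g), p, env, g),
               rep(p$beta_c, 31))
  expect_equal(predator_pointwise_fitness_gradient(
    population_state(0, 1), uniform_strategies(g), model_parameters(c = 0),
    env, g), rep(0, 31))
})

test_that("analytic payoff gradients match finite-difference oracles", {
  g <- habitat_grid(100, 21)
  set.seed(5)
  worst <- 0
  for (i in 1:25) {
    p <- model_parameters(K = stats::runif(1, 0.5, 40),
                          c = stats::runif(1, 0, 1))
    env <- environment_profiles(p, g)
    st <- population_state(stats::runif(1, 0.05, 2),
                           stats::runif(1, 0.005, 0.5))
    sig <- random_pair(g)
    g_c <- consumer_pointwise_fitness(st, sig, p, env, g)
    g_p <- predator_pointwise_fitness_gradient(st, sig, p, env, g)
    worst <- max(worst,
                 abs(g_c - fd_payoff_gradient("c", sig, st, p, env, g)),
                 abs(g_p - fd_payoff_gradient("p", sig, st, p, env, g)))
  }
  expect_lt(worst, 1e-6)
})

test_that("spatially constant environments give constant predator gradients", {
  # k_light = 0 flattens phi, D and hence beta_p; with c = 0 the gradient
  # field has no spatial structure left
  p <- model_parameters(k_light = 0, c = 0)
  g <- habitat_grid(100, 11)
  env <- environment_profiles(p, g)
  st <- population_state(1, 1)
  g_p <- predator_pointwise_fitness_gradient(st, uniform_strategies(g),
                                             p, env, g)
  expect_equal(max(g_p) - min(g_p), 0)
})
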