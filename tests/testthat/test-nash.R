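# closed form for the consumer-only game: sigma_c proportional to the
# capacity profile, lambda_c from normalization
consumer_only_closed_form <- function(params, env, grid, N_c) {
  one <- rep(1, grid$n_nodes)
  csum <- inner_product(env$capacity, one, grid)
  list(sigma = env$capacity / csum,
       lambda = params$beta_c * (1 - N_c / csum))
}

test_that("consumer-only equilibrium matches the closed form", {
  g <- habitat_grid(100, 101)
  for (K in c(0.5, 3, 40)) {
    p <- model_parameters(K = K)
    env <- environment_profiles(p, g)
    st <- population_state(1, 0)
    sol <- solve_nash(st, p, env, g)
    cf <- consumer_only_closed_form(p, env, g, 1)
    expect_lt(max(abs(sol$strategies$sigma_c - cf$sigma)), 1e-8)
    expect_equal(sol$lambda_c, cf$lambda, tolerance = 1e-10)
  }
})

test_that("a homogeneous habitat yields uniform strategies", {
  p <- model_parameters(k_light = 0, K = 3, c = 0.2)
  g <- habitat_grid(100, 31)
  env <- environment_profiles(p, g)
  sol <- solve_nash(population_state(1, 1), p, env, g)
  expect_lt(max(abs(sol$strategies$sigma_c - 1)), 1e-9)
  expect_lt(max(abs(sol$strategies$sigma_p - 1)), 1e-9)
})

test_that("kkt_residual validates exact solutions and flags perturbed ones", {
  g <- habitat_grid(100, 51)
  p <- model_parameters(K = 3)
  env <- environment_profiles(p, g)

  # single-species closed form wrapped as a candidate
  st <- population_state(1, 0)
  cf <- consumer_only_closed_form(p, env, g, 1)
  sigma <- strategy_pair(cf$sigma, rep(1, 51), g, check = FALSE)
  g_c <- consumer_pointwise_fitness(st, sigma, p, env, g)
  cand <- list(strategies = sigma, lambda_c = cf$lambda, lambda_p = 0,
               nu_c = pmax(0, cf$lambda - g_c), nu_p = rep(0, 51))
  rep1 <- kkt_residual(cand, st, p, env, g)
  expect_lt(rep1$stationarity_inf_norm, 1e-10)
  expect_lt(rep1$complementarity, 1e-10)
  expect_lt(rep1$normalization, 1e-10)
  expect_equal(rep1$negativity, 0)

  # uniform strategies in a homogeneous habitat with matching multipliers
  ph <- model_parameters(k_light = 0, c = 0.2)
  envh <- environment_profiles(ph, g)
  sth <- population_state(1, 1)
  u <- uniform_strategies(g)
  g_ch <- consumer_pointwise_fitness(sth, u, ph, envh, g)
  g_ph <- predator_pointwise_fitness_gradient(sth, u, ph, envh, g)
  cand2 <- list(strategies = u, lambda_c = g_ch[1], lambda_p = g_ph[1],
                nu_c = rep(0, 51), nu_p = rep(0, 51))
  rep2 <- kkt_residual(cand2, sth, ph, envh, g)
  expect_lt(rep2$stationarity_inf_norm, 1e-12)

  # a perturbed density is detected through the stationarity group
  bad_sigma <- cf$sigma
  bad_sigma[10] <- bad_sigma[10] + 0.1
  bad_sigma <- bad_sigma / inner_product(bad_sigma, rep(1, 51), g)
  cand3 <- cand
  cand3$strategies <- strategy_pair(bad_sigma, rep(1, 51), g, check = FALSE)
  rep3 <- kkt_residual(cand3, st, p, env, g)
  expect_gt(rep3$stationarity_inf_norm, 1e-6)

  expect_error(
    kkt_residual(list(strategies = strategy_pair(rep(1, 5), rep(1, 5),
                                                 habitat_grid(100, 5),
                                                 check = FALSE)),
                 st, p, env, g), "conform")
})

test_that("solver output satisfies the ideal-free support structure", {
  g <- habitat_grid(100, 51)
  for (cfg in list(c(3, 0), c(3, 0.5), c(40, 0.2))) {
    p <- model_parameters(K = cfg[1], c = cfg[2])
    env <- environment_profiles(p, g)
    sol <- solve_nash(population_state(1, 1), p, env, g)
    expect_true(sol$residuals$converged)
    expect_lt(sol$residuals$stationarity_inf_norm, 1e-9)
    expect_lt(sol$residuals$complementarity, 1e-10)
    expect_lt(ifd_spread(sol$strategies, population_state(1, 1), p, env, g),
              1e-8)
    for (s in list(sol$strategies$sigma_c, sol$strategies$sigma_p)) {
      chk <- is_probability_density(s, g, tol = 1e-8)
      expect_true(chk$ok)
    }
  }
})

test_that("extinct species are pinned to uniform and excluded", {
  g <- habitat_grid(100, 31)
  p <- model_parameters(K = 3, c = 0.5)
  env <- environment_profiles(p, g)
  sol <- solve_nash(population_state(0, 0), p, env, g)
  expect_equal(sol$strategies$sigma_c, rep(1, 31))
  expect_equal(sol$strategies$sigma_p, rep(1, 31))
  expect_true(sol$residuals$converged)
  # predator-only game still solves for the predator
  sol2 <- solve_nash(population_state(0, 1), p, env, g)
  expect_equal(sol2$strategies$sigma_c, rep(1, 31))
  expect_true(sol2$residuals$converged)
})

test_that("solve_nash agrees with the replicator oracle on a 5-node grid", {
  g <- habitat_grid(100, 5)
  p <- model_parameters(K = 3, c = 0.5)
  env <- environment_profiles(p, g)
  st <- population_state(1, 1)
  sol <- solve_nash(st, p, env, g)
  orc <- replicator_solve(st, p, env, g)
  expect_lt(max(abs(sol$strategies$sigma_c - orc$sigma_c),
                abs(sol$strategies$sigma_p - orc$sigma_p)), 1e-6)
})

test_that("best response concentrates on the argmax of consumer fitness", {
  g <- habitat_grid(100, 21)
  p <- model_parameters(K = 3)
  env <- environment_profiles(p, g)
  st <- population_state(1, 1)
  u <- uniform_strategies(g)

  br <- best_response_consumer(u, st, p, env, g)
  g_c <- consumer_pointwise_fitness(st, u, p, env, g)
  j <- which.max(g_c)
  expect_equal(br[j], 1 / g$weights[j])
  expect_equal(sum(br > 0), 1)
  expect_equal(inner_product(br, rep(1, 21), g), 1)

  # constant fitness: total tie spreads mass uniformly
  p0 <- model_parameters(k_light = 0, c = 0)
  env0 <- environment_profiles(p0, g)
  br0 <- best_response_consumer(uniform_strategies(g),
                                population_state(1, 0), p0, env0, g)
  expect_equal(br0, rep(1, 21))

  # at a solved equilibrium no deviation is profitable
  sol <- solve_nash(st, p, env, g)
  brN <- best_response_consumer(sol$strategies, st, p, env, g)
  gN <- consumer_pointwise_fitness(st, sol$strategies, p, env, g)
  expect_lte(inner_product(brN, gN, g) - sol$lambda_c, 1e-8)
})

test_that("replicator oracle: closed form, stationarity at Nash, seed agreement", {
  g <- habitat_grid(100, 11)
  p <- model_parameters(K = 3, c = 0.2)
  env <- environment_profiles(p, g)

  # consumer-only game reaches the closed form
  st1 <- population_state(1, 0)
  orc <- replicator_solve(st1, p, env, g)
  cf <- consumer_only_closed_form(p, env, g, 1)
  expect_lt(max(abs(orc$sigma_c - cf$sigma)), 1e-6)

  # the oracle limit is replicator-stationary (flat fitness on support)
  st <- population_state(1, 1)
  lim <- replicator_solve(st, p, env, g)
  expect_lt(ifd_spread(lim, st, p, env, g), 1e-9)

  # two jittered starts agree (uniqueness echo)
  l1 <- replicator_solve(st, p, env, g, seed = 1)
  l2 <- replicator_solve(st, p, env, g, seed = 2)
  expect_lt(max(abs(l1$sigma_c - l2$sigma_c),
                abs(l1$sigma_p - l2$sigma_p)), 1e-6)
})

test_that("random solver restarts land on the same equilibrium", {
  g <- habitat_grid(100, 31)
  p <- model_parameters(K = 3, c = 0)
  env <- environment_profiles(p, g)
  st <- population_state(1, 1)
  set.seed(1234)
  sols <- lapply(1:5, function(i) {
    init <- random_pair(g)
    solve_nash(st, p, env, g, init = init)
  })
  for (i in 2:5) {
    expect_lt(max(abs(sols[[i]]$strategies$sigma_c -
                      sols[[1]]$strategies$sigma_c),
                  abs(sols[[i]]$strategies$sigma_p -
                      sols[[1]]$strategies$sigma_p)), 1e-6)
  }
})

test_that("the solution map is continuous in the populations", {
  g <- habitat_grid(100, 51)
  p <- model_parameters(K = 3, c = 0.3)
  env <- environment_profiles(p, g)
  sol1 <- solve_nash(population_state(1, 0.1), p, env, g)
  sol2 <- solve_nash(population_state(1.01, 0.1), p, env, g, init = sol1)
  # a 1% biomass change moves the strategies by a comparable bounded amount
  expect_lt(max(abs(sol1$strategies$sigma_c - sol2$strategies$sigma_c)), 0.1)
  expect_lt(max(abs(sol1$strategies$sigma_p - sol2$strategies$sigma_p)), 0.1)
})

test_that("nash solutions serialize to JSON and CSV", {
  g <- habitat_grid(100, 11)
  p <- model_parameters(K = 3)
  env <- environment_profiles(p, g)
  st <- population_state(1, 1)
  sol <- solve_nash(st, p, env, g)
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  nash_to_files(sol, g, json_path = jp, csv_path = cp,
                state = st, params = p, env = env)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$sigma_c, sol$strategies$sigma_c, tolerance = 1e-12)
  df <- utils::read.csv(cp)
  expect_named(df, c("depth", "sigma_c", "sigma_p", "g_c", "g_p"))
  expect_equal(nrow(df), 11)
  unlink(c(jp, cp))
})
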