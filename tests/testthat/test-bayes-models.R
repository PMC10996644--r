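test_that("the IGP log-likelihood reduces to its limiting forms", {
  # L = 1, tau -> infinity: homogeneous Poisson log-likelihood
  tk <- c(1.2, 3.4, 7.7)
  ll <- igp_loglik(list(tk), 10, lam0 = 0.8, tau = 1e9, L = 1L)
  expect_equal(ll, 3 * log(0.8) - 0.8 * 10, tolerance = 1e-6)
  # empty sequence: probability of zero events, -Lambda(T)
  ll0 <- igp_loglik(list(numeric(0)), 10, lam0 = 2, tau = 6, L = 1L)
  expect_equal(ll0, -2 * 6 * (1 - exp(-10 / 6)))
  # additive over patches
  lla <- igp_loglik(list(tk), 10, 0.8, 5, 2L)
  llb <- igp_loglik(list(c(2, 4)), 8, 0.8, 5, 2L)
  expect_equal(igp_loglik(list(tk, c(2, 4)), c(10, 8), 0.8, 5, 2L),
               lla + llb)
  expect_error(igp_loglik(list(c(3, 2)), 10, 1, 5, 1L), "increasing")
})

test_that("analytic scores match finite differences of the log-density", {
  for (seed in 1:6) {
    fx <- random_sequences(seed, L = if (seed %% 2) 1L else 3L)
    lam0 <- stats::runif(1, 0.5, 3)
    tau <- stats::runif(1, 2, 10)
    prior <- prior_spec(1.5, 0.4, 5, 0.6)
    for (pr in list(NULL, prior)) {
      f <- function(l, t) if (is.null(pr))
        igp_loglik(fx$times, fx$durations, l, t, fx$L)
      else igp_logpost(fx$times, fx$durations, l, t, fx$L, pr)
      g <- igp_score(fx$times, fx$durations, lam0, tau, fx$L, prior = pr)
      h <- 1e-5
      fd <- c((f(lam0 + h, tau) - f(lam0 - h, tau)) / (2 * h),
              (f(lam0, tau + h) - f(lam0, tau - h)) / (2 * h))
      expect_lt(max(abs(g - fd) / pmax(1, abs(g))), 1e-5)
    }
  }
})

test_that("MLE solves the stationarity system and matches a 2-D oracle", {
  for (seed in c(2, 5, 9)) {
    fx <- random_sequences(seed, n_patches = 6, L = 2L)
    fit <- mle_fit(fx$times, fx$durations, fx$L)
    sc <- igp_score(fx$times, fx$durations, fit$lam0, fit$tau, fx$L)
    expect_lt(max(abs(sc)), 1e-6 * (1 + abs(
      igp_loglik(fx$times, fx$durations, fit$lam0, fit$tau, fx$L))))
    # independent oracle: direct 2-D maximization in log parameters
    opt <- stats::optim(log(c(fit$lam0, fit$tau) * c(1.7, 0.6)),
                        function(p) -igp_loglik(fx$times, fx$durations,
                                                exp(p[1]), exp(p[2]),
                                                fx$L),
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    expect_equal(fit$tau, exp(opt$par[2]), tolerance = 1e-3)
    expect_equal(fit$lam0, exp(opt$par[1]), tolerance = 1e-3)
  }
  # single reward in a single patch: interior optimum still matched
  fit1 <- mle_fit(list(2.5), 10, 1L)
  opt1 <- stats::optim(c(0, 0), function(p)
    -igp_loglik(list(2.5), 10, exp(p[1]), exp(p[2]), 1L),
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(fit1$tau, exp(opt1$par[2]), tolerance = 1e-3)
  # zero rewards: degenerate and flagged
  fit0 <- mle_fit(list(numeric(0)), 10, 1L)
  expect_true(fit0$degenerate)
  expect_equal(est_rate(fit0, c(0, 5)), c(0, 0))
})

test_that("doubling the event rate doubles the estimated rate", {
  make_times <- function(r0, seeds) {
    env <- forage_env(6, 1, r0 = r0)
    lapply(seeds, function(i)
      simulate_patch(env, 20, seed = i)$reward_times)
  }
  t1 <- make_times(2.5, 1:60)
  t2 <- make_times(5, 61:120)
  f1 <- mle_fit(t1, rep(20, 60), 1L)
  f2 <- mle_fit(t2, rep(20, 60), 1L)
  expect_lt(abs(est_rate(f2, 0) / est_rate(f1, 0) - 2), 0.3)
})

test_that("gamma mode/variance parameterization round trips", {
  g <- gamma_prior_from_mode_var(1, 1)
  expect_equal(unname(g["beta"]), (1 + sqrt(5)) / 2)
  expect_equal(unname(g["alpha"]), 1 + (1 + sqrt(5)) / 2)
  for (m in c(0.3, 2, 15)) for (v in c(0.01, 1, 50)) {
    g <- gamma_prior_from_mode_var(m, v)
    expect_equal(unname((g["alpha"] - 1) / g["beta"]), m,
                 tolerance = 1e-9)
    expect_equal(unname(g["alpha"] / g["beta"]^2), v, tolerance = 1e-9)
  }
  # vanishing variance concentrates the prior at its mode
  g0 <- gamma_prior_from_mode_var(2, 1e-8)
  expect_gt(unname(g0["beta"]), 1e7)
  expect_error(gamma_prior_from_mode_var(-1, 1), "positive")
})

test_that("MAP limits: prior mode with no data, MLE with a flat prior", {
  prior <- prior_spec(mode_lam = 1.8, var_lam = 0.5, mode_tau = 7,
                      var_tau = 0.5)
  empty <- map_fit(list(), numeric(0), prior, 1L)
  expect_identical(empty$tau, 7)
  expect_identical(empty$lam0, 1.8)

  fx <- random_sequences(3, n_patches = 50, L = 1L)
  mle <- mle_fit(fx$times, fx$durations, fx$L)
  diffuse <- prior_spec(mle$lam0, 1e6, mle$tau, 1e6)
  map <- map_fit(fx$times, fx$durations, diffuse, fx$L)
  expect_lt(abs(map$tau - mle$tau) / mle$tau, 1e-4)
  expect_lt(abs(map$lam0 - mle$lam0) / mle$lam0, 1e-4)

  # MAP satisfies the posterior stationarity equations
  sc <- igp_score(fx$times, fx$durations, map$lam0, map$tau, fx$L,
                  prior = diffuse)
  expect_lt(max(abs(sc)), 1e-5)
})

test_that("an informative prior shrinks single-patch estimates to truth", {
  env <- env_high_stoch()   # tau = 6, lam0 = 1.25
  prior <- prior_spec(env$lam0, 0.05, env$tau, 0.05)
  set.seed(31)
  wins <- 0
  for (i in 1:100) {
    p <- simulate_patch(env, 15, seed = 900 + i)
    if (length(p$reward_times) == 0) next
    mle <- mle_fit(list(p$reward_times), 15, env$L)
    map <- map_fit(list(p$reward_times), 15, prior, env$L)
    if (abs(map$tau - env$tau) <= abs(mle$tau - env$tau)) wins <- wins + 1
  }
  expect_gte(wins, 80)
})

test_that("threshold crossings follow the rate-inversion identity", {
  env <- env_high_stoch()
  tight <- prior_spec(env$lam0, 1e-6, env$tau, 1e-6)
  # with a near point-mass prior and no rewards, the estimate is the true
  # rate curve, so the crossing inverts the exponential decay
  for (frac in c(0.2, 0.5, 0.8)) {
    lam_star <- frac * env$lam0
    tr <- rate_trace(numeric(0), env$L, tight, eval_dt = 0.1, t_max = 30)
    t_pred <- 0.1 * which(tr <= lam_star)[1]
    expect_lt(abs(t_pred - (-env$tau * log(frac))), 0.1 + 1e-9)
  }
  # threshold at or above the first-bin estimate fires immediately
  th <- truth_thresholds(env)
  th$lambda_star <- env$lam0
  m <- threshold_model(th, var_lam = 1e-6, var_tau = 1e-6)
  p <- data.frame(animal = "A1", session = "S1", patch = 1L,
                  tau = env$tau, track = env$track_label,
                  travel_time = env$travel_time, lam0 = env$lam0,
                  L = env$L, residence = 5, stringsAsFactors = FALSE)
  p$rewards <- list(numeric(0))
  expect_equal(predict_leaving(m, p)$yhat, 0.1)
})

test_that("the C++ solver agrees with the R likelihood machinery", {
  fx <- random_sequences(4, n_patches = 8, L = 2L)
  prior <- prior_spec(2, 0.3, 5, 0.3)
  map <- map_fit(fx$times, fx$durations, prior, fx$L)
  sc <- igp_score(fx$times, fx$durations, map$lam0, map$tau, fx$L,
                  prior = prior)
  expect_lt(max(abs(sc)), 1e-5)
  # trace at bin t equals a direct MAP fit on the same truncated data
  rw <- fx$times[[1]]
  tr <- rate_trace(rw, fx$L, prior, eval_dt = 0.5, t_max = 10)
  for (bin in c(4, 20)) {
    t_i <- bin * 0.5
    direct <- map_fit(list(rw[rw <= t_i]), t_i, prior, fx$L)
    expect_equal(tr[bin], est_rate(direct, t_i), tolerance = 1e-6)
  }
})

test_that("prior grid search returns a deterministic, order-free surface", {
  env <- forage_env(6, 0.5, travel_time = 8)
  pol <- agent_policy("MAP_THRESHOLD", noise_sigma_log = 0.1)
  p <- session_patches(simulate_session(env, pol, 25, seed = 21))
  th <- truth_thresholds(env)

  gs1 <- grid_search_priors(p, th, var_lam_grid = 0.3,
                            var_tau_grid = 0.3)
  m <- threshold_model(th, var_lam = 0.3, var_tau = 0.3)
  direct <- predict_leaving(m, p)
  expect_equal(gs1$surface$rmse,
               sqrt(mean((direct$yhat - p$residence)^2)))

  gs2 <- grid_search_priors(p, th, var_lam_grid = c(0.1, 1),
                            var_tau_grid = c(0.1, 1))
  p_shuf <- p[rev(seq_len(nrow(p))), ]
  gs3 <- grid_search_priors(p_shuf, th, var_lam_grid = c(0.1, 1),
                            var_tau_grid = c(0.1, 1))
  expect_equal(gs2$surface$rmse, gs3$surface$rmse)
  expect_error(grid_search_priors(p, th, var_lam_grid = numeric(0)),
               "empty")
})

test_that("threshold refitting descends and recovers shifted thresholds", {
  env <- forage_env(6, 0.5, travel_time = 8)
  th <- truth_thresholds(env)

  # agents generated from the initial thresholds: refit stays put
  pol0 <- agent_policy("MAP_THRESHOLD", threshold = th$lambda_star,
                       prior = prior_spec(env$lam0, 0.3, env$tau, 0.3))
  s0 <- simulate_session(env, pol0, 30, seed = 22)
  p0 <- session_patches(s0)
  m0 <- threshold_model(th, var_lam = 0.3, var_tau = 0.3)
  f0 <- fit_thresholds(m0, p0)
  expect_equal(f0$thresholds$lambda_star, th$lambda_star,
               tolerance = 1e-9)
  d0 <- attr(f0, "rmse")
  expect_true(all(d0$rmse_fit <= d0$rmse_init + 1e-12))

  # agents with shifted thresholds (1.3x): refit recovers the shift
  pol1 <- agent_policy("MAP_THRESHOLD", threshold = 1.3 * th$lambda_star,
                       prior = prior_spec(env$lam0, 0.3, env$tau, 0.3))
  s1 <- simulate_session(env, pol1, 60, seed = 23)
  p1 <- session_patches(s1)
  f1 <- fit_thresholds(m0, p1)
  expect_lt(abs(f1$thresholds$lambda_star / th$lambda_star - 1.3), 0.13)
  d1 <- attr(f1, "rmse")
  expect_true(all(d1$rmse_fit <= d1$rmse_init + 1e-12))
})
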