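test_that("heuristic parameters follow their definitions", {
  df <- data.frame(residence = c(5, 7, 9), n_rewards = c(2L, 3L, 4L),
                   last_reward = c(5, 7, 9))
  h <- fit_heuristics(df)
  expect_equal(h$delta_bar, 0)      # rewards exactly at leaving
  expect_equal(h$m_bar, 3)
  expect_equal(h$mean_residence, 7)
  # rewardless patches contribute their full residence time
  df2 <- data.frame(residence = c(12, 10), n_rewards = c(0L, 1L),
                    last_reward = c(NA, 8))
  expect_equal(fit_heuristics(df2)$delta_bar, (12 + 2) / 2)
})

test_that("HEU-ETR applies the earliest-qualifying-gap rule", {
  env <- env_high_stoch()
  # first gap >= 5 opens after the reward at 2
  expect_equal(as.numeric(
    heu_etr_predict(env, c(1, 2, 9), residence = 9.5, delta_bar = 5)), 7)
  # degenerate zero criterion fires at the first reward
  expect_equal(as.numeric(
    heu_etr_predict(env, c(1, 2, 9), residence = 9.5, delta_bar = 0)), 1)
  # entry gap counts: no reward for delta_bar seconds predicts leaving
  expect_equal(as.numeric(
    heu_etr_predict(env, c(6, 7), residence = 8, delta_bar = 3)), 3)

  # criterion met only on the expected-time extension: equals a brute
  # force scan of the concatenated observed + expected ladder
  rw <- c(0.6, 1.1, 1.9, 2.4)
  delta <- 2.2
  pred <- as.numeric(heu_etr_predict(env, rw, residence = 3,
                                     delta_bar = delta))
  fut <- expected_future_reward_times(env, rw, 3, 12)
  ladder <- c(0, rw, fut[!is.na(fut)])
  m_star <- which(diff(ladder) >= delta)[1]
  expect_equal(pred, ladder[m_star] + delta)
})

test_that("HEU-NR interpolates the m_bar-th reward time", {
  env <- env_high_stoch()
  expect_equal(as.numeric(
    heu_nr_predict(env, c(3, 5, 8), residence = 8.5, m_bar = 2)), 5)
  expect_equal(as.numeric(
    heu_nr_predict(env, c(3, 5, 8), residence = 8.5, m_bar = 2.5)), 6.5)
  expect_equal(as.numeric(
    heu_nr_predict(env, c(3, 5, 8), residence = 8.5, m_bar = 2.5,
                   interpolate = FALSE)), 5)
  # m_bar beyond the observed count: brute-force oracle on the ladder
  rw <- c(1.5, 3)
  fut <- expected_future_reward_times(env, rw, 4, 3)
  pred <- as.numeric(heu_nr_predict(env, rw, residence = 4, m_bar = 3.5))
  expect_equal(pred, fut[1] + 0.5 * (fut[2] - fut[1]))
})

test_that("the MVT-optimal residence solves the marginal-rate equation", {
  expect_equal(mvt_opt_residence(6, 0), 0)
  t_star <- mvt_opt_residence(6, 10)
  expect_lt(abs(exp(-t_star / 6) * (10 + t_star + 6) - 6), 1e-9)

  # bisection oracle
  bisect <- function(tau, travel, lo = 0, hi = 50 * tau) {
    f <- function(t) exp(-t / tau) * (travel + t + tau) - tau
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(t_star, bisect(6, 10), tolerance = 1e-9)

  # qualitative MVT predictions
  expect_gt(mvt_opt_residence(12, 10), mvt_opt_residence(6, 10))
  expect_gt(mvt_opt_residence(6, 20), mvt_opt_residence(6, 10))

  # equals the argmax of the overall reward rate E[V(t)]/(t + travel)
  for (pars in list(c(3, 5), c(6, 10), c(12, 4), c(24, 15))) {
    tau <- pars[1]; travel <- pars[2]
    grid <- seq(0.001, 8 * tau, by = 0.001)
    gain <- tau * (1 - exp(-grid / tau)) / (grid + travel)
    expect_lt(abs(grid[which.max(gain)] - mvt_opt_residence(tau, travel)),
              0.01)
  }

  # the fast Newton path agrees with the bracketed solver
  for (tau in c(3, 6, 12, 24)) for (travel in c(0.5, 5, 20))
    expect_equal(patchforage:::mvt_root_newton(tau, travel),
                 mvt_opt_residence(tau, travel), tolerance = 1e-8)
})

mvt_exact_patches <- function(overharvest = 1) {
  envs <- cohort_envs()
  grid <- expand.grid(rep = 1:10, env = seq_along(envs))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    e <- envs[[grid$env[i]]]
    data.frame(animal = "A1", session = paste0("S", grid$env[i]),
               patch = grid$rep[i], tau = e$tau, track = e$track_label,
               travel_time = e$travel_time, lam0 = e$lam0,
               residence = overharvest *
                 mvt_opt_residence(e$tau, e$travel_time),
               stringsAsFactors = FALSE)
  }))
}

test_that("MVT-IM recovers parameters from noiseless optimal data", {
  p <- mvt_exact_patches()
  fit <- fit_mvt_im(p, lambda_reg = 0)
  expect_true(all(abs(fit$params$hat - fit$params$ref) /
                    fit$params$ref < 0.01))
  expect_true(all(fit$loss$loss <= fit$loss$loss_init + 1e-9))
  # dominant regularizer pins the parameters at the experimental values
  fit2 <- fit_mvt_im(p, lambda_reg = 1e9)
  expect_true(all(abs(fit2$params$hat - fit2$params$ref) < 1e-3))
})

test_that("systematic overharvesting inflates the perceived decay", {
  p <- mvt_exact_patches(overharvest = 1.5)
  fit <- fit_mvt_im(p, lambda_reg = 1)
  tau_rows <- fit$params[fit$params$kind == "tau", ]
  fast <- tau_rows[tau_rows$ref == min(tau_rows$ref), ]
  expect_gt(fast$hat, fast$ref)

  # grid-search oracle on a single-environment loss confirms direction
  e <- cohort_envs()[[1]]
  y <- rep(1.5 * mvt_opt_residence(e$tau, e$travel_time), 20)
  tau_grid <- seq(1, 20, by = 0.05)
  loss <- vapply(tau_grid, function(tg)
    sum((mvt_opt_residence(tg, e$travel_time) - y)^2) +
      1 * ((tg - e$tau)^2), numeric(1))
  expect_gt(tau_grid[which.min(loss)], e$tau)
})

test_that("heuristic predictions ignore the event rate scale", {
  # same reward times, different lam0 (via r0): identical predictions
  env_a <- forage_env(6, 1, r0 = 2.5)
  env_b <- forage_env(6, 1, r0 = 5)
  rw <- c(1, 2.5, 6)
  # HEU predictions depend on env only through expected future times;
  # with the criterion met among observed rewards they are identical
  expect_equal(as.numeric(heu_etr_predict(env_a, rw, 7, 2)),
               as.numeric(heu_etr_predict(env_b, rw, 7, 2)))
  expect_equal(as.numeric(heu_nr_predict(env_a, rw, 7, 2)),
               as.numeric(heu_nr_predict(env_b, rw, 7, 2)))
})

test_that("MVT-IM thresholds invert to the predicted residence", {
  p <- mvt_exact_patches()
  fit <- fit_mvt_im(p, lambda_reg = 1)
  th <- mvt_im_thresholds(fit, p)
  # lambda_star = lam0 e^{-t_hat/tau_hat} inverts back to t_hat
  t_back <- -th$tau_hat * log(th$lambda_star / th$lam0)
  expect_equal(t_back, th$t_hat, tolerance = 1e-9)
})
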