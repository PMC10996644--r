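test_that("event rate follows the exponential decay closed form", {
  env <- forage_env(tau = 6, rsi = 1)   # lam0 = 1.25
  expect_equal(reward_rate(env, 0), 1.25)
  expect_equal(reward_rate(env, 6 * log(2)), 0.625)
  env2 <- forage_env(tau = 3, rsi = 0.05)  # lam0 = 25
  expect_equal(reward_rate(env2, 3), 25 / exp(1))
  expect_error(reward_rate(env, -1), "nonnegative")
  t <- seq(0, 20, by = 0.5)
  expect_true(all(diff(reward_rate(env, t)) < 0))
})

test_that("integrated rate is the exact integral and additive", {
  env <- forage_env(tau = 6, rsi = 1)
  expect_equal(integrated_rate(env, 0, Inf), 7.5)
  expect_equal(integrated_rate(env, 0, 6), 7.5 * (1 - exp(-1)))
  expect_equal(integrated_rate(env, 0, 2) + integrated_rate(env, 2, 3),
               integrated_rate(env, 0, 5))
  # the t-offset factor matters: mass after t is discounted by e^{-t/tau}
  expect_equal(integrated_rate(env, 3, Inf), 7.5 * exp(-0.5))
  expect_error(integrated_rate(env, 0, -1), "nonnegative")
})

test_that("cumulative volume moments match their closed forms", {
  env <- forage_env(tau = 3, rsi = 1)  # r0 = 2.5, V0 = 2
  m <- volume_moments(env, Inf)
  expect_equal(m$mean, 7.5)
  expect_equal(m$var, env$V0 * 7.5)
  m0 <- volume_moments(env, 0)
  expect_equal(m0$mean, 0)
  expect_equal(m0$var, 0)
})

test_that("environment construction enforces the integer-L invariant", {
  env <- forage_env(tau = 6, rsi = 0.05)
  expect_identical(env$L, 20L)
  expect_equal(env$V0 * env$lam0, env$r0, tolerance = 1e-12)
  expect_error(forage_env(tau = 6, rsi = 0.3), "integer")
  expect_error(forage_env(tau = -1, rsi = 1))
})

test_that("simulated patches match the process they claim to follow", {
  env <- env_high_stoch()           # L = 1
  p <- simulate_patch(env, 20, seed = 7)
  expect_identical(p$event_times, p$reward_times)
  expect_true(all(diff(p$event_times) > 0))
  # reproducibility
  p2 <- simulate_patch(env, 20, seed = 7)
  expect_identical(p$event_times, p2$event_times)

  # homogeneous limit: inter-reward intervals have mean 1/lam0
  envh <- forage_env(tau = 1e9, rsi = 1, vr = 2, r0 = 2)  # lam0 = 1
  ph <- simulate_patch(envh, 51000, seed = 11)
  gaps <- diff(ph$event_times)
  expect_gt(length(gaps), 49000)
  expect_lt(abs(mean(gaps) - 1), 0.02)

  # every-L-th-event rule against a direct event-count oracle
  env20 <- forage_env(tau = 6, rsi = 0.05)  # L = 20, lam0 = 25
  set.seed(21)
  n_sim <- 3000
  sim_counts <- vapply(seq_len(n_sim), function(i)
    length(simulate_patch(env20, 30, seed = 5000 + i)$reward_times),
    integer(1))
  oracle_counts <- floor(stats::rpois(n_sim,
                                      integrated_rate(env20, 0, 30)) / 20)
  se <- sqrt(stats::var(sim_counts) / n_sim +
             stats::var(oracle_counts) / n_sim)
  expect_lt(abs(mean(sim_counts) - mean(oracle_counts)), 3 * se)
})

test_that("time-rescaled inter-event intervals are unit exponential", {
  # high event mass per patch so that window censoring of the final
  # (incomplete) interval is negligible relative to the KS resolution
  env <- forage_env(tau = 6, rsi = 0.005)  # L = 200, lam0 = 250
  set.seed(3)
  u <- unlist(lapply(1:8, function(i) {
    p <- simulate_patch(env, 25, seed = 300 + i)
    ev <- p$event_times
    a <- c(0, ev[-length(ev)])
    integrated_rate(env, a, ev - a)
  }))
  expect_gt(length(u), 10000)
  expect_gt(stats::ks.test(u, "pexp")$p.value, 0.01)
})

test_that("variance-to-mean ratio of cumulative volume equals V0", {
  env <- forage_env(tau = 6, rsi = 0.5)   # V0 = 1
  set.seed(5)
  n <- 6000
  counts <- vapply(seq_len(n), function(i) {
    length(simulate_patch(env, 10, seed = 40000 + i)$event_times)
  }, integer(1))
  v <- env$V0 * counts
  expect_lt(abs(stats::var(v) / mean(v) - env$V0) / env$V0, 0.05)
})

test_that("lower RSI regularizes reward timing without moving its mean", {
  # first-reward time: variance strictly decreases as RSI drops at fixed
  # (tau, r0); the conditional mean stays put (within MC error)
  set.seed(9)
  first_rewards <- function(rsi, n = 4000) {
    env <- forage_env(tau = 6, rsi = rsi)
    out <- vapply(seq_len(n), function(i) {
      r <- simulate_patch(env, 60, seed = rsi * 1e5 + i)$reward_times
      if (length(r)) r[1] else NA_real_
    }, numeric(1))
    out[!is.na(out)]
  }
  f1 <- first_rewards(1); f05 <- first_rewards(0.5); f005 <- first_rewards(0.05)
  expect_gt(stats::var(f1), stats::var(f05))
  expect_gt(stats::var(f05), stats::var(f005))
  # conditional means agree with each environment's own quadrature value
  for (pair in list(list(1, f1), list(0.5, f05), list(0.05, f005))) {
    env <- forage_env(tau = 6, rsi = pair[[1]])
    expected <- expected_future_reward_times(env, numeric(0), 0, 1)[1]
    x <- pair[[2]]
    expect_lt(abs(mean(x) - expected), 4 * stats::sd(x) / sqrt(length(x)))
  }
  # and are approximately invariant across stochasticity levels
  expect_lt(abs(mean(f1) - mean(f005)) / mean(f005), 0.10)
})

test_that("unobserved-event expectation is the truncated-Poisson mean", {
  env <- env_low_stoch()   # L = 20, lam0 = 25, tau = 6
  expect_equal(unobserved_event_expectation(env, 2, 2), 0)
  expect_equal(unobserved_event_expectation(env_high_stoch(), 1, 5), 0)
  L0 <- unobserved_event_expectation(env, 2, 3)
  expect_true(L0 >= 0 && L0 < env$L)
  # conditional MC oracle: hidden events in (2, 3) given fewer than L
  set.seed(13)
  lam <- integrated_rate(env, 2, 1)
  n <- stats::rpois(50000, lam)
  n <- n[n < env$L]
  expect_lt(abs(L0 - mean(n)), 3 * stats::sd(n) / sqrt(length(n)))
})

test_that("expected future reward times behave like the conditional mean", {
  # homogeneous limit: E[S1] = 1/lam0
  envh <- forage_env(tau = 1e6, rsi = 1)  # lam0 = 1.25
  e <- expected_future_reward_times(envh, numeric(0), 0, 2)
  expect_equal(e[1], 0.8, tolerance = 1e-4)
  expect_equal(e[2], 1.6, tolerance = 1e-4)

  # L0 correction is zero at patch entry with no prior events
  env <- env_high_stoch()
  expect_equal(unobserved_event_expectation(env, 0, 0), 0)

  # monotone in the reward index; unreachable tail flagged as NA
  e2 <- expected_future_reward_times(env, numeric(0), 4, 30)
  reached <- e2[!is.na(e2)]
  expect_true(all(diff(reached) > 0))
  expect_true(anyNA(e2))  # lam_inf ~ 3.85: the 30th reward is unreachable
  f0 <- attr(e2, "F0")
  expect_true(all(f0[is.na(e2)] < 1e-10))

  # conditional-mean MC oracle at (tau = 6, lam0 = 1.25, L = 1, t = 4)
  set.seed(17)
  lam_inf <- integrated_rate(env, 4, Inf)
  n <- stats::rpois(100000, lam_inf)
  keep <- n >= 1
  u <- stats::rbeta(sum(keep), 1, n[keep])
  s <- -env$tau * log1p(-u)
  mc <- mean(s) + 4
  expect_lt(abs(e2[1] - mc), 3 * stats::sd(s) / sqrt(length(s)))
})

test_that("environment configs round trip through flat key-value files", {
  env <- forage_env(tau = 12, rsi = 0.5, travel_time = 7,
                    track_label = "long")
  for (ext in c(".json", ".yaml")) {
    if (ext == ".yaml" && !requireNamespace("yaml", quietly = TRUE)) next
    path <- tempfile(fileext = ext)
    write_env_config(env, path)
    back <- read_env_config(path)
    expect_equal(unclass(back), unclass(env))
    unlink(path)
  }
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(tau_s = 6), bad, auto_unbox = TRUE)
  expect_error(read_env_config(bad), "missing field")
  unlink(bad)
})

test_that("reward-cue frequency rises two semitones per reward", {
  expect_equal(cue_frequency(0, 440), 440)
  expect_equal(cue_frequency(6, 440), 880)
  expect_equal(cue_frequency(3, 1000), 1000 * sqrt(2))
  expect_error(cue_frequency(-1, 440))
})
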