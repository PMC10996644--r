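# Build a freely-moving fixture with known violations: one short session
# (19 patches), one session with n_lat latency-600ms patches out of 30,
# and one clean 30-patch session.
latency_fixture <- function(n_lat_a = 4L, n_lat_b = 3L) {
  env <- forage_env(6, 0.5, travel_time = 8)
  pol <- agent_policy("FIXED_TIME", mean_time = 10, noise_sigma_log = 0.1)
  mk <- function(n, sid, n_lat = 0L, seed = 1) {
    s <- simulate_session(env, pol, n, seed = seed, animal_id = "A1",
                          session_id = sid)
    if (n_lat > 0) {
      for (i in seq_len(n_lat)) {
        p <- s$patches[[i]]
        if (!length(p$reward_times)) {   # ensure a reward to be late
          p$reward_times <- p$residence_time / 2
          p$event_times <- sort(unique(c(p$event_times,
                                         p$reward_times)))
        }
        p$reward_latencies <- rep(0, length(p$reward_times))
        p$reward_latencies[1] <- 0.6
        s$patches[[i]] <- p
      }
    }
    s
  }
  list(mk(19, "S_short", seed = 1),
       mk(30, "S_latent", n_lat = n_lat_a, seed = 2),
       mk(30, "S_clean", n_lat = n_lat_b, seed = 3))
}

test_that("freely-moving filters exclude exactly the designed violations", {
  out <- apply_inclusion_filters(latency_fixture(), "freely_moving")
  rep <- out$report
  expect_identical(rep$excluded[rep$criterion ==
                                  "fewer than 20 patches"], 1L)
  expect_identical(rep$excluded[rep$criterion ==
                                  "reward latency > 500 ms"], 7L)
  # 4/30 > 10% drops the session; 3/30 = 10% is retained (boundary)
  expect_identical(rep$excluded[rep$criterion ==
                                  "more than 10% latency patches"], 1L)
  expect_length(out$sessions, 1)
  expect_identical(out$sessions[[1]]$session_id, "S_clean")
  expect_length(out$sessions[[1]]$patches, 27L)
  # counts are conserved at the session level
  expect_identical(attr(rep, "n_sessions_in"), 3L)
  expect_identical(attr(rep, "n_sessions_out"), 1L)
})

test_that("outlier exclusion is strictly beyond the SD band", {
  env <- forage_env(6, 0.5, travel_time = 8)
  pol <- agent_policy("FIXED_TIME", mean_time = 10, noise_sigma_log = 0.1)
  s <- simulate_session(env, pol, 25, seed = 4)
  mu <- 1; sdv <- 0.2   # fixed global log10-normal fit
  at_bound <- 10^(mu + 3 * sdv)
  beyond <- 10^(mu + 3.05 * sdv)
  s$patches[[1]]$residence_time <- at_bound
  s$patches[[2]]$residence_time <- beyond
  out <- apply_inclusion_filters(list(s), "freely_moving",
                                 outlier_fit = c(mu, sdv))
  rep <- out$report
  expect_identical(rep$excluded[grepl("outlier", rep$criterion)], 1L)
  kept <- vapply(out$sessions[[1]]$patches, `[[`, numeric(1),
                 "residence_time")
  expect_true(at_bound %in% kept)
  expect_false(beyond %in% kept)
})

test_that("filters with a fixed outlier fit are idempotent", {
  sessions <- latency_fixture()
  once <- apply_inclusion_filters(sessions, "freely_moving",
                                  outlier_fit = c(1, 0.3))
  twice <- apply_inclusion_filters(once$sessions, "freely_moving",
                                   outlier_fit = c(1, 0.3))
  expect_identical(session_patches(twice$sessions),
                   session_patches(once$sessions))
})

test_that("task-relevant travel time follows the stated estimators", {
  # constant travel times: any percentile returns the constant
  df <- data.frame(animal = "A1", track = "short", travel = rep(10, 20))
  expect_equal(task_relevant_travel_time(df, "freely_moving")$travel_hat,
               10)
  # 10th percentile with linear interpolation between order statistics
  df2 <- data.frame(animal = "A1", track = "short", travel = 1:100)
  expect_equal(task_relevant_travel_time(df2, "freely_moving")$travel_hat,
               10.9)
  # head-fixed: supra-threshold time, then geometric mean
  v <- c(rep(2, 1400), rep(0.1, 600))   # 70% of a 20 s interval at 10 ms
  expect_equal(supra_threshold_time(v, 0.01), 14)
  df3 <- data.frame(animal = "A1", track = "short", relevant = c(4, 9))
  expect_equal(task_relevant_travel_time(df3, "head_fixed")$travel_hat,
               6)
})

test_that("engagement is the smoothed-lick-rate supra-threshold fraction", {
  # continuous 8 Hz licking: fully engaged
  es <- engagement_filter(seq(0.05, 39.95, by = 0.125), 40)
  expect_equal(es$engagement_fraction, 1)
  # zero licks
  es0 <- engagement_filter(numeric(0), 40)
  expect_equal(es0$engagement_fraction, 0)
  expect_equal(es0$task_relevant_residence, 0)
  # licks only in the first half: fraction ~ 0.5 up to bin/kernel edges
  es5 <- engagement_filter(seq(0.05, 19.95, by = 0.125), 40)
  expect_lt(abs(es5$engagement_fraction - 0.5), 0.1)
  # sub-bin patch falls back to a single bin
  tiny <- engagement_filter(c(0.05, 0.1, 0.2), 0.3)
  expect_equal(tiny$engagement_fraction, 1)
})

test_that("time-on-task detrending removes exactly a linear trend", {
  base <- data.frame(animal = "A1", session = "S1", patch = 1:100)
  base$residence <- 12
  out <- detrend_time_on_task(base)
  expect_equal(out$residence_adj, base$residence)
  expect_equal(out$delta_resid, rep(0, 100))

  trended <- base
  trended$residence <- 12 - 0.1 * (trended$patch - 1)
  out2 <- detrend_time_on_task(trended)
  expect_equal(stats::sd(out2$residence_adj), 0, tolerance = 1e-10)

  set.seed(8)
  noisy <- base
  noisy$residence <- 12 - 0.05 * (noisy$patch - 1) + stats::rnorm(100)
  out3 <- detrend_time_on_task(noisy)
  refit <- summary(stats::lm(residence_adj ~ patch, out3))$coefficients
  expect_lt(abs(refit["patch", "Estimate"]),
            2 * refit["patch", "Std. Error"])
})

test_that("round trip: noiseless head-fixed logs recover residence", {
  env <- forage_env(6, 0.5, travel_time = 8)
  s <- simulate_headfixed_session(
    env, agent_policy("FIXED_TIME", mean_time = 12), 8, seed = 12,
    stationary_noise_sd = 0)
  rec <- residence_from_traces(s)
  gen <- vapply(s$patches, `[[`, numeric(1), "residence_time")
  expect_true(all(abs(rec$residence - gen) <= s$velocity$dt + 1e-9))
})

test_that("the LMM hook normalizes covariates into [0, 1]", {
  envs <- cohort_envs()
  pol <- function(a, env) agent_policy("FIXED_TIME", mean_time = 10,
                                       noise_sigma_log = 0.1)
  p <- session_patches(simulate_cohort(envs, pol, 2, 4, 8, seed = 3))
  X <- lmm_design_matrix(p)
  for (col in c("tau", "track", "travel_time", "patch_number",
                "patch_start"))
    expect_true(all(X[[col]] >= 0 & X[[col]] <= 1))
  expect_s3_class(X$animal, "factor")
})
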