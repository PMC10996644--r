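# Shared fixtures, built in code at test time.

env_low_stoch <- function(tau = 6, travel = 10, track = "track1")
  forage_env(tau = tau, rsi = 0.05, travel_time = travel,
             track_label = track)   # L = 20, lam0 = 25

env_high_stoch <- function(tau = 6, travel = 10, track = "track1")
  forage_env(tau = tau, rsi = 1, travel_time = travel,
             track_label = track)   # L = 1, lam0 = 1.25

# Standard four-environment layout used by cohort-level tests.
cohort_envs <- function(rsi = 0.5) list(
  forage_env(3, rsi, travel_time = 5, track_label = "short"),
  forage_env(6, rsi, travel_time = 5, track_label = "short"),
  forage_env(12, rsi, travel_time = 10, track_label = "long"),
  forage_env(24, rsi, travel_time = 10, track_label = "long"))

# Small random reward-sequence fixtures for likelihood tests.
random_sequences <- function(seed, n_patches = 4, lam0 = 2, tau = 5,
                             L = 2L, duration = 15) {
  set.seed(seed)
  env <- forage_env(tau = tau, rsi = 1 / L, vr = 2, r0 = lam0 * 2 / L)
  ps <- lapply(seq_len(n_patches), function(i)
    simulate_patch(env, duration, seed = seed * 100 + i))
  list(times = lapply(ps, `[[`, "reward_times"),
       durations = rep(duration, n_patches), L = L, env = env)
}

# Threshold table for a single-cell environment (truth-anchored).
truth_thresholds <- function(env, animal = "A1") {
  tstar <- mvt_opt_residence(env$tau, env$travel_time)
  data.frame(animal = animal, tau = env$tau, track = env$track_label,
             travel_time = env$travel_time, lam0 = env$lam0,
             tau_hat = env$tau, t_hat = tstar,
             lambda_star = reward_rate(env, tstar),
             mode_lam = env$lam0, mode_tau = env$tau,
             stringsAsFactors = FALSE)
}
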