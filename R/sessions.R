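#' Define a ground-truth agent policy
#'
#' Synthetic agents leave patches according to one of five criteria,
#' mirroring the model families used in the analysis:
#' \describe{
#'   \item{FIXED_TIME}{leave after \code{mean_time} seconds in patch.}
#'   \item{N_REWARDS}{leave at the time of the \code{n_rewards}-th reward.}
#'   \item{ELAPSED_TIME}{leave once \code{delta} seconds elapse without a
#'     reward (the entry-to-first-reward wait counts).}
#'   \item{MVT_THRESHOLD}{leave when the true rate
#'     \eqn{\lambda_0 e^{-t/\tau}} falls to \code{threshold} (events/s);
#'     \code{threshold = NULL} derives the MVT-optimal rate threshold from
#'     the environment's \code{tau} and \code{travel_time}.}
#'   \item{MAP_THRESHOLD}{evaluate the MAP rate estimate online at
#'     \code{eval_dt} resolution (history depth \code{history}, gamma
#'     priors \code{prior}) and leave when it crosses \code{threshold}.}
#' }
#' The deterministic criterion is perturbed by multiplicative log-normal
#' decision noise (\code{noise_sigma_log}) and a linear time-on-task drift
#' (\code{drift_slope}, seconds of residence per patch index).
#'
#' @param kind One of \code{"FIXED_TIME"}, \code{"N_REWARDS"},
#'   \code{"ELAPSED_TIME"}, \code{"MVT_THRESHOLD"}, \code{"MAP_THRESHOLD"}.
#' @param mean_time,n_rewards,delta,threshold Policy-specific parameters
#'   (see Details); strictly positive where applicable.
#' @param prior A \code{\link{prior_spec}} for MAP agents; \code{NULL}
#'   anchors a relative-variance-0.3 prior at the environment's true
#'   parameters at simulation time.
#' @param history History depth N for MAP agents (patches including the
#'   current one).
#' @param eval_dt Online evaluation bin for MAP agents (s).
#' @param noise_sigma_log SD of log-normal decision noise (>= 0).
#' @param drift_slope Time-on-task drift (s per patch).
#' @return An object of class \code{agent_policy}.
#' @export
agent_policy <- function(kind = c("FIXED_TIME", "N_REWARDS", "ELAPSED_TIME",
                                  "MVT_THRESHOLD", "MAP_THRESHOLD"),
                         mean_time = NULL, n_rewards = NULL, delta = NULL,
                         threshold = NULL, prior = NULL, history = 1L,
                         eval_dt = 0.1, noise_sigma_log = 0,
                         drift_slope = 0) {
  kind <- match.arg(kind)
  stopifnot(noise_sigma_log >= 0)
  check_pos <- function(x, nm) {
    if (is.null(x)) stop("policy ", kind, " requires parameter ", nm)
    if (x <= 0) stop(nm, " must be strictly positive")
    x
  }
  params <- switch(kind,
    FIXED_TIME = list(mean_time = check_pos(mean_time, "mean_time")),
    N_REWARDS = list(n_rewards = as.integer(check_pos(n_rewards,
                                                      "n_rewards"))),
    ELAPSED_TIME = list(delta = check_pos(delta, "delta")),
    MVT_THRESHOLD = list(threshold = threshold),
    MAP_THRESHOLD = list(threshold = threshold, prior = prior,
                         history = as.integer(history), eval_dt = eval_dt))
  structure(list(kind = kind, params = params,
                 noise_sigma_log = noise_sigma_log,
                 drift_slope = drift_slope),
            class = "agent_policy")
}

# Deterministic leave time for a fully simulated patch (pre-noise).
# Returns list(time, truncated).
policy_leave_time <- function(policy, env, patch, history_patches,
                              max_duration) {
  p <- policy$params
  switch(policy$kind,
    FIXED_TIME = list(time = min(p$mean_time, max_duration),
                      truncated = p$mean_time > max_duration),
    N_REWARDS = {
      rw <- patch$reward_times
      if (length(rw) >= p$n_rewards)
        list(time = rw[p$n_rewards], truncated = FALSE)
      else list(time = max_duration, truncated = TRUE)
    },
    ELAPSED_TIME = {
      prev <- 0
      t <- NA_real_
      for (r in patch$reward_times) {
        if (r - prev >= p$delta) { t <- prev + p$delta; break }
        prev <- r
      }
      if (is.na(t)) t <- prev + p$delta
      list(time = min(t, max_duration), truncated = t > max_duration)
    },
    MVT_THRESHOLD = {
      thr <- p$threshold
      if (is.null(thr)) {
        tstar <- mvt_opt_residence(env$tau, env$travel_time)
        thr <- reward_rate(env, tstar)
      }
      t <- if (thr >= env$lam0) 0 else -env$tau * log(thr / env$lam0)
      list(time = min(t, max_duration), truncated = t > max_duration)
    },
    MAP_THRESHOLD = {
      thr <- p$threshold
      if (is.null(thr)) {
        tstar <- mvt_opt_residence(env$tau, env$travel_time)
        thr <- reward_rate(env, tstar)
      }
      prior <- p$prior
      if (is.null(prior))
        prior <- prior_spec(mode_lam = env$lam0, var_lam = 0.3,
                            mode_tau = env$tau, var_tau = 0.3,
                            relative = TRUE)
      hist <- history_stack(history_patches, policy$params$history - 1L)
      t <- cpp_predict_crossing(
        patch$reward_times, hist$times, hist$offsets, hist$durations,
        env$L, prior$alpha_lam, prior$beta_lam, prior$alpha_tau,
        prior$beta_tau, thr, p$eval_dt, max_duration)
      if (t < 0) list(time = max_duration, truncated = TRUE)
      else list(time = t, truncated = FALSE)
    })
}

# Pack the most recent n_hist patch records into the concatenated layout
# used by the C++ estimator kernels.
history_stack <- function(patches, n_hist) {
  if (n_hist > 0 && length(patches) > 0) {
    keep <- utils::tail(patches, n_hist)
    times <- lapply(keep, `[[`, "reward_times")
    list(times = unlist(times, use.names = FALSE) %||% numeric(0),
         offsets = as.integer(c(0, cumsum(lengths(times)))),
         durations = vapply(keep, `[[`, numeric(1), "residence_time"))
  } else {
    list(times = numeric(0), offsets = 0L, durations = numeric(0))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a freely-moving foraging session
#'
#' Draws \code{n_patches} patches from the environment's reward process,
#' applies the agent policy (with decision noise and time-on-task drift)
#' to obtain residence times, and draws travel intervals as the
#' task-relevant travel cost plus nonnegative log-normal task-irrelevant
#' excess. All randomness derives deterministically from \code{seed}
#' (per-patch streams keyed by \code{(seed, patch_index)}).
#'
#' @param env A \code{\link{forage_env}}.
#' @param policy An \code{\link{agent_policy}}.
#' @param n_patches Number of patches (>= 1).
#' @param seed Integer root seed.
#' @param animal_id,session_id Identifiers stored in the log.
#' @param max_duration Per-patch simulation horizon (s).
#' @param travel_excess_median,travel_excess_sdlog Median (s) and log-SD of
#'   the log-normal task-irrelevant travel excess.
#' @return An object of class \code{session_log}: identifiers, the
#'   environment, a list of \code{\link{patch_record}}s, travel intervals
#'   (length \code{n_patches - 1}), and the generating policy as ground
#'   truth.
#' @export
simulate_session <- function(env, policy, n_patches, seed,
                             animal_id = "A1", session_id = "S1",
                             max_duration = 120,
                             travel_excess_median = 2,
                             travel_excess_sdlog = 0.5) {
  stopifnot(n_patches >= 1)
  patches <- vector("list", n_patches)
  travel <- numeric(max(n_patches - 1L, 0L))
  entry <- 0
  for (i in seq_len(n_patches)) {
    full <- simulate_patch(env, max_duration, seed = derive_seed(seed, i),
                           patch_index = i, entry_clock = entry)
    det <- policy_leave_time(policy, env, full, patches[seq_len(i - 1L)],
                             max_duration)
    res <- det$time
    if (policy$noise_sigma_log > 0)
      res <- res * exp(stats::rnorm(1, 0, policy$noise_sigma_log))
    res <- res + policy$drift_slope * (i - 1)
    res <- min(max(res, 1e-3), max_duration)
    patches[[i]] <- truncate_patch(full, res,
                                   truncated = det$truncated)
    if (i < n_patches) {
      excess <- stats::rlnorm(1, log(travel_excess_median),
                              travel_excess_sdlog)
      travel[i] <- env$travel_time + excess
      entry <- entry + res + travel[i]
    }
  }
  structure(
    list(animal_id = animal_id, session_id = session_id, env = env,
         patches = patches, travel_intervals = travel,
         lick_times = NULL, velocity = NULL,
         ground_truth = policy, seed = as.integer(seed)),
    class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %s/%s: %d patches, tau=%g rsi=%g%s\n",
              x$animal_id, x$session_id, length(x$patches),
              x$env$tau, x$env$rsi,
              if (!is.null(x$velocity)) " (head-fixed traces)" else ""))
  invisible(x)
}

#' Simulate a head-fixed session with velocity and lick traces
#'
#' Wraps \code{\link{simulate_session}} and adds the observables of the
#' head-fixed task: a uniformly sampled treadmill-velocity trace (running
#' at \code{run_speed} between patches, crossing the 5 cm/s leave
#' threshold at patch exit and falling below the 0.5 cm/s entry threshold
#' at patch entry) and session-clock lick times (rate \code{lick_rate_in}
#' Hz within patches, \code{lick_rate_out} Hz outside). Kinematics are a
#' minimal piecewise-constant profile: only the threshold crossings carry
#' information downstream.
#'
#' @inheritParams simulate_session
#' @param trace_dt Velocity sample period (s), default 0.01.
#' @param run_speed Travel running speed (cm/s), must exceed 5.
#' @param stationary_noise_sd SD of in-patch velocity jitter (cm/s),
#'   clipped below 0.45 so it never crosses the entry threshold; set 0 for
#'   noiseless kinematics.
#' @param lick_rate_in,lick_rate_out In-patch / out-of-patch lick rates
#'   (Hz).
#' @return A \code{session_log} with \code{velocity} (list with fields
#'   \code{v}, \code{dt}) and \code{lick_times} populated.
#' @export
simulate_headfixed_session <- function(env, policy, n_patches, seed,
                                       animal_id = "A1", session_id = "S1",
                                       max_duration = 120,
                                       travel_excess_median = 2,
                                       travel_excess_sdlog = 0.5,
                                       trace_dt = 0.01, run_speed = 20,
                                       stationary_noise_sd = 0.05,
                                       lick_rate_in = 8,
                                       lick_rate_out = 0.05) {
  stopifnot(run_speed > 5)
  s <- simulate_session(env, policy, n_patches, seed,
                        animal_id = animal_id, session_id = session_id,
                        max_duration = max_duration,
                        travel_excess_median = travel_excess_median,
                        travel_excess_sdlog = travel_excess_sdlog)
  entries <- vapply(s$patches, `[[`, numeric(1), "entry_clock")
  resid <- vapply(s$patches, `[[`, numeric(1), "residence_time")
  exits <- entries + resid
  # the trace ends mid-run after the final patch so its exit is marked
  total <- exits[length(exits)] + 0.5
  tgrid <- seq(0, total, by = trace_dt)
  v <- numeric(length(tgrid))
  if (stationary_noise_sd > 0) {
    v <- abs(stats::rnorm(length(tgrid), 0,
                          min(stationary_noise_sd, 0.45)))
    v <- pmin(v, 0.45)
  }
  licks <- numeric(0)
  for (i in seq_along(entries)) {
    run_end <- if (i < length(entries)) entries[i + 1]
               else total + trace_dt
    v[tgrid >= exits[i] & tgrid < run_end] <- run_speed
    n_in <- stats::rpois(1, lick_rate_in * resid[i])
    licks <- c(licks, entries[i] + sort(stats::runif(n_in, 0, resid[i])))
    if (i < length(entries) && lick_rate_out > 0) {
      gap <- entries[i + 1] - exits[i]
      n_out <- stats::rpois(1, lick_rate_out * gap)
      licks <- c(licks, exits[i] + sort(stats::runif(n_out, 0, gap)))
    }
  }
  s$velocity <- list(v = v, dt = trace_dt)
  s$lick_times <- licks
  s
}

#' Flatten session logs into a per-patch data frame
#'
#' The tidy surface consumed by the preprocessing, model-fitting and
#' evaluation functions. One row per patch with identifiers, environment
#' parameters, residence summaries and the observed reward times as a
#' list column.
#'
#' @param sessions A \code{session_log} or list of them.
#' @return A data.frame with columns \code{animal, session, patch, tau,
#'   rsi, L, lam0, track, travel_time, entry_clock, residence, n_rewards,
#'   last_reward, truncated, max_latency} and list column \code{rewards}.
#' @export
session_patches <- function(sessions) {
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    n <- length(s$patches)
    data.frame(
      animal = s$animal_id, session = s$session_id,
      patch = vapply(s$patches, `[[`, integer(1), "patch_index"),
      tau = s$env$tau, rsi = s$env$rsi, L = s$env$L, lam0 = s$env$lam0,
      track = s$env$track_label, travel_time = s$env$travel_time,
      entry_clock = vapply(s$patches, `[[`, numeric(1), "entry_clock"),
      residence = vapply(s$patches, `[[`, numeric(1), "residence_time"),
      n_rewards = vapply(s$patches, function(p) length(p$reward_times),
                         integer(1)),
      last_reward = vapply(s$patches, function(p)
        if (length(p$reward_times)) max(p$reward_times) else NA_real_,
        numeric(1)),
      truncated = vapply(s$patches, `[[`, logical(1), "truncated"),
      max_latency = vapply(s$patches, function(p)
        if (length(p$reward_latencies)) max(p$reward_latencies) else 0,
        numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rewards <- do.call(c, lapply(sessions, function(s)
    lapply(s$patches, `[[`, "reward_times")))
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of animals across sessions and environments
#'
#' Convenience driver for multi-animal experiments: each animal completes
#' \code{n_sessions} sessions, cycling through the supplied environments;
#' the per-(animal, environment) policy is produced by \code{policy_fn}.
#'
#' @param envs List of \code{\link{forage_env}}s (cycled across sessions).
#' @param policy_fn Function \code{(animal_index, env) -> agent_policy}.
#' @param n_animals,n_sessions,n_patches Cohort dimensions.
#' @param seed Integer root seed; session seeds are derived
#'   deterministically.
#' @param ... Passed to \code{\link{simulate_session}}.
#' @return A list of \code{session_log}s.
#' @export
simulate_cohort <- function(envs, policy_fn, n_animals, n_sessions,
                            n_patches, seed, ...) {
  if (inherits(envs, "forage_env")) envs <- list(envs)
  out <- vector("list", n_animals * n_sessions)
  k <- 0
  for (a in seq_len(n_animals)) {
    for (ss in seq_len(n_sessions)) {
      env <- envs[[(ss - 1L) %% length(envs) + 1L]]
      k <- k + 1
      out[[k]] <- simulate_session(
        env, policy_fn(a, env), n_patches,
        seed = derive_seed(seed, k),
        animal_id = sprintf("A%02d", a),
        session_id = sprintf("A%02d_S%02d", a, ss), ...)
    }
  }
  out
}
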