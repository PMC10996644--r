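#' Construct a patch record
#'
#' Holds one patch's hidden event times, observed reward times (events at
#' multiples of \code{L}), and occupancy. All within-patch times are
#' measured from patch entry.
#'
#' @param event_times Strictly increasing hidden event times (s).
#' @param reward_times Strictly increasing observed reward times (s);
#'   a subset of \code{event_times} at indices \code{L, 2L, ...}.
#' @param residence_time Patch occupancy duration (s).
#' @param patch_index 1-based ordinal of the patch within its session.
#' @param entry_clock Session time at patch entry (s).
#' @param truncated Logical flag: the leave criterion never fired and the
#'   patch was cut at the simulation horizon.
#' @param reward_latencies Per-reward delivery latencies (s), default 0;
#'   used by the inclusion filters.
#' @return An object of class \code{patch_record}.
#' @export
patch_record <- function(event_times, reward_times, residence_time,
                         patch_index = 1L, entry_clock = 0,
                         truncated = FALSE,
                         reward_latencies = numeric(length(reward_times))) {
  event_times <- as.numeric(event_times)
  reward_times <- as.numeric(reward_times)
  if (is.unsorted(event_times, strictly = TRUE))
    stop("event_times must be strictly increasing")
  if (is.unsorted(reward_times, strictly = TRUE))
    stop("reward_times must be strictly increasing")
  if (length(event_times) && (min(event_times) < 0 ||
      max(event_times) > residence_time + 1e-9))
    stop("event times must lie in [0, residence_time]")
  structure(
    list(event_times = event_times, reward_times = reward_times,
         residence_time = residence_time,
         patch_index = as.integer(patch_index), entry_clock = entry_clock,
         truncated = isTRUE(truncated),
         reward_latencies = as.numeric(reward_latencies)),
    class = "patch_record")
}

# Deterministic per-patch stream seed derived from a session root seed.
# Keeps all root-derived seeds below 2^31.
derive_seed <- function(root, patch_index) {
  as.integer((as.double(root) * 48271 + as.double(patch_index) * 104729) %%
               2147483629)
}

#' Simulate one patch of the inhomogeneous gamma process
#'
#' Hidden events are drawn from the inhomogeneous Poisson process with rate
#' \eqn{\lambda_0 e^{-t/\tau}} by time rescaling: cumulative sums of unit
#' exponentials below the total mass \eqn{\Lambda(0, d)} are mapped through
#' the closed-form inverse of \eqn{\Lambda(0, \cdot)}. Every \code{L}-th
#' event is an observed reward.
#'
#' @param env A \code{\link{forage_env}}.
#' @param max_duration Simulation horizon (s); must be positive.
#' @param seed Optional integer seed for reproducibility.
#' @param patch_index,entry_clock Passed through to the record.
#' @return A \code{\link{patch_record}} with \code{residence_time =
#'   max_duration} (callers truncate to the agent's leave time).
#' @examples
#' env <- forage_env(tau = 6, rsi = 1)
#' p <- simulate_patch(env, max_duration = 20, seed = 1)
#' all.equal(p$event_times, p$reward_times)  # L = 1: every event observable
#' @export
simulate_patch <- function(env, max_duration, seed = NULL,
                           patch_index = 1L, entry_clock = 0) {
  stopifnot(max_duration > 0)
  if (!is.null(seed)) set.seed(seed)
  mass <- integrated_rate(env, 0, max_duration)
  gaps <- numeric(0)
  total <- 0
  block <- max(16L, ceiling(mass + 4 * sqrt(mass)))
  while (total <= mass) {
    e <- stats::rexp(block)
    gaps <- c(gaps, e)
    total <- total + sum(e)
  }
  g <- cumsum(gaps)
  g <- g[g < mass]
  times <- -env$tau * log1p(-g / (env$lam0 * env$tau))
  times <- pmin(times, max_duration)  # guard rounding at the horizon
  ridx <- seq_len(length(times) %/% env$L) * env$L
  patch_record(event_times = times, reward_times = times[ridx],
               residence_time = max_duration, patch_index = patch_index,
               entry_clock = entry_clock)
}

# Truncate a simulated patch at an agent's leave time.
truncate_patch <- function(patch, residence, truncated = FALSE) {
  patch_record(
    event_times = patch$event_times[patch$event_times <= residence + 1e-9],
    reward_times = patch$reward_times[patch$reward_times <= residence + 1e-9],
    residence_time = residence, patch_index = patch$patch_index,
    entry_clock = patch$entry_clock, truncated = truncated)
}

#' Expected number of hidden events since the last reward
#'
#' Between two rewards at most \code{L - 1} hidden events can have accrued.
#' Conditional on fewer than \code{L} events in \eqn{(t_{last}, t_{now})},
#' the count is truncated-Poisson with mean
#' \eqn{L_0 = \sum_{m<L} m \tilde P(m)}, where \eqn{\tilde P} normalizes
#' the Poisson pmf with mean \eqn{\Lambda(t_{last}, t_{now}-t_{last})} over
#' \eqn{m < L}.
#'
#' @param env A \code{\link{forage_env}}.
#' @param t_last_reward Time of the last observed reward (s from entry);
#'   use 0 if no reward has occurred.
#' @param t_now Current time (s from entry), \code{>= t_last_reward}.
#' @return Expected hidden-event count \eqn{L_0 \in [0, L)}.
#' @export
unobserved_event_expectation <- function(env, t_last_reward, t_now) {
  stopifnot(t_now >= t_last_reward, t_last_reward >= 0)
  if (env$L == 1L) return(0)
  lam <- integrated_rate(env, t_last_reward, t_now - t_last_reward)
  if (lam == 0) return(0)
  m <- 0:(env$L - 1L)
  p <- stats::dpois(m, lam)
  sum(m * p) / sum(p)
}

# CDF of the time of the M-th hidden event after t_now (s measured from
# t_now): F_SM(s) = P(N(t_now, t_now+s) >= M) = 1 - ppois(M-1, Lambda).
event_time_cdf <- function(env, M, t_now, s) {
  stats::ppois(M - 1, integrated_rate(env, t_now, s), lower.tail = FALSE)
}

#' Expected future reward times
#'
#' Computes \eqn{E_t[S_M] + t_{now}} for the next \code{n_future} rewards,
#' conditioning on the reward occurring at all (total event mass after
#' \code{t_now} is finite, so late rewards may be unreachable). The first
#' future reward requires \eqn{L - L_0} further events, where \eqn{L_0} is
#' the expected hidden-event count accrued since the last observed reward
#' (\code{\link{unobserved_event_expectation}}); each later reward requires
#' \code{L} events. The conditional mean is evaluated by adaptive
#' quadrature of \eqn{s \tilde f_{S_M}(s)} with the M-th-event density
#' \eqn{f(s) = \lambda(t+s) e^{-\Lambda} \Lambda^{M-1}/(M-1)!}.
#'
#' @param env A \code{\link{forage_env}}.
#' @param observed_rewards Reward times observed so far (s from entry).
#' @param t_now Current time (s from entry), at or after the last
#'   observed reward.
#' @param n_future Number of future rewards to project (>= 1).
#' @return Numeric vector of expected reward times on the patch-entry
#'   clock; \code{NA} marks rewards whose occurrence probability
#'   \eqn{F_0 < 10^{-10}} (unreachable). Attribute \code{"F0"} carries the
#'   per-reward occurrence probabilities.
#' @export
expected_future_reward_times <- function(env, observed_rewards, t_now,
                                         n_future = 1L) {
  stopifnot(n_future >= 1)
  if (length(observed_rewards) && t_now < max(observed_rewards) - 1e-9)
    stop("t_now must be at or after the last observed reward")
  t_last <- if (length(observed_rewards)) max(observed_rewards) else 0
  L0 <- unobserved_event_expectation(env, t_last, t_now)
  M1 <- max(1L, as.integer(round(env$L - L0)))
  Ms <- M1 + (seq_len(n_future) - 1L) * env$L
  lam_inf <- integrated_rate(env, t_now, Inf)
  out <- rep(NA_real_, n_future)
  F0s <- stats::ppois(Ms - 1, lam_inf, lower.tail = FALSE)
  for (j in seq_len(n_future)) {
    if (F0s[j] < 1e-10) break  # this and all later rewards unreachable
    out[j] <- expected_event_time(env, Ms[j], t_now)
  }
  attr(out, "F0") <- F0s
  out
}

# Conditional expected occurrence time of the M-th hidden event after
# t_now (patch-entry clock), E[t_now + S_M | S_M < Inf], by adaptive
# quadrature of s * f_SM(s) / F0 with the M-th-event density
# f(s) = lambda(t+s) e^{-Lambda} Lambda^{M-1}/(M-1)!. NA if the event is
# essentially unreachable (F0 < 1e-10).
expected_event_time <- function(env, M, t_now) {
  lam_inf <- integrated_rate(env, t_now, Inf)
  F0 <- stats::ppois(M - 1, lam_inf, lower.tail = FALSE)
  if (F0 < 1e-10) return(NA_real_)
  # truncate where F_SM has saturated: either the event-count tail is
  # negligible (Poisson mass beyond M + 10 sqrt(M) + 30) or the total
  # mass Lambda(t, s) has plateaued
  target <- min(lam_inf * (1 - 1e-14), M + 10 * sqrt(M) + 30)
  s_max <- min(-env$tau * log1p(-target / lam_inf), 40 * env$tau)
  dens <- function(s) {
    lam <- integrated_rate(env, t_now, s)
    s * reward_rate(env, t_now + s) * stats::dpois(M - 1, lam)
  }
  val <- stats::integrate(dens, 0, s_max, subdivisions = 400L,
                          rel.tol = 1e-9, abs.tol = 0)$value
  t_now + val / F0
}
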