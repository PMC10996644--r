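#' Define a foraging environment
#'
#' An environment fixes the reward dynamics of every patch in a session:
#' hidden Poisson events arrive at rate \eqn{\lambda(t) = \lambda_0
#' e^{-t/\tau}} (time measured from patch entry), each event carries a
#' fixed volume \code{V0}, and every \code{L}-th event is observable as a
#' reward droplet of volume \code{Vr}. The initial volumetric rate
#' \eqn{r_0 = V_0 \lambda_0} is held constant across stochasticity levels,
#' so the reward stochasticity index \code{rsi = V0/Vr} varies reward-timing
#' noise without changing the expected cumulative reward.
#'
#' @param tau Decay time constant of the event rate (s); must be positive.
#' @param rsi Reward stochasticity index in (0, 1]; \code{1/rsi} must be an
#'   integer (the events-per-reward count \code{L}).
#' @param vr Reward droplet volume (uL), default 2.
#' @param r0 Initial volumetric rate (uL/s), default 2.5.
#' @param travel_time Task-relevant travel cost between patches (s).
#' @param track_label Categorical track identifier.
#' @return An object of class \code{forage_env}: a list with fields
#'   \code{tau, lam0, V0, Vr, r0, rsi, L, travel_time, track_label}.
#' @examples
#' env <- forage_env(tau = 6, rsi = 0.5, travel_time = 10)
#' env$L      # 2 events per reward
#' env$lam0   # 2.5 events/s
#' @export
forage_env <- function(tau, rsi, vr = 2, r0 = 2.5, travel_time = 10,
                       track_label = "track1") {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
  stopifnot(is.numeric(rsi), length(rsi) == 1, rsi > 0, rsi <= 1)
  stopifnot(vr > 0, r0 > 0, travel_time >= 0)
  V0 <- rsi * vr
  L <- vr / V0
  if (abs(L - round(L)) > 1e-9) {
    stop("1/rsi must be an integer: every L-th event is a reward (got L = ",
         format(L), ")")
  }
  L <- as.integer(round(L))
  lam0 <- r0 / V0
  structure(
    list(tau = tau, lam0 = lam0, V0 = V0, Vr = vr, r0 = r0, rsi = rsi,
         L = L, travel_time = travel_time,
         track_label = as.character(track_label)),
    class = "forage_env")
}

#' @export
print.forage_env <- function(x, ...) {
  cat(sprintf(
    "<forage_env> tau=%gs rsi=%g (L=%d, lam0=%g ev/s, V0=%g uL) travel=%gs track=%s\n",
    x$tau, x$rsi, x$L, x$lam0, x$V0, x$travel_time, x$track_label))
  invisible(x)
}

#' Instantaneous hidden-event rate
#'
#' \eqn{\lambda(t) = \lambda_0 e^{-t/\tau}}, strictly decreasing in time
#' since patch entry.
#'
#' @param env A \code{\link{forage_env}}.
#' @param t Time since patch entry (s), vectorized; must be nonnegative.
#' @return Event rate (events/s).
#' @export
reward_rate <- function(env, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  env$lam0 * exp(-t / env$tau)
}

#' Integrated event rate over an interval
#'
#' Expected hidden-event count on \eqn{[t, t+s]}:
#' \eqn{\Lambda(t, s) = \lambda_0 \tau e^{-t/\tau} (1 - e^{-s/\tau})}.
#' Additive in the duration: \eqn{\Lambda(t, s_1+s_2) = \Lambda(t, s_1) +
#' \Lambda(t+s_1, s_2)}.
#'
#' @inheritParams reward_rate
#' @param s Interval duration (s); nonnegative, may be \code{Inf}.
#' @return Expected event count (dimensionless).
#' @export
integrated_rate <- function(env, t, s) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (any(s < 0)) stop("duration s must be nonnegative")
  env$lam0 * env$tau * exp(-t / env$tau) * (-expm1(-s / env$tau))
}

#' Moments of the cumulative hidden reward volume
#'
#' The volume accrued by time \code{s} in a patch is \eqn{V(s) = V_0 N(s)}
#' with \eqn{N(s)} Poisson, so \eqn{E[V(s)] = r_0 \tau (1 - e^{-s/\tau})}
#' and \eqn{var[V(s)] = V_0 E[V(s)]}: variance scales with the event volume
#' while the mean is stochasticity-invariant.
#'
#' @inheritParams integrated_rate
#' @return A list with elements \code{mean} (uL) and \code{var} (uL^2).
#' @export
volume_moments <- function(env, s) {
  if (any(s < 0)) stop("duration s must be nonnegative")
  m <- env$r0 * env$tau * (-expm1(-s / env$tau))
  list(mean = m, var = env$V0 * m)
}

#' Reward-cue pure-tone frequency
#'
#' The availability cue rises by two semitones per reward already received:
#' \eqn{f_n = f_0 \cdot 2^{2n/12}}.
#'
#' @param n_rewards Number of rewards received so far (nonnegative integer,
#'   vectorized).
#' @param f0 Base frequency (Hz).
#' @return Frequency (Hz).
#' @export
cue_frequency <- function(n_rewards, f0) {
  if (any(n_rewards < 0)) stop("n_rewards must be nonnegative")
  f0 * 2^(2 * n_rewards / 12)
}

#' Write or read an environment configuration
#'
#' Environments serialize as a flat key-value block
#' \code{{tau_s, rsi, vr_ul, r0_ul_per_s, travel_time_s, track_label}};
#' \code{lam0}, \code{V0} and \code{L} are derived on load. Format is
#' chosen by file extension: \code{.json} (jsonlite) or \code{.yaml}/
#' \code{.yml} (requires the yaml package).
#'
#' @param env A \code{\link{forage_env}}.
#' @param path Output (or input) file path.
#' @return \code{read_env_config} returns a \code{forage_env};
#'   \code{write_env_config} returns \code{path} invisibly.
#' @export
write_env_config <- function(env, path) {
  rec <- list(tau_s = env$tau, rsi = env$rsi, vr_ul = env$Vr,
              r0_ul_per_s = env$r0, travel_time_s = env$travel_time,
              track_label = env$track_label)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML config")
    writeLines(yaml::as.yaml(rec), path)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_env_config
#' @export
read_env_config <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML config")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  needed <- c("tau_s", "rsi", "vr_ul", "r0_ul_per_s", "travel_time_s",
              "track_label")
  missing <- setdiff(needed, names(rec))
  if (length(missing))
    stop("environment config missing field(s): ",
         paste(missing, collapse = ", "))
  forage_env(tau = rec$tau_s, rsi = rec$rsi, vr = rec$vr_ul,
             r0 = rec$r0_ul_per_s, travel_time = rec$travel_time_s,
             track_label = rec$track_label)
}
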