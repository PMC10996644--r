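#' Write and read session logs
#'
#' JSON serialization is field-faithful (full double precision, including
#' ground-truth policy and seed), so a write/read round trip reproduces
#' the log exactly.
#'
#' @param session A \code{\link{session_log}} (or for the bundle writers,
#'   a list of them).
#' @param path Output file (JSON).
#' @return \code{read_session} returns a \code{session_log};
#'   writers return their path invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_log"))
  rec <- unclass(session)
  rec$env <- unclass(rec$env)
  rec$patches <- lapply(rec$patches, unclass)
  if (!is.null(rec$ground_truth))
    rec$ground_truth <- policy_to_list(rec$ground_truth)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

policy_to_list <- function(policy) {
  out <- unclass(policy)
  if (!is.null(out$params$prior)) out$params$prior <- unclass(out$params$prior)
  out
}

policy_from_list <- function(rec) {
  prior <- rec$params$prior
  if (!is.null(prior))
    prior <- structure(lapply(prior, as.numeric), class = "prior_spec")
  args <- rec$params
  args$prior <- prior
  # translate stored param names back to constructor arguments
  do.call(agent_policy, c(list(kind = rec$kind), args,
                          list(noise_sigma_log = rec$noise_sigma_log,
                               drift_slope = rec$drift_slope)))
}

num <- function(x) if (is.null(x)) numeric(0) else as.numeric(unlist(x))

#' @rdname write_session
#' @export
read_session <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  req <- c("animal_id", "session_id", "env", "patches", "travel_intervals")
  missing <- setdiff(req, names(rec))
  if (length(missing))
    stop("session file missing required field(s): ",
         paste(missing, collapse = ", "))
  env <- forage_env(tau = rec$env$tau, rsi = rec$env$rsi, vr = rec$env$Vr,
                    r0 = rec$env$r0, travel_time = rec$env$travel_time,
                    track_label = rec$env$track_label)
  patches <- lapply(rec$patches, function(p)
    patch_record(event_times = num(p$event_times),
                 reward_times = num(p$reward_times),
                 residence_time = p$residence_time,
                 patch_index = p$patch_index, entry_clock = p$entry_clock,
                 truncated = isTRUE(p$truncated),
                 reward_latencies = num(p$reward_latencies)))
  gt <- if (!is.null(rec$ground_truth)) policy_from_list(rec$ground_truth)
  vel <- if (!is.null(rec$velocity))
    list(v = num(rec$velocity$v), dt = rec$velocity$dt)
  structure(
    list(animal_id = rec$animal_id, session_id = rec$session_id, env = env,
         patches = patches, travel_intervals = num(rec$travel_intervals),
         lick_times = if (is.null(rec$lick_times)) NULL
                      else num(rec$lick_times),
         velocity = vel, ground_truth = gt,
         seed = if (is.null(rec$seed)) NA_integer_ else as.integer(rec$seed)),
    class = "session_log")
}

#' Write and read a CSV bundle of sessions
#'
#' Plain-text alternative to JSON for multi-session exports:
#' \code{sessions.csv} (identifiers + environment + seed),
#' \code{patches.csv} (one row per patch), \code{rewards.csv} (one row per
#' reward, with latency), \code{events.csv} (hidden event times, written
#' when \code{include_events}) and \code{traces.csv} (velocity samples and
#' lick times for head-fixed sessions). Times are seconds; patch indices
#' are 1-based. Ground-truth policies travel as a JSON string column.
#'
#' @param sessions List of \code{session_log}s.
#' @param dir Output directory (created if needed).
#' @param include_events Write hidden event times as well.
#' @return \code{read_session_bundle} returns a list of
#'   \code{session_log}s (traces are restored when present).
#' @export
write_session_bundle <- function(sessions, dir, include_events = TRUE) {
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ses <- do.call(rbind, lapply(sessions, function(s) data.frame(
    animal = s$animal_id, session = s$session_id, tau_s = s$env$tau,
    rsi = s$env$rsi, vr_ul = s$env$Vr, r0_ul_per_s = s$env$r0,
    travel_time_s = s$env$travel_time, track_label = s$env$track_label,
    seed = s$seed %||% NA_integer_,
    ground_truth = if (is.null(s$ground_truth)) NA_character_ else
      as.character(jsonlite::toJSON(policy_to_list(s$ground_truth),
                                    auto_unbox = TRUE, digits = NA,
                                    null = "null")),
    travel_intervals = paste(sprintf("%.17g", s$travel_intervals),
                             collapse = ";"),
    trace_dt = if (is.null(s$velocity)) NA_real_ else s$velocity$dt,
    stringsAsFactors = FALSE)))
  per_patch <- function(s, f) do.call(rbind, lapply(s$patches, f))
  pat <- do.call(rbind, lapply(sessions, function(s) per_patch(s,
    function(p) data.frame(
      animal = s$animal_id, session = s$session_id, patch = p$patch_index,
      residence_s = p$residence_time, entry_clock_s = p$entry_clock,
      truncated = p$truncated, stringsAsFactors = FALSE))))
  rew <- do.call(rbind, lapply(sessions, function(s) per_patch(s,
    function(p) if (!length(p$reward_times)) NULL else data.frame(
      animal = s$animal_id, session = s$session_id, patch = p$patch_index,
      reward_time_s = p$reward_times,
      latency_s = if (length(p$reward_latencies)) p$reward_latencies else 0,
      stringsAsFactors = FALSE))))
  utils::write.csv(ses, file.path(dir, "sessions.csv"), row.names = FALSE)
  utils::write.csv(pat, file.path(dir, "patches.csv"), row.names = FALSE)
  utils::write.csv(rew %||% data.frame(), file.path(dir, "rewards.csv"),
                   row.names = FALSE)
  if (include_events) {
    ev <- do.call(rbind, lapply(sessions, function(s) per_patch(s,
      function(p) if (!length(p$event_times)) NULL else data.frame(
        animal = s$animal_id, session = s$session_id, patch = p$patch_index,
        event_time_s = p$event_times, stringsAsFactors = FALSE))))
    utils::write.csv(ev %||% data.frame(), file.path(dir, "events.csv"),
                     row.names = FALSE)
  }
  tr <- do.call(rbind, lapply(sessions, function(s) {
    out <- NULL
    if (!is.null(s$velocity))
      out <- data.frame(animal = s$animal_id, session = s$session_id,
                        kind = "velocity",
                        t_s = (seq_along(s$velocity$v) - 1) * s$velocity$dt,
                        value = s$velocity$v, stringsAsFactors = FALSE)
    if (!is.null(s$lick_times) && length(s$lick_times))
      out <- rbind(out, data.frame(animal = s$animal_id,
                                   session = s$session_id, kind = "lick",
                                   t_s = s$lick_times, value = 1,
                                   stringsAsFactors = FALSE))
    out
  }))
  if (!is.null(tr))
    utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session_bundle
#' @export
read_session_bundle <- function(dir) {
  ses <- utils::read.csv(file.path(dir, "sessions.csv"),
                         stringsAsFactors = FALSE)
  pat <- utils::read.csv(file.path(dir, "patches.csv"),
                         stringsAsFactors = FALSE)
  rew_path <- file.path(dir, "rewards.csv")
  rew <- if (file.exists(rew_path) && length(readLines(rew_path, n = 2)) > 1)
    utils::read.csv(rew_path, stringsAsFactors = FALSE) else NULL
  ev_path <- file.path(dir, "events.csv")
  ev <- if (file.exists(ev_path) && length(readLines(ev_path, n = 2)) > 1)
    utils::read.csv(ev_path, stringsAsFactors = FALSE) else NULL
  tr_path <- file.path(dir, "traces.csv")
  tr <- if (file.exists(tr_path))
    utils::read.csv(tr_path, stringsAsFactors = FALSE) else NULL
  lapply(seq_len(nrow(ses)), function(i) {
    row <- ses[i, ]
    env <- forage_env(tau = row$tau_s, rsi = row$rsi, vr = row$vr_ul,
                      r0 = row$r0_ul_per_s,
                      travel_time = row$travel_time_s,
                      track_label = row$track_label)
    pp <- pat[pat$animal == row$animal & pat$session == row$session, ]
    pp <- pp[order(pp$patch), ]
    patches <- lapply(seq_len(nrow(pp)), function(j) {
      q <- pp[j, ]
      sel <- function(df) df[df$animal == row$animal &
                             df$session == row$session &
                             df$patch == q$patch, , drop = FALSE]
      rw <- if (is.null(rew)) NULL else sel(rew)
      evt <- if (is.null(ev)) NULL else sel(ev)
      rtimes <- if (is.null(rw) || !nrow(rw)) numeric(0)
                else sort(rw$reward_time_s)
      patch_record(
        event_times = if (is.null(evt) || !nrow(evt)) rtimes
                      else sort(evt$event_time_s),
        reward_times = rtimes,
        residence_time = q$residence_s, patch_index = q$patch,
        entry_clock = q$entry_clock_s, truncated = q$truncated,
        reward_latencies = if (is.null(rw) || !nrow(rw)) numeric(0)
          else rw$latency_s[order(rw$reward_time_s)])
    })
    gt <- if (!is.na(row$ground_truth))
      policy_from_list(jsonlite::fromJSON(row$ground_truth,
                                          simplifyVector = TRUE))
    vel <- NULL; licks <- NULL
    if (!is.null(tr)) {
      st <- tr[tr$animal == row$animal & tr$session == row$session, ]
      if (nrow(st)) {
        vrows <- st[st$kind == "velocity", ]
        if (nrow(vrows))
          vel <- list(v = vrows$value[order(vrows$t_s)], dt = row$trace_dt)
        lrows <- st[st$kind == "lick", ]
        if (nrow(lrows)) licks <- sort(lrows$t_s)
      }
    }
    structure(
      list(animal_id = row$animal, session_id = row$session, env = env,
           patches = patches,
           travel_intervals = if (nzchar(row$travel_intervals))
             as.numeric(strsplit(row$travel_intervals, ";")[[1]])
           else numeric(0),
           lick_times = licks, velocity = vel, ground_truth = gt,
           seed = as.integer(row$seed)),
      class = "session_log")
  })
}
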