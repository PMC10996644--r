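#' Apply dataset inclusion and exclusion filters
#'
#' Reproduces the staged quality filters applied before analysis, in
#' order. Freely-moving preset: (1) sessions need at least 20 patches;
#' (2) residence-time outliers more than 3 SD from the mean of a
#' log10-normal fit (pooled over the remaining data) are dropped;
#' (3) patches with any reward latency above 500 ms are dropped, and
#' (4) sessions in which more than 10\% of patches (at the latency stage)
#' had such latencies are dropped entirely; (5) sessions left with fewer
#' than 10 patches are dropped. Head-fixed preset: sessions need at least
#' 12 patches; residence outliers more than 2 SD \emph{below} the
#' log-normal mean are dropped; patches with lick engagement below 60\%
#' are dropped (requires lick traces; see
#' \code{\link{engagement_filter}}); animals for which more than half of
#' their sessions failed the session-level criteria are dropped entirely.
#'
#' Boundary conventions: exclusion thresholds are strict inequalities
#' (a residence exactly at mean + 3 SD is retained; a latency of exactly
#' 500 ms is retained; a session at exactly 10\% latency patches is
#' retained). Filters are idempotent.
#'
#' @param sessions List of \code{\link{session_log}}s.
#' @param preset \code{"freely_moving"} or \code{"head_fixed"}.
#' @param latency_ms,latency_session_frac,min_patches,min_surviving,
#'   outlier_sd,engagement_min,animal_fail_frac Threshold overrides;
#'   defaults follow the preset.
#' @param outlier_fit Optional \code{c(mu, sigma)} in log10 units for a
#'   fixed global log-normal outlier fit; default refits on the data.
#' @return A list with \code{sessions} (filtered, patch lists pruned) and
#'   \code{report}, a \code{filter_report} data.frame itemizing
#'   per-criterion exclusions (patch, session and animal level).
#' @export
apply_inclusion_filters <- function(sessions,
                                    preset = c("freely_moving",
                                               "head_fixed"),
                                    latency_ms = 500,
                                    latency_session_frac = 0.10,
                                    min_patches = NULL,
                                    min_surviving = 10,
                                    outlier_sd = NULL,
                                    outlier_fit = NULL,
                                    engagement_min = 0.60,
                                    animal_fail_frac = 0.50) {
  preset <- match.arg(preset)
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  min_patches <- min_patches %||%
    if (preset == "freely_moving") 20L else 12L
  outlier_sd <- outlier_sd %||% if (preset == "freely_moving") 3 else 2
  report <- list()
  note <- function(level, criterion, excluded, remaining)
    data.frame(level = level, criterion = criterion,
               excluded = as.integer(excluded),
               remaining = as.integer(remaining),
               stringsAsFactors = FALSE)
  n_sessions0 <- length(sessions)
  failed_animals <- character(0)  # animal of each failed session

  # 1. minimum patches per session
  keep <- vapply(sessions, function(s) length(s$patches) >= min_patches,
                 logical(1))
  failed_animals <- c(failed_animals,
                      vapply(sessions[!keep], `[[`, character(1),
                             "animal_id"))
  report$min_patches <- note("session",
                             sprintf("fewer than %d patches", min_patches),
                             sum(!keep), sum(keep))
  sessions <- sessions[keep]

  # 2. residence-time outliers on a pooled log10-normal refit
  all_res <- unlist(lapply(sessions, function(s)
    vapply(s$patches, `[[`, numeric(1), "residence_time")))
  n_out <- 0
  if (length(all_res) >= 3) {
    # default: per-dataset refit of the log10-normal; pass
    # outlier_fit = c(mu, sigma) (log10 units) to use a fixed global fit
    lr <- log10(all_res)
    if (is.null(outlier_fit)) {
      mu <- mean(lr); sdv <- stats::sd(lr)
    } else {
      mu <- outlier_fit[1]; sdv <- outlier_fit[2]
    }
    lo <- if (preset == "freely_moving") mu - outlier_sd * sdv
          else mu - outlier_sd * sdv
    hi <- if (preset == "freely_moving") mu + outlier_sd * sdv else Inf
    sessions <- lapply(sessions, function(s) {
      ok <- vapply(s$patches, function(p) {
        x <- log10(p$residence_time)
        x >= lo & x <= hi   # strictly-beyond convention: boundary retained
      }, logical(1))
      n_out <<- n_out + sum(!ok)
      s$patches <- s$patches[ok]
      s
    })
  }
  report$outliers <- note("patch",
                          sprintf("log-normal residence outlier (%g SD)",
                                  outlier_sd),
                          n_out, sum(vapply(sessions, function(s)
                            length(s$patches), integer(1))))

  if (preset == "freely_moving") {
    # 3. reward-latency patch filter + session-level 10% rule
    n_lat <- 0; lat_frac <- numeric(length(sessions))
    sessions <- lapply(seq_along(sessions), function(i) {
      s <- sessions[[i]]
      bad <- vapply(s$patches, function(p)
        length(p$reward_latencies) > 0 &&
          any(p$reward_latencies > latency_ms / 1000), logical(1))
      lat_frac[i] <<- if (length(bad)) mean(bad) else 0
      n_lat <<- n_lat + sum(bad)
      s$patches <- s$patches[!bad]
      s
    })
    report$latency <- note("patch",
                           sprintf("reward latency > %g ms", latency_ms),
                           n_lat, sum(vapply(sessions, function(s)
                             length(s$patches), integer(1))))
    keep <- lat_frac <= latency_session_frac
    failed_animals <- c(failed_animals,
                        vapply(sessions[!keep], `[[`, character(1),
                               "animal_id"))
    report$latency_session <- note(
      "session", sprintf("more than %g%% latency patches",
                         100 * latency_session_frac),
      sum(!keep), sum(keep))
    sessions <- sessions[keep]

    # 4. minimum surviving patches
    keep <- vapply(sessions, function(s)
      length(s$patches) >= min_surviving, logical(1))
    failed_animals <- c(failed_animals,
                        vapply(sessions[!keep], `[[`, character(1),
                               "animal_id"))
    report$min_surviving <- note(
      "session", sprintf("fewer than %d surviving patches", min_surviving),
      sum(!keep), sum(keep))
    sessions <- sessions[keep]
  } else {
    # head-fixed: engagement filter per patch, then the animal-level rule
    n_eng <- 0
    sessions <- lapply(sessions, function(s) {
      if (is.null(s$lick_times)) return(s)
      ok <- vapply(s$patches, function(p) {
        es <- engagement_filter(
          s$lick_times[s$lick_times >= p$entry_clock &
                       s$lick_times <= p$entry_clock + p$residence_time] -
            p$entry_clock,
          p$residence_time)
        es$engagement_fraction >= engagement_min
      }, logical(1))
      n_eng <<- n_eng + sum(!ok)
      s$patches <- s$patches[ok]
      s
    })
    report$engagement <- note(
      "patch", sprintf("lick engagement below %g%%", 100 * engagement_min),
      n_eng, sum(vapply(sessions, function(s) length(s$patches),
                        integer(1))))
    keep <- vapply(sessions, function(s)
      length(s$patches) >= min_surviving, logical(1))
    failed_animals <- c(failed_animals,
                        vapply(sessions[!keep], `[[`, character(1),
                               "animal_id"))
    report$min_surviving <- note(
      "session", sprintf("fewer than %d surviving patches", min_surviving),
      sum(!keep), sum(keep))
    sessions <- sessions[keep]

    # animal-level rule: drop animals whose failed-session fraction > 50%
    all_animals <- unique(c(vapply(sessions, `[[`, character(1),
                                   "animal_id"), failed_animals))
    n_fail <- table(factor(failed_animals, levels = all_animals))
    n_keep <- table(factor(vapply(sessions, `[[`, character(1),
                                  "animal_id"), levels = all_animals))
    frac_fail <- as.numeric(n_fail) / pmax(as.numeric(n_fail) +
                                             as.numeric(n_keep), 1L)
    bad_animals <- all_animals[frac_fail > animal_fail_frac]
    keep <- !vapply(sessions, function(s) s$animal_id %in% bad_animals,
                    logical(1))
    report$animal <- note(
      "animal", sprintf("more than %g%% failing sessions",
                        100 * animal_fail_frac),
      length(bad_animals), length(all_animals) - length(bad_animals))
    sessions <- sessions[keep]
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  class(report) <- c("filter_report", class(report))
  attr(report, "n_sessions_in") <- n_sessions0
  attr(report, "n_sessions_out") <- length(sessions)
  list(sessions = sessions, report = report)
}

#' Task-relevant travel time
#'
#' Freely-moving: the total inter-patch interval includes task-irrelevant
#' behavior, so the task-relevant travel cost for an (animal, track) group
#' is estimated as the 10th percentile of its total travel times (linear
#' interpolation between order statistics, \code{stats::quantile} type 7).
#' Head-fixed: each travel interval's task-relevant duration is the summed
#' sample time with treadmill velocity at or above the patch-entry
#' threshold (0.5 cm/s), aggregated per group as the geometric mean.
#'
#' @param travel Data frame with columns \code{animal}, \code{track} and
#'   either \code{travel} (total travel times, freely-moving) or
#'   \code{relevant} (per-interval supra-threshold durations, head-fixed).
#' @param preset \code{"freely_moving"} (percentile) or \code{"head_fixed"}
#'   (geometric mean).
#' @param prob Percentile for the freely-moving estimator (default 0.1).
#' @return Data frame with one row per (animal, track) group and column
#'   \code{travel_hat} (s).
#' @export
task_relevant_travel_time <- function(travel,
                                      preset = c("freely_moving",
                                                 "head_fixed"),
                                      prob = 0.1) {
  preset <- match.arg(preset)
  col <- if (preset == "freely_moving") "travel" else "relevant"
  stopifnot(all(c("animal", "track", col) %in% names(travel)),
            nrow(travel) >= 1)
  groups <- unique(travel[c("animal", "track")])
  groups$travel_hat <- vapply(seq_len(nrow(groups)), function(i) {
    x <- travel[travel$animal == groups$animal[i] &
                travel$track == groups$track[i], col]
    if (preset == "freely_moving") {
      unname(stats::quantile(x, prob, type = 7))
    } else {
      if (all(x <= 0)) { warning("all-zero task-relevant travel"); 0 }
      else exp(mean(log(x[x > 0])))
    }
  }, numeric(1))
  rownames(groups) <- NULL
  groups
}

#' Supra-threshold duration of a velocity interval
#'
#' Summed sample time with velocity at or above \code{threshold}; the
#' head-fixed per-interval input to
#' \code{\link{task_relevant_travel_time}}.
#'
#' @param v Velocity samples (cm/s).
#' @param dt Sample period (s).
#' @param threshold Patch-entry threshold (cm/s), default 0.5.
#' @return Duration (s).
#' @export
supra_threshold_time <- function(v, dt, threshold = 0.5) {
  sum(v >= threshold) * dt
}

#' Lick-based engagement of a patch
#'
#' Lick rate is computed in 500 ms bins, smoothed with a Gaussian kernel
#' (sigma = 2 s, truncated at 4 sigma and renormalized within the patch
#' window so short patches are not biased toward zero), and time bins with
#' smoothed rate below 0.5 Hz are deemed task-irrelevant.
#'
#' @param lick_times Lick times within the patch (s from patch entry).
#' @param residence Patch residence time (s).
#' @param bin Bin width (s), default 0.5.
#' @param sigma Gaussian smoothing SD (s), default 2.
#' @param rate_threshold Engagement threshold (Hz), default 0.5.
#' @return A list (class \code{engagement_summary}) with
#'   \code{task_relevant_residence} (s), \code{engagement_fraction},
#'   and the smoothed \code{rate} trace with bin \code{edges}.
#' @export
engagement_filter <- function(lick_times, residence, bin = 0.5,
                              sigma = 2, rate_threshold = 0.5) {
  stopifnot(residence > 0)
  if (length(lick_times) &&
      (min(lick_times) < -1e-9 || max(lick_times) > residence + 1e-9))
    stop("lick times must lie within the patch window")
  edges <- seq(0, residence, by = bin)
  if (utils::tail(edges, 1) < residence) edges <- c(edges, residence)
  if (length(edges) < 2) edges <- c(0, residence)  # sub-bin patch fallback
  widths <- diff(edges)
  counts <- if (length(lick_times))
    tabulate(findInterval(pmin(lick_times, residence - 1e-12), edges),
             nbins = length(widths))
  else numeric(length(widths))
  rate <- counts / widths
  centers <- edges[-1] - widths / 2
  half <- ceiling(4 * sigma / bin)
  sm <- vapply(seq_along(rate), function(i) {
    j <- max(1, i - half):min(length(rate), i + half)
    w <- stats::dnorm(centers[j], centers[i], sigma)
    sum(w * rate[j]) / sum(w)
  }, numeric(1))
  relevant <- sum(widths[sm >= rate_threshold])
  structure(list(task_relevant_residence = relevant,
                 engagement_fraction = relevant / residence,
                 rate = sm, edges = edges),
            class = "engagement_summary")
}

#' Remove the time-on-task trend from residence times
#'
#' Fits, per animal, a least-squares line of residence time against the
#' patch number within session and subtracts the slope component (centered
#' on the mean patch number), leaving a trend-free series with the animal
#' mean preserved. Also returns each patch's deviation from its (adjusted)
#' session mean, the quantity used by the rate-error regression.
#'
#' @param patches Per-patch data frame (\code{\link{session_patches}});
#'   needs columns \code{animal}, \code{session}, \code{patch},
#'   \code{residence}.
#' @return The input with columns \code{residence_adj} and
#'   \code{delta_resid} (deviation of the adjusted residence from its
#'   session mean) appended.
#' @export
detrend_time_on_task <- function(patches) {
  stopifnot(all(c("animal", "session", "patch", "residence") %in%
                  names(patches)))
  patches$residence_adj <- patches$residence
  for (a in unique(patches$animal)) {
    i <- patches$animal == a
    if (sum(i) < 3) next
    x <- patches$patch[i]
    if (length(unique(x)) < 2) {
      warning("degenerate patch numbers for animal ", a, "; not detrended")
      next
    }
    fit <- stats::lm.fit(cbind(1, x), patches$residence[i])
    slope <- fit$coefficients[2]
    patches$residence_adj[i] <- patches$residence[i] -
      slope * (x - mean(x))
  }
  sess_mean <- stats::ave(patches$residence_adj,
                          paste(patches$animal, patches$session),
                          FUN = mean)
  patches$delta_resid <- patches$residence_adj - sess_mean
  patches
}

#' Recover residence times from head-fixed kinematic traces
#'
#' Replays the task's patch-entry/exit logic on a velocity trace: a patch
#' ends at the first sample at or above the 5 cm/s running threshold and
#' the next patch begins at the first subsequent sample below the
#' 0.5 cm/s entry threshold.
#'
#' @param session A head-fixed \code{session_log} with a velocity trace.
#' @param exit_threshold,entry_threshold Velocity thresholds (cm/s).
#' @return Data frame with columns \code{entry}, \code{exit},
#'   \code{residence} (session-clock seconds), one row per detected patch.
#' @export
residence_from_traces <- function(session, exit_threshold = 5,
                                  entry_threshold = 0.5) {
  stopifnot(!is.null(session$velocity))
  v <- session$velocity$v
  dt <- session$velocity$dt
  t <- (seq_along(v) - 1) * dt
  entries <- numeric(0); exits <- numeric(0)
  in_patch <- TRUE; entry_t <- 0
  for (i in seq_along(v)) {
    if (in_patch && v[i] >= exit_threshold) {
      entries <- c(entries, entry_t); exits <- c(exits, t[i])
      in_patch <- FALSE
    } else if (!in_patch && v[i] < entry_threshold) {
      entry_t <- t[i]; in_patch <- TRUE
    }
  }
  if (in_patch) {  # final patch runs to the end of the trace
    entries <- c(entries, entry_t)
    exits <- c(exits, utils::tail(t, 1))
  }
  data.frame(entry = entries, exit = exits, residence = exits - entries)
}

#' Design matrix for an external linear-mixed-model fit
#'
#' Mixed-model fitting is delegated to a dedicated package (e.g. lme4);
#' this hook assembles the response and fixed-effect inputs (decay rate,
#' track, travel-time and time-on-task covariates), each normalized to
#' [0, 1], plus the animal grouping factor.
#'
#' @param patches Per-patch data frame (\code{\link{session_patches}}).
#' @return Data frame with response \code{residence} and normalized
#'   covariates \code{tau, track, travel_time, patch_number,
#'   patch_start}, plus \code{animal}.
#' @export
lmm_design_matrix <- function(patches) {
  norm01 <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) rep(0, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  data.frame(
    residence = patches$residence,
    tau = norm01(patches$tau),
    track = norm01(as.numeric(factor(patches$track))),
    travel_time = norm01(patches$travel_time),
    patch_number = norm01(patches$patch),
    patch_start = norm01(patches$entry_clock),
    animal = factor(patches$animal))
}
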