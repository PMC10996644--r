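#' Fit the heuristic leaving parameters for one animal
#'
#' Three session-level statistics: the mean residence time (constant-time
#' heuristic, HEU-CT, the null model), the mean delay between the last
#' observed reward and patch-leaving (elapsed-time heuristic, HEU-ETR;
#' a rewardless patch contributes its full residence time), and the mean
#' reward count at leaving (number-of-rewards heuristic, HEU-NR,
#' real-valued).
#'
#' @param patches Per-patch data frame for one animal
#'   (\code{\link{session_patches}} rows); needs \code{residence},
#'   \code{n_rewards}, \code{last_reward}.
#' @return A list (class \code{heuristic_params}) with fields
#'   \code{mean_residence}, \code{delta_bar}, \code{m_bar} and \code{n}.
#' @examples
#' df <- data.frame(residence = c(12, 10), n_rewards = c(0L, 2L),
#'                  last_reward = c(NA, 8))
#' fit_heuristics(df)$delta_bar  # (12 + 2) / 2 = 7
#' @export
fit_heuristics <- function(patches) {
  stopifnot(nrow(patches) >= 1)
  dt <- ifelse(patches$n_rewards > 0,
               patches$residence - patches$last_reward,
               patches$residence)
  structure(list(mean_residence = mean(patches$residence),
                 delta_bar = mean(dt),
                 m_bar = mean(patches$n_rewards),
                 n = nrow(patches)),
            class = "heuristic_params")
}

# Concatenated ladder of observed + expected future reward times for one
# patch, extended on demand. Returns list(times, flagged) where `flagged`
# marks that later rewards are unreachable and the ladder is exhausted.
reward_ladder <- function(env, rewards, residence, n_needed,
                          cap = 50L) {
  ladder <- rewards
  flagged <- FALSE
  while (length(ladder) < min(n_needed, cap)) {
    miss <- min(n_needed, cap) - length(ladder)
    fut <- expected_future_reward_times(env, rewards, residence,
                                        n_future = miss)
    # future times are anchored at the observed leaving time, so any
    # already-known extension entries are identical across calls
    if (anyNA(fut)) flagged <- TRUE
    ladder <- c(ladder, fut[!is.na(fut)])
    break
  }
  list(times = ladder, flagged = flagged || n_needed > cap)
}

#' Elapsed-time heuristic prediction (HEU-ETR)
#'
#' Scans the concatenation of observed reward times and expected future
#' reward times for the earliest inter-reward gap at least
#' \code{delta_bar} long (ties fire; the entry-to-first-reward gap is
#' included in the scan) and predicts leaving \code{delta_bar} seconds
#' after the reward opening that gap. The degenerate \code{delta_bar = 0}
#' criterion fires at the first reward itself. If even the expected-time
#' extension (capped at \code{cap} rewards, unreachable rewards dropped)
#' never opens a qualifying gap, the prediction falls back to the last
#' ladder time plus \code{delta_bar} and is flagged.
#'
#' @param env A \code{\link{forage_env}}.
#' @param rewards Observed reward times of the patch (s from entry).
#' @param residence Observed residence time (s); anchors the
#'   expected-future-time extension.
#' @param delta_bar Leaving criterion (s), from
#'   \code{\link{fit_heuristics}}.
#' @param cap Maximum ladder length (observed + expected rewards).
#' @return Predicted residence time (s) with attribute \code{"flagged"}.
#' @examples
#' env <- forage_env(tau = 6, rsi = 1)
#' heu_etr_predict(env, c(1, 2, 9), residence = 9.5, delta_bar = 5)  # 7
#' @export
heu_etr_predict <- function(env, rewards, residence, delta_bar,
                            cap = 50L) {
  stopifnot(delta_bar >= 0)
  lad <- reward_ladder(env, rewards, residence,
                       n_needed = length(rewards) + 8L, cap = cap)
  repeat {
    tt <- c(0, lad$times)
    if (delta_bar == 0) {
      yhat <- if (length(lad$times)) lad$times[1] else 0
      return(structure(yhat, flagged = !length(lad$times)))
    }
    gaps <- diff(tt)
    hit <- which(gaps >= delta_bar)
    if (length(hit))
      return(structure(tt[hit[1]] + delta_bar, flagged = FALSE))
    if (lad$flagged || length(lad$times) >= cap)
      return(structure(utils::tail(tt, 1) + delta_bar, flagged = TRUE))
    lad <- reward_ladder(env, rewards, residence,
                         n_needed = length(lad$times) + 8L, cap = cap)
  }
}

#' Number-of-rewards heuristic prediction (HEU-NR)
#'
#' Predicts leaving at the time the \code{m_bar}-th reward of the
#' observed-plus-expected ladder is received; a non-integer \code{m_bar}
#' interpolates linearly in time between the flooring and ceiling rewards
#' (set \code{interpolate = FALSE} to round to the nearest reward
#' instead). Unreachable expected rewards truncate the ladder; the
#' prediction then uses its last time and is flagged.
#'
#' @inheritParams heu_etr_predict
#' @param m_bar Mean reward count at leaving (real-valued, >= 0).
#' @param interpolate Linear interpolation for fractional \code{m_bar}.
#' @return Predicted residence time (s) with attribute \code{"flagged"}.
#' @examples
#' env <- forage_env(tau = 6, rsi = 1)
#' heu_nr_predict(env, c(3, 5, 8), residence = 8.5, m_bar = 2.5)  # 6.5
#' @export
heu_nr_predict <- function(env, rewards, residence, m_bar,
                           interpolate = TRUE, cap = 50L) {
  stopifnot(m_bar >= 0)
  if (!interpolate) m_bar <- round(m_bar)
  need <- ceiling(m_bar)
  lad <- reward_ladder(env, rewards, residence, n_needed = need, cap = cap)
  tt <- c(0, lad$times)  # position 1 is patch entry (reward 0)
  if (length(tt) - 1 < need) {
    return(structure(utils::tail(tt, 1), flagged = TRUE))
  }
  lo <- floor(m_bar); hi <- ceiling(m_bar)
  yhat <- if (lo == hi) tt[m_bar + 1]
          else tt[lo + 1] + (m_bar - lo) * (tt[hi + 1] - tt[lo + 1])
  structure(yhat, flagged = FALSE)
}

#' MVT-optimal residence time
#'
#' The residence time at which the instantaneous reward rate of an
#' exponentially depleting patch equals the session-average rate, i.e. the
#' positive root of \eqn{e^{-t/\tau} (t^{(t)} + t + \tau) - \tau = 0}.
#' Independent of the initial rate; solved with bracketed Brent iteration
#' (\code{uniroot}) on \eqn{[0, 50\tau]} to residual below 1e-9.
#'
#' @param tau Decay time constant (s), positive.
#' @param travel Travel cost (s), nonnegative.
#' @return Optimal residence time (s); 0 when \code{travel} is 0.
#' @examples
#' mvt_opt_residence(6, 10)  # about 8.4 s
#' @export
mvt_opt_residence <- function(tau, travel) {
  stopifnot(tau > 0, travel >= 0)
  if (travel == 0) return(0)
  f <- function(t) exp(-t / tau) * (travel + t + tau) - tau
  stats::uniroot(f, c(0, 50 * tau), tol = 1e-12)$root
}

# Fast internal MVT root: damped Newton (the criterion is strictly
# decreasing in t for travel > 0), uniroot fallback. Agrees with
# mvt_opt_residence to solver tolerance.
mvt_root_newton <- function(tau, travel, init = NULL) {
  if (travel <= 0) return(0)
  t <- if (!is.null(init) && is.finite(init) && init > 0) init
       else tau * log((travel + tau) / tau)
  for (i in 1:60) {
    e <- exp(-t / tau)
    Fv <- e * (travel + t + tau) - tau
    Ft <- e * (1 - (travel + t + tau) / tau)
    tn <- t - Fv / Ft
    if (!is.finite(tn) || tn < 0) return(mvt_opt_residence(tau, travel))
    if (abs(tn - t) < 1e-12 * (1 + tn)) return(tn)
    t <- tn
  }
  mvt_opt_residence(tau, travel)
}

#' Fit the internal-model MVT parameters (MVT-IM)
#'
#' Per animal, finds perceived decay constants (one per unique
#' experimental \eqn{\tau}) and perceived travel times (one per unique
#' track) minimizing \eqn{\|\hat y - y\|^2 + \lambda \|\hat\theta -
#' \theta\|^2}, where each prediction \eqn{\hat y} is the MVT-optimal
#' residence under the perceived parameters of its patch's environment.
#' Quasi-Newton (BFGS) minimization initialized at the experimental
#' parameters; if the optimizer fails to improve on the initialization the
#' initialization is returned with a diagnostic.
#'
#' @param patches Per-patch data frame; needs \code{animal}, \code{tau},
#'   \code{track}, \code{travel_time}, \code{residence}.
#' @param lambda_reg Regularization weight (squared-seconds units);
#'   default 1.
#' @return Object of class \code{mvt_im_fit}: \code{params} (one row per
#'   fitted parameter: \code{animal, kind, level, ref, hat}),
#'   \code{predictions} (per input patch), \code{loss} per animal, and
#'   \code{lambda_reg}.
#' @export
fit_mvt_im <- function(patches, lambda_reg = 1) {
  stopifnot(all(c("animal", "tau", "track", "travel_time", "residence")
                %in% names(patches)))
  params <- list(); losses <- list()
  preds <- rep(NA_real_, nrow(patches))
  for (a in unique(patches$animal)) {
    idx <- which(patches$animal == a)
    sub <- patches[idx, ]
    taus <- sort(unique(sub$tau))
    tracks <- unique(sub$track)
    travel0 <- vapply(tracks, function(tr)
      sub$travel_time[match(tr, sub$track)], numeric(1))
    theta0 <- c(taus, travel0)
    ntau <- length(taus)
    itau <- match(sub$tau, taus)
    itrk <- match(sub$track, tracks)
    cell <- interaction(itau, itrk, drop = TRUE)
    cell_tau <- itau[!duplicated(cell)]
    cell_trk <- itrk[!duplicated(cell)]
    cell_of <- match(cell, cell[!duplicated(cell)])
    y <- sub$residence
    n_cell <- tabulate(cell_of, nbins = length(cell_tau))
    ysum_cell <- as.numeric(rowsum(y, cell_of)[, 1])
    roots_memo <- rep(NA_real_, length(cell_tau))
    cell_roots <- function(par) {
      roots_memo <<- vapply(seq_along(cell_tau), function(j)
        mvt_root_newton(par[cell_tau[j]], par[ntau + cell_trk[j]],
                        init = roots_memo[j]), numeric(1))
      roots_memo
    }
    loss_fn <- function(par) {
      yc <- cell_roots(par)
      sum((yc[cell_of] - y)^2) + lambda_reg * sum((par - theta0)^2)
    }
    # gradient via implicit differentiation of the root condition
    # F(t*, tau, travel) = e^{-t/tau}(travel + t + tau) - tau = 0
    grad_fn <- function(par) {
      yc <- cell_roots(par)
      g <- 2 * lambda_reg * (par - theta0)
      for (j in seq_along(cell_tau)) {
        tt <- yc[j]; tau_j <- par[cell_tau[j]]
        trv <- par[ntau + cell_trk[j]]
        e <- exp(-tt / tau_j)
        Ft <- e * (1 - (trv + tt + tau_j) / tau_j)
        Ftau <- e * (tt / tau_j^2) * (trv + tt + tau_j) + e - 1
        Ftrv <- e
        resid2 <- 2 * (n_cell[j] * yc[j] - ysum_cell[j])
        g[cell_tau[j]] <- g[cell_tau[j]] + resid2 * (-Ftau / Ft)
        g[ntau + cell_trk[j]] <- g[ntau + cell_trk[j]] +
          resid2 * (-Ftrv / Ft)
      }
      g
    }
    opt <- stats::optim(theta0, loss_fn, gr = grad_fn,
                        method = "L-BFGS-B",
                        lower = rep(1e-3, length(theta0)),
                        control = list(maxit = 500, factr = 1e4))
    roots_memo <- rep(NA_real_, length(cell_tau))
    l0 <- loss_fn(theta0)
    if (!is.finite(opt$value) || opt$value > l0) {
      warning("MVT-IM fit for animal ", a,
              " did not improve on the experimental parameters")
      opt$par <- theta0; opt$value <- l0
    }
    par <- opt$par
    yc <- vapply(seq_along(cell_tau), function(j)
      mvt_opt_residence(par[cell_tau[j]], par[ntau + cell_trk[j]]),
      numeric(1))
    preds[idx] <- yc[cell_of]
    params[[a]] <- data.frame(
      animal = a,
      kind = c(rep("tau", ntau), rep("travel", length(tracks))),
      level = c(as.character(taus), as.character(tracks)),
      ref = theta0, hat = par, stringsAsFactors = FALSE)
    losses[[a]] <- data.frame(animal = a, loss = opt$value,
                              loss_init = l0,
                              converged = opt$convergence == 0,
                              stringsAsFactors = FALSE)
  }
  structure(list(params = do.call(rbind, params),
                 predictions = preds,
                 loss = do.call(rbind, losses),
                 lambda_reg = lambda_reg),
            class = "mvt_im_fit")
}

# Look up an animal's fitted (tau_hat, travel_hat) for given patches;
# unseen levels fall back to the experimental values.
mvt_im_lookup <- function(fit, patches) {
  p <- fit$params
  get <- function(a, kind, level, fallback) {
    i <- which(p$animal == a & p$kind == kind & p$level == level)
    if (length(i)) p$hat[i[1]] else fallback
  }
  tau_hat <- mapply(get, patches$animal, "tau",
                    as.character(patches$tau), patches$tau)
  travel_hat <- mapply(get, patches$animal, "travel",
                       as.character(patches$track), patches$travel_time)
  data.frame(tau_hat = tau_hat, travel_hat = travel_hat)
}

#' Predict residence times from a fitted MVT-IM model
#'
#' @param fit An \code{mvt_im_fit}.
#' @param patches Per-patch data frame (may differ from the training
#'   data); unseen (animal, level) combinations fall back to the
#'   experimental parameters.
#' @return Numeric vector of predicted residence times (s).
#' @export
mvt_im_predict <- function(fit, patches) {
  lk <- mvt_im_lookup(fit, patches)
  key <- paste(lk$tau_hat, lk$travel_hat)
  uk <- !duplicated(key)
  roots <- vapply(which(uk), function(i)
    mvt_opt_residence(lk$tau_hat[i], lk$travel_hat[i]), numeric(1))
  roots[match(key, key[uk])]
}

#' Leaving-rate thresholds implied by an MVT-IM fit
#'
#' For each (animal, environment) cell, the event-rate threshold
#' \eqn{\lambda^* = \lambda_0 e^{-\hat t^{(p)}/\hat\tau}} at which the
#' perceived-parameter MVT model leaves; input to the threshold-crossing
#' predictive models.
#'
#' @param fit An \code{mvt_im_fit}.
#' @param patches Per-patch data frame with \code{animal, tau, track,
#'   travel_time, lam0}.
#' @return Data frame with one row per (animal, tau, track):
#'   \code{tau_hat, travel_hat, t_hat, lambda_star}.
#' @export
mvt_im_thresholds <- function(fit, patches) {
  cells <- unique(patches[c("animal", "tau", "track", "travel_time",
                            "lam0")])
  lk <- mvt_im_lookup(fit, cells)
  cells$tau_hat <- lk$tau_hat
  cells$travel_hat <- lk$travel_hat
  cells$t_hat <- vapply(seq_len(nrow(cells)), function(i)
    mvt_opt_residence(cells$tau_hat[i], cells$travel_hat[i]), numeric(1))
  cells$lambda_star <- cells$lam0 * exp(-cells$t_hat / cells$tau_hat)
  rownames(cells) <- NULL
  cells
}
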