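#' Threshold-crossing predictive model
#'
#' Wraps the per-(animal, environment) leaving thresholds together with
#' the prior shape and history depth used by the online MAP rate
#' estimator. Model variants differ only in construction: MLE-x uses a
#' very weak prior (relative variance 1e4, so the prior only breaks the
#' zero-reward degeneracy); MAP-IM-L uses informative priors with
#' thresholds taken from the MVT-IM fit; MAP-IM-GL additionally refits
#' the thresholds to behavior (\code{\link{fit_thresholds}}).
#'
#' @param thresholds Data frame from \code{\link{mvt_im_thresholds}} (or
#'   equivalent) with columns \code{animal, tau, track, lam0, tau_hat,
#'   lambda_star}; prior modes default to the environment's \code{lam0}
#'   and the fitted \code{tau_hat}.
#' @param var_lam,var_tau Prior variances (relative to mode^2 when
#'   \code{relative}).
#' @param relative Relative-variance interpretation (default TRUE).
#' @param history History depth N: patches (current + preceding) feeding
#'   the estimate; N = 1 uses the current patch only.
#' @param eval_dt Evaluation bin (s), default 0.1.
#' @param source Provenance label (\code{"from_mvt_im"} or
#'   \code{"fitted"}).
#' @return Object of class \code{threshold_model}.
#' @export
threshold_model <- function(thresholds, var_lam = 0.3, var_tau = 0.3,
                            relative = TRUE, history = 1L, eval_dt = 0.1,
                            source = "from_mvt_im") {
  need <- c("animal", "tau", "track", "lam0", "tau_hat", "lambda_star")
  stopifnot(all(need %in% names(thresholds)),
            all(thresholds$lambda_star > 0), history >= 1)
  if (is.null(thresholds$mode_lam)) thresholds$mode_lam <- thresholds$lam0
  if (is.null(thresholds$mode_tau)) thresholds$mode_tau <- thresholds$tau_hat
  structure(list(thresholds = thresholds, var_lam = var_lam,
                 var_tau = var_tau, relative = relative,
                 history = as.integer(history), eval_dt = eval_dt,
                 source = source),
            class = "threshold_model")
}

# Row index of the model's cell for each patch row; error if missing.
cell_index <- function(model, patches) {
  th <- model$thresholds
  key <- paste(patches$animal, patches$tau, patches$track)
  i <- match(key, paste(th$animal, th$tau, th$track))
  if (anyNA(i))
    stop("no threshold defined for cell(s): ",
         paste(unique(key[is.na(i)]), collapse = ", "))
  i
}

prior_for_cell <- function(model, row) {
  prior_spec(mode_lam = row$mode_lam, var_lam = model$var_lam,
             mode_tau = row$mode_tau, var_tau = model$var_tau,
             relative = model$relative)
}

# History stacks (rewards + durations of up to N-1 preceding patches in
# the same session) for every row of a patches data frame.
build_histories <- function(patches, history) {
  n <- nrow(patches)
  out <- vector("list", n)
  empty <- list(times = numeric(0), offsets = 0L, durations = numeric(0))
  if (history <= 1L) return(rep(list(empty), n))
  grp <- paste(patches$animal, patches$session)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(patches$patch[idx])]
    for (j in seq_along(idx)) {
      take <- idx[seq_len(j - 1L)]
      take <- utils::tail(take, history - 1L)
      if (!length(take)) { out[[idx[j]]] <- empty; next }
      tl <- patches$rewards[take]
      out[[idx[j]]] <- list(
        times = unlist(tl, use.names = FALSE) %||% numeric(0),
        offsets = as.integer(c(0, cumsum(lengths(tl)))),
        durations = patches$residence[take])
    }
  }
  out
}

default_t_max <- function(patches) {
  grp <- paste(patches$tau, patches$track)
  mx <- tapply(patches$residence, grp, max)
  pmin(pmax(2.5 * as.numeric(mx[grp]), 30), 240)
}

#' Predict patch-leaving times with a threshold-crossing model
#'
#' For each patch, the MAP (or weak-prior MLE) estimate of the event rate
#' is evaluated on a grid of \code{eval_dt} bins -- using the rewards
#' observed up to each bin in the current patch plus the full sequences
#' of up to N-1 preceding patches -- and the predicted residence is the
#' first bin at which the estimate is at or below the cell's threshold
#' \eqn{\lambda^*} (ties fire). If no crossing occurs within \code{t_max}
#' the prediction is \code{t_max} and the patch is flagged.
#'
#' @param model A \code{\link{threshold_model}}.
#' @param patches Per-patch data frame (\code{\link{session_patches}});
#'   rows must carry \code{rewards}, \code{residence}, \code{L} and the
#'   cell keys \code{animal, tau, track}.
#' @param t_max Evaluation horizon (s); default three times the cell's
#'   maximum observed residence (at least 30 s).
#' @return Data frame with \code{yhat} (s) and logical \code{flagged}.
#' @export
predict_leaving <- function(model, patches, t_max = NULL) {
  ci <- cell_index(model, patches)
  if (is.null(t_max)) t_max <- default_t_max(patches)
  t_max <- rep_len(t_max, nrow(patches))
  hists <- build_histories(patches, model$history)
  yhat <- numeric(nrow(patches))
  flagged <- logical(nrow(patches))
  for (i in seq_len(nrow(patches))) {
    row <- model$thresholds[ci[i], ]
    pr <- prior_for_cell(model, row)
    h <- hists[[i]]
    t <- cpp_predict_crossing(patches$rewards[[i]], h$times, h$offsets,
                              h$durations, patches$L[i],
                              pr$alpha_lam, pr$beta_lam, pr$alpha_tau,
                              pr$beta_tau, row$lambda_star,
                              model$eval_dt, t_max[i])
    if (t < 0) { yhat[i] <- t_max[i]; flagged[i] <- TRUE }
    else yhat[i] <- t
  }
  data.frame(yhat = yhat, flagged = flagged)
}

#' Online rate-estimate trace for one patch
#'
#' The per-bin MAP rate estimate underlying
#' \code{\link{predict_leaving}}, exposed for diagnostics and threshold
#' refitting: entry \code{i} is the estimate at \code{i * eval_dt}
#' seconds using rewards observed up to that bin.
#'
#' @param rewards Observed reward times of the patch (s from entry).
#' @param L Events per reward.
#' @param prior A \code{\link{prior_spec}}.
#' @param history Optional list with \code{times}, \code{offsets},
#'   \code{durations} describing preceding patches (as built by the
#'   prediction driver); omit for current-patch-only estimation.
#' @param eval_dt Bin width (s).
#' @param t_max Trace horizon (s).
#' @return Numeric vector of rate estimates (events/s).
#' @export
rate_trace <- function(rewards, L, prior, history = NULL, eval_dt = 0.1,
                       t_max = 30) {
  if (is.null(history))
    history <- list(times = numeric(0), offsets = 0L,
                    durations = numeric(0))
  cpp_rate_trace(rewards, history$times, history$offsets,
                 history$durations, L, prior$alpha_lam, prior$beta_lam,
                 prior$alpha_tau, prior$beta_tau, eval_dt, t_max)
}

#' Refit leaving thresholds to behavior (MAP-IM-GL)
#'
#' Keeps the model's priors fixed, precomputes each training patch's rate
#' trace once, and searches per animal for the simplex of per-environment
#' leaving thresholds minimizing the RMSE between threshold-crossing
#' predictions and observed residence times (Nelder-Mead on
#' log-thresholds, initialized at the model's current thresholds). If the
#' search fails to improve the training RMSE the initial thresholds are
#' kept, so the refitted model never does worse on its training data.
#'
#' @param model A \code{\link{threshold_model}} (initial thresholds).
#' @param patches Training patches.
#' @param t_max Evaluation horizon (s); as in
#'   \code{\link{predict_leaving}}.
#' @return A new \code{threshold_model} (\code{source = "fitted"}) with
#'   attribute \code{"rmse"} (per-animal training RMSE before/after).
#' @export
fit_thresholds <- function(model, patches, t_max = NULL) {
  ci <- cell_index(model, patches)
  if (is.null(t_max)) {
    # fitting horizon: traces only need to cover plausible predictions
    grp <- paste(patches$tau, patches$track)
    mx <- tapply(patches$residence, grp, max)
    t_max <- pmin(pmax(1.5 * as.numeric(mx[grp]), 20), 120)
  }
  t_max <- rep_len(t_max, nrow(patches))
  hists <- build_histories(patches, model$history)
  traces <- vector("list", nrow(patches))
  for (i in seq_len(nrow(patches))) {
    row <- model$thresholds[ci[i], ]
    pr <- prior_for_cell(model, row)
    traces[[i]] <- cpp_rate_trace(
      patches$rewards[[i]], hists[[i]]$times, hists[[i]]$offsets,
      hists[[i]]$durations, patches$L[i], pr$alpha_lam, pr$beta_lam,
      pr$alpha_tau, pr$beta_tau, model$eval_dt, t_max[i])
  }
  th <- model$thresholds
  diag <- list()
  for (a in unique(patches$animal)) {
    rows <- which(th$animal == a)
    pidx <- which(patches$animal == a)
    cell_of <- match(ci[pidx], rows)
    y <- patches$residence[pidx]
    a_traces <- traces[pidx]
    a_tmax <- t_max[pidx]
    obj <- function(logthr) {
      thr <- exp(logthr)
      preds <- cpp_first_crossing_many(a_traces, thr[cell_of],
                                       model$eval_dt, a_tmax)
      sqrt(mean((preds - y)^2))
    }
    init <- log(th$lambda_star[rows])
    rmse0 <- obj(init)
    opt <- if (length(init) == 1L) {
      o <- stats::optimize(function(x) obj(x), init + c(-3, 3),
                           tol = 1e-6)
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(init, obj, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-5))
    }
    if (is.finite(opt$value) && opt$value < rmse0 - 1e-12) {
      th$lambda_star[rows] <- exp(opt$par)
      rmse1 <- opt$value
    } else {
      rmse1 <- rmse0
    }
    diag[[a]] <- data.frame(animal = a, rmse_init = rmse0,
                            rmse_fit = rmse1, stringsAsFactors = FALSE)
  }
  out <- threshold_model(th, var_lam = model$var_lam,
                         var_tau = model$var_tau,
                         relative = model$relative,
                         history = model$history,
                         eval_dt = model$eval_dt, source = "fitted")
  attr(out, "rmse") <- do.call(rbind, diag)
  out
}

#' Grid search over prior variances and history depths
#'
#' Evaluates the threshold-crossing model's prediction RMSE over a
#' discrete grid of prior variances (for \eqn{\lambda_0} and \eqn{\tau},
#' anchored by mode at the MVT-IM parameters) and history depths, and
#' returns the full surface plus the best configuration.
#'
#' @param patches Per-patch data frame.
#' @param thresholds Threshold table (\code{\link{mvt_im_thresholds}}).
#' @param var_lam_grid,var_tau_grid,history_grid Grid values.
#' @param relative Relative-variance interpretation.
#' @param eval_dt,t_max As in \code{\link{predict_leaving}}.
#' @return List with \code{surface} (data frame: \code{var_lam, var_tau,
#'   history, rmse}) and \code{best} (the minimizing
#'   \code{threshold_model}). The surface minimum is deterministic given
#'   the inputs (no randomness), so its location is invariant to session
#'   ordering.
#' @export
grid_search_priors <- function(patches, thresholds,
                               var_lam_grid = c(0.1, 0.3, 1, 3.2),
                               var_tau_grid = c(0.1, 0.3, 1, 3.2),
                               history_grid = 1L, relative = TRUE,
                               eval_dt = 0.1, t_max = NULL) {
  if (!length(var_lam_grid) || !length(var_tau_grid) ||
      !length(history_grid)) stop("empty prior grid")
  grid <- expand.grid(var_lam = var_lam_grid, var_tau = var_tau_grid,
                      history = as.integer(history_grid))
  grid$rmse <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    m <- threshold_model(thresholds, var_lam = grid$var_lam[i],
                         var_tau = grid$var_tau[i], relative = relative,
                         history = grid$history[i], eval_dt = eval_dt)
    pr <- predict_leaving(m, patches, t_max = t_max)
    grid$rmse[i] <- sqrt(mean((pr$yhat - patches$residence)^2))
    if (is.null(best) || grid$rmse[i] < best$rmse)
      best <- list(model = m, rmse = grid$rmse[i])
  }
  list(surface = grid, best = best$model, best_rmse = best$rmse)
}
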