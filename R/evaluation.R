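#' Hierarchical cluster bootstrap
#'
#' Resamples the environment -> animal -> session -> patch tree: within
#' each environment group, \eqn{N_i} nodes are drawn with replacement at
#' each level, where \eqn{N_i} is the minimum node count at that level
#' within the group (number of animals; minimum sessions per animal;
#' minimum patches per session), yielding balanced samples of size
#' \eqn{N_1 N_2 N_3} per group. Groups are pooled and the Pearson
#' correlation between the covariate and the value column is computed per
#' replicate, giving a bootstrap distribution of r with percentile
#' confidence intervals and the fraction of replicates above zero.
#'
#' @param data Data frame with columns \code{environment}, \code{animal},
#'   \code{session}, the covariate and the value.
#' @param covariate Name of the (numeric) covariate column, e.g. the
#'   decay constant.
#' @param value Name of the response column (default
#'   \code{"residence"}).
#' @param M Number of bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param alpha Two-sided confidence level complement (default 0.05).
#' @param method \code{"pearson"} (default, correlating against the
#'   numeric parameter value) or \code{"spearman"}.
#' @return Object of class \code{bootstrap_result}: \code{samples},
#'   \code{mean}, \code{ci} (percentile), \code{p_greater}, \code{M},
#'   \code{seed}, and the per-group sample size.
#' @export
cluster_bootstrap <- function(data, covariate, value = "residence",
                              M = 10000, seed = 1, alpha = 0.05,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(c("environment", "animal", "session", covariate, value)
                %in% names(data)))
  if (length(unique(data[[covariate]])) < 2)
    stop("covariate '", covariate, "' has a single level; ",
         "correlation undefined")
  x_all <- as.numeric(data[[covariate]])
  y_all <- as.numeric(data[[value]])
  if (method == "spearman") { x_all <- rank(x_all); y_all <- rank(y_all) }

  # index structure: per environment group, animals -> sessions -> rows
  groups <- lapply(split(seq_len(nrow(data)), data$environment),
                   function(rows) {
    by_an <- split(rows, data$animal[rows], drop = TRUE)
    lapply(by_an, function(ar) split(ar, data$session[ar], drop = TRUE))
  })
  n_an <- vapply(groups, length, integer(1))
  n_se <- vapply(groups, function(g)
    min(vapply(g, length, integer(1))), integer(1))
  n_pa <- vapply(groups, function(g)
    min(vapply(g, function(a)
      min(vapply(a, length, integer(1))), integer(1))), integer(1))

  set.seed(seed)
  samples <- numeric(M)
  for (r in seq_len(M)) {
    xs <- NULL; ys <- NULL
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      ai <- sample.int(n_an[gi], n_an[gi], replace = TRUE)
      rows <- unlist(lapply(ai, function(a) {
        sess <- g[[a]]
        si <- sample.int(length(sess), n_se[gi], replace = TRUE)
        unlist(lapply(si, function(s) {
          p <- sess[[s]]
          p[sample.int(length(p), n_pa[gi], replace = TRUE)]
        }), use.names = FALSE)
      }), use.names = FALSE)
      xs <- c(xs, x_all[rows]); ys <- c(ys, y_all[rows])
    }
    samples[r] <- stats::cor(xs, ys)
  }
  ci <- unname(stats::quantile(samples, c(alpha / 2, 1 - alpha / 2),
                               na.rm = TRUE))
  structure(list(samples = samples, mean = mean(samples, na.rm = TRUE),
                 ci = ci, p_greater = mean(samples > 0, na.rm = TRUE),
                 M = M, seed = seed,
                 sample_size = sum(n_an * n_se * n_pa)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> M=%d: r = %.3f [%.3f, %.3f], p(r>0) = %.4f\n",
    x$M, x$mean, x$ci[1], x$ci[2], x$p_greater))
  invisible(x)
}

#' Cross-validation folds of contiguous within-session patch groups
#'
#' Splits each session's patches (in order) into \code{k} contiguous
#' groups of near-equal size (sizes differ by at most one); group g of
#' every session pools into fold g, so every fold represents every
#' session. Sessions with fewer than \code{k} patches are assigned
#' round-robin with a warning.
#'
#' @param patches Per-patch data frame with \code{animal}, \code{session},
#'   \code{patch}.
#' @param k Number of folds (>= 2), default 5.
#' @return Integer fold label per row of \code{patches}.
#' @export
cv_split <- function(patches, k = 5L) {
  stopifnot(k >= 2)
  fold <- integer(nrow(patches))
  grp <- paste(patches$animal, patches$session)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(patches$patch[idx])]
    n <- length(idx)
    if (n < k) {
      warning("session ", g, " has fewer than ", k,
              " patches; assigning round-robin")
      fold[idx] <- rep_len(seq_len(k), n)
    } else {
      cuts <- round(seq(0, n, length.out = k + 1))
      fold[idx] <- rep(seq_len(k), diff(cuts))
    }
  }
  fold
}

# Per-patch rate-estimation error at leaving, current patch only:
# (estimated - true) event rate evaluated at the residence time. A very
# weak prior (relative variance weak_var) breaks the zero-reward
# degeneracy, mirroring the predictive models' MLE-x handling.
patch_rate_errors <- function(patches, weak_var = 1e4,
                              residence = patches$residence) {
  vapply(seq_len(nrow(patches)), function(i) {
    tres <- residence[i]
    rw <- patches$rewards[[i]]
    rw <- rw[rw <= tres + 1e-9]
    pr <- prior_spec(patches$lam0[i], weak_var, patches$tau[i], weak_var,
                     relative = TRUE)
    fit <- map_fit(list(rw), tres, pr, patches$L[i])
    lam_true <- patches$lam0[i] * exp(-tres / patches$tau[i])
    est_rate(fit, tres) - lam_true
  }, numeric(1))
}

#' Regression of residence-time deviation on rate-estimation error
#'
#' For each patch, the rate-estimation error is the difference between
#' the estimated and true event rate at patch-leaving (estimated from the
#' current patch's rewards only; positive = overestimation). Residence
#' deviations are taken from the detrended session mean
#' (\code{\link{detrend_time_on_task}}). Per cross-validation fold, a
#' bivariate Gaussian is fit to the training points, points outside the
#' 99th-percentile Mahalanobis ellipse (chi-squared, 2 df) are excluded,
#' a least-squares line of deviation on error is fit to the survivors,
#' and Pearson r / out-of-fold R-squared are evaluated on the test fold
#' (filtered by the same ellipse). A shuffle control rebuilds both
#' variables after permuting residence times across patches within each
#' session and reruns the identical pipeline.
#'
#' @param patches Per-patch data frame (\code{\link{session_patches}});
#'   rewards list column plus \code{tau}, \code{lam0}, \code{L} required.
#' @param k Folds (default 5).
#' @param seed Seed for the fold-invariant shuffle control.
#' @param shuffle Run the shuffle control (default TRUE).
#' @param ellipse_level Mahalanobis exclusion percentile (default 0.99).
#' @param min_fold_points Folds with fewer surviving test points are
#'   skipped with a warning (default 10).
#' @return Object of class \code{rate_error_regression}: \code{folds}
#'   (per-fold \code{r}, \code{r2}, \code{slope}, n), \code{shuffled}
#'   (same for the control), and the per-patch \code{errors} /
#'   \code{deltas} used.
#' @export
rate_error_regression <- function(patches, k = 5L, seed = 1,
                                  shuffle = TRUE, ellipse_level = 0.99,
                                  min_fold_points = 10L) {
  patches <- detrend_time_on_task(patches)
  err <- patch_rate_errors(patches)
  if (stats::sd(err) < 1e-12) {
    warning("rate-estimation errors are degenerate (zero variance)")
    return(structure(list(folds = NULL, shuffled = NULL, errors = err,
                          deltas = patches$delta_resid,
                          degenerate = TRUE),
                     class = "rate_error_regression"))
  }
  fold <- cv_split(patches, k)
  run <- function(x, y) {
    out <- data.frame(fold = seq_len(k), r = NA_real_, r2 = NA_real_,
                      slope = NA_real_, n_train = NA_integer_,
                      n_test = NA_integer_)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- fold == f
      mu <- c(mean(x[tr]), mean(y[tr]))
      S <- stats::cov(cbind(x[tr], y[tr]))
      thr <- stats::qchisq(ellipse_level, df = 2)
      md <- function(i) {
        d <- rbind(x[i] - mu[1], y[i] - mu[2])
        colSums(d * solve(S, d))
      }
      keep_tr <- which(tr)[md(tr) <= thr]
      keep_te <- which(te)[md(te) <= thr]
      if (length(keep_te) < min_fold_points ||
          length(keep_tr) < min_fold_points) {
        warning("fold ", f, " skipped: fewer than ", min_fold_points,
                " surviving points")
        next
      }
      b <- stats::coef(stats::lm(y[keep_tr] ~ x[keep_tr]))
      pred <- b[1] + b[2] * x[keep_te]
      out$r[f] <- stats::cor(x[keep_te], y[keep_te])
      out$r2[f] <- 1 - sum((y[keep_te] - pred)^2) /
        sum((y[keep_te] - mean(y[keep_te]))^2)
      out$slope[f] <- b[2]
      out$n_train[f] <- length(keep_tr)
      out$n_test[f] <- length(keep_te)
    }
    out
  }
  folds <- run(err, patches$delta_resid)
  shuffled <- NULL
  if (shuffle) {
    set.seed(seed)
    sh_res <- patches$residence
    grp <- paste(patches$animal, patches$session)
    for (g in unique(grp)) {
      i <- which(grp == g)
      sh_res[i] <- patches$residence[i][sample.int(length(i))]
    }
    shp <- patches
    shp$residence <- sh_res
    shp <- detrend_time_on_task(shp[setdiff(names(shp),
                                            c("residence_adj",
                                              "delta_resid"))])
    sh_err <- patch_rate_errors(shp, residence = sh_res)
    shuffled <- run(sh_err, shp$delta_resid)
  }
  structure(list(folds = folds, shuffled = shuffled, errors = err,
                 deltas = patches$delta_resid, degenerate = FALSE),
            class = "rate_error_regression")
}

#' Cross-validated model comparison table
#'
#' Computes mean absolute error, root-mean-square error and R-squared for
#' each model's pooled test-fold predictions, with percentile bootstrap
#' confidence intervals obtained by resampling the per-patch prediction
#' errors. R-squared is computed against the per-animal mean residence
#' (the constant-per-animal null model HEU-CT therefore has R-squared 0
#' by construction on its training data).
#'
#' @param predictions Data frame with columns \code{model}, \code{animal},
#'   \code{fold}, \code{y} (observed), \code{yhat} (predicted).
#' @param M_ci Bootstrap replicates for the CIs (default 10000).
#' @param alpha Two-sided CI complement (default 0.05).
#' @param seed Integer seed.
#' @return Object of class \code{comparison_table}: data frame with one
#'   row per model (\code{mae, mae_lo, mae_hi, rmse, rmse_lo, rmse_hi,
#'   r2, n}).
#' @export
model_compare <- function(predictions, M_ci = 10000, alpha = 0.05,
                          seed = 1) {
  stopifnot(all(c("model", "animal", "fold", "y", "yhat") %in%
                  names(predictions)))
  set.seed(seed)
  ybar <- stats::ave(predictions$y, predictions$animal, FUN = mean)
  rows <- lapply(split(seq_len(nrow(predictions)), predictions$model),
                 function(i) {
    e <- predictions$yhat[i] - predictions$y[i]
    n <- length(e)
    boot_mae <- numeric(M_ci); boot_rmse <- numeric(M_ci)
    for (b in seq_len(M_ci)) {
      eb <- e[sample.int(n, n, replace = TRUE)]
      boot_mae[b] <- mean(abs(eb))
      boot_rmse[b] <- sqrt(mean(eb^2))
    }
    q <- function(v) unname(stats::quantile(v, c(alpha / 2,
                                                 1 - alpha / 2)))
    ci_mae <- q(boot_mae); ci_rmse <- q(boot_rmse)
    data.frame(
      model = predictions$model[i[1]],
      mae = mean(abs(e)), mae_lo = ci_mae[1], mae_hi = ci_mae[2],
      rmse = sqrt(mean(e^2)), rmse_lo = ci_rmse[1], rmse_hi = ci_rmse[2],
      r2 = 1 - sum(e^2) / sum((predictions$y[i] - ybar[i])^2),
      n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", class(out))
  out
}

#' Run the full cross-validated model comparison on session logs
#'
#' Orchestrates the full comparison pipeline: per-patch extraction, contiguous
#' within-session fold assignment, per-fold fitting of the requested
#' models on the training folds (per animal), prediction of the held-out
#' fold, and the pooled \code{\link{model_compare}} table.
#'
#' Available models: \code{"heu-ct"} (per-animal mean residence, the
#' null), \code{"heu-nr"}, \code{"heu-etr"}, \code{"mvt-opt"} (true
#' parameters), \code{"mvt-im"} (fitted internal model),
#' \code{"mle-x"} (weak-prior threshold crossing), \code{"map-im-l"}
#' (informative priors, MVT-IM thresholds), \code{"map-im-gl"}
#' (additionally refits thresholds on the training folds).
#'
#' @param sessions List of \code{session_log}s.
#' @param models Character vector of model names (see Details).
#' @param k Folds (default 5).
#' @param lambda_reg MVT-IM regularization weight.
#' @param var_lam,var_tau Relative prior variances for the MAP models.
#' @param history History depth N for the threshold models.
#' @param eval_dt Evaluation bin (s).
#' @param M_ci,alpha,seed Passed to \code{\link{model_compare}}.
#' @return List with \code{table} (the \code{comparison_table}),
#'   \code{predictions} (per patch, model and fold) and \code{folds}.
#' @export
run_model_comparison <- function(sessions,
                                 models = c("heu-ct", "heu-nr", "heu-etr",
                                            "mvt-opt", "mvt-im"),
                                 k = 5L, lambda_reg = 1,
                                 var_lam = 0.3, var_tau = 0.3,
                                 history = 1L, eval_dt = 0.1,
                                 M_ci = 2000, alpha = 0.05, seed = 1) {
  patches <- session_patches(sessions)
  fold <- cv_split(patches, k)
  envs <- lapply(sessions, `[[`, "env")
  names(envs) <- vapply(sessions, function(s)
    paste(s$env$tau, s$env$track_label), character(1))
  env_of <- function(i) envs[[paste(patches$tau[i], patches$track[i])]]
  preds <- list()
  needs_mvt_im <- any(models %in% c("mvt-im", "mle-x", "map-im-l",
                                    "map-im-gl"))
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    train <- patches[tr, ]
    test <- patches[te, ]
    heu <- lapply(split(train, train$animal), fit_heuristics)
    mvt_fit <- if (needs_mvt_im) fit_mvt_im(train, lambda_reg)
    thr_tab <- if (needs_mvt_im) mvt_im_thresholds(mvt_fit, train)
    for (mod in models) {
      yhat <- switch(mod,
        "heu-ct" = vapply(test$animal, function(a)
          heu[[a]]$mean_residence, numeric(1)),
        "heu-nr" = vapply(seq_len(nrow(test)), function(j) {
          i <- te[j]
          as.numeric(heu_nr_predict(env_of(i), test$rewards[[j]],
                                    test$residence[j],
                                    heu[[test$animal[j]]]$m_bar))
        }, numeric(1)),
        "heu-etr" = vapply(seq_len(nrow(test)), function(j) {
          i <- te[j]
          as.numeric(heu_etr_predict(env_of(i), test$rewards[[j]],
                                     test$residence[j],
                                     heu[[test$animal[j]]]$delta_bar))
        }, numeric(1)),
        "mvt-opt" = {
          key <- paste(test$tau, test$travel_time)
          uk <- !duplicated(key)
          r <- vapply(which(uk), function(j)
            mvt_opt_residence(test$tau[j], test$travel_time[j]),
            numeric(1))
          r[match(key, key[uk])]
        },
        "mvt-im" = mvt_im_predict(mvt_fit, test),
        "mle-x" = predict_leaving(
          threshold_model(thr_tab, var_lam = 1e4, var_tau = 1e4,
                          history = history, eval_dt = eval_dt),
          test)$yhat,
        "map-im-l" = predict_leaving(
          threshold_model(thr_tab, var_lam = var_lam, var_tau = var_tau,
                          history = history, eval_dt = eval_dt),
          test)$yhat,
        "map-im-gl" = {
          m0 <- threshold_model(thr_tab, var_lam = var_lam,
                                var_tau = var_tau, history = history,
                                eval_dt = eval_dt)
          m1 <- fit_thresholds(m0, train)
          predict_leaving(m1, test)$yhat
        },
        stop("unknown model: ", mod))
      preds[[length(preds) + 1]] <- data.frame(
        model = mod, animal = test$animal, fold = f,
        y = test$residence, yhat = as.numeric(yhat),
        stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, preds)
  list(table = model_compare(predictions, M_ci = M_ci, alpha = alpha,
                             seed = seed),
       predictions = predictions, folds = fold)
}
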