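#' Qini curve and coefficient for an uplift ranking
#'
#' Subjects are sorted by score descending (ties grouped as one block). At
#' each prefix the incremental gain is g = sum(y_t) - sum(y_c) * (n_t / n_c)
#' over the prefix (g = sum(y_t) when the prefix holds no controls). The
#' curve plots g / n against the prefix fraction; the random baseline is the
#' straight line from 0 to the full-population gain; the Qini coefficient is
#' the trapezoidal area between curve and baseline. A constant score (one
#' tie block) gives exactly 0.
#'
#' @param y Binary outcomes.
#' @param t Binary treatment indicators.
#' @param scores Real-valued uplift scores (higher = ranked earlier).
#' @return A \code{qini_result}: \code{fraction}, \code{gain} (curve values,
#'   both starting at 0), \code{baseline}, \code{coefficient}.
#' @export
qini_curve <- function(y, t, scores) {
  n <- length(y)
  if (length(t) != n || length(scores) != n)
    stop_validation("y, t, scores must share length")
  if (!any(t == 1) || !any(t == 0))
    stop_validation("qini_curve requires both arms")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; t <- t[ord]; s <- scores[ord]
  # block boundaries: last index of each tie group
  ends <- which(c(s[-n] != s[-1L], TRUE))
  cum_yt <- cumsum(y * (t == 1))[ends]
  cum_yc <- cumsum(y * (t == 0))[ends]
  cum_nt <- cumsum(t == 1)[ends]
  cum_nc <- cumsum(t == 0)[ends]
  g <- ifelse(cum_nc == 0, cum_yt, cum_yt - cum_yc * (cum_nt / cum_nc))
  frac <- c(0, ends / n)
  gain <- c(0, g / n)
  total <- gain[length(gain)]
  baseline <- frac * total
  trapz <- function(xv, yv) sum(diff(xv) * (utils::head(yv, -1) + utils::tail(yv, -1)) / 2)
  coefficient <- trapz(frac, gain) - trapz(frac, baseline)
  structure(list(fraction = frac, gain = gain, baseline = baseline,
                 coefficient = coefficient),
            class = "qini_result")
}

#' @export
print.qini_result <- function(x, ...) {
  cat(sprintf("<qini_result> coefficient = %.4f (%d curve points)\n",
              x$coefficient, length(x$fraction)))
  invisible(x)
}

#' Qini coefficient of forest predictions on a dataset
#'
#' @param forest An \code{uplift_forest} (or any object for which
#'   \code{predict_fun} yields scores).
#' @param ds Evaluation \code{trial_dataset} (held-out real subjects).
#' @param predict_fun Function (model, ds) -> scores.
#' @return The Qini coefficient.
#' @export
qini_score <- function(forest, ds,
                       predict_fun = function(m, d) predict_tau(m, d)) {
  qini_curve(ds$outcome, ds$treatment, predict_fun(forest, ds))$coefficient
}

#' Cross-validated hyperparameter selection
#'
#' Stratified-by-arm k-fold split; each grid point is fit on k-1 folds and
#' scored on the held-out fold (validation Qini of the forest's estimates by
#' default); the parameters with the best mean score win, ties going to the
#' first grid point. A fold that ends up with a single arm triggers a
#' re-split with a new derived seed (at most 10 attempts).
#'
#' @param ds Training \code{trial_dataset}.
#' @param param_grid Non-empty list of parameter lists.
#' @param k Number of folds (>= 2).
#' @param fit_fun Function (train_ds, params) -> model. Default grows an
#'   uplift forest with \code{params} merged over \code{\link{forest_params}}.
#' @param score_fun Function (model, valid_ds) -> numeric (higher = better).
#' @param seed Seed for the fold assignment.
#' @return List with \code{best} (winning params), \code{best_index},
#'   \code{mean_scores}, and the per-fold \code{scores} matrix.
#' @export
cross_validate <- function(ds, param_grid, k = 4,
                           fit_fun = function(d, p) grow_forest(d, utils::modifyList(forest_params(), p)),
                           score_fun = function(m, d) qini_score(m, d),
                           seed = 1) {
  if (k < 2) stop_config("cross_validate needs k >= 2")
  if (length(param_grid) == 0L) stop_config("empty parameter grid")
  n <- n_subjects(ds)
  fold <- NULL
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    f <- integer(n)
    for (arm in c(0L, 1L)) {
      idx <- which(ds$treatment == arm)
      f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(fi)
      length(unique(ds$treatment[f == fi])) == 2L, TRUE))
    if (ok) { fold <- f; break }
  }
  if (is.null(fold))
    stop_validation("could not build %d folds with both arms in each", k)
  scores <- matrix(NA_real_, k, length(param_grid))
  for (fi in seq_len(k)) {
    train <- subset_dataset(ds, which(fold != fi))
    valid <- subset_dataset(ds, which(fold == fi))
    for (gi in seq_along(param_grid)) {
      model <- fit_fun(train, param_grid[[gi]])
      scores[fi, gi] <- score_fun(model, valid)
    }
  }
  means <- colMeans(scores)
  best <- which.max(means)              # which.max takes the first tie
  list(best = param_grid[[best]], best_index = best,
       mean_scores = means, scores = scores)
}

#' Repeat the full pipeline across seeds and summarize
#'
#' For each seed the configured pipeline runs end to end: simulate (or load)
#' the trial, hold out a test set of real subjects, optionally augment the
#' training portion, grow the forest, extract and select rules, fit the rule
#' model, and evaluate the held-out Qini of both the forest and the rule
#' model. The summary reports per-seed Qini values, mean and SD, and the
#' selected-rule counts under the three threshold kinds (nonzero
#' coefficient, |coefficient| > 0.005, importance > 0.002). A failing seed
#' is recorded and skipped.
#'
#' @param config A pipeline configuration as from
#'   \code{\link{pipeline_config}}.
#' @param n_seeds Number of repetitions (seeds are \code{seed + 0:(n-1)}).
#' @param seeds Optional explicit seed vector (overrides \code{n_seeds}).
#' @return An \code{experiment_summary}: per-seed data frame plus
#'   \code{mean}, \code{sd}, and \code{single_seed} flag.
#' @export
repeat_experiment <- function(config, n_seeds = 30, seeds = NULL) {
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_seeds) - 1L
  rows <- lapply(seeds, function(sd) {
    res <- tryCatch(run_single_experiment(config, seed = sd),
                    error = function(e)
                      list(failed = TRUE, message = conditionMessage(e)))
    if (isTRUE(res$failed)) {
      data.frame(seed = sd, qini_forest = NA_real_, qini_rules = NA_real_,
                 n_significant = NA_integer_, n_nonzero = NA_integer_,
                 n_coef_gt = NA_integer_, n_imp_gt = NA_integer_,
                 failed = TRUE)
    } else {
      data.frame(seed = sd, qini_forest = res$qini_forest,
                 qini_rules = res$qini_rules,
                 n_significant = res$n_significant,
                 n_nonzero = res$n_nonzero, n_coef_gt = res$n_coef_gt,
                 n_imp_gt = res$n_imp_gt, failed = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  ok <- df$qini_forest[!df$failed]
  structure(list(per_seed = df,
                 mean = mean(ok), sd = if (length(ok) > 1L) stats::sd(ok) else 0,
                 single_seed = length(ok) == 1L,
                 n_failed = sum(df$failed)),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary> %d seeds (%d failed): Qini %.4f +/- %.4f%s\n",
              nrow(x$per_seed), x$n_failed, x$mean, x$sd,
              if (x$single_seed) " [single seed: SD undefined, reported 0]" else ""))
  invisible(x)
}
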