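# Model matrix for propensity fitting: continuous/binary as-is, categorical
# as full one-hot minus first level. Standardization is left to glmnet.
propensity_design <- function(ds) {
  cols <- list()
  for (f in ds$schema$features) {
    if (f$role != "covariate") next
    v <- ds$x[[f$name]]
    if (f$kind == "categorical") {
      for (lv in f$levels[-1L])
        cols[[paste0(f$name, "=", lv)]] <- as.numeric(as.character(v) == lv)
    } else {
      cols[[f$name]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Fit an elastic-net propensity model
#'
#' Penalized logistic regression of the treatment indicator (or any supplied
#' binary label) on the covariates, with internal standardization; the
#' penalty strength is chosen by cross-validation with deterministic folds
#' derived from \code{seed}.
#'
#' @param ds A \code{trial_dataset} with both classes present.
#' @param label Optional binary label to model instead of the treatment
#'   indicator (e.g. real-vs-synthetic group membership).
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param seed Seed for the fold assignment.
#' @return A \code{propensity_model}: fitted \code{scores} in (0, 1) for all
#'   rows, \code{coef}, \code{auc} (in-sample), and the glmnet fit.
#' @export
fit_propensity <- function(ds, label = NULL, alpha = 0.5, seed = 1) {
  y <- if (is.null(label)) ds$treatment else as.integer(label)
  if (length(unique(y)) < 2L)
    stop_validation("propensity fitting requires both classes present")
  X <- propensity_design(ds)
  if (anyNA(X))
    stop_validation("covariates must be imputed before propensity fitting")
  set.seed(seed)
  foldid <- sample(rep(seq_len(5), length.out = length(y)))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                          foldid = foldid, nlambda = 50)
  scores <- drop(stats::predict(cv, newx = X, s = "lambda.min",
                                type = "response"))
  scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  auc <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  structure(list(scores = scores, auc = auc,
                 coef = as.matrix(stats::coef(cv, s = "lambda.min")),
                 fit = cv, alpha = alpha),
            class = "propensity_model")
}

#' Greedy 1:1 caliper nearest-neighbor matching on the propensity logit
#'
#' Side A is iterated in descending propensity order; each A unit is paired
#' without replacement to the nearest unused B unit on the logit scale, if
#' that distance is within the caliper (caliper_sd times the pooled SD of
#' the logit scores). A zero caliper degenerates to no matches.
#'
#' @param scores_a,scores_b Propensity scores in (0, 1) for the two sides.
#' @param caliper_sd Caliper width in pooled-logit-SD units (default 0.2).
#' @return A \code{match_result}: \code{pairs} (data frame of a/b indices
#'   and distances), \code{caliper}, and unmatched index vectors.
#' @export
nn_match <- function(scores_a, scores_b, caliper_sd = 0.2) {
  if (length(scores_a) == 0L || length(scores_b) == 0L)
    stop_validation("both sides of the matching must be non-empty")
  la <- stats::qlogis(pmin(pmax(scores_a, 1e-12), 1 - 1e-12))
  lb <- stats::qlogis(pmin(pmax(scores_b, 1e-12), 1 - 1e-12))
  pooled_sd <- stats::sd(c(la, lb))
  if (!is.finite(pooled_sd) || pooled_sd == 0)
    stop_validation("zero pooled SD of logit propensity scores; caliper undefined")
  caliper <- caliper_sd * pooled_sd
  order_a <- order(scores_a, decreasing = TRUE)
  used_b <- rep(FALSE, length(lb))
  pa <- integer(0); pb <- integer(0); pd <- numeric(0)
  if (caliper > 0) {
    for (i in order_a) {
      d <- abs(lb - la[i])
      d[used_b] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= caliper) {
        used_b[j] <- TRUE
        pa <- c(pa, i); pb <- c(pb, j); pd <- c(pd, d[j])
      }
    }
  }
  structure(list(pairs = data.frame(a = pa, b = pb, distance = pd),
                 caliper = caliper, caliper_sd = caliper_sd,
                 n_a = length(la), n_b = length(lb),
                 unmatched_a = setdiff(seq_along(la), pa),
                 unmatched_b = setdiff(seq_along(lb), pb)),
            class = "match_result")
}

# Matching wrapper used by the augmentation workflows: when the propensity
# model is degenerate (constant scores, e.g. an intercept-only elastic net
# because the groups are indistinguishable), every candidate is equally
# close, so pair greedily in index order at distance 0 instead of failing.
match_or_degenerate <- function(scores_a, scores_b, caliper_sd) {
  tryCatch(nn_match(scores_a, scores_b, caliper_sd = caliper_sd),
           uplift_validation_error = function(e) {
             if (!grepl("pooled SD", conditionMessage(e))) stop(e)
             message("matching: constant propensity scores; pairing in order")
             k <- min(length(scores_a), length(scores_b))
             structure(list(pairs = data.frame(a = seq_len(k), b = seq_len(k),
                                               distance = numeric(k)),
                            caliper = 0, caliper_sd = caliper_sd,
                            n_a = length(scores_a), n_b = length(scores_b),
                            unmatched_a = setdiff(seq_along(scores_a), seq_len(k)),
                            unmatched_b = setdiff(seq_along(scores_b), seq_len(k))),
                       class = "match_result")
           })
}

#' Standardized mean differences between arms
#'
#' Continuous: (m1 - m0) / sqrt((v1 + v0) / 2); binary and categorical-level
#' indicators use the same formula on the indicator means. The summary mean
#' is the unweighted average of absolute per-feature SMDs. Zero pooled
#' variance gives SMD 0 when the means agree and Inf otherwise.
#'
#' @param ds A \code{trial_dataset} with both arms present.
#' @return List with \code{smd} (named per-feature vector) and
#'   \code{mean_abs}.
#' @export
smd_report <- function(ds) {
  if (!any(ds$treatment == 1) || !any(ds$treatment == 0))
    stop_validation("smd_report requires both arms")
  X <- propensity_design(ds)
  t1 <- ds$treatment == 1
  smd <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    m1 <- mean(v[t1], na.rm = TRUE); m0 <- mean(v[!t1], na.rm = TRUE)
    v1 <- stats::var(v[t1]); v0 <- stats::var(v[!t1])
    pool <- sqrt((v1 + v0) / 2)
    if (!is.finite(pool) || pool == 0) {
      if (isTRUE(all.equal(m1, m0))) 0 else Inf
    } else {
      (m1 - m0) / pool
    }
  }, 0)
  names(smd) <- colnames(X)
  list(smd = smd, mean_abs = mean(abs(smd)))
}

#' In-sample AUC for discriminating the two arms
#'
#' Fits a fresh elastic-net propensity model and reports how well its scores
#' separate treated from control subjects, in-sample. Lower is better
#' balance: after successful matching the covariates should no longer
#' predict the arm.
#'
#' @param ds A \code{trial_dataset} with both arms.
#' @param ... Passed to \code{\link{fit_propensity}}.
#' @return AUC in [0, 1].
#' @export
arm_auc <- function(ds, ...) {
  fit_propensity(ds, ...)$auc
}

#' Augment an RCT with matched historical controls
#'
#' The observational pool is filtered by the trial's eligibility criteria; an
#' elastic-net propensity model is fit on the combined data; pool controls
#' are matched 1:1 (greedy, caliper) to the RCT's TREATED subjects; matched
#' pool rows are appended. Every real subject is kept regardless of matching
#' status. Balance diagnostics (mean SMD and arm AUC, before = naive pooling
#' and after = matched cohort) are attached as the \code{"balance"}
#' attribute.
#'
#' @param rct The randomized \code{trial_dataset}.
#' @param pool A control-only historical \code{trial_dataset}.
#' @param criteria Eligibility predicates applied to the pool (see
#'   \code{\link{apply_eligibility}}), or \code{NULL}.
#' @param caliper_sd Matching caliper in pooled-logit-SD units.
#' @param alpha Elastic-net mixing for the propensity model.
#' @param seed Seed for the propensity fit.
#' @return The augmented \code{trial_dataset} with attributes
#'   \code{"match"} (the \code{match_result}) and \code{"balance"}.
#' @export
borrow_historical <- function(rct, pool, criteria = NULL, caliper_sd = 0.2,
                              alpha = 0.5, seed = 1) {
  if (!is.null(pool) && any(pool$treatment == 1))
    stop_validation("the historical pool must be control-only")
  if (is.null(pool) || n_subjects(pool) == 0L) {
    warning("borrow_historical: empty pool; returning the trial unchanged")
    return(rct)
  }
  pool <- tryCatch(apply_eligibility(pool, criteria),
                   uplift_validation_error = function(e) NULL)
  if (is.null(pool)) {
    warning("borrow_historical: no pool subject meets the eligibility criteria")
    return(rct)
  }
  combined <- bind_datasets(rct, pool)
  ps <- fit_propensity(combined, alpha = alpha, seed = seed)
  treated_idx <- which(rct$treatment == 1)
  pool_offset <- n_subjects(rct)
  pool_idx <- pool_offset + seq_len(n_subjects(pool))
  mr <- match_or_degenerate(ps$scores[treated_idx], ps$scores[pool_idx],
                            caliper_sd = caliper_sd)
  matched_pool <- pool_idx[mr$pairs$b] - pool_offset
  out <- if (length(matched_pool)) {
    bind_datasets(rct, subset_dataset(pool, matched_pool))
  } else {
    rct
  }
  attr(out, "match") <- mr
  attr(out, "balance") <- list(
    before = balance_snapshot(combined, alpha = alpha, seed = seed),
    after = balance_snapshot(out, alpha = alpha, seed = seed))
  out
}

balance_snapshot <- function(ds, alpha = 0.5, seed = 1) {
  s <- smd_report(ds)
  list(n = n_subjects(ds), n_treated = sum(ds$treatment == 1),
       n_control = sum(ds$treatment == 0),
       mean_smd = s$mean_abs, smd = s$smd,
       arm_auc = arm_auc(ds, alpha = alpha, seed = seed))
}

#' Built-in smoothed-bootstrap synthetic-data generator
#'
#' A simple, fully deterministic-given-seed generator satisfying the
#' generator interface (\code{fit}/\code{sample}): rows are resampled within
#' (T, Y) cells of the real data, continuous features are jittered with
#' Gaussian kernel noise at Silverman's bandwidth (times
#' \code{bandwidth_factor}), and categorical features are resampled from the
#' within-cell frequencies. An empty (T, Y) cell falls back to the arm-level
#' cell. Deep generative models can be plugged in behind the same interface.
#'
#' @param bandwidth_factor Multiplier on Silverman's rule-of-thumb bandwidth
#'   (0 reproduces exact copies of real rows).
#' @param freeze_categorical Keep the resampled row's categorical values
#'   instead of redrawing from cell frequencies.
#' @return A generator: \code{fit(ds)} -> state, and
#'   \code{sample(state, n_treated, n_control, seed)} -> \code{trial_dataset}
#'   with \code{source = "synthetic"}.
#' @export
smoothed_bootstrap_generator <- function(bandwidth_factor = 1,
                                         freeze_categorical = FALSE) {
  list(
    fit = function(ds) {
      if (anyNA(ds$x))
        stop_validation("generator training data must be imputed")
      list(ds = ds)
    },
    sample = function(state, n_treated, n_control, seed = 1) {
      ds <- state$ds
      set.seed(seed)
      draw_cell <- function(tr, n_out) {
        rows_t <- which(ds$treatment == tr)
        if (length(rows_t) == 0L)
          stop_validation("generator: no real subjects with T = %d", tr)
        p1 <- mean(ds$outcome[rows_t] == 1)
        n1 <- round(n_out * p1)
        cells <- list()
        for (spec in list(list(y = 1L, n = n1), list(y = 0L, n = n_out - n1))) {
          if (spec$n <= 0) next
          cell <- rows_t[ds$outcome[rows_t] == spec$y]
          if (length(cell) == 0L) {
            message(sprintf("generator: empty (T=%d, Y=%d) cell; arm-level fallback",
                            tr, spec$y))
            cell <- rows_t
          }
          cells[[length(cells) + 1L]] <- list(
            rows = sample(cell, spec$n, replace = TRUE), y = spec$y)
        }
        cells
      }
      synth_x <- list(); synth_t <- integer(0); synth_y <- integer(0)
      for (spec in list(list(tr = 1L, n = n_treated), list(tr = 0L, n = n_control))) {
        if (spec$n <= 0) next
        cells <- draw_cell(spec$tr, spec$n)
        for (cell in cells) {
          rows <- cell$rows
          x_new <- ds$x[rows, , drop = FALSE]
          for (f in ds$schema$features) {
            if (f$role != "covariate") next
            if (f$kind == "categorical") {
              if (!freeze_categorical) {
                pool_v <- as.character(ds$x[[f$name]][ds$treatment == spec$tr &
                                                        ds$outcome == cell$y])
                if (length(pool_v) == 0L)
                  pool_v <- as.character(ds$x[[f$name]][ds$treatment == spec$tr])
                x_new[[f$name]] <- sample(pool_v, length(rows), replace = TRUE)
              }
            } else if (f$kind == "continuous") {
              v <- ds$x[[f$name]]
              bw <- bandwidth_factor * 1.06 * stats::sd(v) * length(v)^(-1/5)
              if (bw > 0)
                x_new[[f$name]] <- x_new[[f$name]] + stats::rnorm(length(rows), 0, bw)
            }
          }
          synth_x[[length(synth_x) + 1L]] <- x_new
          synth_t <- c(synth_t, rep(spec$tr, length(rows)))
          synth_y <- c(synth_y, rep(cell$y, length(rows)))
        }
      }
      x_all <- do.call(rbind, synth_x)
      trial_dataset(x_all, synth_t, synth_y, ds$schema, source = "synthetic")
    }
  )
}

#' Fit the baseline generator and draw a synthetic cohort
#'
#' @param real Imputed real \code{trial_dataset} (trial plus any borrowed
#'   controls).
#' @param n_treated,n_control Synthetic sample sizes per arm (default
#'   500 + 500).
#' @param seed Seed for the draw.
#' @param generator A generator interface (default the smoothed bootstrap).
#' @return A synthetic \code{trial_dataset}.
#' @export
generate_synthetic <- function(real, n_treated = 500, n_control = 500,
                               seed = 1,
                               generator = smoothed_bootstrap_generator()) {
  state <- generator$fit(real)
  generator$sample(state, n_treated, n_control, seed = seed)
}

#' Match synthetic subjects to a real cohort and append them
#'
#' Two independent 1:1 matchings: the real treated subjects against the
#' synthetic controls, and the real control side (including any matched
#' historical controls) against the synthetic treated subjects. A fresh
#' propensity model (real vs synthetic membership) is fit for each stage.
#' Matched synthetic rows are appended; every real row is kept.
#'
#' @param real_cohort Real (possibly historical-augmented)
#'   \code{trial_dataset}.
#' @param synthetic A synthetic \code{trial_dataset} with both arms (a
#'   missing arm skips that matching with a warning).
#' @param caliper_sd,alpha,seed As in \code{\link{borrow_historical}}.
#' @return The augmented dataset, with \code{"balance"} attribute (before =
#'   naive pooling of all synthetic rows, after = matched cohort).
#' @export
match_synthetic <- function(real_cohort, synthetic, caliper_sd = 0.2,
                            alpha = 0.5, seed = 1) {
  if (is.null(synthetic) || n_subjects(synthetic) == 0L) {
    warning("match_synthetic: empty synthetic data; returning cohort unchanged")
    return(real_cohort)
  }
  stage <- function(real_idx, synth_arm, seed_off) {
    synth_idx <- which(synthetic$treatment == synth_arm)
    if (length(synth_idx) == 0L || length(real_idx) == 0L) {
      warning(sprintf("match_synthetic: no %s-arm synthetic subjects; matching skipped",
                      if (synth_arm == 1) "treated" else "control"))
      return(integer(0))
    }
    both <- bind_datasets(subset_dataset(real_cohort, real_idx),
                          subset_dataset(synthetic, synth_idx))
    membership <- c(rep(1L, length(real_idx)), rep(0L, length(synth_idx)))
    ps <- fit_propensity(both, label = membership, alpha = alpha,
                         seed = seed + seed_off)
    mr <- match_or_degenerate(ps$scores[seq_along(real_idx)],
                              ps$scores[length(real_idx) + seq_along(synth_idx)],
                              caliper_sd = caliper_sd)
    synth_idx[mr$pairs$b]
  }
  m1 <- stage(which(real_cohort$treatment == 1), 0L, 0L)  # real treated vs synth control
  m2 <- stage(which(real_cohort$treatment == 0), 1L, 1L)  # real control side vs synth treated
  keep <- c(m1, m2)
  out <- if (length(keep)) {
    bind_datasets(real_cohort, subset_dataset(synthetic, keep))
  } else {
    real_cohort
  }
  naive <- bind_datasets(real_cohort, synthetic)
  attr(out, "balance") <- list(
    before = balance_snapshot(naive, alpha = alpha, seed = seed),
    after = balance_snapshot(out, alpha = alpha, seed = seed))
  out
}

#' Per-variable similarity between real and synthetic data
#'
#' Continuous variables: 1 minus the two-sample Kolmogorov-Smirnov statistic
#' (sup distance of the empirical CDFs). Categorical variables: 1 minus the
#' total variation distance, TVD = 0.5 * sum |p_level - q_level|. Variables
#' absent on either side are skipped with a warning.
#'
#' @param real,synth \code{trial_dataset}s (or covariate data frames) sharing
#'   the schema.
#' @param schema The \code{feature_schema} (taken from \code{real} when it is
#'   a \code{trial_dataset}).
#' @return Named numeric vector of similarities in [0, 1].
#' @export
similarity_report <- function(real, synth, schema = NULL) {
  if (inherits(real, "trial_dataset")) {
    schema <- schema %||% real$schema
    real <- real$x
  }
  if (inherits(synth, "trial_dataset")) synth <- synth$x
  if (is.null(schema)) stop_config("similarity_report needs a schema")
  out <- numeric(0)
  for (f in schema$features) {
    if (f$role != "covariate") next
    if (!f$name %in% names(real) || !f$name %in% names(synth)) {
      warning(sprintf("similarity_report: '%s' absent on one side; skipped", f$name))
      next
    }
    a <- real[[f$name]]; b <- synth[[f$name]]
    sim <- if (f$kind == "categorical") {
      lv <- f$levels
      p <- table(factor(as.character(a), levels = lv)) / length(a)
      q <- table(factor(as.character(b), levels = lv)) / length(b)
      1 - 0.5 * sum(abs(as.numeric(p) - as.numeric(q)))
    } else {
      ks <- suppressWarnings(stats::ks.test(a, b))
      1 - as.numeric(ks$statistic)
    }
    out[f$name] <- sim
  }
  out
}
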