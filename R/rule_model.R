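# Coordinate descent for the rule-selection objective
#   sum((y - c - X b)^2) + lambda * sum(|b|),  intercept c unpenalized.
# The intercept is profiled out by centering; columns are used as supplied
# (rule indicators stay 0/1, linear terms are standardized by the caller).
lasso_cd <- function(X, y, lambda, tol = 1e-8, max_sweeps = 2000,
                     beta_init = NULL, trace = FALSE,
                     stall = if (lambda == 0) 1e-14 else 1e-10) {
  if (lambda < 0) stop_domain("lambda must be non-negative")
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  ym <- mean(y)
  yc <- y - ym
  cn <- colSums(Xc^2)
  beta <- if (is.null(beta_init)) numeric(p) else beta_init
  if (p > 0) {
    sol <- .cd_solve(Xc, yc, cn, lambda, tol, as.integer(max_sweeps),
                     beta, trace, stall)
    beta <- sol$beta
  } else {
    sol <- list(objective = sum(yc^2),
                objective_path = if (trace) sum(yc^2))
  }
  intercept <- ym - sum(xm * beta)
  out <- list(beta = beta, intercept = intercept, lambda = lambda,
              objective = sol$objective)
  if (trace) out$objective_path <- sol$objective_path
  out
}

# Smallest lambda at which every penalized coefficient is zero, for the
# sum-of-squares objective: lambda_max = 2 * max |x_c' y_c|.
lambda_max_sse <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X))
  2 * max(abs(crossprod(Xc, y - mean(y))), 0)
}

# Pathwise descent: fit a decreasing lambda sequence with warm starts
# (coordinate descent converges in few sweeps per step, as in glmnet's
# pathwise strategy). Returns one fit per lambda, in input order.
lasso_path <- function(X, y, lambdas, tol = 1e-8, max_sweeps = 500) {
  ord <- order(lambdas, decreasing = TRUE)
  beta <- NULL
  fits <- vector("list", length(lambdas))
  for (i in ord) {
    fit <- lasso_cd(X, y, lambdas[i], tol = tol, max_sweeps = max_sweeps,
                    beta_init = beta)
    beta <- fit$beta
    fits[[i]] <- fit
  }
  fits
}

#' Fit the L1-regularized rule-selection model
#'
#' Regresses the forest's treatment-effect estimates tau_hat on the binary
#' rule indicators plus the raw baseline features, minimizing
#' \code{sum((tau - [R a + X b + c])^2) + lambda * sum(|a| + |b|)} with an
#' unpenalized intercept, by cyclic coordinate descent. Continuous linear
#' terms are z-scored internally and coefficients reported on the original
#' feature scale; categorical features enter as level indicators (first
#' level dropped). When \code{lambda} is \code{NULL} it is chosen by k-fold
#' cross-validation on the pseudo-label regression MSE over a log-spaced
#' grid.
#'
#' @param tau_hat Estimated treatment effects for the same subjects
#'   (typically out-of-bag forest estimates).
#' @param rules Rules from \code{\link{extract_rules}}.
#' @param ds Training \code{trial_dataset} (supplies the raw features).
#' @param lambda Non-negative penalty, or \code{NULL} for cross-validation.
#' @param cv_folds Folds for the lambda search.
#' @param n_lambda,lambda_min_ratio Grid size and lower endpoint (relative
#'   to the all-zero lambda).
#' @param seed Seed for the cross-validation fold split.
#' @return A \code{rule_linear_model}: rule coefficients \code{a}, feature
#'   coefficients \code{b}, \code{intercept}, \code{lambda}, importances
#'   (\code{importance_rules} = |a| sqrt(s(1-s)),
#'   \code{importance_features} = |b| SD(X)), supports, and the rules.
#' @export
fit_rule_model <- function(tau_hat, rules, ds, lambda = NULL, cv_folds = 4,
                           n_lambda = 8, lambda_min_ratio = 1e-3, seed = 1) {
  if (!is.null(lambda) && lambda < 0) stop_domain("lambda must be >= 0")
  R <- rule_matrix(rules, ds$x)
  n_rules <- ncol(R)
  # rules whose member sets coincide on the training data are exactly
  # collinear; fit only the first of each group (the others keep a = 0)
  rule_cols <- seq_len(n_rules)
  if (n_rules > 1L) {
    keys <- apply(R, 2, paste, collapse = "")
    rule_cols <- which(!duplicated(keys))
  }
  lin <- linear_terms(ds)
  X <- cbind(R[, rule_cols, drop = FALSE], lin$X)
  if (is.null(lambda)) {
    lambda <- cv_lambda(X, tau_hat, k = cv_folds, n_lambda = n_lambda,
                        lambda_min_ratio = lambda_min_ratio, seed = seed)
  }
  # warm-started descent from the all-zero end of the path to the target
  lmax <- lambda_max_sse(X, tau_hat)
  lams <- unique(c(lmax * exp(seq(0, -3, length.out = 8)), lambda))
  lams <- sort(lams[lams >= lambda], decreasing = TRUE)
  fit <- lasso_path(X, tau_hat, lams)[[length(lams)]]
  a <- numeric(n_rules)
  a[rule_cols] <- fit$beta[seq_along(rule_cols)]
  b_std <- fit$beta[setdiff(seq_len(ncol(X)), seq_along(rule_cols))]
  # back-transform standardized linear terms to the original feature scale
  b <- b_std / lin$scale
  supports <- attr(R, "supports")
  # undo the centering implied by the internal standardization so that
  # predictions use the original-scale features directly
  intercept <- fit$intercept - sum(lin$center * b)
  model <- list(a = a, b = b, intercept = intercept, lambda = lambda,
                rules = rules, supports = supports,
                feature_names = colnames(lin$X),
                feature_center = lin$center, feature_scale = lin$scale,
                feature_sd = lin$sd,
                importance_rules = rule_importance(a, supports),
                importance_features = abs(b) * lin$sd,
                objective = fit$objective)
  class(model) <- "rule_linear_model"
  model
}

# Raw-feature design: continuous features z-scored (constant features get
# scale 1), binaries as 0/1, categorical level indicators with the first
# level dropped. Returns the design plus per-column center/scale/original SD.
linear_terms <- function(ds) {
  cols <- list(); centers <- numeric(); scales <- numeric(); sds <- numeric()
  for (f in ds$schema$features) {
    if (f$role != "covariate") next
    v <- ds$x[[f$name]]
    if (f$kind == "categorical") {
      for (lv in f$levels[-1L]) {
        ind <- as.numeric(as.character(v) == lv)
        cols[[paste0(f$name, "=", lv)]] <- ind
        centers <- c(centers, 0); scales <- c(scales, 1)
        sds <- c(sds, stats::sd(ind))
      }
    } else {
      s <- stats::sd(v)
      if (f$kind == "continuous" && is.finite(s) && s > 0) {
        cols[[f$name]] <- (v - mean(v)) / s
        centers <- c(centers, mean(v)); scales <- c(scales, s); sds <- c(sds, s)
      } else {
        cols[[f$name]] <- v
        centers <- c(centers, 0); scales <- c(scales, 1)
        sds <- c(sds, if (is.finite(s)) s else 0)
      }
    }
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(0, n_subjects(ds), 0)
  colnames(X) <- names(cols)
  list(X = X, center = centers, scale = scales, sd = sds)
}

cv_lambda <- function(X, y, k = 4, n_lambda = 8, lambda_min_ratio = 1e-3,
                      seed = 1) {
  lmax <- lambda_max_sse(X, y)
  if (lmax <= 0) return(0)
  grid <- lmax * exp(seq(0, log(lambda_min_ratio), length.out = n_lambda))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(y)))
  mse <- matrix(NA_real_, k, n_lambda)
  for (f in seq_len(k)) {
    tr <- fold != f
    # per-fold lambdas rescaled so the penalty-to-SSE balance matches
    fits <- lasso_path(X[tr, , drop = FALSE], y[tr],
                       grid * sum(tr) / length(y))
    for (li in seq_along(grid)) {
      fit <- fits[[li]]
      pred <- fit$intercept + drop(X[!tr, , drop = FALSE] %*% fit$beta)
      mse[f, li] <- mean((y[!tr] - pred)^2)
    }
  }
  grid[which.min(colMeans(mse))]
}

#' Rule importance score
#'
#' The rule-ensemble effect size: |coefficient| * sqrt(support * (1 -
#' support)), i.e. the absolute coefficient scaled by the binary indicator's
#' standard deviation.
#'
#' @param coefficient Rule coefficient(s) from the sparse linear model.
#' @param support Support fraction(s) in [0, 1].
#' @return Importance score(s).
#' @export
rule_importance <- function(coefficient, support) {
  abs(coefficient) * sqrt(support * (1 - support))
}

#' Average treatment effect within a rule-defined subgroup
#'
#' ate = mean(Y | T=1, in) - mean(Y | T=0, in), with the binomial standard
#' error sqrt(p1(1-p1)/n1 + p0(1-p0)/n0).
#'
#' @param ds A \code{trial_dataset}.
#' @param rule A rule (list with \code{conditions}) or a bare condition list.
#' @return List with \code{ate}, \code{se}, \code{n_in}, \code{n_t},
#'   \code{n_c}.
#' @export
subgroup_ate <- function(ds, rule) {
  conds <- if (!is.null(rule$conditions)) rule$conditions else rule
  m <- eval_conditions(conds, ds$x)
  t_in <- ds$treatment[m]; y_in <- ds$outcome[m]
  n1 <- sum(t_in == 1); n0 <- sum(t_in == 0)
  if (n1 == 0 || n0 == 0)
    stop_validation("subgroup '%s' lacks %s subjects", describe_rule(conds),
                    if (n1 == 0) "treated" else "control")
  p1 <- mean(y_in[t_in == 1]); p0 <- mean(y_in[t_in == 0])
  list(ate = p1 - p0,
       se = sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0),
       n_in = sum(m), n_t = n1, n_c = n0)
}

#' Rank selected rules into favorable and unfavorable subgroup reports
#'
#' Rules are partitioned by the sign of their coefficient, filtered by the
#' configured threshold (\code{"nonzero"}: a != 0; \code{"coefficient"}:
#' |a| > value; \code{"importance"}: importance > value), sorted by
#' importance descending, and the top k of each sign reported. If a test
#' dataset is supplied, the within-subgroup ATE and its standard error are
#' attached.
#'
#' @param model A \code{rule_linear_model}.
#' @param threshold Filter kind, one of \code{"nonzero"},
#'   \code{"coefficient"}, \code{"importance"}.
#' @param value Threshold value (ignored for \code{"nonzero"}).
#' @param top_k Rules reported per sign.
#' @param ds_test Optional dataset for subgroup ATEs.
#' @return List with data frames \code{favorable} and \code{unfavorable}
#'   (class \code{subgroup_report}).
#' @export
rank_and_select <- function(model, threshold = c("importance", "coefficient",
                                                 "nonzero"),
                            value = 0.002, top_k = 5, ds_test = NULL) {
  if (length(threshold) > 1L) threshold <- threshold[1L]
  if (!threshold %in% c("nonzero", "coefficient", "importance"))
    stop_config("unknown threshold kind '%s'", threshold)
  a <- model$a
  imp <- model$importance_rules
  keep <- switch(threshold,
                 nonzero = a != 0,
                 coefficient = abs(a) > value,
                 importance = a != 0 & imp > value)
  build <- function(sel) {
    sel <- sel[order(imp[sel], decreasing = TRUE)]
    sel <- utils::head(sel, top_k)
    df <- data.frame(
      description = vapply(model$rules[sel], `[[`, "", "description"),
      coefficient = a[sel],
      support_n = vapply(model$rules[sel], function(r) r$support_n %||% NA_integer_, 0),
      support = model$supports[sel],
      importance = imp[sel],
      stringsAsFactors = FALSE)
    if (!is.null(ds_test) && nrow(df) > 0) {
      ate <- lapply(model$rules[sel], function(r)
        tryCatch(subgroup_ate(ds_test, r),
                 uplift_validation_error = function(e) list(ate = NA_real_, se = NA_real_)))
      df$ate_test <- vapply(ate, `[[`, 0, "ate")
      df$ate_se <- vapply(ate, `[[`, 0, "se")
    }
    rownames(df) <- NULL
    df
  }
  out <- list(favorable = build(which(keep & a > 0)),
              unfavorable = build(which(keep & a < 0)),
              threshold = threshold, value = value)
  class(out) <- "subgroup_report"
  out
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat("Favorable treatment effects\n")
  print(x$favorable, digits = 4)
  cat("Unfavorable treatment effects\n")
  print(x$unfavorable, digits = 4)
  invisible(x)
}

#' Predict treatment effects from a fitted rule model
#'
#' @param object A \code{rule_linear_model}.
#' @param newdata A \code{trial_dataset} or covariate data frame.
#' @param ... Unused.
#' @return Numeric predictions of tau.
#' @export
predict.rule_linear_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "trial_dataset")) newdata$x else newdata
  R <- rule_matrix(object$rules, x)
  pred <- object$intercept + drop(R %*% object$a)
  if (length(object$b)) {
    Xl <- raw_linear_design(object, x)
    pred <- pred + drop(Xl %*% object$b)
  }
  pred
}

# Rebuild the raw-feature design on new data, on the ORIGINAL scale (the
# stored b coefficients are already back-transformed).
raw_linear_design <- function(model, x) {
  cols <- lapply(model$feature_names, function(nm) {
    if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1L]]
      as.numeric(as.character(x[[parts[1L]]]) == parts[2L])
    } else {
      x[[nm]]
    }
  })
  X <- do.call(cbind, cols)
  colnames(X) <- model$feature_names
  X
}
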