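#' Configure the trial simulator
#'
#' The simulator emulates the study design the framework targets: a
#' randomized trial (Bernoulli(0.5) treatment, independent of covariates)
#' plus a control-only observational pool whose covariate means are shifted
#' by a confounding vector. Outcomes are Bernoulli with
#' P(Y=1 | X, T) = plogis(beta0 + beta'X + T * delta(X)), where delta(X) sums
#' the logit-scale effects of the planted rules the subject satisfies.
#' Planting effects on the logit scale keeps the generating model a proper
#' probability model; the true heterogeneous treatment effect is the exact
#' risk difference tau(X) = plogis(lin + delta) - plogis(lin).
#'
#' The default fixture mirrors the structure of a small blood-pressure trial
#' analysis: 800 randomized subjects, one favorable two-feature rule
#' (x1 >= -1 and x2 < 1.5, about 79% support) and one unfavorable one-feature
#' rule on the complementary boundary (x1 < -1, about 16% support), with
#' subgroup risk differences of roughly +0.2 and -0.3.
#'
#' @param n_rct Number of randomized subjects (>= 2).
#' @param n_pool Number of observational (control-only) subjects.
#' @param d_cont Number of correlated Gaussian continuous covariates.
#' @param d_cat Number of independent categorical covariates.
#' @param rho Equicorrelation of the continuous covariates.
#' @param planted_rules List of planted subgroups; each element is
#'   \code{list(conditions = <list of split_condition>, delta = <logit shift>)}.
#' @param beta0 Intercept of the baseline outcome model (logit scale).
#' @param beta Coefficients on the continuous covariates.
#' @param shift Confounding mean-shift vector (in SD units) applied to the
#'   continuous covariates of the observational pool.
#' @param seed Integer seed; regeneration with the same config is
#'   bit-identical.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_rct = 800, n_pool = 2000, d_cont = 4, d_cat = 2,
                       rho = 0.2, planted_rules = default_planted_rules(),
                       beta0 = -0.3, beta = c(0.4, 0.3, -0.3, 0.2),
                       shift = c(0.5, 0.5, 0, 0), seed = 1) {
  if (n_rct < 2) stop_config("n_rct must be >= 2")
  if (d_cont < 1) stop_config("at least one continuous covariate is required")
  if (length(beta) != d_cont) stop_config("beta must have length d_cont")
  if (length(shift) != d_cont) stop_config("shift must have length d_cont")
  if (abs(rho) >= 1) stop_config("rho must lie in (-1, 1)")
  feats <- c(
    lapply(seq_len(d_cont), function(j)
      list(name = paste0("x", j), kind = "continuous", role = "covariate")),
    lapply(seq_len(d_cat), function(j)
      list(name = paste0("c", j), kind = "categorical", role = "covariate",
           levels = if (j %% 2 == 1) c("a", "b", "c") else c("a", "b"))),
    list(list(name = "treat", kind = "binary", role = "treatment"),
         list(name = "resp", kind = "binary", role = "outcome"))
  )
  schema <- feature_schema(feats)
  cfg <- list(n_rct = n_rct, n_pool = n_pool, d_cont = d_cont, d_cat = d_cat,
              rho = rho, planted_rules = planted_rules, beta0 = beta0,
              beta = beta, shift = shift, seed = as.integer(seed),
              schema = schema)
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted subgroups for the simulation fixture
#' @return A list of two planted rules (favorable conjunction, unfavorable
#'   single boundary) with logit-scale effects +1.0 and -1.5.
#' @export
default_planted_rules <- function() {
  list(
    list(conditions = list(split_condition("x1", ">=", -1),
                           split_condition("x2", "<", 1.5)),
         delta = 1.0),
    list(conditions = list(split_condition("x1", "<", -1)),
         delta = -1.5)
  )
}

#' Null configuration (no planted effects)
#' @param ... Passed to \code{\link{sim_config}}.
#' @export
null_sim_config <- function(...) {
  sim_config(planted_rules = list(), ...)
}

sim_covariates <- function(cfg, n) {
  sigma <- matrix(cfg$rho, cfg$d_cont, cfg$d_cont)
  diag(sigma) <- 1
  xc <- MASS::mvrnorm(n, mu = rep(0, cfg$d_cont), Sigma = sigma)
  x <- as.data.frame(xc)
  names(x) <- paste0("x", seq_len(cfg$d_cont))
  for (j in seq_len(cfg$d_cat)) {
    lv <- schema_levels(cfg$schema, paste0("c", j))
    pr <- if (length(lv) == 3L) c(0.5, 0.3, 0.2) else c(0.6, 0.4)
    x[[paste0("c", j)]] <- sample(lv, n, replace = TRUE, prob = pr)
  }
  x
}

sim_delta <- function(cfg, x) {
  d <- rep(0, nrow(x))
  for (r in cfg$planted_rules)
    d <- d + r$delta * eval_conditions(r$conditions, x)
  d
}

#' Simulate a randomized trial with planted treatment-effect subgroups
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A list with \code{data} (a \code{trial_dataset}) and \code{truth}
#'   (per-subject exact risk-difference \code{tau} and a logical
#'   \code{membership} matrix, one column per planted rule).
#' @export
simulate_rct <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_rct
  x <- sim_covariates(cfg, n)
  tr <- stats::rbinom(n, 1, 0.5)
  lin <- cfg$beta0 + as.matrix(x[paste0("x", seq_len(cfg$d_cont))]) %*% cfg$beta
  lin <- drop(lin)
  delta <- sim_delta(cfg, x)
  p1 <- stats::plogis(lin + delta)
  p0 <- stats::plogis(lin)
  if (any(!is.finite(p1)) || any(!is.finite(p0)) ||
      any(pmin(p1, p0) <= 0) || any(pmax(p1, p0) >= 1))
    stop_config("outcome model produced probabilities outside (0,1)")
  y <- stats::rbinom(n, 1, ifelse(tr == 1, p1, p0))
  ds <- trial_dataset(x, tr, y, cfg$schema, source = "rct")
  membership <- vapply(cfg$planted_rules,
                       function(r) eval_conditions(r$conditions, x),
                       logical(n))
  if (length(cfg$planted_rules) == 0L)
    membership <- matrix(FALSE, n, 0)
  truth <- list(tau = p1 - p0,
                membership = matrix(membership, nrow = n))
  list(data = ds, truth = truth)
}

#' Simulate a confounded control-only observational pool
#'
#' Every subject receives standard care (T = 0, source = historical); the
#' continuous covariate means are shifted by the config's confounding vector
#' (in SD units). Outcomes follow the same baseline model with T = 0.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Optional seed override (defaults to \code{cfg$seed + 1} so the
#'   pool is independent of the trial draw).
#' @return A \code{trial_dataset} of historical controls.
#' @export
simulate_observational_pool <- function(cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  n <- cfg$n_pool
  x <- sim_covariates(cfg, n)
  for (j in seq_len(cfg$d_cont))
    x[[paste0("x", j)]] <- x[[paste0("x", j)]] + cfg$shift[j]
  lin <- cfg$beta0 + as.matrix(x[paste0("x", seq_len(cfg$d_cont))]) %*% cfg$beta
  p0 <- stats::plogis(drop(lin))
  y <- stats::rbinom(n, 1, p0)
  trial_dataset(x, rep(0L, n), y, cfg$schema, source = "historical")
}

#' Score recovery of a planted subgroup by selected rules
#'
#' The best (maximum) Jaccard index between the member set of any selected
#' rule and the planted subgroup's member set, evaluated on a dataset.
#'
#' @param selected List of rules (each a list with a \code{conditions}
#'   element, e.g. as returned by \code{\link{extract_rules}}), or a list of
#'   bare condition lists.
#' @param truth Ground truth from \code{\link{simulate_rct}}.
#' @param ds The dataset on which membership is evaluated.
#' @param subgroup Which planted subgroup to score against (column of the
#'   membership matrix).
#' @return A number in [0, 1].
#' @export
recovery_score <- function(selected, truth, ds, subgroup = 1L) {
  if (ncol(truth$membership) < 1L)
    stop_validation("ground truth contains no planted subgroup")
  planted <- truth$membership[, subgroup]
  if (length(selected) == 0L) {
    warning("recovery_score: no selected rules; returning 0")
    return(0)
  }
  best <- 0
  for (r in selected) {
    conds <- if (!is.null(r$conditions)) r$conditions else r
    m <- eval_conditions(conds, ds$x)
    inter <- sum(m & planted)
    uni <- sum(m | planted)
    j <- if (uni == 0) 0 else inter / uni
    best <- max(best, j)
  }
  best
}
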