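make_rule <- function(feature, op, value, desc = NULL) {
  conds <- list(split_condition(feature, op, value))
  list(conditions = conds,
       description = desc %||% describe_rule(conds),
       support_n = NA_integer_)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_model_ds <- function(n = 200, seed = 1) {
  set.seed(seed)
  schema <- feature_schema(list(
    list(name = "x1", kind = "continuous", role = "covariate"),
    list(name = "x2", kind = "continuous", role = "covariate"),
    list(name = "T", kind = "binary", role = "treatment"),
    list(name = "Y", kind = "binary", role = "outcome")))
  trial_dataset(data.frame(x1 = rnorm(n), x2 = rnorm(n)),
                rbinom(n, 1, 0.5), rbinom(n, 1, 0.5), schema)
}

test_that("a large penalty shrinks everything to the intercept", {
  ds <- toy_model_ds()
  tau <- rnorm(200, 0.1, 0.2)
  rules <- list(make_rule("x1", ">=", 0), make_rule("x2", "<", 1))
  m <- fit_rule_model(tau, rules, ds, lambda = 1e6)
  expect_equal(m$a, c(0, 0))
  expect_equal(unname(m$b), c(0, 0))
  expect_equal(m$intercept, mean(tau), tolerance = 1e-10)
  expect_error(fit_rule_model(tau, rules, ds, lambda = -1),
               class = "uplift_domain_error")
})

test_that("lambda = 0 reproduces ordinary least squares", {
  ds <- toy_model_ds(n = 150, seed = 2)
  tau <- 0.05 + 0.3 * ds$x$x1 - 0.2 * (ds$x$x2 >= 0.5) + rnorm(150, 0, 0.05)
  rules <- list(make_rule("x2", ">=", 0.5))
  m <- fit_rule_model(tau, rules, ds, lambda = 0)
  R <- as.numeric(ds$x$x2 >= 0.5)
  ols <- lm(tau ~ R + ds$x$x1 + ds$x$x2)
  expect_equal(m$a, unname(coef(ols)["R"]), tolerance = 1e-6)
  expect_equal(unname(m$b), unname(coef(ols)[c("ds$x$x1", "ds$x$x2")]),
               tolerance = 1e-6)
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
})

test_that("the coordinate-descent objective never increases", {
  set.seed(3)
  X <- cbind(rbinom(100, 1, 0.4), rnorm(100), rnorm(100))
  y <- 0.2 * X[, 1] - 0.1 * X[, 2] + rnorm(100, 0, 0.1)
  fit <- upliftrules:::lasso_cd(X, y, lambda = 2, trace = TRUE)
  path <- fit$objective_path
  expect_true(all(diff(path) <= 1e-10))
})

test_that("coordinate descent matches a brute-force grid on 2-coefficient toys", {
  set.seed(4)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(40, 0, 0.1)
  lambda <- 3
  fit <- upliftrules:::lasso_cd(X, y, lambda)
  obj <- function(b1, b2) {
    ic <- mean(y) - b1 * mean(X[, 1]) - b2 * mean(X[, 2])
    sum((y - ic - b1 * X[, 1] - b2 * X[, 2])^2) + lambda * (abs(b1) + abs(b2))
  }
  # coarse grid, then a refined grid around the coarse minimizer
  search <- function(c1, c2, half, step) {
    g1 <- seq(c1 - half, c1 + half, by = step)
    g2 <- seq(c2 - half, c2 + half, by = step)
    best <- c(NA, NA); best_val <- Inf
    for (b1 in g1) {
      vals <- vapply(g2, function(b2) obj(b1, b2), 0)
      j <- which.min(vals)
      if (vals[j] < best_val) { best_val <- vals[j]; best <- c(b1, g2[j]) }
    }
    list(beta = best, val = best_val)
  }
  coarse <- search(0, 0, 1, 0.01)
  fine <- search(coarse$beta[1], coarse$beta[2], 0.02, 1e-4)
  expect_equal(fit$objective, fine$val, tolerance = 1e-6)
  expect_equal(fit$beta, fine$beta, tolerance = 2e-3)
})

test_that("coordinate descent agrees with glmnet on the translated problem", {
  # glmnet minimizes (1/2n)SSE + lambda_g * sum|b| on standardized or raw
  # columns; our objective is SSE + lambda * sum|b|, so lambda_g =
  # lambda / (2n). Independent cross-check of the solver.
  set.seed(5)
  n <- 300
  X <- cbind(rbinom(n, 1, 0.3), rbinom(n, 1, 0.6), rnorm(n))
  y <- 0.15 * X[, 1] - 0.25 * X[, 2] + 0.05 * X[, 3] + rnorm(n, 0, 0.05)
  lambda <- 4
  ours <- upliftrules:::lasso_cd(X, y, lambda)
  g <- glmnet::glmnet(X, y, lambda = lambda / (2 * n), standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(ours$beta, as.numeric(g$beta), tolerance = 1e-4)
  expect_equal(ours$intercept, as.numeric(g$a0), tolerance = 1e-4)
})

test_that("a planted rule dominates noise rules in the fitted model", {
  wins <- 0L
  for (sd in 1:20) {
    set.seed(sd)
    ds <- toy_model_ds(n = 300, seed = sd + 100)
    planted <- make_rule("x1", ">=", 0)
    ind <- as.numeric(ds$x$x1 >= 0)
    tau <- 0.2 * ind + rnorm(300, 0, 0.01)
    noise <- lapply(1:10, function(j)
      make_rule("x2", ">=", qnorm(j / 11)))
    rules <- c(list(planted), noise)
    m <- fit_rule_model(tau, rules, ds, lambda = 1, seed = sd)
    if (which.max(abs(m$a)) == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 11L)
})

test_that("importance arithmetic follows |a| sqrt(s(1-s)) and |b| SD(x)", {
  expect_equal(round(rule_importance(0.0090, 0.8191), 4), 0.0035)
  expect_equal(round(rule_importance(-0.0046, 0.4991), 4), 0.0023)
  expect_equal(rule_importance(0, 0.3), 0)

  ds <- toy_model_ds(n = 120, seed = 6)
  tau <- 0.1 * ds$x$x1 + rnorm(120, 0, 0.02)
  m <- fit_rule_model(tau, list(make_rule("x1", ">=", 0)), ds, lambda = 0.5)
  expect_equal(unname(m$importance_rules),
               unname(abs(m$a) * sqrt(m$supports * (1 - m$supports))))
  expect_equal(unname(m$importance_features),
               unname(abs(m$b) * c(sd(ds$x$x1), sd(ds$x$x2))))
})

test_that("rule model predictions reproduce the fitted linear form", {
  ds <- toy_model_ds(n = 150, seed = 7)
  tau <- 0.3 * (ds$x$x1 >= 0) - 0.1 * ds$x$x2 + rnorm(150, 0, 0.05)
  rules <- list(make_rule("x1", ">=", 0))
  m <- fit_rule_model(tau, rules, ds, lambda = 0.2)
  pred <- predict(m, ds)
  manual <- m$intercept + m$a[1] * (ds$x$x1 >= 0) +
    m$b[1] * ds$x$x1 + m$b[2] * ds$x$x2
  expect_equal(pred, unname(manual), tolerance = 1e-10)
})

test_that("rank_and_select applies the three threshold kinds", {
  ds <- toy_model_ds(n = 100, seed = 8)
  rules <- list(make_rule("x1", ">=", 0), make_rule("x2", ">=", 0),
                make_rule("x1", "<", 0))
  m <- fit_rule_model(rnorm(100, 0, 0.05), rules, ds, lambda = 1e6)
  empty <- rank_and_select(m, threshold = "nonzero")
  expect_equal(nrow(empty$favorable), 0)
  expect_equal(nrow(empty$unfavorable), 0)

  # hand-built model: filter semantics on coefficients (0.009, 0.004, -0.006)
  m$a <- c(0.009, 0.004, -0.006)
  m$supports <- c(0.8, 0.5, 0.1)
  m$importance_rules <- rule_importance(m$a, m$supports)
  m$rules <- lapply(rules, function(r) { r$support_n <- 0L; r })
  sel <- rank_and_select(m, threshold = "coefficient", value = 0.005)
  expect_equal(sel$favorable$coefficient, 0.009)
  expect_equal(sel$unfavorable$coefficient, -0.006)

  # importance filter at 0.002 on the favorable rules keeps 4 of 5 when
  # importances are recomputed (unrounded) from coefficient and support
  imps <- rule_importance(c(0.0090, 0.0084, 0.0057, 0.0054, 0.0052),
                          c(0.8191, 0.8495, 0.8294, 0.1700, 0.8553))
  expect_equal(sum(imps > 0.002), 4)

  expect_error(rank_and_select(m, threshold = "bogus"),
               class = "uplift_config_error")
})
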