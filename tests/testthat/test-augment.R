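test_that("propensity model behaves at the no-signal and separable extremes", {
  cfg <- null_sim_config(n_rct = 2000, seed = 1)
  ds <- simulate_rct(cfg)$data
  ps <- fit_propensity(ds, seed = 1)
  expect_true(all(ps$scores > 0 & ps$scores < 1))
  expect_lt(abs(ps$auc - 0.5), 0.05)   # randomized: no signal

  # perfectly separable single covariate
  sep <- ds
  sep$x$x1 <- ifelse(ds$treatment == 1, ds$x$x1 + 10, ds$x$x1)
  expect_equal(fit_propensity(sep, seed = 1)$auc, 1.0, tolerance = 1e-6)

  # determinism in the seed
  ps2 <- fit_propensity(ds, seed = 1)
  expect_identical(ps$coef, ps2$coef)

  single <- subset_dataset(ds, which(ds$treatment == 1))
  expect_error(fit_propensity(single), class = "uplift_validation_error")
})

test_that("greedy caliper matching pairs injectively within the caliper", {
  # B a copy of A: every A matched at distance 0
  sa <- c(0.2, 0.4, 0.6, 0.8)
  mr <- nn_match(sa, sa, caliper_sd = 0.2)
  expect_equal(nrow(mr$pairs), 4)
  expect_equal(mr$pairs$distance, rep(0, 4))
  expect_length(mr$unmatched_a, 0)

  # injective on both sides, distances within the caliper
  set.seed(2)
  sa <- runif(50, 0.2, 0.8); sb <- runif(80, 0.2, 0.8)
  mr <- nn_match(sa, sb, caliper_sd = 0.2)
  expect_false(anyDuplicated(mr$pairs$a) > 0)
  expect_false(anyDuplicated(mr$pairs$b) > 0)
  expect_true(all(mr$pairs$distance <= mr$caliper))

  # zero caliper degenerates to no matches
  mr0 <- nn_match(sa, sb, caliper_sd = 0)
  expect_equal(nrow(mr0$pairs), 0)

  # identical scores everywhere: caliper undefined
  expect_error(nn_match(rep(0.5, 3), rep(0.5, 3)),
               class = "uplift_validation_error")
})

test_that("greedy rule matches the nearest eligible candidate only", {
  # A's logit 0; B's logits ~0.1 and 5: with a caliper below 5 the far
  # candidate is never eligible and A pairs with the near one
  inv <- plogis
  mr <- nn_match(inv(0), inv(c(0.1, 5)), caliper_sd = 0.3)
  expect_lt(mr$caliper, 5)
  expect_gt(mr$caliper, abs(0.1))
  expect_equal(mr$pairs$b, 1L)
  expect_equal(mr$pairs$distance, 0.1, tolerance = 1e-9)
})

test_that("SMD arithmetic matches the pooled-variance formula", {
  schema <- feature_schema(list(
    list(name = "v", kind = "continuous", role = "covariate"),
    list(name = "b", kind = "binary", role = "covariate"),
    list(name = "T", kind = "binary", role = "treatment"),
    list(name = "Y", kind = "binary", role = "outcome")))
  set.seed(3)
  n <- 4000
  tr <- rep(c(1, 0), each = n / 2)
  v <- ifelse(tr == 1, rnorm(n, 1, 1), rnorm(n, 0, 1))
  bb <- ifelse(tr == 1, rbinom(n, 1, 0.5), rbinom(n, 1, 0.3))
  ds <- trial_dataset(data.frame(v = v, b = bb), tr, rbinom(n, 1, 0.5), schema)
  s <- smd_report(ds)
  expect_equal(unname(s$smd["v"]), 1.0, tolerance = 0.08)
  expect_equal(unname(s$smd["b"]), (0.5 - 0.3) / sqrt((0.25 + 0.21) / 2),
               tolerance = 0.12)

  # identical arms -> all SMDs zero
  ds0 <- trial_dataset(data.frame(v = rep(c(1, 2), 4), b = rep(c(0, 1), 4)),
                       rep(c(1, 0), each = 4), rep(0:1, 4), schema)
  expect_equal(max(abs(smd_report(ds0)$smd)), 0)
})

test_that("arm AUC sits near chance for randomized data, 1 when separable", {
  cfg <- null_sim_config(n_rct = 2000, seed = 4)
  ds <- simulate_rct(cfg)$data
  a <- arm_auc(ds, seed = 1)
  expect_gt(a, 0.45); expect_lt(a, 0.60)
  expect_identical(a, arm_auc(ds, seed = 1))   # deterministic given seed
})

test_that("borrowing historical controls keeps all real subjects", {
  cfg <- sim_config(n_rct = 400, n_pool = 600, seed = 5)
  sim <- simulate_rct(cfg)
  pool <- simulate_observational_pool(cfg)
  aug <- borrow_historical(sim$data, pool, seed = 5)
  expect_gte(n_subjects(aug), n_subjects(sim$data))
  expect_equal(sum(aug$source == "rct"), 400)   # no real subject dropped
  expect_true(all(aug$treatment[aug$source == "historical"] == 0))
  mr <- attr(aug, "match")
  expect_equal(n_subjects(aug), 400 + nrow(mr$pairs))

  # empty pool: unchanged with a warning
  expect_warning(same <- borrow_historical(sim$data, NULL), "empty pool")
  expect_identical(same$x, sim$data$x)
})

test_that("matching historical controls improves balance over naive pooling", {
  cfg <- sim_config(n_rct = 400, n_pool = 600, seed = 6)
  sim <- simulate_rct(cfg)
  pool <- simulate_observational_pool(cfg)
  aug <- borrow_historical(sim$data, pool, seed = 6)
  bal <- attr(aug, "balance")
  expect_lt(bal$after$mean_smd, bal$before$mean_smd)
  expect_lt(bal$after$arm_auc, bal$before$arm_auc)
})

test_that("the smoothed bootstrap generator honors its contract", {
  cfg <- sim_config(n_rct = 400, seed = 7)
  real <- simulate_rct(cfg)$data

  # zero bandwidth + frozen categoricals -> exact copies of real rows
  gen0 <- smoothed_bootstrap_generator(bandwidth_factor = 0,
                                       freeze_categorical = TRUE)
  s0 <- generate_synthetic(real, 50, 50, seed = 1, generator = gen0)
  expect_true(all(s0$source == "synthetic"))
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  expect_true(all(key(s0$x) %in% key(real$x)))

  # same seed -> identical draw; arms sized as requested
  s1 <- generate_synthetic(real, 100, 150, seed = 9)
  s2 <- generate_synthetic(real, 100, 150, seed = 9)
  expect_identical(s1$x, s2$x)
  expect_equal(sum(s1$treatment == 1), 100)
  expect_equal(sum(s1$treatment == 0), 150)

  # default bandwidth: every continuous variable similar to the real data
  s3 <- generate_synthetic(real, 500, 500, seed = 11)
  sim_scores <- similarity_report(real, s3)
  expect_true(all(sim_scores > 0.7))
})

test_that("synthetic matching appends matched rows and keeps real ones", {
  cfg <- sim_config(n_rct = 400, seed = 8)
  real <- simulate_rct(cfg)$data
  synth <- generate_synthetic(real, 200, 200, seed = 8)
  out <- match_synthetic(real, synth, seed = 8)
  expect_equal(sum(out$source == "rct"), 400)
  expect_gt(sum(out$source == "synthetic"), 0)
  bal <- attr(out, "balance")
  expect_true(is.finite(bal$after$mean_smd))

  # empty synthetic: unchanged with a warning
  expect_warning(same <- match_synthetic(real, NULL), "empty synthetic")
  expect_identical(same$x, real$x)

  # synthetic missing an arm: that matching is skipped
  ctrl_only <- subset_dataset(synth, which(synth$treatment == 0))
  expect_warning(out2 <- match_synthetic(real, ctrl_only, seed = 8),
                 "matching skipped")
  expect_equal(sum(out2$source == "rct"), 400)
})

test_that("similarity scores are exact for hand-built distributions", {
  schema <- feature_schema(list(
    list(name = "v", kind = "continuous", role = "covariate"),
    list(name = "c1", kind = "categorical", role = "covariate",
         levels = c("a", "b")),
    list(name = "T", kind = "binary", role = "treatment"),
    list(name = "Y", kind = "binary", role = "outcome")))
  mk <- function(v, c1) trial_dataset(data.frame(v = v, c1 = c1),
                                      rep_len(0:1, length(v)),
                                      rep_len(0:1, length(v)), schema)
  real <- mk(c(1, 2, 3, 4), c("a", "a", "b", "b"))

  # identical data: similarity 1 everywhere
  expect_equal(unname(similarity_report(real, real)), c(1, 1))

  # disjoint continuous supports: KS = 1 -> similarity 0
  far <- mk(c(10, 20, 30, 40), c("a", "a", "b", "b"))
  expect_equal(unname(similarity_report(real, far)["v"]), 0)

  # categorical (0.5, 0.5) vs (0.8, 0.2): TVD 0.3 -> similarity 0.7
  skew <- mk(c(1, 2, 3, 4, 1), c("a", "a", "a", "a", "b"))
  expect_equal(unname(similarity_report(real, skew)["c1"]), 0.7)

  # symmetry up to estimator tie handling
  s_ab <- similarity_report(real, skew)
  s_ba <- similarity_report(skew, real)
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
})
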