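test_that("binary KL divergence matches hand evaluation", {
  expect_equal(binary_kl(0.5, 0.5), 0)
  expect_equal(binary_kl(0.5, 0.25), 0.143841, tolerance = 1e-6)
  expect_equal(binary_kl(0.25, 0.5), 0.130812, tolerance = 1e-6)  # asymmetric
  expect_gt(binary_kl(0.5, 0.25), binary_kl(0.25, 0.5))
  expect_error(binary_kl(0, 0.5), class = "uplift_domain_error")
  expect_error(binary_kl(0.5, 1), class = "uplift_domain_error")
})

test_that("split gain is zero for uninformative splits and matches the oracle", {
  ns <- function(t, y, mask = rep(TRUE, length(t))) {
    tt <- t[mask]; yy <- y[mask]
    list(n_t = sum(tt == 1), n_c = sum(tt == 0),
         s_t = sum(yy[tt == 1]), s_c = sum(yy[tt == 0]),
         p_t = (sum(yy[tt == 1]) + 0.5) / (sum(tt == 1) + 1),
         p_c = (sum(yy[tt == 0]) + 0.5) / (sum(tt == 0) + 1))
  }

  # children replicating the parent's smoothed rates -> gain 0
  t1 <- rep(c(1, 0), each = 8)
  y1 <- rep(c(1, 0, 1, 0), each = 4)   # rates identical in both halves
  right1 <- rep(c(TRUE, FALSE), times = 8)
  g0 <- split_gain(ns(t1, y1), ns(t1, y1, !right1), ns(t1, y1, right1))
  expect_equal(g0, 0, tolerance = 1e-12)

  # hand-specified 8-subject node: gain equals the independent oracle
  t2 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  y2 <- c(1, 1, 0, 0, 1, 0, 0, 0)
  right2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  g <- split_gain(ns(t2, y2), ns(t2, y2, !right2), ns(t2, y2, right2))
  expect_equal(g, oracle_gain(t2, y2, right2), tolerance = 1e-12)

  # a child emptied of one arm is rejected (NA), not an error
  right3 <- t2 == 1
  expect_true(is.na(split_gain(ns(t2, y2), ns(t2, y2, !right3),
                               ns(t2, y2, right3))))
})

test_that("candidate splits cover the declared search space", {
  expect_identical(candidate_splits(rep(5, 10), "continuous"), list())
  expect_identical(candidate_splits(rep("a", 5), "categorical",
                                    all_levels = c("a", "b")), list())

  bin <- candidate_splits(c(0, 1, 0, 1), "binary", feature = "g")
  expect_length(bin, 1)
  expect_equal(bin[[1]]$value, 1)
  expect_equal(bin[[1]]$op, ">=")

  cont <- candidate_splits(1:100, "continuous", k = 3, feature = "x")
  expect_equal(vapply(cont, `[[`, 0, "value"),
               unname(quantile(1:100, c(0.25, 0.5, 0.75), type = 7)))

  cat3 <- candidate_splits(c("a", "b", "c", "a"), "categorical",
                           feature = "c1", all_levels = c("a", "b", "c"))
  expect_length(cat3, 3)   # one-vs-rest per present level
  cat2 <- candidate_splits(c("a", "b", "a"), "categorical",
                           feature = "c1", all_levels = c("a", "b", "c"))
  expect_length(cat2, 1)   # two present levels -> a single split
})

test_that("trees respect depth and minimum-size stopping rules", {
  ds <- planted_binary_ds(n = 500, seed = 2)
  params <- forest_params(max_depth = 3, min_node = 50, min_treated = 10)
  tree <- grow_tree(ds, params)
  max_path <- function(node) {
    if (is.null(node$split)) return(0L)
    1L + max(max_path(node$left), max_path(node$right))
  }
  expect_lte(max_path(tree), 3L)

  # root below the node minimum: single leaf with tau = p_t - p_c
  small <- planted_binary_ds(n = 30, seed = 3)
  leaf <- grow_tree(small, forest_params(min_node = 100))
  expect_null(leaf$split)
  expect_equal(leaf$tau,
               mean(small$outcome[small$treatment == 1]) -
                 mean(small$outcome[small$treatment == 0]))

  single_arm <- planted_binary_ds(n = 40, seed = 4)
  single_arm$treatment <- rep(1L, 40)
  expect_error(grow_tree(single_arm, params), class = "uplift_validation_error")
})

test_that("the chosen root split is the exhaustive-gain argmax", {
  # the informative binary feature should win the root split in most seeds
  hits <- 0L
  for (sd in 1:20) {
    ds <- planted_binary_ds(n = 400, seed = sd)
    tree <- grow_tree(ds, forest_params(min_node = 100, min_treated = 25))
    if (!is.null(tree$split) && tree$split$feature == "g") hits <- hits + 1L
    # and whatever was chosen must equal the oracle argmax
    oracle <- oracle_best_split(ds)
    if (!is.null(tree$split)) {
      expect_equal(tree$split$feature, oracle$feature)
      expect_equal(tree$split$value, oracle$value)
    }
  }
  expect_gte(hits, 11L)   # seed-majority
})

test_that("child node statistics conserve the parent's counts", {
  cfg <- sim_config(n_rct = 600, seed = 21)
  ds <- simulate_rct(cfg)$data
  tree <- grow_tree(ds, forest_params())
  check <- function(node) {
    if (is.null(node$split)) return(invisible())
    expect_equal(node$left$stats$n_t + node$right$stats$n_t, node$stats$n_t)
    expect_equal(node$left$stats$n_c + node$right$stats$n_c, node$stats$n_c)
    expect_equal(node$left$stats$s_t + node$right$stats$s_t, node$stats$s_t)
    expect_equal(node$left$stats$s_c + node$right$stats$s_c, node$stats$s_c)
    check(node$left); check(node$right)
  }
  check(tree)
})

test_that("forest predictions average leaf estimates", {
  ds <- planted_binary_ds(n = 300, seed = 6)
  # bootstrap disabled, one tree: forest equals the single tree
  f1 <- grow_forest(ds, forest_params(n_trees = 1, bootstrap = FALSE, seed = 1))
  tree <- grow_tree(ds, forest_params())
  expect_equal(predict_tau(f1, ds), upliftrules:::tree_tau(tree, ds$x))

  # a forest of identical trees predicts exactly one tree's value
  f3 <- grow_forest(ds, forest_params(n_trees = 3, bootstrap = FALSE, seed = 1))
  expect_equal(predict_tau(f3, ds), predict_tau(f1, ds))

  # single-leaf tree: constant tau = p_t - p_c for every subject
  small <- planted_binary_ds(n = 60, seed = 7)
  fleaf <- grow_forest(small, forest_params(n_trees = 1, bootstrap = FALSE,
                                            min_node = 1000))
  tau <- mean(small$outcome[small$treatment == 1]) -
    mean(small$outcome[small$treatment == 0])
  expect_equal(predict_tau(fleaf, small), rep(tau, 60))
  expect_true(all(abs(predict_tau(fleaf, small)) <= 1))
})

test_that("forests are deterministic in the master seed", {
  ds <- planted_binary_ds(n = 300, seed = 8)
  fa <- grow_forest(ds, forest_params(n_trees = 5, seed = 99))
  fb <- grow_forest(ds, forest_params(n_trees = 5, seed = 99))
  expect_identical(predict_tau(fa, ds), predict_tau(fb, ds))
  expect_identical(fa$in_bag, fb$in_bag)
  fc <- grow_forest(ds, forest_params(n_trees = 5, seed = 100))
  expect_false(identical(predict_tau(fa, ds), predict_tau(fc, ds)))
})

test_that("forests serialize to JSON and back without loss", {
  ds <- planted_binary_ds(n = 300, seed = 9)
  f <- grow_forest(ds, forest_params(n_trees = 4, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_forest_json(f, path)
  back <- read_forest_json(path)
  expect_equal(predict_tau(back, ds), predict_tau(f, ds))
  expect_equal(back$weights, f$weights)
  expect_equal(back$params$max_depth, f$params$max_depth)
  # out-of-bag structure survives the round trip
  expect_equal(lapply(back$in_bag, sort), lapply(f$in_bag, sort))
})

test_that("a planted subgroup appears as a shallow node of some tree", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_rct(cfg)
  f <- grow_forest(sim$data, forest_params(n_trees = 100, seed = 31))
  rules <- extract_rules(f, alpha = 1, reference = sim$data)  # all nodes
  shallow <- Filter(function(r) r$provenance$depth <= 2, rules)
  best <- recovery_score(shallow, sim$truth, sim$data)
  expect_gte(best, 0.8)
})
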