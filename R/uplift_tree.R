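#' Kullback-Leibler divergence between two Bernoulli rates
#'
#' KL(p || q) = p*log(p/q) + (1-p)*log((1-p)/(1-q)), natural logarithm.
#' Inputs must lie strictly inside (0, 1); node rates are Jeffreys-smoothed
#' upstream so empty cells never reach this function.
#'
#' @param p,q Success rates in (0, 1).
#' @return Non-negative divergence; 0 iff p == q.
#' @export
binary_kl <- function(p, q) {
  if (any(p <= 0 | p >= 1) || any(q <= 0 | q >= 1))
    stop_domain("binary_kl requires rates strictly inside (0, 1)")
  p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
}

# Per-node arm counts and Jeffreys-smoothed success rates.
# Smoothing p = (s + 1/2) / (n + 1) keeps the KL finite at empty outcome
# cells without materially distorting large nodes.
node_stats <- function(treatment, outcome) {
  n_t <- sum(treatment == 1)
  n_c <- sum(treatment == 0)
  s_t <- sum(outcome[treatment == 1])
  s_c <- sum(outcome[treatment == 0])
  list(n_t = n_t, n_c = n_c, s_t = s_t, s_c = s_c,
       p_t = (s_t + 0.5) / (n_t + 1), p_c = (s_c + 0.5) / (n_c + 1))
}

#' Split gain of a candidate partition (KL criterion)
#'
#' gain = (n_L/n) KL(p_t^L, p_c^L) + (n_R/n) KL(p_t^R, p_c^R) - KL(p_t, p_c),
#' where n counts all samples in a node and arm rates are Jeffreys-smoothed.
#' A candidate that empties either arm of either child is rejected (returns
#' \code{NA}, signalled rather than thrown).
#'
#' @param parent,left,right Node statistics as produced internally (lists
#'   with \code{n_t}, \code{n_c}, \code{s_t}, \code{s_c}, smoothed
#'   \code{p_t}, \code{p_c}).
#' @return The gain, or \code{NA} for a rejected candidate.
#' @export
split_gain <- function(parent, left, right) {
  if (left$n_t == 0 || left$n_c == 0 || right$n_t == 0 || right$n_c == 0)
    return(NA_real_)
  n <- parent$n_t + parent$n_c
  n_l <- left$n_t + left$n_c
  n_r <- right$n_t + right$n_c
  (n_l / n) * binary_kl(left$p_t, left$p_c) +
    (n_r / n) * binary_kl(right$p_t, right$p_c) -
    binary_kl(parent$p_t, parent$p_c)
}

#' Enumerate candidate split conditions for one feature within a node
#'
#' Continuous features: thresholds at up to k empirical quantiles
#' (probabilities 1/(k+1), ..., k/(k+1), type-7 quantiles) of the in-node
#' values, as "x >= t" conditions; thresholds that would leave an empty side
#' are dropped. Binary features: the single threshold at the larger observed
#' value. Categorical features: one-vs-rest level splits (a single condition
#' when only two levels are present). A constant feature yields no
#' candidates.
#'
#' @param values The feature's in-node values.
#' @param kind Feature kind (\code{"continuous"}, \code{"binary"},
#'   \code{"categorical"}).
#' @param k Number of candidate quantile thresholds for continuous features.
#' @param feature Feature name recorded in the conditions.
#' @param all_levels Declared level set for categorical features.
#' @return List of \code{\link{split_condition}}s (possibly empty).
#' @export
candidate_splits <- function(values, kind, k = 10, feature = "x",
                             all_levels = NULL) {
  if (kind == "categorical") {
    present <- sort(unique(as.character(values)))
    if (length(present) < 2L) return(list())
    pick <- if (length(present) == 2L) present[2L] else present
    lapply(pick, function(lv)
      split_condition(feature, "in", lv, all_levels = all_levels))
  } else {
    v <- values[!is.na(values)]
    u <- unique(v)
    if (length(u) < 2L) return(list())
    th <- if (kind == "binary" || length(u) == 2L) {
      max(u)
    } else {
      sort(unique(stats::quantile(v, probs = seq_len(k) / (k + 1),
                                  type = 7, names = FALSE)))
    }
    th <- th[th > min(v)]            # both sides non-empty
    lapply(th, function(t) split_condition(feature, ">=", t))
  }
}

# Argmax-gain split over all covariates of a node. Ties broken by schema
# feature order, then ascending threshold/level order (deterministic).
best_split <- function(x, treatment, outcome, schema, params, parent) {
  best <- NULL
  best_gain <- 0
  for (nm in covariate_names(schema)) {
    f <- schema$features[[nm]]
    cands <- candidate_splits(x[[nm]], f$kind, k = params$k, feature = nm,
                              all_levels = f$levels)
    for (cond in cands) {
      right <- eval_condition(cond, x)
      if (!any(right) || all(right)) next
      ls <- node_stats(treatment[!right], outcome[!right])
      rs <- node_stats(treatment[right], outcome[right])
      g <- split_gain(parent, ls, rs)
      if (!is.na(g) && g > best_gain + 1e-12) {
        best_gain <- g
        best <- list(condition = cond, gain = g, right = right,
                     left_stats = ls, right_stats = rs)
      }
    }
  }
  best
}

#' Grow a single uplift tree
#'
#' Recursive partitioning that, at each node, takes the split maximizing the
#' KL-divergence gain between arm outcome distributions. Growth stops when
#' the node has fewer than \code{min_node} samples or fewer than
#' \code{min_treated} treated samples, when the maximum depth is reached, or
#' when no candidate split has positive gain. Every node retains its arm
#' counts; the leaf treatment-effect estimate is the unsmoothed rate
#' difference p_t - p_c.
#'
#' @param ds A \code{trial_dataset} with both arms present.
#' @param params List of growth parameters: \code{max_depth} (default 3),
#'   \code{min_node} (100), \code{min_treated} (25), \code{k} candidate
#'   thresholds per continuous feature (10).
#' @param indices Optional row indices (e.g. a bootstrap resample).
#' @return The root \code{uplift_tree_node} (nested list).
#' @export
grow_tree <- function(ds, params = forest_params(), indices = NULL) {
  if (is.null(indices)) indices <- seq_len(n_subjects(ds))
  tr <- ds$treatment[indices]
  if (!any(tr == 1) || !any(tr == 0))
    stop_validation("grow_tree requires both arms at the root")
  build <- function(idx, depth) {
    t_i <- ds$treatment[idx]
    y_i <- ds$outcome[idx]
    st <- node_stats(t_i, y_i)
    node <- list(stats = st, depth = depth,
                 tau = if (st$n_t > 0 && st$n_c > 0)
                   st$s_t / st$n_t - st$s_c / st$n_c else 0,
                 split = NULL, left = NULL, right = NULL)
    n <- st$n_t + st$n_c
    if (n < params$min_node || st$n_t < params$min_treated ||
        depth >= params$max_depth)
      return(node)
    bs <- best_split(ds$x[idx, , drop = FALSE], t_i, y_i, ds$schema, params, st)
    if (is.null(bs)) return(node)
    node$split <- bs$condition
    node$gain <- bs$gain
    node$left <- build(idx[!bs$right], depth + 1L)
    node$right <- build(idx[bs$right], depth + 1L)
    node
  }
  build(indices, 0L)
}

#' Default uplift-forest growth parameters
#'
#' @param n_trees Number of bootstrapped trees.
#' @param max_depth Maximum number of splits on any root-to-leaf path
#'   (default 3, so rules interact at most two features below a root split).
#' @param min_node Minimum samples to attempt a split.
#' @param min_treated Minimum treated samples to attempt a split.
#' @param k Candidate quantile thresholds per continuous feature.
#' @param bootstrap Grow each tree on an n-out-of-n arm-stratified bootstrap
#'   resample (\code{FALSE} reuses the full sample for every tree).
#' @param seed Master seed; per-tree seeds are derived deterministically.
#' @export
forest_params <- function(n_trees = 100, max_depth = 3, min_node = 100,
                          min_treated = 25, k = 10, bootstrap = TRUE,
                          seed = 1) {
  list(n_trees = n_trees, max_depth = max_depth, min_node = min_node,
       min_treated = min_treated, k = k, bootstrap = bootstrap,
       seed = as.integer(seed))
}

#' Grow a bootstrapped ensemble of uplift trees
#'
#' Each tree is grown on an n-out-of-n bootstrap resample stratified by arm;
#' per-tree seeds are derived deterministically from the master seed, so the
#' same parameters always reproduce the same forest. Trees carry uniform
#' weights.
#'
#' @param ds A \code{trial_dataset} with both arms.
#' @param params See \code{\link{forest_params}}.
#' @return An \code{uplift_forest} (trees, in-bag index lists, weights,
#'   params).
#' @export
grow_forest <- function(ds, params = forest_params()) {
  set.seed(params$seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, params$n_trees)
  idx_t <- which(ds$treatment == 1)
  idx_c <- which(ds$treatment == 0)
  trees <- vector("list", params$n_trees)
  in_bag <- vector("list", params$n_trees)
  for (b in seq_len(params$n_trees)) {
    set.seed(tree_seeds[b])
    idx <- if (params$bootstrap) {
      c(sample(idx_t, length(idx_t), replace = TRUE),
        sample(idx_c, length(idx_c), replace = TRUE))
    } else {
      seq_len(n_subjects(ds))
    }
    trees[[b]] <- grow_tree(ds, params, idx)
    in_bag[[b]] <- unique(idx)
  }
  structure(list(trees = trees, in_bag = in_bag,
                 weights = rep(1 / params$n_trees, params$n_trees),
                 params = params, n_train = n_subjects(ds),
                 schema = ds$schema),
            class = "uplift_forest")
}

# Leaf tau assignment for one tree over all rows of x (vectorized recursion).
# Rows whose categorical level was unseen in training are routed to the
# child with more training samples.
tree_tau <- function(node, x) {
  out <- numeric(nrow(x))
  assign_node <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (is.null(node$split)) {
      out[idx] <<- node$tau
      return()
    }
    cond <- node$split
    right <- eval_condition(cond, x[idx, , drop = FALSE])
    if (cond$op == "in" && !is.null(cond$all_levels)) {
      unseen <- !as.character(x[[cond$feature]][idx]) %in% cond$all_levels
      if (any(unseen)) {
        nl <- node$left$stats$n_t + node$left$stats$n_c
        nr <- node$right$stats$n_t + node$right$stats$n_c
        right[unseen] <- nr >= nl
      }
    }
    assign_node(node$left, idx[!right])
    assign_node(node$right, idx[right])
  }
  assign_node(node, seq_len(nrow(x)))
  out
}

#' Estimate per-subject treatment effects from a forest
#'
#' The heterogeneous treatment effect estimate is the weighted mean over
#' trees of the leaf estimate (rate difference) the subject falls into;
#' values lie in [-1, 1]. With \code{oob = TRUE} (valid only when \code{x}
#' is the training table in training order), each subject is averaged over
#' the trees whose bootstrap resample did not contain it; subjects in every
#' bag fall back to the full-forest average.
#'
#' @param forest An \code{uplift_forest}.
#' @param x Covariate data frame conforming to the training schema.
#' @param oob Use out-of-bag averaging (training data only).
#' @return Numeric vector of estimated treatment effects.
#' @export
predict_tau <- function(forest, x, oob = FALSE) {
  if (inherits(x, "trial_dataset")) x <- x$x
  miss <- setdiff(covariate_names(forest$schema), names(x))
  if (length(miss))
    stop_schema("prediction data lacks covariate(s): %s", paste(miss, collapse = ", "))
  ntree <- length(forest$trees)
  taus <- vapply(forest$trees, tree_tau, numeric(nrow(x)), x = x)
  taus <- matrix(taus, nrow = nrow(x))
  if (!oob) return(drop(taus %*% forest$weights))
  if (nrow(x) != forest$n_train)
    stop_validation("oob prediction requires the training table")
  w <- matrix(rep(forest$weights, each = nrow(x)), nrow = nrow(x))
  for (b in seq_len(ntree)) w[forest$in_bag[[b]], b] <- 0
  denom <- rowSums(w)
  full <- drop(taus %*% forest$weights)
  ifelse(denom > 0, rowSums(taus * w) / pmax(denom, .Machine$double.eps), full)
}

#' @export
print.uplift_forest <- function(x, ...) {
  cat(sprintf("<uplift_forest> %d trees (max depth %d, min node %d, min treated %d)\n",
              length(x$trees), x$params$max_depth, x$params$min_node,
              x$params$min_treated))
  invisible(x)
}
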