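#' Chi-square test of arm-by-outcome independence within a node
#'
#' Pearson chi-square on the 2x2 arm x outcome table (1 df, no continuity
#' correction), computed from the node's arm counts. A zero row or column
#' margin makes the table degenerate; the test then returns statistic 0 and
#' p = 1 with a degenerate flag instead of failing.
#'
#' @param stats Node statistics (\code{n_t}, \code{n_c}, \code{s_t},
#'   \code{s_c}).
#' @return List with \code{statistic}, \code{p_value}, \code{degenerate}.
#' @export
node_chi_square <- function(stats) {
  a <- stats$s_t; b <- stats$n_t - stats$s_t
  c_ <- stats$s_c; d <- stats$n_c - stats$s_c
  n <- a + b + c_ + d
  m <- c(a + b, c_ + d, a + c_, b + d)   # row and column margins
  if (any(m == 0))
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  stat <- n * (a * d - b * c_)^2 / prod(m)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

# Merge conditions on the same feature into a single interval / level set.
# On a root-to-node path, same-feature numeric conditions tighten one
# another (">= 70" then ">= 80" becomes ">= 80"; ">= 70" then "< 147"
# becomes the interval) and categorical level sets are nested intersections.
merge_conditions <- function(conds) {
  feats <- vapply(conds, `[[`, "", "feature")
  out <- list()
  for (nm in unique(feats)) {
    cs <- conds[feats == nm]
    if (cs[[1L]]$op == "in") {
      lv <- Reduce(intersect, lapply(cs, `[[`, "value"))
      if (length(lv) == 0L) return(NULL)     # contradictory path
      out <- c(out, list(split_condition(nm, "in", sort(lv),
                                         all_levels = cs[[1L]]$all_levels)))
    } else {
      lo <- suppressWarnings(max(vapply(cs[vapply(cs, `[[`, "", "op") == ">="],
                                        `[[`, 0, "value")))
      hi <- suppressWarnings(min(vapply(cs[vapply(cs, `[[`, "", "op") == "<"],
                                        `[[`, 0, "value")))
      if (is.finite(lo) && is.finite(hi) && lo >= hi) return(NULL)
      if (is.finite(lo)) out <- c(out, list(split_condition(nm, ">=", lo)))
      if (is.finite(hi)) out <- c(out, list(split_condition(nm, "<", hi)))
    }
  }
  out
}

# Negate one split condition (used when descending into a left child).
negate_condition <- function(cond) {
  switch(cond$op,
         "<"  = split_condition(cond$feature, ">=", cond$value),
         ">=" = split_condition(cond$feature, "<", cond$value),
         "in" = {
           lv <- setdiff(cond$all_levels, cond$value)
           split_condition(cond$feature, "in", lv, all_levels = cond$all_levels)
         })
}

#' Flatten a forest into significant candidate rules
#'
#' Every non-root node of every tree yields the conjunction of split
#' conditions from root to that node. Nodes whose arm-by-outcome chi-square
#' is significant at \code{alpha} are retained; same-feature conditions are
#' merged into intervals, exact duplicates (identical merged condition sets)
#' are collapsed keeping the first provenance, and supports are computed on
#' the reference dataset.
#'
#' @param forest An \code{uplift_forest}.
#' @param alpha Significance level for the per-node chi-square test.
#' @param reference A \code{trial_dataset} (or covariate data frame) on which
#'   rule supports are evaluated.
#' @return A list of rules (class \code{uplift_rules}); each rule carries
#'   \code{conditions}, \code{provenance} (tree, depth), \code{statistic},
#'   \code{p_value}, \code{node_tau}, \code{support_n}, \code{support}.
#' @export
extract_rules <- function(forest, alpha = 0.05, reference) {
  x_ref <- if (inherits(reference, "trial_dataset")) reference$x else reference
  rules <- list()
  seen <- character()
  for (ti in seq_along(forest$trees)) {
    walk <- function(node, path, node_id) {
      if (length(path) > 0L) {      # non-root
        cs <- node_chi_square(node$stats)
        if (!cs$degenerate && cs$p_value < alpha) {
          merged <- merge_conditions(path)
          if (!is.null(merged)) {
            key <- rule_key(merged)
            if (!key %in% seen) {
              seen <<- c(seen, key)
              rules[[length(rules) + 1L]] <<- list(
                conditions = merged,
                description = describe_rule(merged),
                provenance = list(tree = ti, node = node_id, depth = length(path)),
                statistic = cs$statistic,
                p_value = cs$p_value,
                node_tau = node$tau)
            }
          }
        }
      }
      if (!is.null(node$split)) {
        walk(node$left, c(path, list(negate_condition(node$split))), node_id * 2L)
        walk(node$right, c(path, list(node$split)), node_id * 2L + 1L)
      }
    }
    walk(forest$trees[[ti]], list(), 1L)
  }
  if (length(rules)) {
    m <- rule_matrix(rules, x_ref)
    for (i in seq_along(rules)) {
      rules[[i]]$support_n <- sum(m[, i])
      rules[[i]]$support <- mean(m[, i])
    }
  }
  structure(rules, class = "uplift_rules")
}

#' @export
print.uplift_rules <- function(x, ...) {
  cat(sprintf("<uplift_rules> %d rules\n", length(x)))
  for (r in utils::head(x, 10L))
    cat(sprintf("  [p=%.3g, s=%.3f] %s\n", r$p_value, r$support %||% NA, r$description))
  if (length(x) > 10L) cat(sprintf("  ... and %d more\n", length(x) - 10L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary rule design matrix
#'
#' Entry (i, m) is 1 iff subject i satisfies every condition of rule m
#' (thresholds are inclusive on \code{>=}, exclusive on \code{<}).
#'
#' @param rules A list of rules (each with a \code{conditions} element).
#' @param x Covariate data frame.
#' @return An n x M 0/1 matrix with rule descriptions as column names and a
#'   \code{"supports"} attribute (column means).
#' @export
rule_matrix <- function(rules, x) {
  if (inherits(x, "trial_dataset")) x <- x$x
  if (length(rules) == 0L) {
    m <- matrix(0, nrow(x), 0)
    attr(m, "supports") <- numeric(0)
    return(m)
  }
  m <- vapply(rules, function(r) as.numeric(eval_conditions(r$conditions, x)),
              numeric(nrow(x)))
  m <- matrix(m, nrow = nrow(x))
  colnames(m) <- vapply(rules, function(r) r$description %||% describe_rule(r$conditions), "")
  attr(m, "supports") <- colMeans(m)
  m
}
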