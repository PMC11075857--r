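#' Create a single decision boundary
#'
#' A split condition is one decision boundary on a covariate: \code{x < t} or
#' \code{x >= t} for continuous/binary features, or \code{x in S} for a
#' categorical level set. Conjunctions of conditions form rules.
#'
#' @param feature Covariate name.
#' @param op One of \code{"<"}, \code{">="}, \code{"in"}.
#' @param value Numeric threshold (finite) or character level set (non-empty).
#' @param all_levels For categorical conditions, the feature's full declared
#'   level set (used to render complements compactly).
#' @return A \code{split_condition} list.
#' @export
split_condition <- function(feature, op, value, all_levels = NULL) {
  op <- match.arg(op, c("<", ">=", "in"))
  if (op == "in") {
    value <- as.character(value)
    if (length(value) == 0L) stop_validation("categorical level set must be non-empty")
    if (!is.null(all_levels) && !all(value %in% all_levels))
      stop_validation("level set for '%s' outside declared levels", feature)
  } else {
    value <- as.numeric(value)
    if (!is.finite(value)) stop_validation("split threshold must be finite")
  }
  structure(list(feature = feature, op = op, value = value,
                 all_levels = all_levels),
            class = "split_condition")
}

eval_condition <- function(cond, x) {
  v <- x[[cond$feature]]
  if (is.null(v)) stop_schema("condition references unknown feature '%s'", cond$feature)
  out <- switch(cond$op,
                "<"  = v < cond$value,
                ">=" = v >= cond$value,
                "in" = as.character(v) %in% cond$value)
  out & !is.na(out)
}

# Conjunction membership: logical vector of subjects satisfying all conditions.
eval_conditions <- function(conds, x) {
  m <- rep(TRUE, nrow(x))
  for (cond in conds) m <- m & eval_condition(cond, x)
  m
}

describe_condition <- function(cond) {
  if (cond$op == "in") {
    lv <- cond$all_levels
    if (!is.null(lv) && length(cond$value) == length(lv) - 1L) {
      out_level <- setdiff(lv, cond$value)
      return(sprintf("%s not in {%s}", cond$feature, paste(out_level, collapse = ", ")))
    }
    return(sprintf("%s in {%s}", cond$feature, paste(cond$value, collapse = ", ")))
  }
  sprintf("%s %s %s", cond$feature, cond$op, format(cond$value))
}

#' Render a conjunction of split conditions
#' @param conds List of \code{split_condition}s.
#' @return A single description string, e.g. \code{"DBP >= 70 and SBP < 215"}.
#' @export
describe_rule <- function(conds) {
  paste(vapply(conds, describe_condition, ""), collapse = " and ")
}

condition_key <- function(cond) {
  val <- if (cond$op == "in") paste(sort(cond$value), collapse = "|")
         else format(cond$value, digits = 15)
  paste(cond$feature, cond$op, val, sep = "\r")
}

rule_key <- function(conds) {
  paste(sort(vapply(conds, condition_key, "")), collapse = "\n")
}
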