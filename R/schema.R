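#' Define a feature schema for subject-level trial tables
#'
#' A schema declares, for every column of a trial table, its name, kind
#' (\code{"continuous"}, \code{"binary"} or \code{"categorical"}), its role
#' (\code{"covariate"}, \code{"treatment"}, \code{"outcome"}, \code{"id"} or
#' \code{"source"}), the closed level set for categoricals, and per-feature
#' transform flags (log-transform with optional shift, z-normalization).
#' Exactly one treatment and one outcome column are required.
#'
#' @param features A list; each element is a list with fields \code{name},
#'   \code{kind}, \code{role}, and optionally \code{levels} (character vector,
#'   required for categoricals), \code{log} (logical), \code{znorm} (logical),
#'   \code{shift} (numeric, added before the log).
#' @return An object of class \code{feature_schema}.
#' @export
feature_schema <- function(features) {
  if (!is.list(features) || length(features) == 0L)
    stop_schema("schema must be a non-empty list of feature definitions")
  kinds <- c("continuous", "binary", "categorical")
  roles <- c("covariate", "treatment", "outcome", "id", "source")
  feats <- lapply(features, function(f) {
    if (is.null(f$name) || !nzchar(f$name))
      stop_schema("every schema feature needs a name")
    f$kind <- match.arg(f$kind, kinds)
    f$role <- if (is.null(f$role)) "covariate" else match.arg(f$role, roles)
    f$log <- isTRUE(f$log)
    f$znorm <- isTRUE(f$znorm)
    f$shift <- if (is.null(f$shift)) 0 else as.numeric(f$shift)
    if (f$kind == "categorical") {
      if (is.null(f$levels) || length(f$levels) < 2L)
        stop_schema("categorical feature '%s' must enumerate >= 2 levels", f$name)
      f$levels <- as.character(f$levels)
      if (anyDuplicated(f$levels))
        stop_schema("duplicate levels for feature '%s'", f$name)
    } else {
      f$levels <- NULL
    }
    f
  })
  nm <- vapply(feats, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop_schema("feature '%s' declared twice", nm[duplicated(nm)][1L])
  names(feats) <- nm
  rl <- vapply(feats, `[[`, "", "role")
  if (sum(rl == "treatment") != 1L)
    stop_schema("schema must declare exactly one treatment column")
  if (sum(rl == "outcome") != 1L)
    stop_schema("schema must declare exactly one outcome column")
  structure(list(features = feats), class = "feature_schema")
}

schema_names <- function(schema, role = NULL) {
  f <- schema$features
  if (!is.null(role)) {
    f <- f[vapply(f, `[[`, "", "role") %in% role]
  }
  vapply(f, `[[`, "", "name")
}

covariate_names <- function(schema) unname(schema_names(schema, "covariate"))
treatment_name <- function(schema) unname(schema_names(schema, "treatment"))
outcome_name <- function(schema) unname(schema_names(schema, "outcome"))

schema_feature <- function(schema, name) {
  f <- schema$features[[name]]
  if (is.null(f)) stop_schema("unknown feature '%s'", name)
  f
}

schema_kind <- function(schema, name) schema_feature(schema, name)$kind
schema_levels <- function(schema, name) schema_feature(schema, name)$levels

#' Read or write a feature schema as YAML
#'
#' The YAML sidecar has a top-level \code{features} sequence (fields as in
#' \code{\link{feature_schema}}) and optionally an \code{eligibility} sequence
#' of predicates (\code{feature}, \code{op}, \code{value}).
#'
#' @param path File path.
#' @return \code{read_schema} returns a list with elements \code{schema} and
#'   \code{eligibility} (possibly \code{NULL}).
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop_config("schema file '%s' not found", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$features)) stop_schema("schema YAML lacks a 'features' block")
  elig <- NULL
  if (!is.null(doc$eligibility)) {
    elig <- lapply(doc$eligibility, function(p)
      list(feature = p$feature, op = p$op, value = p$value))
  }
  list(schema = feature_schema(doc$features), eligibility = elig)
}

#' @rdname read_schema
#' @param schema A \code{feature_schema}.
#' @param eligibility Optional list of eligibility predicates.
#' @export
write_schema <- function(schema, path, eligibility = NULL) {
  feats <- lapply(unname(schema$features), function(f) {
    out <- list(name = f$name, kind = f$kind, role = f$role)
    if (!is.null(f$levels)) out$levels <- f$levels
    if (f$log) out$log <- TRUE
    if (f$znorm) out$znorm <- TRUE
    if (f$shift != 0) out$shift <- f$shift
    out
  })
  doc <- list(features = feats)
  if (!is.null(eligibility)) doc$eligibility <- eligibility
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d features\n", length(x$features)))
  for (f in x$features) {
    cat(sprintf("  %-16s %-12s %-10s%s\n", f$name, f$kind, f$role,
                if (!is.null(f$levels)) paste0(" {", paste(f$levels, collapse = ","), "}") else ""))
  }
  invisible(x)
}
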