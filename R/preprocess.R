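#' Binarize a modified Rankin Scale (mRS) outcome
#'
#' The 0-6 post-stroke disability score is dichotomized at functional
#' independence: 1 if the score is 2 or less, 0 otherwise. Y = 1 is the
#' favorable outcome, so responsive subgroups have positive treatment effect.
#'
#' @param mrs_scores Integer vector with values in 0..6.
#' @return Integer 0/1 vector.
#' @export
binarize_mrs <- function(mrs_scores) {
  s <- mrs_scores
  if (anyNA(s) || any(s != round(s)) || any(s < 0 | s > 6))
    stop_validation("mRS scores must be integers in 0..6")
  as.integer(s <= 2)
}

#' Derive mean arterial pressure and pulse pressure
#'
#' Appends MAP = SBP/3 + DBP*2/3 and PP = SBP - DBP as continuous covariates;
#' the original blood-pressure columns are left unchanged.
#'
#' @param ds A \code{trial_dataset} whose schema includes continuous SBP and
#'   DBP features.
#' @param sbp,dbp Column names of the systolic and diastolic pressures.
#' @return The dataset with two extra covariates (\code{MAP}, \code{PP}) and
#'   an extended schema.
#' @export
derive_bp_features <- function(ds, sbp = "SBP", dbp = "DBP") {
  covs <- names(ds$x)
  if (!sbp %in% covs || !dbp %in% covs)
    stop_schema("derive_bp_features requires covariates '%s' and '%s'", sbp, dbp)
  x <- ds$x
  x$MAP <- x[[sbp]] / 3 + x[[dbp]] * 2 / 3
  x$PP <- x[[sbp]] - x[[dbp]]
  feats <- unname(ds$schema$features)
  feats <- c(feats,
             list(list(name = "MAP", kind = "continuous", role = "covariate"),
                  list(name = "PP", kind = "continuous", role = "covariate")))
  trial_dataset(x, ds$treatment, ds$outcome, feature_schema(feats),
                id = ds$id, source = ds$source)
}

#' Log-transform and z-normalize flagged covariates
#'
#' Features flagged \code{log} in the schema are log-transformed (after adding
#' the configured \code{shift}); features flagged \code{znorm} are centered
#' and scaled. The transformation parameters (per-feature means and SDs,
#' computed after any log step) are recorded so held-out data can be
#' transformed with the training parameters via the \code{params} argument.
#' Re-transforming an already-preprocessed dataset is rejected.
#'
#' @param ds A \code{trial_dataset}.
#' @param params Parameters returned by a previous call (as
#'   \code{attr(out, "preprocess_params")}); if \code{NULL}, parameters are
#'   estimated from \code{ds}.
#' @return The transformed dataset, with attribute \code{preprocess_params}.
#' @export
preprocess <- function(ds, params = NULL) {
  if (isTRUE(attr(ds, "preprocessed")))
    stop_validation("dataset is already preprocessed; transforms are not reapplied")
  x <- ds$x
  fit <- is.null(params)
  if (fit) params <- list()
  for (f in ds$schema$features) {
    if (f$role != "covariate" || f$kind != "continuous") next
    if (!f$log && !f$znorm) next
    v <- x[[f$name]]
    if (f$log) {
      if (any(v + f$shift <= 0, na.rm = TRUE))
        stop_validation("feature '%s': non-positive values under log transform (shift = %g)",
                        f$name, f$shift)
      v <- log(v + f$shift)
    }
    if (f$znorm) {
      if (fit) {
        params[[f$name]] <- list(mean = mean(v, na.rm = TRUE),
                                 sd = stats::sd(v, na.rm = TRUE))
      }
      p <- params[[f$name]]
      if (is.null(p))
        stop_validation("no stored preprocessing parameters for feature '%s'", f$name)
      if (!is.finite(p$sd) || p$sd <= 0)
        stop_validation("feature '%s' has zero/undefined SD; cannot z-normalize", f$name)
      v <- (v - p$mean) / p$sd
    }
    x[[f$name]] <- v
  }
  out <- trial_dataset(x, ds$treatment, ds$outcome, ds$schema,
                       id = ds$id, source = ds$source)
  attr(out, "preprocessed") <- TRUE
  attr(out, "preprocess_params") <- params
  out
}

#' Filter subjects by eligibility criteria
#'
#' Criteria are a conjunctive list of predicates over schema covariates; each
#' predicate is a list with \code{feature}, \code{op} (one of \code{"<"},
#' \code{"<="}, \code{">"}, \code{">="}, \code{"=="}, \code{"in"},
#' \code{"not_in"}) and \code{value}. Row order is preserved; the number of
#' removed subjects is reported.
#'
#' @param ds A \code{trial_dataset}.
#' @param criteria List of predicates (may be empty or \code{NULL}).
#' @return The filtered \code{trial_dataset}.
#' @export
apply_eligibility <- function(ds, criteria) {
  if (is.null(criteria) || length(criteria) == 0L) return(ds)
  keep <- rep(TRUE, n_subjects(ds))
  for (p in criteria) {
    if (is.null(p$feature) || !p$feature %in% names(ds$x))
      stop_schema("eligibility predicate references unknown feature '%s'",
                  if (is.null(p$feature)) "<missing>" else p$feature)
    v <- ds$x[[p$feature]]
    ok <- switch(p$op,
                 "<"  = v < p$value,
                 "<=" = v <= p$value,
                 ">"  = v > p$value,
                 ">=" = v >= p$value,
                 "==" = v == p$value,
                 "in" = v %in% p$value,
                 "not_in" = !v %in% p$value,
                 stop_config("unknown eligibility comparator '%s'", p$op))
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  removed <- sum(!keep)
  if (removed > 0)
    message(sprintf("apply_eligibility: removed %d of %d subjects", removed, length(keep)))
  if (!any(keep)) stop_validation("eligibility criteria removed every subject")
  subset_dataset(ds, which(keep))
}

#' Median/mode baseline imputer
#'
#' A deterministic imputer: continuous covariates get the observed median,
#' categorical (and binary) covariates the observed mode, computed on the
#' training partition. Returned as a fit/transform pair so alternative
#' imputers (e.g. chained-equation methods) can be plugged in with the same
#' contract.
#'
#' @return A list with functions \code{fit(ds)} -> params and
#'   \code{transform(ds, params)} -> dataset.
#' @export
median_mode_imputer <- function() {
  list(
    fit = function(ds) {
      params <- list()
      for (f in ds$schema$features) {
        if (f$role != "covariate") next
        v <- ds$x[[f$name]]
        obs <- v[!is.na(v)]
        if (length(obs) == 0L)
          stop_validation("feature '%s' is 100%% missing; cannot impute", f$name)
        params[[f$name]] <- if (f$kind == "continuous") {
          stats::median(obs)
        } else {
          tab <- sort(table(obs), decreasing = TRUE)
          names(tab)[1L]
        }
      }
      params
    },
    transform = function(ds, params) {
      x <- ds$x
      for (nm in names(params)) {
        v <- x[[nm]]
        if (anyNA(v)) {
          fill <- params[[nm]]
          if (is.numeric(v)) fill <- as.numeric(fill)
          v[is.na(v)] <- fill
          x[[nm]] <- v
        }
      }
      out <- trial_dataset(x, ds$treatment, ds$outcome, ds$schema,
                           id = ds$id, source = ds$source)
      attr(out, "impute_params") <- params
      out
    }
  )
}

#' Impute missing baseline covariates
#'
#' @param ds A \code{trial_dataset} (missingness only in covariates).
#' @param imputer An imputer interface as returned by
#'   \code{\link{median_mode_imputer}}.
#' @param params Optional previously fitted imputation parameters (to apply
#'   training-partition values to held-out data).
#' @return Dataset with no missing covariates; attribute
#'   \code{impute_params} holds the fitted parameters.
#' @export
impute_baseline <- function(ds, imputer = median_mode_imputer(), params = NULL) {
  if (is.null(params)) params <- imputer$fit(ds)
  imputer$transform(ds, params)
}
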