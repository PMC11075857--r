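#' Construct a trial dataset
#'
#' The container for subject-level data: a covariate table typed by a
#' \code{\link{feature_schema}}, a binary treatment indicator, a binary
#' outcome, and a per-subject source label (\code{"rct"}, \code{"historical"}
#' or \code{"synthetic"}). Historical rows must be controls (T = 0);
#' covariates may carry missing values until imputed, treatment and outcome
#' never.
#'
#' @param x Data frame of covariates (columns must match the schema's
#'   covariate features).
#' @param treatment Integer/numeric vector in \{0, 1\}.
#' @param outcome Integer/numeric vector in \{0, 1\}.
#' @param schema A \code{feature_schema}.
#' @param id Optional subject ids (default \code{seq_len(n)}).
#' @param source Character vector or scalar in
#'   \{"rct", "historical", "synthetic"\}.
#' @return An object of class \code{trial_dataset}.
#' @export
trial_dataset <- function(x, treatment, outcome, schema, id = NULL,
                          source = "rct") {
  n <- nrow(x)
  if (is.null(n) || n < 1L) stop_validation("a trial dataset needs n >= 1 subjects")
  covs <- covariate_names(schema)
  missing_cols <- setdiff(covs, names(x))
  if (length(missing_cols))
    stop_schema("covariate columns missing from data: %s",
                paste(missing_cols, collapse = ", "))
  x <- x[covs]
  if (length(treatment) != n || length(outcome) != n)
    stop_validation("treatment/outcome length must equal nrow(x)")
  if (anyNA(treatment) || anyNA(outcome))
    stop_validation("treatment and outcome must contain no missing values")
  bad_t <- which(!treatment %in% c(0, 1))
  if (length(bad_t))
    stop_validation("treatment must be 0/1; offending row(s): %s",
                    paste(utils::head(bad_t, 5L), collapse = ", "))
  bad_y <- which(!outcome %in% c(0, 1))
  if (length(bad_y))
    stop_validation("outcome must be 0/1; offending row(s): %s",
                    paste(utils::head(bad_y, 5L), collapse = ", "))
  if (length(source) == 1L) source <- rep(source, n)
  if (!all(source %in% c("rct", "historical", "synthetic")))
    stop_validation("source labels must be rct/historical/synthetic")
  if (any(source == "historical" & treatment == 1))
    stop_validation("historical subjects must be controls (T = 0)")
  # type-check covariates against the schema
  for (nm in covs) {
    f <- schema$features[[nm]]
    if (f$kind == "categorical") {
      v <- as.character(x[[nm]])
      bad <- !is.na(v) & !v %in% f$levels
      if (any(bad))
        stop_validation("feature '%s' has value(s) outside declared levels: %s",
                        nm, paste(unique(v[bad])[1:min(3, sum(bad))], collapse = ", "))
      x[[nm]] <- v
    } else {
      if (!is.numeric(x[[nm]]))
        x[[nm]] <- suppressWarnings(as.numeric(x[[nm]]))
    }
  }
  if (is.null(id)) id <- seq_len(n)
  structure(list(x = x,
                 id = id,
                 treatment = as.integer(treatment),
                 outcome = as.integer(outcome),
                 source = as.character(source),
                 schema = schema),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> n=%d (treated %d, control %d) | sources: %s\n",
              n_subjects(x), sum(x$treatment == 1), sum(x$treatment == 0),
              paste(sprintf("%s=%d", names(table(x$source)), table(x$source)),
                    collapse = ", ")))
  cat(sprintf("  covariates: %s\n", paste(names(x$x), collapse = ", ")))
  invisible(x)
}

#' Number of subjects in a trial dataset
#' @param ds A \code{trial_dataset}.
#' @export
n_subjects <- function(ds) nrow(ds$x)

subset_dataset <- function(ds, idx) {
  trial_dataset(ds$x[idx, , drop = FALSE],
                ds$treatment[idx], ds$outcome[idx], ds$schema,
                id = ds$id[idx], source = ds$source[idx])
}

bind_datasets <- function(a, b) {
  trial_dataset(rbind(a$x, b$x),
                c(a$treatment, b$treatment),
                c(a$outcome, b$outcome),
                a$schema,
                id = c(a$id, b$id),
                source = c(a$source, b$source))
}

#' Load a delimited trial table against a schema
#'
#' Reads a CSV with a header row, checks the columns the schema requires,
#' drops (and reports) rows with missing treatment or outcome, and validates
#' the treatment/outcome encodings.
#'
#' @param path CSV file path.
#' @param schema A \code{feature_schema}.
#' @return A \code{trial_dataset}.
#' @export
load_trial_table <- function(path, schema) {
  if (!file.exists(path)) stop_config("trial table '%s' not found", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- treatment_name(schema)
  ycol <- outcome_name(schema)
  required <- c(covariate_names(schema), tcol, ycol)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_schema("input '%s' lacks required column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  drop <- is.na(df[[tcol]]) | is.na(df[[ycol]])
  if (any(drop)) {
    message(sprintf("load_trial_table: dropped %d row(s) with missing treatment/outcome",
                    sum(drop)))
    df <- df[!drop, , drop = FALSE]
  }
  idcol <- schema_names(schema, "id")
  scol <- schema_names(schema, "source")
  trial_dataset(df,
                df[[tcol]], df[[ycol]], schema,
                id = if (length(idcol) && idcol %in% names(df)) df[[idcol]] else NULL,
                source = if (length(scol) && scol %in% names(df)) df[[scol]] else "rct")
}

#' Write a trial dataset to CSV
#'
#' @param ds A \code{trial_dataset}.
#' @param path Output file path.
#' @export
write_trial_table <- function(ds, path) {
  tcol <- treatment_name(ds$schema)
  ycol <- outcome_name(ds$schema)
  df <- cbind(data.frame(id = ds$id), ds$x)
  df[[tcol]] <- ds$treatment
  df[[ycol]] <- ds$outcome
  df$source <- ds$source
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
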