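#' Assemble a pipeline configuration
#'
#' Collects every stage's settings in one list: data sources (simulation
#' config or file paths), the augmentation block, forest growth parameters,
#' rule-selection settings, and evaluation settings. Defaults follow the
#' package's standard analysis: tree depth 3, node minimums 100/25, alpha
#' 0.05, caliper 0.2 SD, 500 + 500 synthetic subjects, 4-fold
#' cross-validation, 30-seed repetition.
#'
#' @param sim A \code{\link{sim_config}} (used when no paths are given).
#' @param rct_path,pool_path,schema_path Optional CSV/YAML inputs replacing
#'   the simulator.
#' @param augment List: \code{enabled}, \code{historical}, \code{synthetic},
#'   \code{caliper_sd}, \code{n_treated}, \code{n_control}, \code{alpha}
#'   (elastic-net mixing).
#' @param forest Forest growth parameters (see \code{\link{forest_params}}).
#' @param selection List: \code{alpha} (rule significance level),
#'   \code{lambda} (\code{NULL} = cross-validated), \code{threshold},
#'   \code{value}, \code{top_k}.
#' @param evaluation List: \code{test_n} held-out real subjects, \code{cv_k}
#'   folds, \code{n_seeds} repetitions.
#' @param seed Master seed.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            rct_path = NULL, pool_path = NULL,
                            schema_path = NULL,
                            augment = list(),
                            forest = list(),
                            selection = list(),
                            evaluation = list(),
                            seed = 1) {
  aug <- utils::modifyList(list(enabled = TRUE, historical = TRUE,
                                synthetic = TRUE, caliper_sd = 0.2,
                                n_treated = 500, n_control = 500,
                                alpha = 0.5), augment)
  sel <- utils::modifyList(list(alpha = 0.05, lambda = NULL,
                                threshold = "importance", value = 0.002,
                                top_k = 5), selection)
  ev <- utils::modifyList(list(test_n = 200, cv_k = 4, n_seeds = 30),
                          evaluation)
  fp <- utils::modifyList(forest_params(), forest)
  if (fp$max_depth < 1) stop_config("max_depth must be >= 1")
  if (sel$alpha <= 0 || sel$alpha >= 1) stop_config("alpha must lie in (0, 1)")
  structure(list(sim = sim, rct_path = rct_path, pool_path = pool_path,
                 schema_path = schema_path, augment = aug, forest = fp,
                 selection = sel, evaluation = ev, seed = as.integer(seed)),
            class = "pipeline_config")
}

# One end-to-end run at a given seed; shared by repeat_experiment and
# run_pipeline. Held-out evaluation always uses real RCT rows only
# (augmented rows are used in training exclusively).
run_single_experiment <- function(config, seed = config$seed,
                                  return_objects = FALSE) {
  inputs <- pipeline_inputs(config, seed)
  rct <- inputs$rct
  set.seed(seed + 10000L)
  test_idx <- sample(n_subjects(rct), min(config$evaluation$test_n,
                                          floor(n_subjects(rct) / 2)))
  test_ds <- subset_dataset(rct, test_idx)
  train_rct <- subset_dataset(rct, setdiff(seq_len(n_subjects(rct)), test_idx))

  train <- train_rct
  balance <- NULL
  if (isTRUE(config$augment$enabled)) {
    if (isTRUE(config$augment$historical) && !is.null(inputs$pool)) {
      train <- borrow_historical(train, inputs$pool,
                                 criteria = inputs$eligibility,
                                 caliper_sd = config$augment$caliper_sd,
                                 alpha = config$augment$alpha, seed = seed)
      balance <- attr(train, "balance")
    }
    if (isTRUE(config$augment$synthetic)) {
      synth <- generate_synthetic(train,
                                  n_treated = config$augment$n_treated,
                                  n_control = config$augment$n_control,
                                  seed = seed + 20000L)
      train <- match_synthetic(train, synth,
                               caliper_sd = config$augment$caliper_sd,
                               alpha = config$augment$alpha, seed = seed)
      balance <- c(balance %||% list(), list(synthetic = attr(train, "balance")))
    }
  }

  fp <- config$forest
  fp$seed <- seed
  forest <- grow_forest(train, fp)
  tau_hat <- predict_tau(forest, train, oob = TRUE)
  rules <- extract_rules(forest, alpha = config$selection$alpha,
                         reference = train)
  model <- fit_rule_model(tau_hat, rules, train,
                          lambda = config$selection$lambda,
                          cv_folds = config$evaluation$cv_k, seed = seed)
  report <- rank_and_select(model, threshold = config$selection$threshold,
                            value = config$selection$value,
                            top_k = config$selection$top_k,
                            ds_test = test_ds)
  qini_forest <- qini_score(forest, test_ds)
  qini_rules <- qini_curve(test_ds$outcome, test_ds$treatment,
                           predict(model, test_ds))$coefficient
  imp <- model$importance_rules
  out <- list(qini_forest = qini_forest, qini_rules = qini_rules,
              n_significant = length(rules),
              n_nonzero = sum(model$a != 0),
              n_coef_gt = sum(abs(model$a) > 0.005),
              n_imp_gt = sum(model$a != 0 & imp > 0.002),
              report = report, balance = balance, seed = seed)
  if (return_objects) {
    out$forest <- forest
    out$model <- model
    out$rules <- rules
    out$train <- train
    out$test <- test_ds
    out$truth <- inputs$truth
  }
  out
}

pipeline_inputs <- function(config, seed) {
  if (!is.null(config$rct_path)) {
    sc <- read_schema(config$schema_path %||%
                        stop_config("schema_path required with rct_path"))
    rct <- load_trial_table(config$rct_path, sc$schema)
    pool <- if (!is.null(config$pool_path))
      load_trial_table(config$pool_path, sc$schema)
    list(rct = rct, pool = pool, eligibility = sc$eligibility, truth = NULL)
  } else {
    cfg <- config$sim
    cfg$seed <- as.integer(seed)
    sim <- simulate_rct(cfg)
    pool <- if (cfg$n_pool > 0) simulate_observational_pool(cfg)
    list(rct = sim$data, pool = pool, eligibility = NULL, truth = sim$truth)
  }
}

#' Run the full pipeline and write its artifacts
#'
#' Executes simulate/load -> augment -> grow forest -> extract and select
#' rules -> evaluate, and writes to \code{out_dir}: the augmented training
#' table (\code{augmented.csv}), the forest (\code{forest.json}), the
#' selected rules (\code{rules.json}), the subgroup table
#' (\code{subgroups.csv}), balance and Qini reports (JSON), and a run
#' manifest holding the full configuration, seed and package version (so
#' every artifact is re-derivable from the manifest alone). A stage failure
#' raises a classed error naming the stage; artifacts written so far are
#' preserved.
#'
#' @param config A \code{\link{pipeline_config}} (or YAML path understood by
#'   \code{\link{read_pipeline_config}}).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the result list of the run.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- withCallingHandlers(
    run_single_experiment(config, seed = config$seed, return_objects = TRUE),
    error = function(e) if (!inherits(e, "uplift_stage_error"))
      stop_stage("pipeline", conditionMessage(e)))

  write_trial_table(res$train, file.path(out_dir, "augmented.csv"))
  write_forest_json(res$forest, file.path(out_dir, "forest.json"))
  write_rules_json(res$rules, res$model, file.path(out_dir, "rules.json"))
  sub <- rbind(
    if (nrow(res$report$favorable)) cbind(direction = "favorable", res$report$favorable),
    if (nrow(res$report$unfavorable)) cbind(direction = "unfavorable", res$report$unfavorable))
  utils::write.csv(sub, file.path(out_dir, "subgroups.csv"), row.names = FALSE)
  jsonlite::write_json(res$balance %||% list(),
                       file.path(out_dir, "balance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(qini_forest = res$qini_forest,
                            qini_rules = res$qini_rules,
                            n_significant_rules = res$n_significant,
                            n_nonzero = res$n_nonzero),
                       file.path(out_dir, "qini.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "upliftrules",
                   version = as.character(utils::packageVersion("upliftrules")),
                   seed = config$seed,
                   config = serialize_config(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

# Config as a plain list for the manifest (schemas and planted rules
# rendered to primitive fields).
serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) {
    sim <- unclass(cfg$sim)
    sim$schema <- NULL
    sim$planted_rules <- lapply(sim$planted_rules, function(r)
      list(delta = r$delta,
           conditions = lapply(r$conditions, function(cd)
             list(feature = cd$feature, op = cd$op, value = cd$value))))
    cfg$sim <- sim
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level blocks mirror \code{\link{pipeline_config}} arguments
#' (\code{sim}, \code{augment}, \code{forest}, \code{selection},
#' \code{evaluation}, \code{seed}, and optional \code{rct_path} /
#' \code{pool_path} / \code{schema_path}).
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file '%s' not found", path)
  doc <- yaml::read_yaml(path)
  sim <- if (!is.null(doc$sim)) {
    args <- doc$sim
    if (!is.null(args$planted_rules)) {
      args$planted_rules <- lapply(args$planted_rules, function(r)
        list(delta = r$delta,
             conditions = lapply(r$conditions, function(cd)
               split_condition(cd$feature, cd$op, cd$value))))
    }
    if (!is.null(args$beta)) args$beta <- as.numeric(unlist(args$beta))
    if (!is.null(args$shift)) args$shift <- as.numeric(unlist(args$shift))
    do.call(sim_config, args)
  } else {
    sim_config()
  }
  pipeline_config(sim = sim,
                  rct_path = doc$rct_path, pool_path = doc$pool_path,
                  schema_path = doc$schema_path,
                  augment = doc$augment %||% list(),
                  forest = doc$forest %||% list(),
                  selection = doc$selection %||% list(),
                  evaluation = doc$evaluation %||% list(),
                  seed = doc$seed %||% 1)
}

# Rules + model coefficients exported as JSON, mirroring the subgroup table.
write_rules_json <- function(rules, model, path) {
  payload <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    list(description = r$description,
         conditions = lapply(r$conditions, function(cd)
           list(feature = cd$feature, op = cd$op, value = cd$value)),
         provenance = r$provenance,
         statistic = r$statistic, p_value = r$p_value,
         support_n = r$support_n, support = r$support,
         coefficient = model$a[i],
         importance = model$importance_rules[i])
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
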