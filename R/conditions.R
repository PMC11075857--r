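# Classed conditions so callers (and the CLI) can map failures to exit codes:
# config errors -> 2, data validation errors -> 3, stage failures -> 4.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("uplift_config_error", "uplift_error")))
}

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("uplift_schema_error", "uplift_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("uplift_validation_error", "uplift_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("uplift_domain_error", "uplift_error")))
}

stop_stage <- function(stage, parent_msg) {
  stop(errorCondition(sprintf("stage '%s' failed: %s", stage, parent_msg),
                      class = c("uplift_stage_error", "uplift_error")))
}
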