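# JSON round trip for fitted forests: nodes with stats and splits, growth
# parameters, in-bag indices. Numeric precision is preserved (digits = NA).

node_to_list <- function(node) {
  out <- list(stats = node$stats[c("n_t", "n_c", "s_t", "s_c")],
              depth = node$depth, tau = node$tau)
  if (!is.null(node$split)) {
    out$split <- list(feature = node$split$feature, op = node$split$op,
                      value = node$split$value,
                      all_levels = node$split$all_levels)
    out$gain <- node$gain
    out$left <- node_to_list(node$left)
    out$right <- node_to_list(node$right)
  }
  out
}

node_from_list <- function(lst) {
  st <- lst$stats
  st$n_t <- as.integer(st$n_t); st$n_c <- as.integer(st$n_c)
  st$s_t <- as.integer(st$s_t); st$s_c <- as.integer(st$s_c)
  st$p_t <- (st$s_t + 0.5) / (st$n_t + 1)
  st$p_c <- (st$s_c + 0.5) / (st$n_c + 1)
  node <- list(stats = st, depth = as.integer(lst$depth), tau = lst$tau,
               split = NULL, left = NULL, right = NULL)
  if (!is.null(lst$split)) {
    node$split <- split_condition(lst$split$feature, lst$split$op,
                                  unlist(lst$split$value),
                                  all_levels = unlist(lst$split$all_levels))
    node$gain <- lst$gain
    node$left <- node_from_list(lst$left)
    node$right <- node_from_list(lst$right)
  }
  node
}

#' Serialize / restore an uplift forest as JSON
#'
#' @param forest An \code{uplift_forest}.
#' @param path Output (or input) JSON file path.
#' @return \code{write_forest_json} invisibly returns the path;
#'   \code{read_forest_json} returns the restored \code{uplift_forest}.
#' @export
write_forest_json <- function(forest, path) {
  payload <- list(
    params = forest$params,
    n_train = forest$n_train,
    weights = forest$weights,
    in_bag = forest$in_bag,
    schema = lapply(unname(forest$schema$features), function(f)
      f[!vapply(f, is.null, TRUE)]),
    trees = lapply(forest$trees, node_to_list)
  )
  # 17 significant digits: exact round trip for IEEE doubles, so split
  # thresholds that coincide with data values never flip a boundary subject
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_forest_json
#' @export
read_forest_json <- function(path) {
  payload <- jsonlite::read_json(path)
  params <- payload$params
  params$seed <- as.integer(params$seed)
  feats <- lapply(payload$schema, function(f) {
    f$levels <- if (!is.null(f$levels)) unlist(f$levels)
    f
  })
  structure(list(
    trees = lapply(payload$trees, node_from_list),
    in_bag = lapply(payload$in_bag, function(v) as.integer(unlist(v))),
    weights = as.numeric(unlist(payload$weights)),
    params = params,
    n_train = as.integer(payload$n_train),
    schema = feature_schema(feats)
  ), class = "uplift_forest")
}
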