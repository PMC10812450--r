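#' Configuration for an end-to-end modelling run
#'
#' Defaults mirror the study settings: the shipped fixture tables, a
#' 70/15/15 data split, 20 candidate networks with 5 retained, and unit
#' desirability weights with concentrations maximised and IC50s minimised.
#'
#' @param output_dir Directory for run artifacts (`NULL` = no files).
#' @param split_fractions Train/validation/test fractions.
#' @param seed Master seed for the split and the network search.
#' @param n_candidates Candidate networks trained in the search.
#' @param retain Networks retained from the search.
#' @param maxit BFGS iteration cap per network.
#' @param infection_step Grid step (\%) for the infection factor in the
#'   desirability search.
#' @param weights Desirability weights (recycled over the responses).
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(output_dir = NULL,
                       split_fractions = c(0.70, 0.15, 0.15),
                       seed = 1L, n_candidates = 20L, retain = 5L,
                       maxit = 300L, infection_step = 0.5, weights = 1) {
  structure(list(output_dir = output_dir,
                 split_fractions = split_fractions,
                 seed = as.integer(seed),
                 n_candidates = as.integer(n_candidates),
                 retain = as.integer(retain), maxit = as.integer(maxit),
                 infection_step = infection_step, weights = weights),
            class = "run_config")
}

#' Run the full modelling pipeline on the study fixtures
#'
#' Orchestrates ingest, class aggregation, factor coding, the five
#' response-surface fits, the desirability optimisation over realizable
#' harvest conditions, the network architecture search, Garson
#' sensitivity of the top network, and the RSM-versus-ANN comparison.
#'
#' @param config A [run_config()].
#' @param data Study data from [load_study_data()] (or a synthetic
#'   equivalent with the same shape).
#' @return A manifest list with the fitted objects (`rsm_models`,
#'   `optimum`, `search`, `sensitivity`, `report`, ...) plus seeds and,
#'   when `output_dir` is set, paths and md5 hashes of written artifacts.
#' @export
run_pipeline <- function(config = run_config(), data = load_study_data()) {
  stopifnot(inherits(config, "run_config"))
  cond <- data$conditions
  resp <- data$responses
  message("stage ingest: ", nrow(cond), " conditions, ",
          nrow(data$measurements %||% data.frame()), " measurements")

  coding <- factor_coding(cond)
  X <- code_factors(cond, coding)
  resp_names <- intersect(straw_responses(), names(resp))
  rsm_models <- lapply(stats::setNames(resp_names, resp_names), function(r) {
    rsm_fit(X, resp[[r]], response = r)
  })
  message("stage fit-rsm: ", length(rsm_models), " responses fitted")

  spec <- desirability_spec(resp_names, weights = config$weights, data = resp)
  grid <- list(
    X1 = unique(X[, "X1"]),
    X2 = unique(X[, "X2"]),
    X3 = unique(X[, "X3"]),
    X4 = code_affine(seq(coding$infection[1L], coding$infection[2L],
                         by = config$infection_step),
                     coding$infection, "infection level"),
    X5 = unique(X[, "X5"])
  )
  optimum <- optimize_desirability(rsm_models, spec, grid, coding = coding)
  message(sprintf("stage optimize: D = %.3f over %d candidates",
                  optimum$D, optimum$n_grid))

  feats <- expand_inputs(cond)
  y <- as.matrix(resp[, resp_names, drop = FALSE])
  complete <- stats::complete.cases(y)
  split <- split_data(sum(complete), config$split_fractions,
                      seed = config$seed)
  search <- mlp_search(feats$features[complete, , drop = FALSE],
                       y[complete, , drop = FALSE], split,
                       retain = config$retain, seed = config$seed,
                       maxit = config$maxit)
  message("stage search: retained ",
          paste(vapply(search$retained, function(f) f$architecture$name,
                       character(1)), collapse = ", "))

  sensitivity <- garson_importance(search$retained[[1L]], map = feats$map)
  report <- comparison_report(
    rsm_models, search$retained, feats$features[complete, , drop = FALSE],
    X[complete, , drop = FALSE],
    resp[complete, resp_names, drop = FALSE], split = split,
    partitions = c("full", "train", "validation", "test"))
  message("stage compare: ", nrow(report), " report rows")

  manifest <- list(
    package_version = as.character(utils::packageVersion("strawpoly")),
    seed = config$seed,
    n_conditions = nrow(cond),
    n_complete = sum(complete),
    responses = resp_names,
    coding = coding, rsm_models = rsm_models, optimum = optimum,
    split = split, search = search, sensitivity = sensitivity,
    report = report, response_table = resp
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    p <- file.path(config$output_dir, "responses.csv")
    write_responses_csv(resp, p); paths <- c(paths, p)
    for (r in resp_names) {
      p <- file.path(config$output_dir, paste0("rsm_", r, ".json"))
      write_rsm_json(rsm_models[[r]], p); paths <- c(paths, p)
    }
    p <- file.path(config$output_dir, "optimum.json")
    jsonlite::write_json(list(
      coded = as.list(optimum$coded),
      condition = optimum$condition,
      predictions = optimum$predictions,
      D = optimum$D), p, auto_unbox = TRUE, digits = NA, na = "null",
      dataframe = "rows")
    paths <- c(paths, p)
    p <- file.path(config$output_dir, "sensitivity.csv")
    utils::write.csv(data.frame(factor = rownames(sensitivity),
                                sensitivity, check.names = FALSE),
                     p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(config$output_dir, "comparison.csv")
    utils::write.csv(report, p, row.names = FALSE); paths <- c(paths, p)
    manifest$artifacts <- data.frame(
      path = paths, md5 = tools::md5sum(paths), row.names = NULL)
    p <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(list(
      package_version = manifest$package_version,
      seed = manifest$seed,
      n_conditions = manifest$n_conditions,
      n_complete = manifest$n_complete,
      responses = manifest$responses,
      artifacts = manifest$artifacts), p, auto_unbox = TRUE, digits = NA)
  }
  manifest
}
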