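#' Specification of a synthetic straw-harvest simulation
#'
#' Describes the generative model the analysis assumes: a known
#' second-order polynomial surface in the five coded harvest factors plus
#' homoscedastic Gaussian noise per response, over a 2-area x 7-date x
#' 2-infection-class design mirroring the study fixtures. Defaults are the
#' study conditions: the published coefficient columns as true
#' coefficients and the published per-response RMSE values as noise SDs,
#' so synthetic fits land in the same fit-quality regime as the real
#' tables. An optional smooth non-polynomial distortion
#' `amplitude * sin(pi * X5) * X1` can be injected to create surfaces a
#' second-order polynomial cannot represent.
#'
#' @param dates Collection dates (default the 7 study dates).
#' @param varieties Variety levels (default the closed 9-variety list).
#' @param areas Area levels.
#' @param infection_levels Numeric infection levels (\%) available to the
#'   design; levels <= 4 form the low-infection class and levels > 4 the
#'   high class, mirroring the sampling plan's 0--4\% and 4--11\% bands.
#'   The default spreads four levels over each band so the quadratic
#'   infection term is identifiable.
#' @param harvests Harvest numbers available to the design.
#' @param beta Matrix of true coefficients (20 terms x responses); default
#'   the published coefficient columns.
#' @param sigma Named noise SD per response, in response units; default the
#'   published RMSE row (7.455, 38.418, 8.948, 0.04, 0.12).
#' @param replicates Copies of the design (default 1 = 28 conditions).
#' @param distortion Amplitude of the non-polynomial distortion (default 0).
#' @param seed Mandatory integer seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(dates = NULL, varieties = straw_varieties(),
                            areas = c("Guariba", "Valparaiso"),
                            infection_levels = c(0.5, 1.5, 2.5, 3.5,
                                                 5, 7, 9, 11),
                            harvests = 1:7,
                            beta = NULL, sigma = NULL,
                            replicates = 1L, distortion = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  dates <- dates %||% as.Date(c("2020-06-04", "2020-07-03", "2020-07-24",
                                "2020-08-08", "2020-09-22", "2020-10-14",
                                "2020-11-16"))
  if (!length(dates) || !length(varieties) || !length(areas) ||
      !length(infection_levels) || !length(harvests)) {
    stop("empty factor level list", call. = FALSE)
  }
  if (is.null(beta)) {
    models <- read_coefficient_models()
    beta <- vapply(models, coef, numeric(20L))
  }
  beta <- as.matrix(beta)
  if (nrow(beta) != length(rsm_terms())) {
    stop("beta must have one row per model term (", length(rsm_terms()), ")",
         call. = FALSE)
  }
  rownames(beta) <- rsm_terms()
  sigma <- sigma %||% stats::setNames(
    c(7.455, 38.418, 8.948, 0.04, 0.12),
    c("hydroxybenzoic", "hydroxycinnamic", "flavones", "abts", "dpph"))
  sigma <- rep_len(sigma, ncol(beta))
  if (any(sigma < 0)) stop("noise SD must be >= 0", call. = FALSE)
  if (is.null(colnames(beta))) {
    colnames(beta) <- names(sigma) %||% paste0("y", seq_len(ncol(beta)))
  }
  names(sigma) <- colnames(beta)
  structure(list(dates = dates, varieties = varieties, areas = areas,
                 infection_levels = infection_levels, harvests = harvests,
                 beta = beta, sigma = sigma,
                 replicates = as.integer(replicates),
                 distortion = distortion, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a deterministic sampling design from a simulation spec
#'
#' One condition per area x date x infection-class combination (28 rows
#' for the default spec), with the numeric infection level cycling through
#' its class's levels and variety and harvest number cycling through their
#' level lists. The design is deterministic: two specs that differ only in
#' seed produce identical designs, and only the simulated responses are
#' stochastic.
#'
#' @param spec A [simulation_spec()].
#' @return Conditions data frame compatible with [code_factors()].
#' @export
simulate_design <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  lows <- spec$infection_levels[spec$infection_levels <= 4]
  highs <- spec$infection_levels[spec$infection_levels > 4]
  classes <- c(if (length(lows)) "low", if (length(highs)) "high")
  g <- expand.grid(infection_class = classes,
                   collection_date = spec$dates,
                   area = spec$areas,
                   stringsAsFactors = FALSE)
  n <- nrow(g)
  cyc <- function(levels, k) levels[(seq_len(k) - 1L) %% length(levels) + 1L]
  g$infection_level <- NA_real_
  g$infection_level[g$infection_class == "low"] <-
    cyc(lows, sum(g$infection_class == "low"))
  g$infection_level[g$infection_class == "high"] <-
    cyc(highs, sum(g$infection_class == "high"))
  g$variety <- cyc(spec$varieties, n)
  g$harvest_number <- cyc(spec$harvests, n)
  if (spec$replicates > 1L) {
    g <- g[rep(seq_len(n), spec$replicates), , drop = FALSE]
  }
  g$sample_id <- sprintf("SIM-%03d", seq_len(nrow(g)))
  rownames(g) <- NULL
  cond <- g[, c("sample_id", "area", "collection_date", "variety",
                "infection_class", "infection_level", "harvest_number")]
  validate_conditions(cond)
  cond
}

#' Simulate class responses from a known polynomial surface
#'
#' `y = D(x) beta + N(0, sigma) + distortion * sigma * sin(pi * X5) * X1`,
#' where `D(x)` is the 20-term design row of the coded condition. The
#' distortion amplitude is expressed in units of each response's noise SD
#' so one amplitude perturbs every response comparably.
#'
#' @param design Conditions from [simulate_design()].
#' @param spec The [simulation_spec()] that generated the design.
#' @param coding Optional `factor_coding`; default built from the design.
#' @return Response table (one column per response) with attributes
#'   `truth` (the spec) and `coded` (the coded factor matrix).
#' @export
simulate_responses <- function(design, spec, coding = factor_coding(design)) {
  X <- code_factors(design, coding)
  D <- build_design_matrix(X, rownames(spec$beta))
  mu <- D %*% spec$beta
  if (spec$distortion != 0) {
    bump <- spec$distortion * sin(pi * X[, "X5"]) * X[, "X1"]
    mu <- mu + outer(bump, spec$sigma)
  }
  noise <- with_seed(spec$seed, {
    matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) %*%
      diag(spec$sigma, ncol(mu))
  })
  y <- mu + noise
  out <- data.frame(sample_id = design$sample_id, y,
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", colnames(spec$beta))
  attr(out, "truth") <- spec
  attr(out, "coded") <- X
  out
}

#' Flag selected response cells as missing
#'
#' Mirrors the not-determined antioxidant rows of the study: the flagged
#' cells become `NA` and are thereby excluded from any model fitted to
#' that response; all other values are untouched.
#'
#' @param table Response table.
#' @param pattern Data frame with columns `sample_id` and `response`; an
#'   empty pattern is the identity.
#' @return The response table with the flagged cells set to `NA`.
#' @export
inject_missingness <- function(table, pattern) {
  if (is.null(pattern) || !nrow(pattern)) return(table)
  unknown <- setdiff(pattern$sample_id, table$sample_id)
  if (length(unknown)) {
    stop("unknown sample(s) in pattern: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad_resp <- setdiff(pattern$response, names(table))
  if (length(bad_resp)) {
    stop("unknown response(s) in pattern: ",
         paste(bad_resp, collapse = ", "), call. = FALSE)
  }
  for (k in seq_len(nrow(pattern))) {
    i <- match(pattern$sample_id[k], table$sample_id)
    table[i, pattern$response[k]] <- NA_real_
  }
  table
}
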