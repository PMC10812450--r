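#' One-sided Derringer desirability of a response value
#'
#' For a maximised response, values at or below `y_min` score 0, values at
#' or above `y_max` score 1, and in between the desirability rises as
#' `((y - y_min) / (y_max - y_min))^weight`. A minimised response mirrors
#' the transform (IC50s are configured this way: a lower IC50 means a
#' stronger antioxidant).
#'
#' @param y Response value(s).
#' @param y_min,y_max Lowest and highest desired levels (`y_min < y_max`).
#' @param weight Positive desirability weight (1 = linear).
#' @param direction `"maximize"` or `"minimize"`.
#' @return Desirability value(s) in \[0, 1\].
#' @export
#' @examples
#' desirability(5, 0, 10)            # 0.5
#' desirability(2, 0, 10, direction = "minimize")
desirability <- function(y, y_min, y_max, weight = 1,
                         direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  if (!is.finite(y_min) || !is.finite(y_max) || y_min >= y_max) {
    stop("need finite y_min < y_max", call. = FALSE)
  }
  if (weight <= 0) stop("weight must be positive", call. = FALSE)
  u <- (y - y_min) / (y_max - y_min)
  if (direction == "minimize") u <- 1 - u
  pmin(pmax(u, 0), 1)^weight
}

#' Composite desirability (weighted geometric mean)
#'
#' The overall score of a candidate condition: the weighted geometric mean
#' of the per-response desirabilities. It is 1 exactly when every response
#' is fully desirable and 0 as soon as any response is fully undesirable.
#'
#' @param d Vector of per-response desirabilities in \[0, 1\].
#' @param weights Positive weights (recycled); default equal.
#' @return Composite desirability D in \[0, 1\].
#' @export
#' @examples
#' composite_desirability(c(0.25, 1))  # sqrt(0.25) = 0.5
composite_desirability <- function(d, weights = rep(1, length(d))) {
  if (!length(d)) stop("empty desirability vector", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]",
                               call. = FALSE)
  weights <- rep_len(weights, length(d))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(sum(weights * log(d)) / sum(weights))
}

#' Desirability specification for a set of responses
#'
#' @param responses Character vector of response names.
#' @param y_min,y_max Named (or positional) vectors of desired levels;
#'   default to the observed range of each response in `data`.
#' @param weights Positive weights, default 1 for every response.
#' @param directions `"maximize"`/`"minimize"` per response; defaults to
#'   maximise concentrations and minimise any response whose name contains
#'   `"ic50"`.
#' @param data Optional response table supplying observed ranges.
#' @return Object of class `desirability_spec` (a data frame).
#' @export
desirability_spec <- function(responses, y_min = NULL, y_max = NULL,
                              weights = 1, directions = NULL, data = NULL) {
  if (is.null(y_min) || is.null(y_max)) {
    if (is.null(data)) stop("supply y_min/y_max or data", call. = FALSE)
    obs <- lapply(responses, function(r) range(data[[r]], na.rm = TRUE))
    if (is.null(y_min)) y_min <- vapply(obs, `[`, numeric(1), 1L)
    if (is.null(y_max)) y_max <- vapply(obs, `[`, numeric(1), 2L)
  }
  if (is.null(directions)) {
    directions <- ifelse(grepl("ic50", responses), "minimize", "maximize")
  }
  spec <- data.frame(
    response = responses,
    y_min = rep_len(y_min, length(responses)),
    y_max = rep_len(y_max, length(responses)),
    weight = rep_len(weights, length(responses)),
    direction = rep_len(directions, length(responses)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(spec$y_min < spec$y_max), all(spec$weight > 0),
            all(spec$direction %in% c("maximize", "minimize")))
  class(spec) <- c("desirability_spec", "data.frame")
  spec
}

#' Find the most desirable harvest condition by exhaustive grid search
#'
#' Evaluates every combination of the supplied coded factor levels, scores
#' each candidate by the composite desirability of the model predictions,
#' and returns the best realizable condition. The grid is restricted to
#' levels that exist in the study (dates, varieties, areas, harvests are
#' discrete), so the optimum is always a harvestable condition rather than
#' a point between varieties. Ties break to the lexicographically smallest
#' coded point.
#'
#' @param models Named list of `rsm` fits, one per spec response.
#' @param spec A [desirability_spec()].
#' @param grid Named list of coded level vectors for `X1`..`X5`.
#' @param coding Optional `factor_coding` used to decode the optimum.
#' @param level Confidence level for the reported prediction intervals.
#' @return Object of class `desirability_optimum`: coded and decoded
#'   optimum, per-response predictions (with CIs when the models carry fit
#'   data), per-response desirabilities and the composite `D`.
#' @export
optimize_desirability <- function(models, spec, grid, coding = NULL,
                                  level = 0.95) {
  stopifnot(inherits(spec, "desirability_spec"))
  if (!all(spec$response %in% names(models))) {
    stop("models missing for response(s): ",
         paste(setdiff(spec$response, names(models)), collapse = ", "),
         call. = FALSE)
  }
  if (!length(grid) || any(!vapply(grid, length, integer(1)))) {
    stop("empty grid", call. = FALSE)
  }
  grid <- lapply(grid, sort)
  cand <- as.matrix(expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE))
  cand <- cand[, rev(seq_len(ncol(cand))), drop = FALSE]
  colnames(cand) <- names(grid)
  # lexicographic candidate order on coded coordinates, first factor major
  ord <- do.call(order, as.data.frame(cand))
  cand <- cand[ord, , drop = FALSE]

  D <- rep(1, nrow(cand))
  d_mat <- matrix(NA_real_, nrow(cand), nrow(spec),
                  dimnames = list(NULL, spec$response))
  pred <- matrix(NA_real_, nrow(cand), nrow(spec),
                 dimnames = list(NULL, spec$response))
  for (i in seq_len(nrow(spec))) {
    r <- spec$response[i]
    pred[, r] <- predict(models[[r]], cand)
    d_mat[, r] <- desirability(pred[, r], spec$y_min[i], spec$y_max[i],
                               spec$weight[i], spec$direction[i])
  }
  logd <- ifelse(d_mat == 0, -Inf, log(d_mat))
  D <- exp(as.vector(logd %*% spec$weight) / sum(spec$weight))
  D[apply(d_mat == 0, 1L, any)] <- 0

  best <- which.max(D)  # first max = lexicographically smallest tie
  if (D[best] == 0) {
    warning("degenerate optimum: composite desirability is 0 everywhere",
            call. = FALSE)
    best <- 1L
  }
  x_opt <- cand[best, ]
  preds <- lapply(spec$response, function(r) {
    p <- predict(models[[r]], matrix(x_opt, nrow = 1,
                                     dimnames = list(NULL, names(x_opt))),
                 interval = "confidence", level = level)
    if (is.data.frame(p)) p else data.frame(fit = p, lwr = NA, upr = NA)
  })
  preds <- do.call(rbind, preds)
  preds$response <- spec$response
  outside <- preds$fit > spec$y_max | preds$fit < spec$y_min
  if (any(outside)) {
    warning("optimum predicts ", paste(spec$response[outside], collapse = ", "),
            " outside the desired response range (extrapolation beyond the ",
            "observed data hull)", call. = FALSE)
  }
  structure(list(
    coded = x_opt,
    condition = if (!is.null(coding)) decode_factors(x_opt, coding) else NULL,
    predictions = preds[, c("response", "fit", "lwr", "upr")],
    d = stats::setNames(d_mat[best, ], spec$response),
    D = D[best],
    spec = spec,
    n_grid = nrow(cand)
  ), class = "desirability_optimum")
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat(sprintf("Optimum over %d candidate conditions: D = %.4f\n",
              x$n_grid, x$D))
  cat("Coded point:", paste(sprintf("%s = %.3f", names(x$coded), x$coded),
                            collapse = ", "), "\n")
  if (!is.null(x$condition)) {
    cat("Decoded condition:\n")
    print(x$condition, row.names = FALSE)
  }
  cat("Predicted responses:\n")
  print(x$predictions, row.names = FALSE, digits = 5)
  invisible(x)
}
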