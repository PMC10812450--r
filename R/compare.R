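#' Coefficient of determination
#'
#' `R2 = 1 - SSE/SST` with mean-centred SST.
#'
#' @param y Observed values (>= 2).
#' @param yhat Predicted values.
#' @return R2, or `NA` with a warning when `y` has zero variance.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("zero variance in y; R2 undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / sst
}

#' Root mean square error
#'
#' `RMSE = sqrt(sum((y - yhat)^2) / n)`.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Non-negative RMSE.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1L)
  sqrt(mean((y - yhat)^2))
}

#' RSM-versus-ANN comparison report
#'
#' One row per response and model: the response-surface fit first, then
#' the retained networks in rank order, each scored by R2, RMSE and the
#' residual standard deviation. The publication this mirrors never states
#' which data partition its comparison metrics use, so the report labels
#' the partition of every row and can emit several partitions at once; the
#' RSM model (fitted on all rows) is always reported on the full data.
#'
#' @param rsm_models Named list of `rsm` fits (one per response).
#' @param networks List of retained `mlp` fits, rank order (e.g.
#'   `mlp_search()$retained`).
#' @param features Feature matrix for the networks (all rows).
#' @param coded Coded factor matrix for the RSM models (all rows).
#' @param responses Response table with one column per modelled response.
#' @param split Optional [split_data()] partition enabling per-partition
#'   network rows.
#' @param partitions Partitions to report for the networks: subset of
#'   `"full"`, `"train"`, `"validation"`, `"test"` (default `"full"`).
#' @return Data frame of class `comparison_report`.
#' @export
comparison_report <- function(rsm_models, networks, features, coded,
                              responses, split = NULL,
                              partitions = "full") {
  resp_names <- names(rsm_models)
  if (is.null(resp_names) || !all(resp_names %in% names(responses))) {
    stop("rsm_models must be named after response columns", call. = FALSE)
  }
  part_idx <- list(full = seq_len(nrow(responses)))
  if (!is.null(split)) {
    part_idx$train <- split$train
    part_idx$validation <- split$validation
    part_idx$test <- split$test
  }
  if (!all(partitions %in% names(part_idx))) {
    stop("unknown partition(s); supply 'split' for train/validation/test",
         call. = FALSE)
  }
  net_pred <- lapply(networks, predict, features)
  rows <- list()
  for (r in resp_names) {
    y_all <- responses[[r]]
    ok <- !is.na(y_all)
    yhat_rsm <- predict(rsm_models[[r]], coded[ok, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      response = r, model = "RSM", rank = 0L, partition = "full",
      r2 = r_squared(y_all[ok], yhat_rsm),
      rmse = rmse(y_all[ok], yhat_rsm),
      resid_sd = stats::sd(y_all[ok] - yhat_rsm),
      stringsAsFactors = FALSE
    )
    for (k in seq_along(networks)) {
      yhat_net <- net_pred[[k]][, r]
      for (p in partitions) {
        i <- intersect(part_idx[[p]], which(ok))
        if (length(i) < 2L) next
        rows[[length(rows) + 1L]] <- data.frame(
          response = r, model = networks[[k]]$architecture$name,
          rank = k, partition = p,
          r2 = r_squared(y_all[i], yhat_net[i]),
          rmse = rmse(y_all[i], yhat_net[i]),
          resid_sd = stats::sd(y_all[i] - yhat_net[i]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison (", length(unique(x$response)), " responses, ",
      length(unique(x$model)), " models)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
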