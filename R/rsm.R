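#' The 20-term second-order model of the study
#'
#' Intercept, the five linear factors, four quadratics (the area quadratic
#' `X3^2` is excluded: with a two-level factor coded to -1/+1 it is
#' constant and redundant), and all ten pairwise interactions, in the
#' printed coefficient-table order.
#'
#' @return Character vector of 20 term labels.
#' @export
rsm_terms <- function() {
  c("intercept", paste0("X", 1:5),
    "X1^2", "X2^2", "X4^2", "X5^2",
    "X1:X2", "X1:X3", "X1:X4", "X1:X5",
    "X2:X3", "X2:X4", "X2:X5",
    "X3:X4", "X3:X5", "X4:X5")
}

#' Full quadratic term set for k coded factors
#'
#' @param k Number of factors.
#' @return Term labels: intercept, linear, quadratic, all interactions.
#' @export
full_quadratic_terms <- function(k) {
  nm <- paste0("X", seq_len(k))
  inter <- if (k >= 2L) {
    utils::combn(nm, 2L, FUN = function(p) paste(p, collapse = ":"))
  } else character()
  c("intercept", nm, paste0(nm, "^2"), inter)
}

# Evaluate one term label on a coded matrix.
eval_term <- function(term, X) {
  if (term == "intercept") return(rep(1, nrow(X)))
  if (grepl("\\^2$", term)) {
    v <- sub("\\^2$", "", term)
    return(X[, v]^2)
  }
  if (grepl(":", term, fixed = TRUE)) {
    p <- strsplit(term, ":", fixed = TRUE)[[1L]]
    return(X[, p[1L]] * X[, p[2L]])
  }
  X[, term]
}

#' Build the polynomial design matrix
#'
#' @param X Coded factor matrix (columns named `X1`, `X2`, ...).
#' @param terms Term labels; defaults to the study's 20-term set.
#' @return n x length(terms) design matrix with the terms as columns.
#' @export
build_design_matrix <- function(X, terms = rsm_terms()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  D <- vapply(terms, function(t) eval_term(t, X), numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X), dimnames = list(rownames(X), terms))
  D
}

#' Fit the second-order response-surface model by ordinary least squares
#'
#' @param X Coded factor matrix (rows = samples).
#' @param y Response vector; rows with `NA` are dropped (e.g. IC50 not
#'   determined).
#' @param terms Term labels, default the 20-term study set.
#' @param response Response name carried in the fitted object.
#' @return An object of class `rsm`: coefficients, standard errors,
#'   two-sided t-test p-values (df = n - rank), R2, adjusted R2, RMSE
#'   (`sqrt(SSE/n)`), residuals and fitted values. A rank-deficient design
#'   triggers a warning and a minimum-norm least-squares solution with the
#'   non-identifiable terms flagged in `$aliased`.
#' @export
rsm_fit <- function(X, y, terms = rsm_terms(), response = "y") {
  keep <- !is.na(y)
  if (any(!keep)) {
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  D <- build_design_matrix(X, terms)
  n <- nrow(D); p <- ncol(D)
  if (n < 1L) stop("no observations to fit", call. = FALSE)
  qrD <- qr(D)
  rank <- qrD$rank
  aliased <- rep(FALSE, p)
  if (rank < p) {
    warning("rank-deficient design (rank ", rank, " < ", p,
            " terms); returning minimum-norm solution", call. = FALSE)
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
    aliased[qrD$pivot[-seq_len(rank)]] <- TRUE
  } else {
    beta <- qr.coef(qrD, y)
  }
  names(beta) <- terms
  fitted <- drop(D %*% beta)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) {
    warning("zero-variance response; R2 defined as 0", call. = FALSE)
    r2 <- 0
  } else {
    r2 <- 1 - sse / sst
  }
  df <- n - rank
  adj_r2 <- if (sst > 0 && df > 0) 1 - (1 - r2) * (n - 1) / df else NA_real_
  sigma2 <- if (df > 0) sse / df else NA_real_
  if (rank == p && df > 0) {
    XtXinv <- chol2inv(qr.R(qrD))
    se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  } else {
    se <- tval <- pval <- rep(NA_real_, p)
  }
  structure(list(
    response = response, terms = terms,
    coefficients = beta, se = se, t = tval, p.value = pval,
    aliased = aliased, r.squared = r2, adj.r.squared = adj_r2,
    rmse = sqrt(sse / n), sigma2 = sigma2, df.residual = df, rank = rank,
    n = n, fitted.values = fitted, residuals = resid, design = D, y = y
  ), class = "rsm")
}

#' Build a response-surface model from published coefficients
#'
#' Seeds an `rsm` object from a coefficient table (no refitting); only
#' point predictions are available, since the design and residuals behind
#' the published fit are not.
#'
#' @param beta Named coefficient vector over [rsm_terms()] (or a subset).
#' @param response Response name.
#' @param stats Optional named list/vector of published fit statistics
#'   (e.g. `R2`, `R2_adj`, `RMSE`), stored as `$published`.
#' @return An object of class `rsm` with `$n = NA`.
#' @export
rsm_from_coefficients <- function(beta, response = "y", stats = NULL) {
  terms <- names(beta)
  bad <- terms[!vapply(terms, function(t)
    t == "intercept" || grepl("^X[0-9]+(\\^2)?$|^X[0-9]+:X[0-9]+$", t),
    logical(1))]
  if (length(bad)) {
    stop("unrecognised term label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    response = response, terms = terms,
    coefficients = beta, se = rep(NA_real_, length(beta)),
    t = rep(NA_real_, length(beta)), p.value = rep(NA_real_, length(beta)),
    aliased = rep(FALSE, length(beta)),
    r.squared = NA_real_, adj.r.squared = NA_real_, rmse = NA_real_,
    sigma2 = NA_real_, df.residual = NA_integer_, rank = length(beta),
    n = NA_integer_, fitted.values = NULL, residuals = NULL,
    design = NULL, y = NULL, published = stats
  ), class = "rsm")
}

#' Read the published coefficient table into seeded models
#'
#' @param path Long CSV fixture (`term`, `response`, `beta`, `stars`).
#' @return Named list of `rsm` objects, one per response, each carrying the
#'   published R2 / adjusted R2 / RMSE rows in `$published`.
#' @export
read_coefficient_models <- function(path = straw_fixture("table5_coefficients.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stat_rows <- c("R2", "R2_adj", "RMSE")
  lapply(split(tab, tab$response)[unique(tab$response)], function(d) {
    stats <- stats::setNames(d$beta[d$term %in% stat_rows],
                             d$term[d$term %in% stat_rows])
    d <- d[!d$term %in% stat_rows, , drop = FALSE]
    rsm_from_coefficients(stats::setNames(d$beta, d$term),
                          response = d$response[1L], stats = as.list(stats))
  })
}

#' Predict from a response-surface model
#'
#' @param object An `rsm` fit.
#' @param newdata Coded factor matrix or a single coded vector.
#' @param interval `"none"` or `"confidence"` (mean response interval from
#'   the OLS prediction variance).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a data frame with `fit`,
#'   `lwr`, `upr` when an interval is requested.
#' @export
predict.rsm <- function(object, newdata, interval = c("none", "confidence"),
                        level = 0.95, ...) {
  interval <- match.arg(interval)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, paste0("X", seq_along(newdata))))
  }
  D <- build_design_matrix(newdata, object$terms)
  fit <- drop(D %*% object$coefficients)
  if (interval == "none") return(fit)
  no_var <- is.null(object$design) || is.na(object$sigma2) ||
    object$rank < length(object$terms)
  if (no_var) {
    warning("no prediction variance available for this model ",
            "(seeded from coefficients, saturated, or rank-deficient); ",
            "returning point predictions", call. = FALSE)
    return(data.frame(fit = fit, lwr = NA_real_, upr = NA_real_))
  }
  XtXinv <- chol2inv(chol(crossprod(object$design)))
  vf <- rowSums((D %*% XtXinv) * D) * object$sigma2
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df.residual)
  half <- tq * sqrt(pmax(vf, 0))
  data.frame(fit = fit, lwr = fit - half, upr = fit + half)
}

#' Significance stars for a p-value
#'
#' Thresholds as printed in the coefficient table: `***` for p <= 0.001,
#' `**` for p <= 0.01, `*` for p <= 0.05, otherwise empty.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-value outside [0, 1]", call. = FALSE)
  }
  out <- rep("", length(p))
  out[!is.na(p) & p <= 0.05] <- "*"
  out[!is.na(p) & p <= 0.01] <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Evaluate a fitted surface on a regular coded grid
#'
#' @param object An `rsm` fit.
#' @param pair Two distinct factor names to vary (e.g. `c("X2", "X5")`).
#' @param fixed Named coded values for the remaining factors (default 0).
#' @param resolution Grid points per axis (>= 2).
#' @return Data frame `(x_i, x_j, y_hat)` over \[-1,1\]^2, row-major with
#'   both axes ascending.
#' @export
surface_grid <- function(object, pair, fixed = NULL, resolution = 21L) {
  if (length(pair) != 2L || pair[1L] == pair[2L]) {
    stop("'pair' must name two distinct factors", call. = FALSE)
  }
  if (resolution < 2L) stop("resolution must be >= 2", call. = FALSE)
  factors <- unique(unlist(lapply(object$terms, function(t) {
    regmatches(t, gregexpr("X[0-9]+", t))[[1L]]
  })))
  s <- seq(-1, 1, length.out = resolution)
  g <- expand.grid(xj = s, xi = s)[, 2:1]  # row-major: x_i varies slowest
  X <- matrix(0, nrow = nrow(g), ncol = length(factors),
              dimnames = list(NULL, factors))
  X[, pair[1L]] <- g[[1L]]
  X[, pair[2L]] <- g[[2L]]
  if (!is.null(fixed)) {
    for (f in names(fixed)) X[, f] <- fixed[[f]]
  }
  out <- data.frame(g[[1L]], g[[2L]], predict(object, X))
  names(out) <- c(pair, "y_hat")
  out
}

#' @export
print.rsm <- function(x, ...) {
  cat("Second-order response-surface model for '", x$response, "'\n", sep = "")
  cat("  terms:", length(x$terms), " n:", x$n, " rank:", x$rank, "\n")
  if (!is.na(x$r.squared)) {
    cat(sprintf("  R2 = %.4f  adj R2 = %.4f  RMSE = %.4f\n",
                x$r.squared, x$adj.r.squared, x$rmse))
  }
  invisible(x)
}

#' @export
coef.rsm <- function(object, ...) object$coefficients

#' @export
residuals.rsm <- function(object, ...) object$residuals

#' @export
fitted.rsm <- function(object, ...) object$fitted.values

#' Coefficient table with significance annotations
#'
#' @param object An `rsm` fit.
#' @param ... Unused.
#' @return Object of class `summary.rsm` wrapping the coefficient table.
#' @export
summary.rsm <- function(object, ...) {
  tab <- data.frame(
    term = object$terms,
    beta = object$coefficients,
    se = object$se,
    p.value = object$p.value,
    stars = significance_stars(object$p.value),
    aliased = object$aliased,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(response = object$response, coefficients = tab,
                 r.squared = object$r.squared,
                 adj.r.squared = object$adj.r.squared,
                 rmse = object$rmse, n = object$n),
            class = "summary.rsm")
}

#' @export
print.summary.rsm <- function(x, ...) {
  cat("Response:", x$response, "\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("R2 = %.4f  adj R2 = %.4f  RMSE = %.4f  (n = %s)\n",
              x$r.squared, x$adj.r.squared, x$rmse, x$n))
  invisible(x)
}

#' Export / import a response-surface model as JSON
#'
#' @param object An `rsm` fit.
#' @param path JSON file path.
#' @return `write_rsm_json` returns `path` invisibly; `read_rsm_json`
#'   returns an `rsm` object (seeded from coefficients; no residual data).
#' @export
write_rsm_json <- function(object, path) {
  jsonlite::write_json(list(
    response = object$response, terms = object$terms,
    coefficients = as.list(object$coefficients),
    se = object$se, p.value = object$p.value,
    r.squared = object$r.squared, adj.r.squared = object$adj.r.squared,
    rmse = object$rmse, n = object$n
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_rsm_json
#' @export
read_rsm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- rsm_from_coefficients(unlist(obj$coefficients),
                             response = obj$response)
  m$se <- as.numeric(obj$se)
  m$p.value <- as.numeric(obj$p.value)
  m$r.squared <- obj$r.squared %||% NA_real_
  m$adj.r.squared <- obj$adj.r.squared %||% NA_real_
  m$rmse <- obj$rmse %||% NA_real_
  m
}
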