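activation_fns <- list(
  identity = list(f = function(z) z, df = function(z, a) rep(1, length(z))),
  logistic = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(z, a) a * (1 - a)),
  tanh = list(f = tanh, df = function(z, a) 1 - a^2),
  exponential = list(f = exp, df = function(z, a) a)
)

#' Describe a single-hidden-layer perceptron architecture
#'
#' Networks are named `"MLP k_i-k_h-k_o"` after their input, hidden and
#' output layer sizes.
#'
#' @param n_in,n_hidden,n_out Layer sizes (all >= 1).
#' @param hidden_activation,output_activation One of `"identity"`,
#'   `"logistic"`, `"tanh"`, `"exponential"`.
#' @return Object of class `mlp_architecture`.
#' @export
mlp_architecture <- function(n_in, n_hidden, n_out,
                             hidden_activation = "tanh",
                             output_activation = "identity") {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1,
            hidden_activation %in% names(activation_fns),
            output_activation %in% names(activation_fns))
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 n_out = as.integer(n_out),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 name = sprintf("MLP %d-%d-%d", n_in, n_hidden, n_out)),
            class = "mlp_architecture")
}

#' One-hot feature expansion of harvest conditions
#'
#' Expands the categorical factors (collection date, variety, area) into
#' indicator columns and appends the two continuous factors (infection
#' level, harvest number) standardized to zero mean and unit variance on
#' the training rows. With the study design (7 dates, 9 varieties, 2
#' areas) this yields the 20-input encoding behind the `MLP 20-h-5`
#' network names.
#'
#' @param conditions Conditions data frame.
#' @param levels Optional list of `date`, `variety`, `area` level vectors
#'   (from a previous call) so new data maps onto the training columns; an
#'   unseen level is an error.
#' @param standardize Optional list of `center`/`scale` from a previous
#'   call; default computed from `conditions`.
#' @return List: `features` (n x p matrix), `map` (parent factor of each
#'   column), `levels`, `standardize`.
#' @export
expand_inputs <- function(conditions, levels = NULL, standardize = NULL) {
  lv <- levels %||% list(
    date = sort(unique(conditions$collection_date)),
    variety = sort(unique(conditions$variety)),
    area = sort(unique(conditions$area))
  )
  onehot <- function(x, lev, what) {
    i <- match(x, lev)
    if (any(is.na(i))) {
      stop("unseen ", what, " level(s): ",
           paste(unique(x[is.na(i)]), collapse = ", "), call. = FALSE)
    }
    m <- matrix(0, length(x), length(lev),
                dimnames = list(NULL, paste0(what, "=", as.character(lev))))
    m[cbind(seq_along(x), i)] <- 1
    m
  }
  cont <- cbind(infection = conditions$infection_level,
                harvest = conditions$harvest_number)
  std <- standardize %||% list(
    center = colMeans(cont),
    scale = apply(cont, 2L, function(v) {
      s <- stats::sd(v); if (is.na(s) || s == 0) 1 else s
    })
  )
  cont <- sweep(sweep(cont, 2L, std$center), 2L, std$scale, "/")
  feats <- cbind(onehot(conditions$collection_date, lv$date, "date"),
                 onehot(conditions$variety, lv$variety, "variety"),
                 onehot(conditions$area, lv$area, "area"),
                 cont)
  rownames(feats) <- conditions$sample_id
  map <- c(rep("date", length(lv$date)),
           rep("variety", length(lv$variety)),
           rep("area", length(lv$area)),
           "infection", "harvest")
  names(map) <- colnames(feats)
  list(features = feats, map = map, levels = lv, standardize = std)
}

#' Seeded 70/15/15 train/validation/test partition
#'
#' Validation and test sizes are the fractions rounded to the nearest
#' integer; the remainder goes to training (so n = 27 splits as 19/4/4).
#'
#' @param n Number of observations (>= 3).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed; the split is reproducible given the seed.
#' @return Object of class `data_split`: index vectors `train`,
#'   `validation`, `test`.
#' @export
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (n < 3L) stop("need at least 3 observations to split", call. = FALSE)
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n_val <- round(fractions[2L] * n)
  n_test <- round(fractions[3L] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("split leaves no training rows", call. = FALSE)
  idx <- with_seed(seed, sample.int(n))
  structure(list(train = sort(idx[seq_len(n_train)]),
                 validation = sort(idx[n_train + seq_len(n_val)]),
                 test = sort(idx[n_train + n_val + seq_len(n_test)]),
                 fractions = fractions, seed = seed, n = n),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("Data split (seed %d): train %d / validation %d / test %d\n",
              x$seed, length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

# Pack/unpack the weight vector used by the optimizer.
mlp_unpack <- function(theta, arch) {
  ki <- arch$n_in; kh <- arch$n_hidden; ko <- arch$n_out
  i <- 0L
  W <- matrix(theta[i + seq_len(ki * kh)], ki, kh); i <- i + ki * kh
  b_h <- theta[i + seq_len(kh)]; i <- i + kh
  V <- matrix(theta[i + seq_len(kh * ko)], kh, ko); i <- i + kh * ko
  b_o <- theta[i + seq_len(ko)]
  list(W = W, b_h = b_h, V = V, b_o = b_o)
}

mlp_forward <- function(w, x, arch) {
  hf <- activation_fns[[arch$hidden_activation]]
  of <- activation_fns[[arch$output_activation]]
  zh <- sweep(x %*% w$W, 2L, w$b_h, "+")
  ah <- hf$f(zh)
  zo <- sweep(ah %*% w$V, 2L, w$b_o, "+")
  list(zh = zh, ah = ah, zo = zo, out = of$f(zo))
}

# Sum-of-squares loss and its analytic gradient (backpropagation).
mlp_sos <- function(theta, x, y, arch) {
  w <- mlp_unpack(theta, arch)
  fw <- mlp_forward(w, x, arch)
  sum((fw$out - y)^2)
}

mlp_sos_grad <- function(theta, x, y, arch) {
  w <- mlp_unpack(theta, arch)
  hf <- activation_fns[[arch$hidden_activation]]
  of <- activation_fns[[arch$output_activation]]
  fw <- mlp_forward(w, x, arch)
  delta_o <- 2 * (fw$out - y) * of$df(fw$zo, fw$out)
  dV <- crossprod(fw$ah, delta_o)
  db_o <- colSums(delta_o)
  delta_h <- (delta_o %*% t(w$V)) * hf$df(fw$zh, fw$ah)
  dW <- crossprod(x, delta_h)
  db_h <- colSums(delta_h)
  c(as.vector(dW), db_h, as.vector(dV), db_o)
}

#' Train a single-hidden-layer perceptron by BFGS
#'
#' Minimises the sum-of-squares (SOS) error over all weights with the
#' quasi-Newton BFGS optimizer, using analytic backpropagation gradients.
#' Inputs and targets are standardized internally; weights initialise
#' uniformly on \[-0.5, 0.5\] under the given seed, so training is
#' deterministic given the seed.
#'
#' @param x Feature matrix (e.g. from [expand_inputs()]).
#' @param y Target matrix or vector (one column per output).
#' @param hidden Hidden-layer size.
#' @param hidden_activation,output_activation Activation names.
#' @param seed Integer seed for the weight initialisation.
#' @param maxit BFGS iteration cap (0 returns the initialised network).
#' @param gradtol Gradient max-norm convergence tolerance.
#' @return Object of class `mlp`: architecture, weight matrices `W`
#'   (input to hidden) and `V` (hidden to output) with biases,
#'   standardization parameters, and a best-so-far SOS trace in
#'   `$loss_trace` (nonincreasing by construction).
#' @export
mlp_fit <- function(x, y, hidden = 5L, hidden_activation = "tanh",
                    output_activation = "identity", seed = 1L,
                    maxit = 500L, gradtol = 1e-6) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  if (nrow(x) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in training data", call. = FALSE)
  }
  std_of <- function(m) list(
    center = colMeans(m),
    scale = apply(m, 2L, function(v) {
      s <- stats::sd(v); if (is.na(s) || s == 0) 1 else s
    }))
  sx <- std_of(x); sy <- std_of(y)
  xs <- sweep(sweep(x, 2L, sx$center), 2L, sx$scale, "/")
  ys <- sweep(sweep(y, 2L, sy$center), 2L, sy$scale, "/")
  arch <- mlp_architecture(ncol(x), hidden, ncol(y),
                           hidden_activation, output_activation)
  n_par <- with(arch, n_in * n_hidden + n_hidden +
                  n_hidden * n_out + n_out)
  theta0 <- with_seed(seed, stats::runif(n_par, -0.5, 0.5))
  trace_env <- new.env()
  trace_env$best <- numeric(0)
  fn <- function(th) {
    v <- mlp_sos(th, xs, ys, arch)
    if (!is.finite(v)) return(.Machine$double.xmax)
    b <- trace_env$best
    trace_env$best <- c(b, if (length(b)) min(v, b[length(b)]) else v)
    v
  }
  if (maxit > 0L) {
    fit <- stats::optim(theta0, fn = fn, gr = function(th)
      mlp_sos_grad(th, xs, ys, arch),
      method = "BFGS",
      control = list(maxit = maxit, reltol = 1e-12))
    theta <- fit$par
    value <- fit$value
    convergence <- fit$convergence
  } else {
    theta <- theta0
    value <- mlp_sos(theta0, xs, ys, arch)
    convergence <- NA_integer_
  }
  if (!is.finite(value)) {
    stop("non-finite SOS loss after training (diverging output weights)",
         call. = FALSE)
  }
  g <- mlp_sos_grad(theta, xs, ys, arch)
  w <- mlp_unpack(theta, arch)
  dimnames(w$W) <- list(colnames(x), NULL)
  dimnames(w$V) <- list(NULL, colnames(y))
  structure(list(
    architecture = arch, W = w$W, b_h = w$b_h, V = w$V, b_o = w$b_o,
    x_standardize = sx, y_standardize = sy,
    sos = value, grad_maxnorm = max(abs(g)),
    converged = max(abs(g)) <= gradtol,
    loss_trace = trace_env$best, seed = seed, maxit = maxit,
    convergence = convergence
  ), class = "mlp")
}

#' @export
predict.mlp <- function(object, x, ...) {
  x <- as.matrix(x)
  sx <- object$x_standardize; sy <- object$y_standardize
  xs <- sweep(sweep(x, 2L, sx$center), 2L, sx$scale, "/")
  fw <- mlp_forward(object[c("W", "b_h", "V", "b_o")], xs,
                    object$architecture)
  out <- sweep(sweep(fw$out, 2L, sy$scale, "*"), 2L, sy$center, "+")
  rownames(out) <- rownames(x)
  out
}

#' @export
print.mlp <- function(x, ...) {
  a <- x$architecture
  cat(a$name, " (", a$hidden_activation, "/", a$output_activation,
      "), SOS = ", format(x$sos, digits = 5),
      if (isTRUE(x$converged)) ", converged" else "", "\n", sep = "")
  invisible(x)
}

#' Fit metrics of a prediction against observations
#'
#' @param y Observed matrix/vector.
#' @param yhat Predicted matrix/vector of the same shape.
#' @return Data frame per output: Pearson `r`, `r2`, `rmse`. A
#'   zero-variance target yields `NA` metrics with a warning.
#' @export
evaluate_predictions <- function(y, yhat) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  stopifnot(dim(y) == dim(yhat))
  if (nrow(y) < 2L) stop("need at least 2 rows to evaluate", call. = FALSE)
  out <- lapply(seq_len(ncol(y)), function(j) {
    if (stats::sd(y[, j]) == 0) {
      warning("zero-variance target in column ", j, "; r undefined",
              call. = FALSE)
      return(data.frame(output = j, r = NA_real_, r2 = NA_real_,
                        rmse = rmse(y[, j], yhat[, j])))
    }
    data.frame(output = j,
               r = stats::cor(y[, j], yhat[, j]),
               r2 = r_squared(y[, j], yhat[, j]),
               rmse = rmse(y[, j], yhat[, j]))
  })
  res <- do.call(rbind, out)
  if (!is.null(colnames(y))) res$output <- colnames(y)
  res
}

#' Automated search over candidate network architectures
#'
#' Trains every candidate on the training rows and retains the top
#' `retain` networks by mean validation-set Pearson correlation across
#' outputs (tie-break: smaller hidden layer, then candidate id). Each
#' candidate's weight initialisation seed derives from its own
#' description, not its position, so the ranking is invariant to the order
#' in which candidates are supplied.
#'
#' @param x,y Full feature and target matrices.
#' @param split A [split_data()] partition of `nrow(x)`.
#' @param candidates Data frame with columns `hidden` and
#'   `hidden_activation`; default 20 candidates cycling hidden sizes 3--5
#'   over the four hidden activations.
#' @param retain Number of networks to keep (default 5).
#' @param seed Master seed combined with each candidate description.
#' @param maxit BFGS iteration cap per candidate.
#' @return Object of class `mlp_search`: `retained` (list of `mlp` fits in
#'   rank order) and the full `ranking` table.
#' @export
mlp_search <- function(x, y, split, candidates = NULL, retain = 5L,
                       seed = 1L, maxit = 300L) {
  if (is.null(candidates)) {
    acts <- c("identity", "logistic", "tanh", "exponential")
    base <- expand.grid(hidden = 3:5, hidden_activation = acts,
                        stringsAsFactors = FALSE)
    candidates <- rbind(base, base[seq_len(20L - nrow(base)), , drop = FALSE])
  }
  if (nrow(candidates) < retain) {
    stop("need at least ", retain, " candidate architectures", call. = FALSE)
  }
  y <- as.matrix(y)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train, , drop = FALSE]
  xva <- x[split$validation, , drop = FALSE]
  yva <- y[split$validation, , drop = FALSE]
  # replicate index within identical descriptions, so duplicated
  # architectures get distinct (but order-independent) initialisations
  desc <- paste(candidates$hidden, candidates$hidden_activation)
  rep_idx <- stats::ave(seq_len(nrow(candidates)), desc, FUN = seq_along)
  fits <- vector("list", nrow(candidates))
  score <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    h <- candidates$hidden[i]
    act <- candidates$hidden_activation[i]
    cand_seed <- (as.integer(seed) + 7919L * as.integer(h) +
                    104729L * match(act, names(activation_fns)) +
                    15485863L * rep_idx[i]) %% .Machine$integer.max
    fits[[i]] <- tryCatch(
      mlp_fit(xtr, ytr, hidden = h, hidden_activation = act,
              seed = cand_seed, maxit = maxit),
      error = function(e) NULL)
    score[i] <- if (is.null(fits[[i]])) -Inf else {
      pv <- predict(fits[[i]], xva)
      rs <- vapply(seq_len(ncol(y)), function(j) {
        if (stats::sd(yva[, j]) == 0 || stats::sd(pv[, j]) == 0) 0
        else stats::cor(yva[, j], pv[, j])
      }, numeric(1))
      mean(rs)
    }
  }
  if (all(!is.finite(score))) stop("all candidates failed", call. = FALSE)
  ranking <- data.frame(
    candidate = seq_len(nrow(candidates)),
    name = vapply(fits, function(f)
      if (is.null(f)) NA_character_ else f$architecture$name, character(1)),
    hidden = candidates$hidden,
    hidden_activation = candidates$hidden_activation,
    validation_r = score
  )
  ord <- order(-ranking$validation_r, ranking$hidden, ranking$candidate)
  ranking <- ranking[ord, ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  keep <- ranking$candidate[seq_len(min(retain, nrow(ranking)))]
  structure(list(retained = fits[keep], ranking = ranking,
                 retain = retain, seed = seed, split = split),
            class = "mlp_search")
}

#' @export
print.mlp_search <- function(x, ...) {
  cat("Architecture search:", nrow(x$ranking), "candidates trained,",
      length(x$retained), "retained\n")
  print(utils::head(x$ranking[, c("rank", "name", "hidden_activation",
                                  "validation_r")], length(x$retained)),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Garson connection-weight relative importance
#'
#' Partitions the absolute connection weights of a single-hidden-layer
#' network to attribute a relative importance (RI) share to each input:
#' for hidden neuron b, input x contributes `|W_xb| / sum_a |W_ab|`
#' weighted by `|V_b|`; the shares are summed over hidden neurons and
#' normalised over all inputs, so the RIs are non-negative and sum to 1.
#' One-hot indicator columns are aggregated back into their parent factor
#' when a column-to-factor map is supplied.
#'
#' @param model An `mlp` fit.
#' @param map Optional named character vector mapping feature columns to
#'   parent factors (as returned by [expand_inputs()]).
#' @return Matrix of relative importances (inputs or factors x outputs);
#'   each column sums to 1.
#' @export
garson_importance <- function(model, map = NULL) {
  W <- abs(model$W)
  V <- abs(model$V)
  if (all(W == 0)) stop("all-zero input weights: importance undefined",
                        call. = FALSE)
  denom <- colSums(W)
  denom[denom == 0] <- 1
  share <- sweep(W, 2L, denom, "/")      # k_i x k_h
  ri <- share %*% V                       # k_i x k_o, weighted by |V_b|
  ri <- sweep(ri, 2L, colSums(ri), "/")
  rownames(ri) <- rownames(model$W)
  if (!is.null(map)) {
    fac <- factor(map[rownames(ri)], levels = unique(map))
    ri <- apply(ri, 2L, function(col) tapply(col, fac, sum))
    ri <- as.matrix(ri)
  }
  ri
}
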