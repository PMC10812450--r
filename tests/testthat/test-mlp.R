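test_that("one-hot expansion yields the study's 20-input encoding", {
  d <- study()
  f <- expand_inputs(d$conditions)
  expect_equal(ncol(f$features), 20L)  # 7 dates + 9 varieties + 2 areas + 2
  expect_equal(unname(table(f$map)[c("date", "variety", "area")]),
               c(7L, 9L, 2L), ignore_attr = TRUE)
  # each row activates exactly one level per categorical block
  onehot <- f$features[, f$map %in% c("date", "variety", "area")]
  expect_true(all(rowSums(onehot) == 3))
  # continuous columns standardized
  expect_equal(mean(f$features[, "infection"]), 0, tolerance = 1e-12)
  expect_equal(sd(f$features[, "harvest"]), 1, tolerance = 1e-12)
})

test_that("small designs expand to 2+2+2+2 columns and reject unseen levels", {
  cond <- tiny_conditions(4L)  # 2 dates? ensure distinct counts
  cond$collection_date <- as.Date("2020-06-04") + c(0, 40, 0, 40)
  cond$variety <- c("CTC4", "CU0618", "CTC4", "CU0618")
  f <- expand_inputs(cond)
  expect_equal(ncol(f$features), 8L)
  new <- cond[1, ]
  new$variety <- "CTC15"
  expect_error(expand_inputs(new, levels = f$levels), "unseen")
})

test_that("the 70/15/15 split follows the stated rounding rule", {
  s <- split_data(27, seed = 5)
  expect_equal(lengths(s[c("train", "validation", "test")]),
               c(train = 19L, validation = 4L, test = 4L))
  s2 <- split_data(20, seed = 5)
  expect_equal(lengths(s2[c("train", "validation", "test")]),
               c(train = 14L, validation = 3L, test = 3L))
  for (n in c(3, 7, 28, 56)) {
    sp <- split_data(n, seed = 2)
    idx <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(idx), seq_len(n))  # disjoint and exhaustive
  }
  expect_identical(split_data(28, seed = 9), split_data(28, seed = 9))
  expect_false(identical(split_data(28, seed = 9)$train,
                         split_data(28, seed = 10)$train))
  expect_error(split_data(2, seed = 1), "at least 3")
})

test_that("a linear-activation network reproduces the OLS solution", {
  set.seed(42)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 * x[, 1] - 0.5 * x[, 2] + 1
  m <- mlp_fit(x, y, hidden = 3, hidden_activation = "identity",
               seed = 7, maxit = 400)
  p <- predict(m, x)[, 1]
  expect_gte(cor(p, y), 0.999)
  ols <- fitted(lm(y ~ x))
  expect_lt(sqrt(mean((p - ols)^2)), 1e-3)
})

test_that("training bookkeeping honours maxit, trace, and degenerate targets", {
  set.seed(1)
  x <- matrix(rnorm(30), 15, 2)
  y <- x[, 1]
  m0 <- mlp_fit(x, y, hidden = 2, seed = 3, maxit = 0)
  m0b <- mlp_fit(x, y, hidden = 2, seed = 3, maxit = 0)
  expect_identical(m0$W, m0b$W)  # initialized network, untouched
  m <- mlp_fit(x, y, hidden = 2, seed = 3, maxit = 200)
  expect_lte(m$sos, m0$sos)                 # training cannot end worse
  expect_true(all(diff(m$loss_trace) <= 0)) # best-so-far SOS trace
  # deterministic given the seed
  m2 <- mlp_fit(x, y, hidden = 2, seed = 3, maxit = 200)
  expect_identical(m$W, m2$W)
  # constant targets are fit with (numerically) zero SOS
  mc <- mlp_fit(x, rep(2.5, 15), hidden = 2, seed = 1, maxit = 100)
  expect_lt(mc$sos, 1e-6)
  expect_equal(unname(predict(mc, x)[, 1]), rep(2.5, 15), tolerance = 1e-3)
  expect_error(mlp_fit(x[1, , drop = FALSE], y[1]), "at least 2")
  xbad <- x; xbad[2, 1] <- Inf
  expect_error(mlp_fit(xbad, y), "non-finite")
})

test_that("prediction metrics match hand arithmetic", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(ev$rmse, sqrt(1 / 3))
  expect_equal(ev$r2, 0.5)
  ev2 <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev2$r, 1)
  expect_equal(ev2$rmse, 0)
  y <- c(-1, 0, 1)
  expect_equal(evaluate_predictions(y, -y)$r, -1)
  expect_warning(ev3 <- evaluate_predictions(c(2, 2, 2), c(1, 2, 3)),
                 "zero-variance")
  expect_true(is.na(ev3$r))
})

test_that("the architecture search retains five ranked networks", {
  d <- study()
  f <- expand_inputs(d$conditions)
  y <- as.matrix(d$responses[, c("hydroxybenzoic", "flavones")])
  split <- split_data(nrow(y), seed = 4)
  s <- mlp_search(f$features, y, split, seed = 4, maxit = 60)
  expect_length(s$retained, 5L)
  expect_equal(nrow(s$ranking), 20L)
  expect_true(all(grepl("^MLP 20-[3-5]-2$", s$ranking$name)))
  expect_true(all(diff(s$ranking$validation_r) <= 1e-12))
  # five candidates in: all retained, still ranked
  cand <- data.frame(hidden = c(3, 4, 5, 3, 4),
                     hidden_activation = c("tanh", "tanh", "identity",
                                           "logistic", "identity"))
  s5 <- mlp_search(f$features, y, split, candidates = cand, seed = 4,
                   maxit = 60)
  expect_length(s5$retained, 5L)
  expect_error(mlp_search(f$features, y, split, candidates = cand[1:3, ],
                          seed = 4), "at least 5")
})

test_that("search ranking is invariant to candidate order", {
  d <- study()
  f <- expand_inputs(d$conditions)
  y <- as.matrix(d$responses[, c("hydroxybenzoic", "flavones")])
  split <- split_data(nrow(y), seed = 8)
  cand <- data.frame(hidden = c(3, 4, 5, 3, 4, 5),
                     hidden_activation = c("tanh", "tanh", "tanh",
                                           "identity", "identity", "logistic"))
  s1 <- mlp_search(f$features, y, split, candidates = cand, seed = 8,
                   maxit = 60)
  perm <- c(4, 1, 6, 3, 5, 2)
  s2 <- mlp_search(f$features, y, split, candidates = cand[perm, ], seed = 8,
                   maxit = 60)
  key <- function(s) s$ranking[, c("name", "hidden_activation",
                                   "validation_r")]
  expect_equal(key(s1), key(s2), ignore_attr = TRUE)
})

test_that("Garson importances partition the connection weights", {
  # hand-evaluated two-input case: W = I, V = (3, 1) -> RI = (0.75, 0.25)
  m <- list(W = diag(2), b_h = c(0, 0), V = matrix(c(3, 1), 2, 1),
            b_o = 0, architecture = mlp_architecture(2, 2, 1))
  class(m) <- "mlp"
  rownames(m$W) <- c("a", "b")
  expect_equal(drop(garson_importance(m)), c(a = 0.75, b = 0.25))

  # equal absolute weights share importance equally
  m$V <- matrix(c(1, 1), 2, 1)
  m$W <- matrix(c(1, -1, 2, 2), 2, 2, dimnames = list(c("a", "b"), NULL))
  ri <- drop(garson_importance(m))
  expect_equal(unname(ri), c(0.5, 0.5))

  # single input gets all the importance
  m1 <- list(W = matrix(c(0.3, -2), 1, 2, dimnames = list("only", NULL)),
             b_h = c(0, 0), V = matrix(c(1, 5), 2, 1), b_o = 0,
             architecture = mlp_architecture(1, 2, 1))
  class(m1) <- "mlp"
  expect_equal(drop(garson_importance(m1)), c(only = 1))

  zero <- m; zero$W[] <- 0
  expect_error(garson_importance(zero), "all-zero")
})

test_that("Garson RI sums to 1 and is invariant to V-rescaling and neuron order", {
  set.seed(6)
  x <- matrix(rnorm(100), 20, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- cbind(a = x[, 1] + rnorm(20, sd = 0.1),
             b = x[, 2] - x[, 3] + rnorm(20, sd = 0.1))
  m <- mlp_fit(x, y, hidden = 4, seed = 2, maxit = 150)
  ri <- garson_importance(m)
  expect_equal(unname(colSums(ri)), c(1, 1), tolerance = 1e-9)
  expect_true(all(ri >= 0))
  # positive rescaling of the output weights
  m2 <- m; m2$V <- m$V * 17.3
  expect_equal(garson_importance(m2), ri, tolerance = 1e-12)
  # hidden-neuron permutation
  perm <- c(3, 1, 4, 2)
  m3 <- m; m3$W <- m$W[, perm]; m3$b_h <- m$b_h[perm]; m3$V <- m$V[perm, ]
  expect_equal(garson_importance(m3), ri, tolerance = 1e-12)
})

test_that("signal-carrying factors dominate the aggregated Garson importance", {
  # only date (X1) and variety (X2) drive the response surface
  beta <- matrix(0, 20, 1, dimnames = list(rsm_terms(), "y"))
  beta[c("X1", "X2", "X1:X2", "X2^2"), 1] <- c(300, -250, 150, 200)
  signal <- 0; null <- 0
  for (k in 1:20) {
    sp <- simulation_spec(seed = 500 + k, beta = beta, sigma = 10)
    des <- simulate_design(sp)
    y <- simulate_responses(des, sp)
    f <- expand_inputs(des)
    m <- mlp_fit(f$features, y$y, hidden = 4, seed = 500 + k, maxit = 150)
    ri <- drop(garson_importance(m, map = f$map))
    signal <- signal + ri[["date"]] + ri[["variety"]]
    null <- null + ri[["area"]] + ri[["infection"]] + ri[["harvest"]]
  }
  expect_gt(signal / 20, null / 20)
})
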