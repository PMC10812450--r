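test_that("the study term set has 20 terms in coefficient-table order", {
  tt <- rsm_terms()
  expect_length(tt, 20L)
  expect_equal(tt[1], "intercept")
  expect_false("X3^2" %in% tt)  # area quadratic excluded as redundant
  expect_length(grep(":", tt), 10L)
})

test_that("design matrices evaluate each term columnwise", {
  X <- matrix(runif(10, -1, 1), 2, 5,
              dimnames = list(NULL, paste0("X", 1:5)))
  D <- build_design_matrix(X)
  expect_equal(dim(D), c(2L, 20L))
  expect_equal(D[, "intercept"], c(1, 1))
  expect_equal(D[, "X2^2"], X[, "X2"]^2)
  expect_equal(D[, "X1:X3"], X[, "X1"] * X[, "X3"])

  # one factor, full quadratic: 1, X, X^2
  x1 <- matrix(seq(-1, 1, 0.5), ncol = 1, dimnames = list(NULL, "X1"))
  D1 <- build_design_matrix(x1, full_quadratic_terms(1))
  expect_equal(ncol(D1), 3L)
  expect_equal(D1[, 3], x1[, 1]^2, ignore_attr = TRUE)

  # the coded origin maps to (1, 0, ..., 0)
  D0 <- build_design_matrix(matrix(0, 1, 5,
                                   dimnames = list(NULL, paste0("X", 1:5))))
  expect_equal(drop(D0), c(1, rep(0, 19)), ignore_attr = TRUE)
})

test_that("noiseless data are interpolated and the normal equations hold", {
  spec <- simulation_spec(seed = 11, sigma = rep(0, 5))
  des <- simulate_design(spec)
  y <- simulate_responses(des, spec)
  X <- attr(y, "coded")
  f <- rsm_fit(X, y$hydroxybenzoic, response = "hydroxybenzoic")
  expect_lt(max(abs(coef(f) - spec$beta[, "hydroxybenzoic"])), 1e-8)
  expect_equal(f$r.squared, 1, tolerance = 1e-12)

  # residual orthogonality on a noisy fit
  spec2 <- simulation_spec(seed = 12)
  y2 <- simulate_responses(des, spec2)
  for (r in c("hydroxybenzoic", "flavones")) {
    f2 <- rsm_fit(X, y2[[r]], response = r)
    expect_lt(max(abs(crossprod(f2$design, residuals(f2)))), 1e-7)
    expect_gte(f2$r.squared, 0)
    expect_gte(f2$rmse, 0)
  }
})

test_that("degenerate fits are handled by convention", {
  X <- matrix(runif(50, -1, 1), 10, 5,
              dimnames = list(NULL, paste0("X", 1:5)))
  expect_warning(f <- rsm_fit(X, rnorm(10)), "rank-deficient")
  expect_true(any(f$aliased))
  expect_length(coef(f), 20L)

  # constant response: R2 is 0 by convention, slope terms are 0
  Xs <- matrix(runif(40, -1, 1), 20, 2, dimnames = list(NULL, c("X1", "X2")))
  expect_warning(fc <- rsm_fit(Xs, rep(3, 20), terms = full_quadratic_terms(2)),
                 "zero-variance")
  expect_equal(fc$r.squared, 0)
  expect_equal(unname(coef(fc)["intercept"]), 3, tolerance = 1e-10)
  expect_lt(max(abs(coef(fc)[-1])), 1e-10)
})

test_that("prediction at the coded origin returns the intercept exactly", {
  spec <- simulation_spec(seed = 13)
  des <- simulate_design(spec)
  y <- simulate_responses(des, spec)
  f <- rsm_fit(attr(y, "coded"), y$flavones)
  expect_identical(unname(predict(f, rep(0, 5))), unname(coef(f)["intercept"]))

  zero <- rsm_from_coefficients(stats::setNames(rep(0, 20), rsm_terms()))
  expect_equal(predict(zero, matrix(runif(15, -1, 1), 3, 5,
                                    dimnames = list(NULL, paste0("X", 1:5)))),
               rep(0, 3), ignore_attr = TRUE)
})

test_that("models seeded from the published coefficients predict the printed intercepts", {
  models <- read_coefficient_models()
  origin <- rep(0, 5)
  expect_equal(predict(models$hydroxybenzoic, origin), 157.15)
  expect_equal(predict(models$flavones, origin), 214.59)
  expect_equal(predict(models$abts, origin), 2.78)
  # published fit statistics travel with the model
  expect_equal(models$hydroxybenzoic$published$R2, 0.949)
  expect_equal(models$hydroxycinnamic$published$RMSE, 38.418)
})

test_that("significance stars follow the printed inclusive thresholds", {
  expect_equal(significance_stars(c(0.03, 0.0005, 0.5, 0.05, 0.01, 0.001)),
               c("*", "***", "", "*", "**", "***"))
  expect_error(significance_stars(1.2), "outside")
  expect_error(significance_stars(-0.1), "outside")
})

test_that("confidence intervals from the OLS variance bracket the truth", {
  # coverage of the 95% CI across seeded replicates, true model known
  spec0 <- simulation_spec(seed = 1, replicates = 2)
  des <- simulate_design(spec0)
  truth <- spec0$beta[, "flavones"]
  hits <- 0L; total <- 0L
  for (k in 1:40) {
    sp <- simulation_spec(seed = 3000 + k, replicates = 2)
    y <- simulate_responses(des, sp)
    f <- rsm_fit(attr(y, "coded"), y$flavones)
    tq <- stats::qt(0.975, f$df.residual)
    hits <- hits + sum(abs(coef(f) - truth) <= tq * f$se)
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.90)
})

test_that("pure-noise regressors never decrease R2 but can decrease adjusted R2", {
  spec <- simulation_spec(seed = 21)
  des <- simulate_design(spec)
  y <- simulate_responses(des, spec)
  X <- attr(y, "coded")
  base_terms <- c("intercept", "X1", "X2", "X3")
  f0 <- rsm_fit(X, y$hydroxybenzoic, terms = base_terms)
  seen_adj_drop <- FALSE
  for (k in 1:5) {
    Xk <- cbind(X, N1 = with_seed_noise(100 + k, nrow(X)))
    f1 <- rsm_fit(Xk, y$hydroxybenzoic, terms = c(base_terms, "N1"))
    expect_gte(f1$r.squared, f0$r.squared - 1e-12)
    if (f1$adj.r.squared < f0$adj.r.squared) seen_adj_drop <- TRUE
  }
  expect_true(seen_adj_drop)
})

test_that("surface grids are regular, ordered, and agree with predict", {
  models <- read_coefficient_models()
  m <- models$hydroxybenzoic
  g <- surface_grid(m, c("X2", "X5"), resolution = 2L)
  expect_equal(nrow(g), 4L)
  expect_equal(g$X2, c(-1, -1, 1, 1))  # row-major, first factor slowest

  g3 <- surface_grid(m, c("X1", "X4"), resolution = 3L)
  origin_row <- g3[g3$X1 == 0 & g3$X4 == 0, ]
  expect_equal(origin_row$y_hat, predict(m, rep(0, 5)))

  zero <- rsm_from_coefficients(stats::setNames(c(5, rep(0, 19)), rsm_terms()))
  gz <- surface_grid(zero, c("X1", "X2"), resolution = 4L)
  expect_true(all(gz$y_hat == 5))

  expect_error(surface_grid(m, c("X1", "X1")), "distinct")
  expect_error(surface_grid(m, c("X1", "X2"), resolution = 1L), ">= 2")
})

test_that("models round-trip through JSON export", {
  spec <- simulation_spec(seed = 31)
  des <- simulate_design(spec)
  y <- simulate_responses(des, spec)
  f <- rsm_fit(attr(y, "coded"), y$abts, response = "abts")
  path <- withr::local_tempfile(fileext = ".json")
  write_rsm_json(f, path)
  back <- read_rsm_json(path)
  expect_equal(coef(back), coef(f))
  probe <- matrix(runif(25, -1, 1), 5, 5,
                  dimnames = list(NULL, paste0("X", 1:5)))
  expect_equal(predict(back, probe), predict(f, probe), tolerance = 1e-12)
})
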