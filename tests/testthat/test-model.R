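orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * p), n, p)
  M <- scale(M, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))[, seq_len(p)]
  colnames(Q) <- paste0("g", seq_len(p))
  Q
}

test_that("unpenalized fits match ordinary least squares", {
  set.seed(10)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(40, sd = 0.1)
  fm <- fit_one(X, y, model_spec("lasso", lambda = 0, standardize = FALSE),
                list(train = 1:30, test = 31:40))
  ols <- stats::coef(stats::lm(y[1:30] ~ X[1:30, ]))
  expect_equal(unname(fm$intercept), unname(ols[1]), tolerance = 1e-6)
  expect_equal(unname(fm$coefficients), unname(ols[-1]), tolerance = 1e-6)
})

test_that("fixed-penalty lasso soft-thresholds OLS on orthonormal designs", {
  n <- 60; p <- 5
  Q <- orthonormal_design(n, p, seed = 2)
  set.seed(3)
  y <- as.numeric(Q %*% c(3, -2, 1, 0.2, 0)) + rnorm(n, sd = 0.3)
  lambda <- 1.2
  fm <- fit_one(Q, y, model_spec("lasso", lambda = lambda,
                                 standardize = FALSE),
                list(train = seq_len(n), test = integer(0)))
  b_ols <- drop(crossprod(Q, y - mean(y)))
  # minimizing RSS + lambda * sum|beta| with Q'Q = I thresholds at lambda/2
  expected <- sign(b_ols) * pmax(abs(b_ols) - lambda / 2, 0)
  expect_equal(unname(fm$coefficients), unname(expected), tolerance = 1e-6)
})

test_that("penalized objectives are minimized to coordinate-descent accuracy", {
  set.seed(4)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- as.numeric(X[, 1] - X[, 2]) + rnorm(20, sd = 0.5)
  split <- list(train = 1:20, test = integer(0))
  for (algo in c("lasso", "elastic_net")) {
    l2 <- algo == "elastic_net"
    for (lambda in c(0.5, 2, 8)) {
      fm <- fit_one(X, y, model_spec(algo, lambda = lambda,
                                     standardize = FALSE), split)
      oracle <- cd_penalized(X, y, lambda, l2 = l2)
      obj_fit <- penalized_objective(X, y, fm$intercept, fm$coefficients,
                                     lambda, l2 = l2)
      obj_oracle <- penalized_objective(X, y, oracle$intercept,
                                        oracle$beta, lambda, l2 = l2)
      expect_lt(obj_fit - obj_oracle, 1e-5 * max(1, abs(obj_oracle)))
    }
  }
})

test_that("strong penalties zero out permuted-response fits", {
  set.seed(5)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- sample(rnorm(50))
  fm <- fit_one(X, y, model_spec("lasso", lambda = 1e4,
                                 standardize = FALSE),
                list(train = 1:50, test = integer(0)))
  expect_true(all(fm$coefficients == 0))
})

test_that("fit_one validates its split and response contracts", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  spec <- model_spec("lasso", lambda = 1)
  expect_error(fit_one(X, y, spec, list(train = 1:5, test = 6:20)),
               "fewer than 10")
  expect_error(fit_one(X, rep(1, 20), spec,
                       list(train = 1:15, test = 16:20)), "constant")
  expect_error(fit_one(X, y, spec, list(train = 1:15, test = 15:20)),
               "overlap")
  expect_error(fit_one(X, y[1:10], spec, list(train = 1:8, test = 9:10)),
               "align")
})

test_that("ensembles recover noiseless signal and are seed-deterministic", {
  set.seed(6)
  X <- matrix(rnorm(50 * 3), 50, 3,
              dimnames = list(sprintf("CL%02d", 1:50), c("g1", "g2", "g3")))
  y <- 2 * X[, 1]
  ens <- run_ensemble(X, y, model_spec("lasso", nfolds = 5),
                      n_models = 40, seed = 11)
  expect_gte(ens$r, 0.999)
  ens2 <- run_ensemble(X, y, model_spec("lasso", nfolds = 5),
                       n_models = 40, seed = 11)
  expect_identical(ens$predictions, ens2$predictions)
  expect_identical(ens$r, ens2$r)
  expect_error(run_ensemble(X[1:20, ], y[1:20]), "at least 25")
})

test_that("split bookkeeping: 80/20 sizes and test coverage", {
  set.seed(7)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("CL%02d", 1:n), paste0("g", 1:4)))
  y <- X[, 1] + rnorm(n)
  ens <- run_ensemble(X, y, model_spec("lasso", lambda = 1), n_models = 100,
                      seed = 3)
  sizes <- vapply(ens$models, function(m) length(m$train), integer(1))
  expect_true(all(sizes == round(0.8 * n)))
  overlap <- vapply(ens$models,
                    function(m) length(intersect(m$train, m$test)),
                    integer(1))
  expect_true(all(overlap == 0L))
  expect_equal(ens$n, n)
  expect_true(all(ens$predictions$n_test_appearances >= 5))
  expect_equal(mean(ens$predictions$n_test_appearances), 20, tolerance = 0.1)
})

test_that("all algorithms share the split schedule at a common seed", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("CL%02d", 1:n), paste0("g", 1:5)))
  y <- X[, 1] - X[, 2] + rnorm(n, sd = 0.5)
  splits_of <- function(spec) {
    # 5 resamples leave some lines uncovered; irrelevant here
    ens <- suppressWarnings(run_ensemble(X, y, spec, n_models = 5,
                                         seed = 21))
    lapply(ens$models, `[[`, "train")
  }
  lasso <- splits_of(model_spec("lasso", lambda = 1))
  enet <- splits_of(model_spec("elastic_net", lambda = 1))
  forest <- splits_of(model_spec("random_forest", ntree = 20))
  expect_identical(lasso, enet)
  expect_identical(lasso, forest)
})

test_that("absolute errors are reported in ascending dependency order", {
  ens <- structure(list(predictions = data.frame(
    cell_line = c("C1", "C2", "C3"), observed = c(0.5, -1, 2),
    predicted_mean = c(0.5, 0, 2), n_test_appearances = c(3L, 4L, 2L),
    abs_error = c(0, 1, 0), stringsAsFactors = FALSE)),
    class = "ensemble_result")
  got <- evaluate_absolute_error(ens)
  expect_equal(got$cell_line, c("C2", "C1", "C3"))
  expect_true(!is.unsorted(got$observed))
  expect_equal(got$abs_error, c(1, 0, 0))
})

test_that("predictor frequency counts signed non-zero coefficients", {
  m1 <- structure(list(coefficients = c(A = -0.3, B = 0, C = 0.1)),
                  class = "fitted_model")
  m2 <- structure(list(coefficients = c(A = -0.2, D = 0.4)),
                  class = "fitted_model")
  got <- predictor_frequency(list(m1, m2))
  expect_equal(got$gene, c("A", "C", "D"))  # B omitted; A first by total
  expect_equal(got$neg_count, c(2L, 0L, 0L))
  expect_equal(got$pos_count, c(0L, 1L, 1L))
  expect_equal(got$total, got$neg_count + got$pos_count)

  expect_equal(extract_nonzero_predictors(list(m1)), c("A", "C"))
  expect_equal(extract_nonzero_predictors(list(m1, m2)), c("A", "C", "D"))
  zero <- structure(list(coefficients = c(A = 0)), class = "fitted_model")
  expect_warning(none <- extract_nonzero_predictors(list(zero)), "non-zero")
  expect_length(none, 0L)
})

test_that("an empty exclusion reproduces the full-network ensemble", {
  set.seed(9)
  n <- 40
  genes <- paste0("g", 1:6)
  expr <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(sprintf("CL%02d", 1:n), genes))
  y <- expr[, 1] + rnorm(n, sd = 0.5)
  spec <- model_spec("lasso", lambda = 2)
  full <- suppressWarnings(run_ensemble(expr, y, spec, n_models = 10,
                                        seed = 5))
  same <- suppressWarnings(exclusion_run(genes, character(0), expr, y,
                                         spec, n_models = 10, seed = 5))
  expect_equal(same$r, full$r, tolerance = 1e-12)
  w <- testthat::capture_warnings(
    exclusion_run(genes, "NOT_A_GENE", expr, y, spec, n_models = 10,
                  seed = 5))
  expect_true(any(grepl("ignored", w)))
  expect_error(exclusion_run(genes, genes, expr, y, spec), "remain")
})

test_that("model plans count scheduled fits across grids and datasets", {
  expect_equal(nrow(model_plan(enumerate_grid(), n_models = 100)), 12000L)
  expect_equal(nrow(model_plan(c("mutation", "rna"), n_models = 100)), 400L)
  expect_equal(nrow(model_plan("a", "crispr", 1)), 1L)
  expect_error(model_plan(character(0)), "nonempty")
})
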