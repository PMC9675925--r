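test_that("fit statistics reproduce the Gaussian-MLE reporting conventions", {
  # build a residual vector with a prescribed SSE
  sse <- 9980.6204
  obs <- c(sqrt(sse), rep(0, 23))
  pred <- rep(0, 24)
  fs <- fit_statistics(obs, pred)
  expect_equal(fs$sse, sse, tolerance = 1e-10)
  expect_equal(fs$rmse, 20.3926, tolerance = 1e-4)
  expect_equal(fs$neg_log_lik, 106.4187, tolerance = 1e-4)
  expect_equal(fs$n, 24)
  # perfect fit
  perfect <- fit_statistics(1:5, 1:5)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mad, 0)
  # degenerate: zero observed variance with nonzero error
  expect_equal(fit_statistics(rep(2, 4), rep(3, 4))$r_squared, -Inf)
  expect_error(fit_statistics(1, 1), "at least 2")
  expect_error(fit_statistics(1:3, 1:4), "lengths")
})

test_that("rmse^2 * n equals sse for arbitrary data", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    fs <- fit_statistics(stats::rnorm(n), stats::rnorm(n))
    expect_equal(fs$rmse^2 * fs$n, fs$sse, tolerance = 1e-9)
  }
})

test_that("K-fold splits are balanced, exhaustive and seeded", {
  a <- kfold_split(30, 5, seed = 3)
  expect_equal(as.vector(table(a$fold)), rep(6, 5))
  expect_identical(a, kfold_split(30, 5, seed = 3))
  expect_false(identical(a$fold, kfold_split(30, 5, seed = 4)$fold))
  # uneven n: sizes differ by at most 1, folds cover all runs
  b <- kfold_split(32, 5, seed = 1)
  sizes <- as.vector(table(b$fold))
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(b$run, 1:32)
  expect_error(kfold_split(10, 11, seed = 1), "infeasible")
  expect_error(kfold_split(10, 1, seed = 1), ">= 2")
})

test_that("training recovers a realizable function to near-perfect R2", {
  # data generated exactly by a small network with outputs on the scales of
  # the four responses (nm, PDI, mV, %), zero noise
  truth <- local({
    set.seed(21)
    new_surrogate(
      weights = list(matrix(stats::rnorm(3 * 4, sd = 0.3), 3, 4),
                     matrix(stats::rnorm(4 * 3), 4, 3) * c(60, 0.08, 2, 8)),
      biases = list(stats::rnorm(3), c(150, 0.3, -10, 60)),
      input_space = "actual")
  })
  truth$input_names <- nlc_factors()$symbol
  truth$response_names <- c("Y1", "Y2", "Y3", "Y4")
  design <- generate_ccrd(nlc_factors())
  d <- simulate_dataset(design, truth_network = truth, noise_sd = rep(0, 4),
                        seed = 1)
  fit <- nn_train(d, hidden = c(6), n_restarts = 4, maxit = 400, seed = 2)
  expect_true(all(fit$fit_report$r_squared >= 0.999))
})

test_that("training is deterministic for fixed data, seed and settings", {
  d <- nlc_study_data()
  f1 <- nn_train(d, n_restarts = 2, maxit = 60, seed = 9)
  f2 <- nn_train(d, n_restarts = 2, maxit = 60, seed = 9)
  expect_identical(f1$fit_report, f2$fit_report)
  expect_identical(f1$network$weights, f2$network$weights)
})

test_that("returned network predicts in actual units after standardization", {
  d <- nlc_study_data()
  fit <- nn_train(d, n_restarts = 2, maxit = 150, seed = 4)
  pred <- predict_responses(fit$network, d)
  # particle size predictions on the nm scale, PDI on the unit scale
  expect_gt(stats::cor(pred$Y1, d$Y1_nm_mean), 0.98)
  expect_true(all(pred$Y2 > -0.5 & pred$Y2 < 1.5))
  expect_error(nn_train(d[1:5, ], seed = 1), "too few")
})

test_that("held-out runs are excluded from fitting and reported separately", {
  d <- nlc_study_data()
  held <- c(2, 10, 11, 12, 20, 29)
  fit <- nn_train(d, test_runs = held, n_restarts = 3, maxit = 200, seed = 7)
  rep <- fit$fit_report
  expect_setequal(unique(rep$partition), c("training", "testing"))
  expect_equal(unique(rep$n[rep$partition == "training"]), 24)
  expect_equal(unique(rep$n[rep$partition == "testing"]), 6)
})

test_that("cross-validation stacks per-fold reports", {
  d <- nlc_study_data()
  cv <- nn_crossvalidate(d, k = 3, seed = 2, n_restarts = 2, maxit = 60)
  expect_equal(length(cv$fits), 3)
  expect_equal(nrow(cv$report), 3 * 8)  # 4 responses x 2 partitions x 3 folds
  expect_true(all(c("fold", "response", "partition") %in% names(cv$report)))
  td <- tidy(cv)
  expect_identical(td, cv$report)
})

test_that("per-response training fits a single-output network", {
  d <- nlc_study_data()
  fit <- nn_train(d, hidden = c(4), responses = "Y1", n_restarts = 2,
                  maxit = 150, seed = 3)
  expect_equal(fit$network$layer_sizes, c(4, 4, 1))
  expect_equal(unique(fit$fit_report$response), "Y1")
  expect_gt(fit$fit_report$r_squared[1], 0.9)
  expect_error(nn_train(d, responses = "Y9"), "unknown response")
})
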