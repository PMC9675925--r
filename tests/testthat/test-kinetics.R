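test_that("each model recovers its own noiseless data exactly", {
  t6 <- c(0.5, 1, 2, 4, 8, 24)
  cases <- list(
    list(model = "zero_order", params = c(k = 4)),
    list(model = "first_order", params = c(k = 0.08)),
    list(model = "higuchi", params = c(k = 12.5)),
    list(model = "hixson_crowell", params = c(k = 0.012)),
    list(model = "korsmeyer_peppas", params = c(k = 0.15, n = 0.43))
  )
  for (cs in cases) {
    prof <- simulate_release(cs$model, cs$params, times = t6)
    fit <- fit_kinetic(prof, cs$model)
    expect_true(fit$converged)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(fit$params[["k"]], cs$params[["k"]], tolerance = 1e-6)
    if (cs$model == "korsmeyer_peppas") {
      expect_equal(fit$params[["n"]], 0.43, tolerance = 1e-6)
    }
    # and rank_models places the generating model first
    ranked <- rank_models(fit_all_kinetics(prof))
    expect_equal(ranked$model[1], cs$model)
  }
})

test_that("higuchi closed-form: Q = 12.5 sqrt(t) gives Q(4) = 25", {
  prof <- simulate_release("higuchi", c(k = 12.5), times = c(1, 4, 9))
  expect_equal(prof$cumulative_release_pct[2], 25)
})

test_that("korsmeyer-peppas nests higuchi at n = 0.5", {
  prof <- simulate_release("higuchi", c(k = 12.5), times = c(0.5, 1, 2, 4, 8, 24))
  kp <- fit_kinetic(prof, "korsmeyer_peppas")
  expect_equal(kp$params[["n"]], 0.5, tolerance = 1e-6)
  expect_equal(kp$r_squared, 1, tolerance = 1e-9)
})

test_that("equally good fits rank by parsimony, then canonical name order", {
  # identical residuals and sample size: the information criterion reduces
  # to the parameter-count penalty
  aicc <- function(sse, n, p) {
    k <- p + 1
    n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  mk <- function(model, params, sse, n = 8) {
    p <- length(params)
    structure(list(model = model, params = params, r_squared = 1 - sse / 100,
                   converged = TRUE, curve = identity, sse = sse, sst = 100,
                   n_obs = n, aicc = aicc(sse, n, p),
                   profile = tibble::tibble()),
              class = "nlc_kinetic_fit")
  }
  fits <- list(mk("korsmeyer_peppas", c(k = 0.1, n = 0.5), sse = 5),
               mk("higuchi", c(k = 10), sse = 5),
               mk("zero_order", c(k = 2), sse = 50))
  ranked <- rank_models(fits)
  expect_equal(ranked$model, c("higuchi", "korsmeyer_peppas", "zero_order"))
  # single successful fit: returned as the only row
  expect_equal(rank_models(fits[3])$model, "zero_order")
  expect_error(rank_models(list()), "no successful")
})

test_that("profile validation rejects malformed release tables", {
  expect_error(fit_kinetic(tibble::tibble(time_h = c(2, 1),
                                          cumulative_release_pct = c(1, 2)),
                           "higuchi"), "increasing")
  expect_error(fit_kinetic(tibble::tibble(time_h = 1:3,
                                          cumulative_release_pct = c(1, 2, 150)),
                           "higuchi"), "110")
  expect_error(fit_kinetic(tibble::tibble(time_h = 1:2,
                                          cumulative_release_pct = c(1, 2)),
                           "higuchi"), "insufficient")
  expect_error(simulate_release("weibull", c(k = 1), 1:3), "unknown")
})

test_that("the packaged release profile is ranked as diffusion-controlled", {
  prof <- nlc_release_data()
  expect_equal(nrow(prof), 3)
  ranked <- rank_models(fit_all_kinetics(prof))
  expect_equal(ranked$model[1], "higuchi")
})

test_that("noise can only degrade the generating model's fit on average", {
  t8 <- c(0.5, 1, 2, 3, 5, 8, 12, 24)
  r2 <- vapply(1:30, function(s) {
    prof <- simulate_release("higuchi", c(k = 12.5), t8, noise_sd = 2, seed = s)
    fit_kinetic(prof, "higuchi")$r_squared
  }, numeric(1))
  expect_lt(mean(r2), 1)
  expect_gt(mean(r2), 0.9)
})

test_that("the releasable-dose plateau is configurable for saturation laws", {
  t6 <- c(0.5, 1, 2, 4, 8, 24)
  q <- 60 * (1 - exp(-0.25 * t6))  # incomplete release: plateau at 60%
  prof <- tibble::tibble(time_h = t6, cumulative_release_pct = q)
  with_plateau <- fit_kinetic(prof, "first_order", q_inf = 60)
  expect_equal(with_plateau$params[["k"]], 0.25, tolerance = 1e-6)
  expect_equal(with_plateau$r_squared, 1, tolerance = 1e-9)
  default <- fit_kinetic(prof, "first_order")
  expect_lt(default$r_squared, with_plateau$r_squared)
})
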