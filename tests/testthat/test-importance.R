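test_that("garson importance equals the exhaustive path-product oracle", {
  for (seed in c(101, 202, 303, 404, 505)) {
    net <- random_net(seed, n_in = 3, n_hidden = 4, n_out = 2)
    gi <- garson_importance(net)
    for (r in 1:2) {
      oracle <- garson_oracle_1h(net$weights[[1]], net$weights[[2]], r)
      got <- gi$percent[gi$response == paste0("Y", r)]
      expect_equal(got, oracle, tolerance = 1e-10)
    }
  }
})

test_that("garson percentages sum to 100 per response", {
  for (net in list(random_net(7), published_network())) {
    gi <- garson_importance(net)
    sums <- tapply(gi$percent, gi$response, sum)
    expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-6)
    expect_true(all(gi$percent >= 0))
  }
})

test_that("symmetric and degenerate attributions behave as expected", {
  # single input: everything attributed to it
  single <- toy_net(W1 = matrix(c(0.4, -1.1), 2, 1), b1 = c(0, 0),
                    W2 = matrix(c(1, 2), 1, 2), b2 = 0)
  expect_equal(garson_importance(single)$percent, 100)
  # two inputs with equal absolute weights into every hidden unit: 50/50
  sym <- toy_net(W1 = matrix(c(1, -2, 0.5, -1, 2, 0.5), 3, 2), b1 = rep(0, 3),
                 W2 = matrix(c(1, -1, 3), 1, 3), b2 = 0)
  expect_equal(garson_importance(sym)$percent, c(50, 50))
  # all-zero weights: undefined
  zero <- toy_net(W1 = matrix(0, 2, 2), b1 = c(1, 1),
                  W2 = matrix(0, 1, 2), b2 = 0)
  expect_error(garson_importance(zero), "undefined")
})

test_that("a disconnected input gets 0% and leaves the others' order intact", {
  net <- random_net(31, n_in = 3, n_hidden = 4, n_out = 1)
  base <- garson_importance(net)
  W1aug <- cbind(net$weights[[1]], 0)  # 4th input with all-zero weights
  aug <- toy_net(W1aug, net$biases[[1]], net$weights[[2]], net$biases[[2]])
  gi <- garson_importance(aug)
  expect_equal(gi$percent[4], 0)
  expect_equal(order(-gi$percent[1:3]), order(-base$percent))
  expect_equal(gi$percent[1:3], base$percent, tolerance = 1e-10)
})

test_that("garson is invariant to positive rescaling of incoming weights", {
  net <- random_net(57, n_in = 3, n_hidden = 4, n_out = 2)
  scaled <- net
  scaled$weights[[1]][2, ] <- 5 * scaled$weights[[1]][2, ]  # one hidden unit
  expect_equal(garson_importance(scaled)$percent,
               garson_importance(net)$percent, tolerance = 1e-10)
})

test_that("permutation importance is seeded and behaviorally grounded", {
  d <- nlc_study_data()
  net <- published_network()
  p1 <- permutation_importance(net, d, seed = 5, n_perm = 5)
  p2 <- permutation_importance(net, d, seed = 5, n_perm = 5)
  expect_identical(p1, p2)
  sums <- tapply(p1$percent, p1$response, sum)
  expect_equal(as.numeric(sums), rep(100, 4), tolerance = 1e-6)
  # input with all-zero outgoing weights has zero importance
  W1 <- matrix(c(1, -1, 0.5, 2, 0, 0), 2, 3)  # third input disconnected
  net0 <- toy_net(W1, c(0, 0), matrix(c(1, 1), 1, 2), 0,
                  input_names = c("X1", "X2", "X3"))
  dat <- tibble::tibble(X1 = stats::rnorm(10), X2 = stats::rnorm(10),
                        X3 = stats::rnorm(10))
  p <- permutation_importance(net0, dat, seed = 1, n_perm = 10,
                              factors = new_factors(
                                c("X1", "X2", "X3"), letters[1:3],
                                rep("wt%", 3), center = rep(10, 3),
                                step = rep(1, 3)))
  expect_equal(p$percent[p$input == "X3"], 0)
})

test_that("garson and permutation agree on a separable coded-space network", {
  # each input feeds its own hidden unit; output weights set the strengths,
  # so both the weight-path and the behavioral method must recover the same
  # ordering
  d <- nlc_study_data()
  W1 <- diag(c(0.9, 1.1, 1.0, 0.8))
  W2 <- matrix(c(8, 4, 2, 1), 1, 4)
  net <- new_surrogate(weights = list(W1, W2),
                       biases = list(rep(0, 4), 0),
                       input_space = "coded",
                       input_names = nlc_factors()$symbol,
                       response_names = "Y1")
  g <- garson_importance(net)
  p <- permutation_importance(net, d, seed = 2, n_perm = 20)
  expect_equal(order(-g$percent), order(-p$percent))
  expect_equal(g$input[order(-g$percent)], c("X1", "X2", "X3", "X4"))
})

test_that("constant input columns yield a warning and zero importance", {
  net <- random_net(8, n_in = 3, n_hidden = 4, n_out = 1)
  net$input_names <- c("X1", "X2", "X3")
  dat <- tibble::tibble(X1 = rep(1, 8), X2 = stats::rnorm(8),
                        X3 = stats::rnorm(8))
  f <- new_factors(c("X1", "X2", "X3"), letters[1:3], rep("wt%", 3),
                   center = rep(10, 3), step = rep(1, 3))
  expect_warning(p <- permutation_importance(net, dat, seed = 1, n_perm = 3,
                                             factors = f),
                 "constant")
  expect_equal(p$percent[p$input == "X1"], 0)
})
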