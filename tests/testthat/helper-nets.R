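# small networks and fixtures built in code for the tests

# 1-hidden-layer net with given weight matrices (hidden tanh_half, linear out)
toy_net <- function(W1, b1, W2, b2, input_space = "actual",
                    input_names = paste0("X", seq_len(ncol(W1))),
                    response_names = paste0("Y", seq_len(nrow(W2)))) {
  new_surrogate(weights = list(W1, W2), biases = list(b1, b2),
                input_space = input_space, input_names = input_names,
                response_names = response_names)
}

# seeded random 1-hidden-layer net
random_net <- function(seed, n_in = 3, n_hidden = 4, n_out = 2) {
  set.seed(seed)
  toy_net(
    W1 = matrix(stats::rnorm(n_hidden * n_in), n_hidden, n_in),
    b1 = stats::rnorm(n_hidden),
    W2 = matrix(stats::rnorm(n_out * n_hidden), n_out, n_hidden),
    b2 = stats::rnorm(n_out)
  )
}

# independent evaluation of the published 4-9-9-4 coefficients, written as
# plain scalar arithmetic (no shared code with the package's forward pass)
published_oracle <- function(x) {
  th <- function(z) (exp(0.5 * z) - exp(-0.5 * z)) / (exp(0.5 * z) + exp(-0.5 * z))
  X1 <- x[1]; X2 <- x[2]; X3 <- x[3]; X4 <- x[4]
  H1 <- th(0.69 * X1 - 0.09 * X2 - 0.28 * X3 - 2.79 * X4 + 3.07)
  H2 <- th(-0.66 * X1 - 0.26 * X2 - 1.99 * X3 - 0.62 * X4 + 18.45)
  H3 <- th(-0.24 * X1 + 0.07 * X2 - 0.07 * X3 - 2.57 * X4 + 0.50)
  H4 <- th(0.22 * X1 + 0.26 * X2 - 0.29 * X3 - 1.00 * X4 - 4.35)
  H5 <- th(0.05 * X1 - 0.22 * X2 + 0.74 * X3 + 2.24 * X4 + 1.08)
  H6 <- th(0.09 * X1 + 0.05 * X2 - 1.88 * X3 + 4.23 * X4 - 2.99)
  H7 <- th(0.05 * X1 - 0.14 * X2 - 1.91 * X3 + 2.81 * X4 + 7.28)
  H8 <- th(-1.22 * X1 + 0.13 * X2 + 0.66 * X3 + 0.01 * X4 + 2.31)
  H9 <- th(-0.92 * X1 - 0.08 * X2 - 1.42 * X3 - 2.40 * X4 + 14.92)
  HH1 <- th(-2.47 * H1 + 1.80 * H2 - 1.04 * H3 + 0.17 * H4 + 2.64 * H5 +
              2.81 * H6 + 2.45 * H7 + 0.76 * H8 - 4.03 * H9 + 1.97)
  HH2 <- th(-0.58 * H1 + 3.96 * H2 - 0.95 * H3 + 1.12 * H4 - 2.31 * H5 -
              2.05 * H6 + 1.00 * H7 - 1.42 * H8 + 0.14 * H9 - 0.61)
  HH3 <- th(-0.55 * H1 + 2.30 * H2 + 0.51 * H3 + 0.31 * H4 - 1.62 * H5 +
              0.14 * H6 + 0.49 * H7 - 0.77 * H8 + 4.15 * H9 - 1.34)
  HH4 <- th(0.81 * H1 - 0.25 * H2 + 0.48 * H3 - 5.18 * H4 + 0.60 * H5 -
              0.70 * H6 - 0.78 * H7 + 1.88 * H8 + 2.67 * H9 + 0.34)
  HH5 <- th(2.41 * H1 - 1.86 * H2 - 1.43 * H3 + 1.12 * H4 - 1.49 * H5 -
              0.55 * H6 + 3.74 * H7 - 1.08 * H8 - 0.14 * H9 + 2.29)
  HH6 <- th(0.12 * H1 + 2.43 * H2 - 1.94 * H3 - 0.92 * H4 - 1.63 * H5 -
              2.39 * H6 + 1.14 * H7 - 1.90 * H8 + 0.50 * H9 - 0.97)
  HH7 <- th(-0.64 * H1 - 0.17 * H2 - 1.41 * H3 - 0.68 * H4 + 0.32 * H5 -
              2.35 * H6 + 0.73 * H7 - 1.95 * H8 - 0.18 * H9 - 0.92)
  HH8 <- th(0.10 * H1 + 0.87 * H2 - 1.34 * H3 - 1.35 * H4 - 0.56 * H5 -
              3.26 * H6 + 1.15 * H7 - 0.77 * H8 - 0.94 * H9 - 0.82)
  HH9 <- th(-1.09 * H1 - 2.39 * H2 - 2.54 * H3 - 0.35 * H4 + 0.40 * H5 -
              1.37 * H6 - 0.10 * H7 + 0.05 * H8 + 1.26 * H9 - 1.94)
  c(Y1 = 18.19 * HH1 - 40.03 * HH2 + 26.22 * HH3 - 146.97 * HH4 -
      78.91 * HH5 + 180.00 * HH6 + 121.12 * HH7 - 112.00 * HH8 -
      102.29 * HH9 + 170.31,
    Y2 = -0.02 * HH1 + 0.09 * HH2 - 0.04 * HH3 - 0.07 * HH4 - 0.10 * HH5 +
      0.20 * HH6 + 0.03 * HH7 - 0.13 * HH8 + 0.13 * HH9 + 0.30,
    Y3 = -2.54 * HH1 + 0.15 * HH2 - 1.86 * HH3 + 0.35 * HH4 + 0.94 * HH5 +
      2.50 * HH6 - 0.33 * HH7 - 0.10 * HH8 + 3.16 * HH9 - 10.73,
    Y4 = 3.90 * HH1 + 29.57 * HH2 - 10.98 * HH3 - 1.71 * HH4 - 5.88 * HH5 -
      18.64 * HH6 - 12.30 * HH7 + 14.02 * HH8 + 11.59 * HH9 + 61.43)
}

# exhaustive path-product Garson oracle for a 1-hidden-layer net (loops,
# independent of the package's matrix formulation)
garson_oracle_1h <- function(W1, W2, response_row) {
  n_in <- ncol(W1); n_h <- nrow(W1)
  imp <- numeric(n_in)
  for (j in seq_len(n_in)) {
    for (h in seq_len(n_h)) {
      imp[j] <- imp[j] +
        abs(W1[h, j]) / sum(abs(W1[h, ])) * abs(W2[response_row, h])
    }
  }
  100 * imp / sum(imp)
}
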