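#' Half-argument hyperbolic tangent activation
#'
#' The hidden-unit transfer function of the surrogate network,
#' `tanh_half(z) = (exp(z/2) - exp(-z/2)) / (exp(z/2) + exp(-z/2))`,
#' i.e. `tanh(0.5 z)`. Odd, strictly increasing, range (-1, 1); saturates
#' smoothly for large |z|.
#'
#' @param z Numeric vector.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' tanh_half(0)   # 0
#' tanh_half(2)   # tanh(1) = 0.7615942...
tanh_half <- function(z) tanh(0.5 * z)

#' Construct a feed-forward surrogate network
#'
#' A layered multilayer perceptron: each layer applies an affine map
#' (weights %*% input + biases) followed by its activation. Hidden layers
#' use [tanh_half()]; the output layer is linear (identity).
#'
#' @param weights List of weight matrices; `weights[[l]]` has one row per
#'   unit of layer `l` and one column per unit of the previous layer.
#' @param biases List of bias vectors, conformable with `weights`.
#' @param activation Character vector of per-layer activation tags,
#'   `"tanh_half"` or `"identity"`; the last entry must be `"identity"`.
#' @param input_space `"actual"` or `"coded"`: the units the first layer
#'   expects.
#' @param input_names,response_names Names of inputs and outputs.
#' @return An object of class `nlc_surrogate`.
#' @export
new_surrogate <- function(weights, biases,
                          activation = c(rep("tanh_half", length(weights) - 1L),
                                         "identity"),
                          input_space = c("actual", "coded"),
                          input_names = paste0("X", seq_len(ncol(weights[[1]]))),
                          response_names = paste0("Y", seq_len(nrow(weights[[length(weights)]])))) {
  input_space <- match.arg(input_space)
  stopifnot(length(weights) == length(biases),
            length(activation) == length(weights))
  for (l in seq_along(weights)) {
    w <- weights[[l]] <- as.matrix(weights[[l]])
    if (length(biases[[l]]) != nrow(w)) {
      stop("bias length does not match weight rows at layer ", l, call. = FALSE)
    }
    if (l > 1L && ncol(w) != nrow(weights[[l - 1L]])) {
      stop("weight matrices do not chain at layer ", l, call. = FALSE)
    }
    if (any(!is.finite(w)) || any(!is.finite(biases[[l]]))) {
      stop("non-finite network parameter at layer ", l, call. = FALSE)
    }
  }
  if (activation[length(activation)] != "identity") {
    stop("output layer activation must be identity", call. = FALSE)
  }
  if (!all(activation %in% c("tanh_half", "identity"))) {
    stop("unknown activation tag", call. = FALSE)
  }
  structure(
    list(
      layer_sizes = c(ncol(weights[[1]]), vapply(weights, nrow, integer(1))),
      weights = weights, biases = lapply(biases, as.numeric),
      activation = activation, input_space = input_space,
      input_names = input_names, response_names = response_names
    ),
    class = "nlc_surrogate"
  )
}

#' @export
print.nlc_surrogate <- function(x, ...) {
  cat("<nlc_surrogate> ", paste(x$layer_sizes, collapse = "-"),
      " feed-forward network (", x$input_space, " inputs)\n", sep = "")
  cat("  inputs:    ", paste(x$input_names, collapse = ", "), "\n", sep = "")
  cat("  responses: ", paste(x$response_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

apply_activation <- function(z, tag) {
  switch(tag, tanh_half = tanh_half(z), identity = z,
         stop("unknown activation tag", call. = FALSE))
}

# Core propagation on a points-in-rows matrix; returns n x n_responses matrix.
forward_matrix <- function(net, x) {
  if (ncol(x) != net$layer_sizes[1]) {
    stop("input dimension ", ncol(x), " does not match network input size ",
         net$layer_sizes[1], call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite network input", call. = FALSE)
  a <- x
  for (l in seq_along(net$weights)) {
    z <- tcrossprod(a, net$weights[[l]])
    z <- sweep(z, 2, net$biases[[l]], `+`)
    a <- apply_activation(z, net$activation[l])
  }
  colnames(a) <- net$response_names
  a
}

#' Evaluate a surrogate network
#'
#' Propagates formulation compositions through the network and returns the
#' predicted responses. Accepts a data frame with factor columns (actual
#' units by default), a numeric matrix (points in rows), or a single numeric
#' vector of length 4.
#'
#' @param net An `nlc_surrogate`.
#' @param newdata Data frame, matrix, or numeric vector of compositions in
#'   `net$input_space` units.
#' @param factors Factor table used to resolve data-frame columns and to
#'   convert between coded and actual spaces when needed.
#' @param input_space Space of the supplied values (`net$input_space` by
#'   default); values are converted if it differs from the network's.
#' @return A tibble with one row per point and one column per response.
#' @export
#' @examples
#' net <- published_network()
#' predict_responses(net, c(4.80, 30.00, 3.50, 1.65))
predict_responses <- function(net, newdata, factors = nlc_factors(),
                              input_space = net$input_space) {
  if (is.data.frame(newdata)) {
    x <- factor_matrix(newdata, factors)
    input_space <- "actual"
  } else if (is.matrix(newdata)) {
    x <- newdata
  } else {
    x <- matrix(as.numeric(newdata), nrow = 1)
  }
  if (input_space != net$input_space) {
    x <- if (net$input_space == "actual") {
      coded_matrix_to_actual(x, factors)
    } else {
      actual_matrix_to_coded(x, factors)
    }
  }
  tibble::as_tibble(forward_matrix(net, x))
}

#' @export
predict.nlc_surrogate <- function(object, newdata, ...) {
  predict_responses(object, newdata, ...)
}

#' The published 4-9-9-4 surrogate network
#'
#' Loads the packaged coefficients of the published CFE-NLC surrogate: a
#' 4-9-9-4 network with `tanh(0.5 z)` hidden activations and a linear output
#' layer, whose inputs are the four formulation factors in actual units and
#' whose outputs are particle size (nm), PDI, zeta potential (mV) and %EE.
#'
#' @return An `nlc_surrogate`.
#' @export
#' @examples
#' predict_responses(published_network(), c(4.80, 30.00, 3.50, 1.65))
published_network <- function() {
  path <- system.file("extdata", "published_network_4_9_9_4.json",
                      package = "nlcoptim", mustWork = TRUE)
  net <- read_network(path)
  total <- sum(vapply(net$weights, function(w) sum(abs(w)), numeric(1))) +
    sum(vapply(net$biases, function(b) sum(abs(b)), numeric(1)))
  if (abs(total - 1400.33) > 1e-6) {
    stop("published-network fixture is corrupted (checksum mismatch)",
         call. = FALSE)
  }
  net
}

#' Read/write surrogate networks as JSON
#'
#' Networks are serialized with row-major weight matrices, biases,
#' activation tags and the input-space flag, so fitted and transcribed
#' networks share one portable format.
#'
#' @param path File path.
#' @param net An `nlc_surrogate`.
#' @param provenance Optional free-text note stored in the file.
#' @return `read_network()` returns an `nlc_surrogate`; `write_network()`
#'   returns `path` invisibly.
#' @export
read_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_along(j$biases), function(l) {
    w <- if (is.data.frame(j$weights)) j$weights[l, ] else j$weights[[l]]
    matrix(unlist(w$values), nrow = unlist(w$nrow), ncol = unlist(w$ncol),
           byrow = TRUE)
  })
  biases <- if (is.list(j$biases)) j$biases else as.list(j$biases)
  new_surrogate(
    weights = weights, biases = biases, activation = j$activation,
    input_space = j$input_space, input_names = j$input_names,
    response_names = j$response_names
  )
}

#' @rdname read_network
#' @export
write_network <- function(net, path, provenance = NULL) {
  out <- list(
    layer_sizes = net$layer_sizes,
    input_space = net$input_space,
    input_names = net$input_names,
    response_names = net$response_names,
    activation = net$activation,
    weights = lapply(net$weights, function(w) {
      list(nrow = nrow(w), ncol = ncol(w), values = as.vector(t(w)))
    }),
    biases = net$biases
  )
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
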