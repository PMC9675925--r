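#' Garson connection-weight importance
#'
#' Attributes each response to the network inputs by Garson's algorithm:
#' every input-to-output path contributes the product of absolute connection
#' weights along the path, with each hidden unit's contribution normalized
#' by the sum of absolute incoming weights at that unit. For networks with
#' two hidden layers the per-layer normalized products are chained along
#' every path. Percentages are scaled to sum to 100 per response.
#'
#' Note the known scale ambiguity of weight-based importance: rescaling a
#' tanh unit's incoming weights while compensating downstream changes the
#' attribution; [permutation_importance()] provides the behavioral
#' cross-check.
#'
#' @param net An `nlc_surrogate` with at least one hidden layer.
#' @param response Response name(s) to attribute; default all.
#' @return A tibble with columns `response`, `input`, `method`
#'   (`"garson_path"`), `percent`.
#' @export
#' @examples
#' garson_importance(published_network())
garson_importance <- function(net, response = net$response_names) {
  L <- length(net$weights)
  if (L < 2) stop("network has no hidden layer", call. = FALSE)
  # per-layer matrices of |w| normalized over inputs at each receiving unit
  norm_abs <- function(w) {
    a <- abs(w)
    rs <- rowSums(a)
    if (any(rs == 0)) {
      stop("undefined importance: a hidden unit has all-zero incoming weights",
           call. = FALSE)
    }
    a / rs
  }
  chain <- norm_abs(net$weights[[1]])
  if (L > 2) {
    for (l in 2:(L - 1L)) chain <- norm_abs(net$weights[[l]]) %*% chain
  }
  contrib <- abs(net$weights[[L]]) %*% chain  # responses x inputs
  rownames(contrib) <- net$response_names
  colnames(contrib) <- net$input_names
  if (all(contrib == 0)) {
    stop("undefined importance: zero output weights", call. = FALSE)
  }
  purrr::map_dfr(response, function(r) {
    v <- contrib[r, ]
    tibble::tibble(response = r, input = names(v), method = "garson_path",
                   percent = as.numeric(100 * v / sum(v)))
  })
}

#' Permutation importance
#'
#' Behavioral importance of each input: the mean increase in squared
#' prediction error for a response when that input's column is permuted
#' across the design points, averaged over `n_perm` seeded permutations and
#' normalized to sum to 100% per response. Serves as a model-agnostic
#' cross-check of [garson_importance()].
#'
#' @param net An `nlc_surrogate`.
#' @param data Study dataset or any data frame with the factor columns.
#' @param response Response name(s); default all.
#' @param seed Integer seed.
#' @param n_perm Number of permutations per input (>= 1).
#' @param factors Factor table.
#' @return A tibble with columns `response`, `input`, `method`
#'   (`"permutation"`), `percent`.
#' @export
permutation_importance <- function(net, data, response = net$response_names,
                                   seed = 1, n_perm = 20,
                                   factors = nlc_factors()) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  x <- factor_matrix(data, factors)
  if (net$input_space == "coded") x <- actual_matrix_to_coded(x, factors)
  base <- forward_matrix(net, x)
  n <- nrow(x)
  perms <- with_preserved_seed(seed, {
    lapply(seq_len(n_perm * ncol(x)), function(i) sample.int(n))
  })
  rises <- array(0, dim = c(ncol(x), ncol(base)),
                 dimnames = list(net$input_names, net$response_names))
  for (j in seq_len(ncol(x))) {
    if (stats::sd(x[, j]) == 0) {
      warning("input ", net$input_names[j],
              " is constant; permutation importance is zero", call. = FALSE)
      next
    }
    for (p in seq_len(n_perm)) {
      xp <- x
      xp[, j] <- x[perms[[(j - 1L) * n_perm + p]], j]
      pred <- forward_matrix(net, xp)
      rises[j, ] <- rises[j, ] + colMeans((pred - base)^2) / n_perm
    }
  }
  purrr::map_dfr(response, function(r) {
    v <- rises[, r]
    total <- sum(v)
    tibble::tibble(response = r, input = rownames(rises),
                   method = "permutation",
                   percent = if (total == 0) rep(0, length(v)) else
                     as.numeric(100 * v / total))
  })
}

#' Variable-importance bar chart
#'
#' @param importance A tibble from [garson_importance()] or
#'   [permutation_importance()] (or both row-bound).
#' @return A ggplot object: inputs on the x axis, percent importance on the
#'   y axis, faceted by response, colored by method.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = .data$input, y = .data$percent,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~response) +
    ggplot2::labs(x = NULL, y = "relative importance (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
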