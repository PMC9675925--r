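#' Single-response Derringer-Suich desirability
#'
#' Maps a predicted response to [0, 1] relative to its goal. For
#' `goal = "minimize"`: d = 1 at `y <= anchor_low`, 0 at `y >= anchor_high`,
#' and `((anchor_high - y) / (anchor_high - anchor_low))^shape` in between.
#' `goal = "maximize"` mirrors this.
#'
#' @param y Numeric vector of response values.
#' @param goal `"minimize"` or `"maximize"`.
#' @param anchor_low,anchor_high Anchors with `anchor_low < anchor_high`.
#' @param shape Positive exponent (1 = linear).
#' @return Numeric vector of desirabilities in [0, 1].
#' @export
#' @examples
#' desirability_one(5, "minimize", 0, 10)  # 0.5
desirability_one <- function(y, goal = c("minimize", "maximize"),
                             anchor_low, anchor_high, shape = 1) {
  goal <- match.arg(goal)
  if (!is.finite(anchor_low) || !is.finite(anchor_high) ||
      anchor_low >= anchor_high) {
    stop("anchors must satisfy anchor_low < anchor_high", call. = FALSE)
  }
  if (shape <= 0) stop("shape must be > 0", call. = FALSE)
  frac <- (anchor_high - y) / (anchor_high - anchor_low)
  if (goal == "maximize") frac <- 1 - frac
  pmin(1, pmax(0, frac))^shape
}

#' Overall desirability
#'
#' Geometric-mean composite of single-response desirabilities: zero if any
#' component is zero (the veto property), one only when all components are.
#'
#' @param d Numeric vector of desirabilities in [0, 1].
#' @return A single number in [0, 1].
#' @export
#' @examples
#' overall_desirability(c(0.25, 1, 1, 1))  # 0.25^(1/4) = 0.7071
overall_desirability <- function(d) {
  if (length(d) == 0) stop("empty desirability vector", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(mean(log(d)))
}

#' Build a desirability specification
#'
#' One row per response: the optimization goal and anchors. With
#' `anchors = "observed"` the anchors are the observed minimum and maximum
#' of each response in the dataset (the default study configuration:
#' minimize particle size, PDI and zeta potential, maximize %EE, all
#' linear and equally weighted).
#'
#' @param data Study dataset used to derive observed anchors.
#' @param goals Named character vector mapping response to
#'   `"minimize"`/`"maximize"`.
#' @param shapes Named numeric vector of exponents (default 1).
#' @param zeta_mode `"raw"` (literal minimization of the signed mV value) or
#'   `"magnitude"` (minimize |zeta|); the study's "minimize" constraint is
#'   ambiguous for negative values.
#' @return A tibble with columns `response`, `goal`, `anchor_low`,
#'   `anchor_high`, `shape`, `zeta_mode`.
#' @export
desirability_spec <- function(data = nlc_study_data(),
                              goals = c(Y1 = "minimize", Y2 = "minimize",
                                        Y3 = "minimize", Y4 = "maximize"),
                              shapes = NULL, zeta_mode = c("raw", "magnitude")) {
  zeta_mode <- match.arg(zeta_mode)
  obs <- response_matrix(data)
  resp <- response_columns()$response
  if (!setequal(names(goals), resp)) {
    stop("incomplete desirability spec: goals must name ",
         paste(resp, collapse = ", "), call. = FALSE)
  }
  y3 <- obs[, "Y3"]
  if (zeta_mode == "magnitude") obs[, "Y3"] <- abs(y3)
  tibble::tibble(
    response = resp,
    goal = unname(goals[resp]),
    anchor_low = unname(apply(obs[, resp], 2, min)),
    anchor_high = unname(apply(obs[, resp], 2, max)),
    shape = if (is.null(shapes)) 1 else unname(shapes[resp]),
    zeta_mode = zeta_mode
  )
}

# desirability of an n x 4 response matrix under a spec; returns n-vector
desirability_matrix <- function(pred, spec) {
  d <- matrix(NA_real_, nrow(pred), nrow(spec))
  for (i in seq_len(nrow(spec))) {
    y <- pred[, spec$response[i]]
    if (spec$response[i] == "Y3" && spec$zeta_mode[i] == "magnitude") {
      y <- abs(y)
    }
    d[, i] <- desirability_one(y, spec$goal[i], spec$anchor_low[i],
                               spec$anchor_high[i], spec$shape[i])
  }
  apply(d, 1, overall_desirability)
}

#' Multi-response desirability optimization of a surrogate
#'
#' Deterministic two-stage search over the coded design box [-2, +2]^4 (the
#' region supported by data; no extrapolation): a regular coded-space grid,
#' then Nelder-Mead simplex refinement from the best grid point with
#' desirability evaluated as zero outside the box. Returns the incumbent
#' composition, its predicted responses and per-response desirabilities.
#'
#' @param net An `nlc_surrogate`.
#' @param spec A [desirability_spec()] tibble.
#' @param grid_step Coded-space grid spacing per axis (default 0.25, i.e.
#'   17^4 = 83,521 candidate points, evaluated vectorized).
#' @param factors Factor table.
#' @return An `nlc_optimum` object: list with `x_star_actual`,
#'   `x_star_coded`, `desirability`, `predicted` (tibble of responses),
#'   `per_response_d`, `n_evaluations`.
#' @export
#' @examples
#' \donttest{
#' opt <- optimize_formulation(published_network(), desirability_spec())
#' opt$x_star_actual
#' }
optimize_formulation <- function(net, spec, grid_step = 0.25,
                                 factors = nlc_factors()) {
  needed <- response_columns()$response
  if (!setequal(spec$response, needed)) {
    stop("incomplete desirability spec", call. = FALSE)
  }
  lo <- factors$coded_min
  hi <- factors$coded_max
  axes <- purrr::map2(lo, hi, ~seq(.x, .y, by = grid_step))
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- factors$symbol
  eval_coded <- function(coded_m) {
    actual <- coded_matrix_to_actual(coded_m, factors)
    pred <- forward_matrix(net, actual)
    desirability_matrix(pred, spec)
  }
  D <- eval_coded(grid)
  n_eval <- nrow(grid)
  best <- which.max(D)
  x0 <- grid[best, ]

  neg_d <- function(coded) {
    if (any(coded < lo - 1e-12) || any(coded > hi + 1e-12)) return(0)
    n_eval <<- n_eval + 1L
    -eval_coded(matrix(coded, nrow = 1))
  }
  refine <- stats::optim(x0, neg_d, method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-10))
  x_star <- pmin(pmax(refine$par, lo), hi)
  d_star <- eval_coded(matrix(x_star, nrow = 1))
  if (d_star < D[best]) {  # simplex never allowed to lose to the grid
    x_star <- x0
    d_star <- D[best]
  }
  actual_star <- drop(coded_matrix_to_actual(matrix(x_star, nrow = 1), factors))
  pred_star <- predict_responses(net, matrix(actual_star, nrow = 1),
                                 factors = factors, input_space = "actual")
  per_d <- vapply(seq_len(nrow(spec)), function(i) {
    y <- pred_star[[spec$response[i]]]
    if (spec$response[i] == "Y3" && spec$zeta_mode[i] == "magnitude") y <- abs(y)
    desirability_one(y, spec$goal[i], spec$anchor_low[i], spec$anchor_high[i],
                     spec$shape[i])
  }, numeric(1))
  names(per_d) <- spec$response
  structure(
    list(x_star_actual = stats::setNames(actual_star, factors$symbol),
         x_star_coded = stats::setNames(as.numeric(x_star), factors$symbol),
         desirability = as.numeric(d_star), predicted = pred_star,
         per_response_d = per_d, n_evaluations = n_eval,
         grid_step = grid_step, spec = spec),
    class = "nlc_optimum"
  )
}

#' @export
print.nlc_optimum <- function(x, ...) {
  cat("<nlc_optimum> overall desirability =",
      formatC(x$desirability, digits = 4, format = "f"), "\n")
  cat("  composition (actual units):",
      paste(names(x$x_star_actual),
            formatC(x$x_star_actual, digits = 3, format = "f"),
            sep = " = ", collapse = ", "), "\n")
  cat("  predicted responses:\n")
  print(x$predicted)
  invisible(x)
}

#' @rdname tidy.nlc_surrogate_fit
#' @method tidy nlc_optimum
#' @export
tidy.nlc_optimum <- function(x, ...) {
  tibble::tibble(
    response = names(x$per_response_d),
    predicted = as.numeric(x$predicted[1, names(x$per_response_d)]),
    desirability = as.numeric(x$per_response_d)
  )
}

#' @rdname tidy.nlc_surrogate_fit
#' @method glance nlc_optimum
#' @export
glance.nlc_optimum <- function(x, ...) {
  tibble::tibble(
    desirability = x$desirability,
    n_evaluations = x$n_evaluations,
    grid_step = x$grid_step
  )
}
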