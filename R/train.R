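#' Goodness-of-fit statistics for one response
#'
#' Computes the indicator set reported for the surrogate: error sum of
#' squares `sse = sum((obs - pred)^2)`, `rmse = sqrt(sse / n)`, mean absolute
#' deviation `mad = mean(|obs - pred|)`,
#' `r_squared = 1 - sse / sum((obs - mean(obs))^2)`, and the Gaussian
#' negative log-likelihood at the maximum-likelihood variance,
#' `neg_log_lik = (n / 2) * (log(2 * pi * sse / n) + 1)`.
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 2).
#' @return A one-row tibble with columns `r_squared`, `rmse`, `mad`,
#'   `neg_log_lik`, `sse`, `n`.
#' @export
#' @examples
#' # sqrt(9980.6204 / 24) = 20.3926
#' fit_statistics(c(0, 0), c(0, 0))
fit_statistics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  resid <- observed - predicted
  sse <- sum(resid^2)
  sst <- sum((observed - mean(observed))^2)
  tibble::tibble(
    r_squared = if (sst == 0 && sse > 0) -Inf else 1 - sse / sst,
    rmse = sqrt(sse / n),
    mad = mean(abs(resid)),
    neg_log_lik = (n / 2) * (log(2 * pi * sse / n) + 1),
    sse = sse,
    n = n
  )
}

#' Seeded K-fold assignment
#'
#' Randomly partitions `n_runs` runs into `k` folds whose sizes differ by at
#' most one; each fold serves once as the held-out set. Deterministic for a
#' given seed.
#'
#' @param n_runs Number of runs.
#' @param k Number of folds (2 <= k <= n_runs).
#' @param seed Integer seed.
#' @return A tibble with columns `run` and `fold`.
#' @export
#' @examples
#' table(kfold_split(30, 5, seed = 1)$fold)  # five folds of 6
kfold_split <- function(n_runs, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n_runs) stop("infeasible split: k exceeds number of runs", call. = FALSE)
  fold <- with_preserved_seed(seed, {
    sample(rep_len(seq_len(k), n_runs))
  })
  tibble::tibble(run = seq_len(n_runs), fold = fold)
}

# ---- parameter packing -------------------------------------------------

param_shapes <- function(layer_sizes) {
  L <- length(layer_sizes) - 1L
  lapply(seq_len(L), function(l) {
    c(out = layer_sizes[l + 1L], `in` = layer_sizes[l])
  })
}

n_params <- function(layer_sizes) {
  sum(vapply(param_shapes(layer_sizes),
             function(s) s[1] * s[2] + s[1], numeric(1)))
}

unpack_params <- function(theta, layer_sizes) {
  shapes <- param_shapes(layer_sizes)
  weights <- vector("list", length(shapes))
  biases <- vector("list", length(shapes))
  pos <- 0L
  for (l in seq_along(shapes)) {
    s <- shapes[[l]]
    nw <- s[1] * s[2]
    weights[[l]] <- matrix(theta[pos + seq_len(nw)], nrow = s[1], ncol = s[2])
    pos <- pos + nw
    biases[[l]] <- theta[pos + seq_len(s[1])]
    pos <- pos + s[1]
  }
  list(weights = weights, biases = biases)
}

# forward pass keeping per-layer activations; hidden layers tanh_half,
# output linear
forward_cache <- function(par, x) {
  L <- length(par$weights)
  acts <- vector("list", L + 1L)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- sweep(tcrossprod(acts[[l]], par$weights[[l]]), 2, par$biases[[l]], `+`)
    acts[[l + 1L]] <- if (l < L) tanh_half(z) else z
  }
  acts
}

sse_loss <- function(theta, layer_sizes, x, y, w) {
  par <- unpack_params(theta, layer_sizes)
  pred <- forward_cache(par, x)[[length(layer_sizes)]]
  v <- sum(w * (pred - y)^2)
  if (!is.finite(v)) 1e300 else v
}

sse_grad <- function(theta, layer_sizes, x, y, w) {
  par <- unpack_params(theta, layer_sizes)
  acts <- forward_cache(par, x)
  L <- length(par$weights)
  pred <- acts[[L + 1L]]
  delta <- 2 * w * (pred - y)
  g <- numeric(length(theta))
  # walk backwards; derivative of tanh_half is 0.5 * (1 - h^2)
  shapes <- param_shapes(layer_sizes)
  offsets <- cumsum(c(0, vapply(shapes, function(s) s[1] * s[2] + s[1],
                                numeric(1))))
  for (l in rev(seq_len(L))) {
    dW <- crossprod(delta, acts[[l]])
    db <- colSums(delta)
    s <- shapes[[l]]
    g[offsets[l] + seq_len(s[1] * s[2])] <- as.vector(dW)
    g[offsets[l] + s[1] * s[2] + seq_len(s[1])] <- db
    if (l > 1L) {
      delta <- (delta %*% par$weights[[l]]) * 0.5 * (1 - acts[[l]]^2)
    }
  }
  g
}

#' Train a feed-forward surrogate on a study dataset
#'
#' Fits one network jointly to all four responses (shared hidden layers,
#' the study convention) by full-batch BFGS on the summed squared error,
#' with analytic backpropagation gradients; a subset of responses can be
#' fitted instead via `responses` (per-response networks). Inputs and responses are standardized internally (responses
#' span orders of magnitude: nm vs PDI); the standardization is folded back
#' into the returned network so its forward pass works directly in actual
#' units. Multiple seeded random restarts are run and the restart with the
#' lowest held-out RMSE (summed over standardized responses; training RMSE
#' when no held-out rows are given) is kept, ties broken by lower training
#' negative log-likelihood, then lower restart index.
#'
#' @param data Study dataset tibble (see [nlc_study_data()]).
#' @param hidden Integer vector of hidden-layer sizes (default `c(9, 9)`).
#' @param test_runs Optional integer vector of `run_id`s to hold out.
#' @param n_restarts Number of random restarts (default 20).
#' @param maxit BFGS iteration cap per restart (default 500).
#' @param seed Integer seed controlling initialization.
#' @param weight_by_sd If `TRUE`, rows are weighted by `1 / sd^2` per
#'   response (replicate-precision weighting); default `FALSE` (the
#'   replicate means are fitted unweighted).
#' @param responses Responses to fit (default all of Y1..Y4 jointly);
#'   pass a single name for a per-response network.
#' @param factors Factor table.
#' @return An object of class `nlc_surrogate_fit` with elements
#'   `network` (an [new_surrogate()] object in actual units), `fit_report`
#'   (tibble: response, partition, r_squared, rmse, mad, neg_log_lik, sse,
#'   n), `converged`, `best_restart`, `seed`.
#' @export
nn_train <- function(data, hidden = c(9, 9), test_runs = NULL,
                     n_restarts = 20, maxit = 500, seed = 1,
                     weight_by_sd = FALSE, responses = NULL,
                     factors = nlc_factors()) {
  x_all <- factor_matrix(data, factors)
  y_all <- response_matrix(data)
  if (!is.null(responses)) {
    bad <- setdiff(responses, colnames(y_all))
    if (length(bad) > 0) {
      stop("unknown response(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    y_all <- y_all[, responses, drop = FALSE]
  }
  is_test <- data$run_id %in% test_runs
  x <- x_all[!is_test, , drop = FALSE]
  y <- y_all[!is_test, , drop = FALSE]
  if (nrow(x) < ncol(y_all) + 2) {
    stop("too few training rows for the number of responses", call. = FALSE)
  }
  layer_sizes <- c(ncol(x), hidden, ncol(y))

  mx <- colMeans(x); sx <- apply(x, 2, stats::sd)
  my <- colMeans(y); sy <- apply(y, 2, stats::sd)
  sx[sx == 0] <- 1; sy[sy == 0] <- 1
  xs <- sweep(sweep(x, 2, mx, `-`), 2, sx, `/`)
  ys <- sweep(sweep(y, 2, my, `-`), 2, sy, `/`)

  w <- matrix(1, nrow(ys), ncol(ys))
  if (weight_by_sd) {
    cols <- response_columns()
    sd_cols <- cols$sd_col[match(colnames(y), cols$response)]
    sds <- as.matrix(data[!is_test, sd_cols])
    prec <- 1 / pmax(sds, 1e-3)^2
    w <- sweep(prec, 2, colMeans(prec), `/`)  # mean weight 1 per response
  }

  np <- n_params(layer_sizes)
  restarts <- with_preserved_seed(seed, {
    lapply(seq_len(n_restarts), function(r) stats::runif(np, -0.5, 0.5))
  })

  eval_restart <- function(theta0, r) {
    fit <- stats::optim(theta0, fn = sse_loss, gr = sse_grad,
                        layer_sizes = layer_sizes, x = xs, y = ys, w = w,
                        method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (!is.finite(fit$value)) {
      stop("training diverged (non-finite loss) at restart ", r, call. = FALSE)
    }
    fit
  }
  fits <- purrr::imap(restarts, eval_restart)

  score_restart <- function(fit) {
    par <- unpack_params(fit$par, layer_sizes)
    if (any(is_test)) {
      xts <- sweep(sweep(x_all[is_test, , drop = FALSE], 2, mx, `-`), 2, sx, `/`)
      yts <- sweep(sweep(y_all[is_test, , drop = FALSE], 2, my, `-`), 2, sy, `/`)
      pred <- forward_cache(par, xts)[[length(layer_sizes)]]
      sqrt(mean((pred - yts)^2))
    } else {
      sqrt(fit$value / length(ys))
    }
  }
  scores <- vapply(fits, score_restart, numeric(1))
  train_loss <- vapply(fits, function(f) f$value, numeric(1))
  best <- order(scores, train_loss, seq_along(fits))[1]
  fit <- fits[[best]]
  par <- unpack_params(fit$par, layer_sizes)

  # fold input/response standardization back into the outer layers so the
  # network maps actual units to response units
  L <- length(par$weights)
  par$biases[[1]] <- par$biases[[1]] - as.vector(par$weights[[1]] %*% (mx / sx))
  par$weights[[1]] <- sweep(par$weights[[1]], 2, sx, `/`)
  par$weights[[L]] <- sweep(par$weights[[L]], 1, sy, `*`)
  par$biases[[L]] <- sy * par$biases[[L]] + my

  net <- new_surrogate(
    weights = par$weights, biases = par$biases,
    input_space = "actual", input_names = factors$symbol,
    response_names = colnames(y)
  )

  report <- surrogate_fit_report(net, data, test_runs = test_runs,
                                 factors = factors)
  structure(
    list(network = net, fit_report = report,
         converged = fit$convergence == 0, best_restart = best,
         restart_scores = scores, seed = seed, layer_sizes = layer_sizes,
         test_runs = test_runs),
    class = "nlc_surrogate_fit"
  )
}

# per-response, per-partition indicator table for a network on a dataset
surrogate_fit_report <- function(net, data, test_runs = NULL,
                                 factors = nlc_factors()) {
  pred <- as.matrix(predict_responses(net, data, factors = factors))
  obs <- response_matrix(data)[, net$response_names, drop = FALSE]
  is_test <- data$run_id %in% test_runs
  parts <- list(training = !is_test)
  if (any(is_test)) parts$testing <- is_test
  purrr::imap_dfr(parts, function(idx, part) {
    purrr::map_dfr(colnames(obs), function(resp) {
      dplyr::bind_cols(
        tibble::tibble(response = resp, partition = part),
        fit_statistics(obs[idx, resp], pred[idx, resp])
      )
    })
  })
}

#' @export
print.nlc_surrogate_fit <- function(x, ...) {
  cat("<nlc_surrogate_fit> ", paste(x$layer_sizes, collapse = "-"),
      " network, best of ", length(x$restart_scores), " restarts",
      if (!x$converged) " (iteration cap reached)", "\n", sep = "")
  print(x$fit_report)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted surrogate
#'
#' @param x An `nlc_surrogate_fit`.
#' @param ... Unused.
#' @return The per-response, per-partition fit-indicator tibble.
#' @method tidy nlc_surrogate_fit
#' @export
tidy.nlc_surrogate_fit <- function(x, ...) x$fit_report

#' @rdname tidy.nlc_surrogate_fit
#' @method glance nlc_surrogate_fit
#' @export
glance.nlc_surrogate_fit <- function(x, ...) {
  tr <- x$fit_report[x$fit_report$partition == "training", ]
  tibble::tibble(
    n_restarts = length(x$restart_scores),
    best_restart = x$best_restart,
    converged = x$converged,
    mean_r_squared = mean(tr$r_squared),
    min_r_squared = min(tr$r_squared),
    total_neg_log_lik = sum(tr$neg_log_lik)
  )
}

#' K-fold cross-validation of the surrogate
#'
#' Splits the runs into `k` folds, trains on each complement and evaluates on
#' the held-out fold, mirroring the K = 5 (80/20) scheme used for the study
#' dataset.
#'
#' @inheritParams nn_train
#' @param k Number of folds.
#' @param ... Passed to [nn_train()] (e.g. `n_restarts`, `maxit`).
#' @return An `nlc_cv` object: list with `folds` (the assignment tibble),
#'   `fits` (per-fold `nlc_surrogate_fit`s) and `report` (stacked fit
#'   reports with a `fold` column).
#' @export
nn_crossvalidate <- function(data, k = 5, seed = 1, ...) {
  assign <- kfold_split(nrow(data), k, seed = seed)
  fits <- purrr::map(seq_len(k), function(f) {
    held <- data$run_id[assign$fold == f]
    nn_train(data, test_runs = held, seed = seed + f, ...)
  })
  report <- purrr::imap_dfr(fits, function(fit, f) {
    dplyr::mutate(fit$fit_report, fold = f, .before = 1)
  })
  structure(list(folds = assign, fits = fits, report = report, k = k,
                 seed = seed),
            class = "nlc_cv")
}

#' @export
print.nlc_cv <- function(x, ...) {
  cat("<nlc_cv> ", x$k, "-fold cross-validation\n", sep = "")
  s <- dplyr::summarise(
    dplyr::group_by(x$report, .data$response, .data$partition),
    r_squared = mean(.data$r_squared), rmse = mean(.data$rmse),
    .groups = "drop")
  print(s)
  invisible(x)
}

#' @rdname tidy.nlc_surrogate_fit
#' @method tidy nlc_cv
#' @export
tidy.nlc_cv <- function(x, ...) x$report
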