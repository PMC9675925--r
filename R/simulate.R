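#' Default replicate-noise scale
#'
#' Per-response noise SDs for the synthetic dataset generator: the median of
#' the per-run replicate SDs in the packaged 30-run study dataset, computed
#' at call time (not hardcoded).
#'
#' @return Named numeric vector (Y1..Y4) of SDs in response units.
#' @export
default_noise_sd <- function() {
  d <- nlc_study_data()
  cols <- response_columns()
  stats::setNames(vapply(cols$sd_col, function(cc) stats::median(d[[cc]]),
                         numeric(1)),
                  cols$response)
}

#' Simulate a CCRD study dataset from a known truth network
#'
#' For each design point, draws `n_replicates` Gaussian observations per
#' response around the truth network's prediction and records their mean and
#' SD, emulating the replicate structure of the real study table. PDI means
#' are clipped to [0, 1] and %EE means to [0, 100]; a warning reports the
#' number of clipped values. With `heteroscedastic = TRUE` the noise SD of a
#' run is scaled by its predicted mean relative to the average predicted
#' mean of that response.
#'
#' @param design A design tibble from [generate_ccrd()].
#' @param truth_network The generating `nlc_surrogate`
#'   (default [published_network()]).
#' @param noise_sd 4-vector of per-response replicate SDs (response units);
#'   default [default_noise_sd()].
#' @param n_replicates Replicates per run (default 3).
#' @param seed Integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @param heteroscedastic Scale noise with the predicted mean (default
#'   `FALSE`: constant SD per response).
#' @param factors Factor table.
#' @return A study-dataset tibble with the same columns as
#'   [nlc_study_data()].
#' @export
#' @examples
#' d <- simulate_dataset(generate_ccrd(nlc_factors()), seed = 1)
simulate_dataset <- function(design, truth_network = published_network(),
                             noise_sd = default_noise_sd(), n_replicates = 3,
                             seed = 1, heteroscedastic = FALSE,
                             factors = nlc_factors()) {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  coded <- as.matrix(design[, tolower(factors$symbol)])
  if (any(coded < factors$coded_min - 1e-9) ||
      any(coded > factors$coded_max + 1e-9)) {
    stop("design extends outside the coded box", call. = FALSE)
  }
  actual <- coded_matrix_to_actual(coded, factors)
  colnames(actual) <- factors$symbol
  truth <- forward_matrix(
    truth_network,
    if (truth_network$input_space == "actual") actual else coded)
  n <- nrow(truth)
  cols <- response_columns()
  sim <- with_preserved_seed(seed, {
    reps <- array(stats::rnorm(n * 4 * n_replicates), c(n, 4, n_replicates))
    for (r in seq_len(4)) {
      sd_run <- if (heteroscedastic) {
        noise_sd[r] * truth[, r] / mean(truth[, r])
      } else {
        rep(noise_sd[r], n)
      }
      reps[, r, ] <- truth[, r] + reps[, r, ] * sd_run
    }
    reps
  })
  means <- apply(sim, c(1, 2), mean)
  sds <- if (n_replicates > 1) apply(sim, c(1, 2), stats::sd) else
    matrix(0, n, 4)

  clipped <- 0L
  clip <- function(v, lo, hi) {
    out <- pmin(pmax(v, lo), hi)
    clipped <<- clipped + sum(out != v)
    out
  }
  means[, 2] <- clip(means[, 2], 0, 1)     # PDI
  means[, 4] <- clip(means[, 4], 0, 100)   # %EE
  if (clipped > 0) {
    warning(clipped, " simulated mean(s) clipped to the response bounds",
            call. = FALSE)
  }

  out <- tibble::tibble(
    run_id = design$run_id,
    X1_wt_pct = actual[, "X1"], X2_pct_total_lipid = actual[, "X2"],
    X3_wt_pct = actual[, "X3"], X4_wt_pct = actual[, "X4"]
  )
  for (r in seq_len(4)) {
    out[[cols$mean_col[r]]] <- means[, r]
    out[[cols$sd_col[r]]] <- sds[, r]
  }
  out$n_replicates <- n_replicates
  coded_named <- coded
  colnames(coded_named) <- tolower(factors$symbol)
  out <- dplyr::bind_cols(out, tibble::as_tibble(coded_named))
  out$point_class <- design$point_class
  out
}

#' Simulate a cumulative-release profile
#'
#' Evaluates one of the five kinetic model forms at the given times, adds
#' zero-mean Gaussian noise, and clips below zero.
#'
#' @param model Kinetic model name (see [fit_kinetic()]).
#' @param params Named list/vector of parameters (`k`, plus `n` for
#'   Korsmeyer-Peppas).
#' @param times Strictly increasing sampling times (h).
#' @param noise_sd Noise SD in % released (default 0).
#' @param seed Integer seed.
#' @return A release-profile tibble.
#' @export
#' @examples
#' simulate_release("higuchi", c(k = 12.5), times = c(1, 4, 9))
simulate_release <- function(model, params, times, noise_sd = 0, seed = 1) {
  if (!model %in% kinetic_model_names()) {
    stop("unknown kinetic model `", model, "`", call. = FALSE)
  }
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  q <- kinetic_curve(model, as.list(params))(times)
  if (noise_sd > 0) {
    q <- q + with_preserved_seed(seed, stats::rnorm(length(q), 0, noise_sd))
  }
  tibble::tibble(time_h = times, cumulative_release_pct = pmax(q, 0))
}

#' Simulate HET-CAM observations for a target irritation category
#'
#' Draws per-egg onset times from category-specific windows chosen so the
#' expected score falls inside the category's score bin: nonirritant eggs
#' show no endpoint (score 0); mild eggs show hemorrhage and lysis late in
#' the window; moderate eggs show all three endpoints at intermediate
#' times; strong eggs show all three early.
#'
#' @param category `"nonirritant"`, `"mild"`, `"moderate"` or `"strong"`.
#' @param n_eggs Number of eggs (>= 1).
#' @param seed Integer seed.
#' @return A scored observation tibble (see [score_hetcam()]).
#' @export
#' @examples
#' simulate_hetcam("strong", n_eggs = 6, seed = 1)
simulate_hetcam <- function(category = c("nonirritant", "mild", "moderate",
                                         "strong"),
                            n_eggs = 6, seed = 1) {
  category <- match.arg(category)
  if (n_eggs < 1) stop("n_eggs must be >= 1", call. = FALSE)
  windows <- switch(category,
    nonirritant = NULL,
    # (lo, hi) per endpoint; NA row = endpoint never observed
    mild = list(hemorrhage = c(150, 230), lysis = c(180, 280),
                coagulation = NULL),
    moderate = list(hemorrhage = c(100, 200), lysis = c(150, 250),
                    coagulation = c(200, 290)),
    strong = list(hemorrhage = c(5, 60), lysis = c(5, 60),
                  coagulation = c(5, 60)))
  draw <- function(w) {
    if (is.null(w)) rep(NA_real_, n_eggs) else
      round(stats::runif(n_eggs, w[1], w[2]))
  }
  times <- with_preserved_seed(seed, {
    if (is.null(windows)) {
      list(hemorrhage = rep(NA_real_, n_eggs),
           lysis = rep(NA_real_, n_eggs),
           coagulation = rep(NA_real_, n_eggs))
    } else {
      lapply(windows, draw)
    }
  })
  score_hetcam(tibble::tibble(
    sample = paste0(category, "_egg", seq_len(n_eggs)),
    hemorrhage_s = times$hemorrhage,
    lysis_s = times$lysis,
    coagulation_s = times$coagulation
  ))
}
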