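#' Default pipeline configuration
#'
#' @param dataset `"builtin:table2"` (the packaged 30-run study dataset) or
#'   a CSV path.
#' @param seed Integer seed used for every stochastic stage.
#' @param k Cross-validation folds.
#' @param n_restarts Training restarts per fold/final fit.
#' @param maxit BFGS iteration cap.
#' @param grid_step Coded-space grid step for the desirability search.
#' @param out_dir Output directory for the report bundle.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(dataset = "builtin:table2", seed = 1, k = 5,
                            n_restarts = 20, maxit = 500, grid_step = 0.25,
                            out_dir = tempfile("nlcoptim_run_")) {
  list(dataset = dataset, seed = seed, k = k, n_restarts = n_restarts,
       maxit = maxit, grid_step = grid_step, out_dir = out_dir)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file does not exist: ", config, call. = FALSE)
    }
    raw <- if (grepl("\\.ya?ml$", config) &&
               requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    config <- utils::modifyList(pipeline_config(), raw)
  }
  config
}

#' Run the end-to-end optimization pipeline
#'
#' Executes the full analysis chain on a study dataset: load and validate,
#' K-fold cross-validated surrogate training, final fit on all runs, fit
#' statistics, variable importance by both the connection-weight and the
#' permutation method, and desirability optimization over the design box.
#' Writes a report bundle (`fit_report.csv`, `importance.csv`,
#' `optimization.json`, `network.json`, `run.log`) to `config$out_dir`; the
#' log records the seed, the configuration hash and per-stage wall times, so
#' a rerun from the same config reproduces the reports.
#'
#' @param config A list from [pipeline_config()], or a path to a JSON/YAML
#'   file with the same fields.
#' @return Invisibly, a list with elements `data`, `cv`, `fit`,
#'   `importance`, `optimum`, `config`, `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- read_pipeline_config(config)
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  log_line <- function(stage, msg) {
    cat(sprintf("stage=%s seed=%d elapsed=%.2fs %s\n", stage, config$seed,
                as.numeric(difftime(Sys.time(), t0, units = "secs")), msg),
        file = log_path, append = TRUE)
  }
  fail <- function(stage, e) {
    log_line(stage, paste0("FAILED: ", conditionMessage(e)))
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  }
  cat(sprintf("nlcoptim pipeline | R %s | config_hash=%s seed=%d\n",
              getRversion(), cfg_hash, config$seed), file = log_path)

  data <- tryCatch({
    if (identical(config$dataset, "builtin:table2")) nlc_study_data()
    else load_study_dataset(config$dataset)
  }, error = function(e) fail("load", e))
  log_line("load", sprintf("rows=%d", nrow(data)))

  cv <- tryCatch(
    nn_crossvalidate(data, k = config$k, seed = config$seed,
                     n_restarts = config$n_restarts, maxit = config$maxit),
    error = function(e) fail("crossvalidate", e))
  log_line("crossvalidate", sprintf("k=%d", config$k))

  fit <- tryCatch(
    nn_train(data, n_restarts = config$n_restarts, maxit = config$maxit,
             seed = config$seed),
    error = function(e) fail("train", e))
  log_line("train", sprintf("best_restart=%d", fit$best_restart))

  importance <- tryCatch(
    dplyr::bind_rows(
      garson_importance(fit$network),
      permutation_importance(fit$network, data, seed = config$seed)),
    error = function(e) fail("importance", e))
  log_line("importance", "methods=garson_path,permutation")

  optimum <- tryCatch(
    optimize_formulation(fit$network, desirability_spec(data),
                         grid_step = config$grid_step),
    error = function(e) fail("optimize", e))
  log_line("optimize", sprintf("desirability=%.4f", optimum$desirability))

  files <- list(
    fit_report = file.path(config$out_dir, "fit_report.csv"),
    importance = file.path(config$out_dir, "importance.csv"),
    optimization = file.path(config$out_dir, "optimization.json"),
    network = file.path(config$out_dir, "network.json"),
    log = log_path
  )
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(fit$fit_report, fold = NA_integer_, .before = 1),
    cv$report), files$fit_report)
  readr::write_csv(importance, files$importance)
  jsonlite::write_json(list(
    config_hash = cfg_hash, seed = config$seed,
    x_star_actual = as.list(optimum$x_star_actual),
    x_star_coded = as.list(optimum$x_star_coded),
    desirability = optimum$desirability,
    per_response_d = as.list(optimum$per_response_d),
    predicted_responses = as.list(optimum$predicted[1, ])
  ), files$optimization, auto_unbox = TRUE, digits = NA)
  write_network(fit$network, files$network,
                provenance = paste0("fitted by nlcoptim run; seed=",
                                    config$seed, "; config_hash=", cfg_hash))
  log_line("report", "bundle written")

  invisible(list(data = data, cv = cv, fit = fit, importance = importance,
                 optimum = optimum, config = config, files = files))
}
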