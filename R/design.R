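#' Formulation factor definitions
#'
#' Build a factor table for a rotatable central composite design (CCRD).
#' Each factor carries the center (`X0`) and step (`dX`) of the linear coded
#' transform `x = (X - X0) / dX`, so that coded levels -2..+2 map onto the
#' actual concentration levels of the design.
#'
#' @param symbol Character vector of factor symbols (e.g. `"X1"`).
#' @param name Human-readable factor names.
#' @param units Units of the actual scale (e.g. `"wt%"`).
#' @param center Actual value at coded 0.
#' @param step Actual increment per coded unit; must be positive.
#' @param coded_min,coded_max Coded range covered by the design (default -2, +2).
#'
#' @return A tibble with one row per factor and columns
#'   `symbol`, `name`, `units`, `center`, `step`, `coded_min`, `coded_max`.
#' @export
#' @examples
#' nlc_factors()
new_factors <- function(symbol, name, units, center, step,
                        coded_min = -2, coded_max = 2) {
  stopifnot(length(symbol) == length(name), length(name) == length(units),
            length(units) == length(center), length(center) == length(step))
  if (any(!is.finite(center)) || any(!is.finite(step))) {
    stop("factor centers and steps must be finite", call. = FALSE)
  }
  if (any(step <= 0)) stop("factor `step` must be > 0", call. = FALSE)
  low <- center + coded_min * step
  if (any(low < -1e-9)) {
    stop("actual value at the low coded extreme is negative; ",
         "compositions cannot be negative", call. = FALSE)
  }
  tibble::tibble(
    symbol = as.character(symbol), name = as.character(name),
    units = as.character(units),
    center = as.numeric(center), step = as.numeric(step),
    coded_min = coded_min, coded_max = coded_max
  )
}

#' @describeIn new_factors The four formulation factors of the CFE-NLC study:
#'   solid lipid content, liquid lipid content (as % of total lipid),
#'   emulsifier content, and plant-extract (CFE) content. The extract factor
#'   stores the exact center 1.375 and step 0.625 (tables round these to
#'   2 decimals for display).
#' @export
nlc_factors <- function() {
  new_factors(
    symbol = c("X1", "X2", "X3", "X4"),
    name = c("solid lipid content", "liquid lipid content",
             "emulsifier content", "plant extract content"),
    units = c("wt%", "% of total lipid", "wt%", "wt%"),
    center = c(6.75, 30, 3.5, 1.375),
    step = c(3.25, 15, 1.5, 0.625)
  )
}

one_factor <- function(factors, symbol) {
  row <- factors[factors$symbol == symbol, ]
  if (nrow(row) != 1L) {
    stop("factor `", symbol, "` not found (or duplicated)", call. = FALSE)
  }
  row
}

#' Coded/actual factor transforms
#'
#' `actual_to_coded()` applies `x = (X - center) / step`;
#' `coded_to_actual()` inverts it, `X = center + x * step`. Both are exact
#' inverses in floating point up to rounding.
#'
#' @param value Numeric vector of values to transform.
#' @param factors A factor table from [new_factors()] / [nlc_factors()].
#' @param symbol Which factor to use.
#' @return Numeric vector of transformed values.
#' @export
#' @examples
#' actual_to_coded(10, nlc_factors(), "X1")  # +1
#' coded_to_actual(2, nlc_factors(), "X1")   # 13.25
actual_to_coded <- function(value, factors, symbol) {
  if (any(!is.finite(value))) stop("non-finite actual value", call. = FALSE)
  f <- one_factor(factors, symbol)
  (value - f$center) / f$step
}

#' @rdname actual_to_coded
#' @export
coded_to_actual <- function(value, factors, symbol) {
  if (any(!is.finite(value))) stop("non-finite coded value", call. = FALSE)
  f <- one_factor(factors, symbol)
  f$center + value * f$step
}

# Matrix versions used internally: rows = points, cols follow factors$symbol.
coded_matrix_to_actual <- function(m, factors) {
  sweep(sweep(m, 2, factors$step, `*`), 2, factors$center, `+`)
}
actual_matrix_to_coded <- function(m, factors) {
  sweep(sweep(m, 2, factors$center, `-`), 2, factors$step, `/`)
}

classify_point <- function(coded, tol = 1e-6) {
  a <- abs(coded)
  if (all(a < tol)) return("center")
  if (all(abs(a - 1) < tol)) return("factorial")
  if (sum(abs(a - 2) < tol) == 1L && sum(a < tol) == length(coded) - 1L) {
    return("axial")
  }
  "other"
}

#' Generate a rotatable central composite design
#'
#' Produces the full CCRD for four factors: a 2^4 factorial cube (all +/-1
#' combinations), 2*4 axial points at +/- alpha with alpha = (2^4)^(1/4) = 2
#' (the rotatability condition alpha^4 = number of factorial points), and
#' `n_center` center replicates. Run order is deterministic (factorial in
#' binary order, then axial, then center) unless `shuffle_seed` is given.
#'
#' @param factors Factor table with exactly four rows.
#' @param n_center Number of center-point replicates (>= 1).
#' @param shuffle_seed Optional integer; if supplied the run order is
#'   randomized reproducibly.
#' @return A tibble with columns `run_id`, `point_class`, coded factor columns
#'   (`x1`..`x4` in lower case) and actual factor columns named after the
#'   factor symbols.
#' @export
#' @examples
#' nrow(generate_ccrd(nlc_factors(), n_center = 6))  # 30
generate_ccrd <- function(factors, n_center = 6, shuffle_seed = NULL) {
  if (nrow(factors) != 4L) {
    stop("unsupported design: exactly 4 factors required", call. = FALSE)
  }
  if (n_center < 1) stop("n_center must be >= 1", call. = FALSE)
  k <- 4L
  alpha <- (2^k)^(1 / 4)  # rotatable axial distance; equals 2 for k = 4
  cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k))[, k:1])
  axial <- matrix(0, 2L * k, k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -alpha
    axial[2L * i, i] <- alpha
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(cube, axial, center)
  cls <- c(rep("factorial", 2^k), rep("axial", 2L * k), rep("center", n_center))
  if (!is.null(shuffle_seed)) {
    perm <- with_preserved_seed(shuffle_seed, sample.int(nrow(coded)))
    coded <- coded[perm, , drop = FALSE]
    cls <- cls[perm]
  }
  actual <- coded_matrix_to_actual(coded, factors)
  colnames(coded) <- tolower(factors$symbol)
  colnames(actual) <- factors$symbol
  tibble::tibble(
    run_id = seq_len(nrow(coded)),
    point_class = cls,
    tibble::as_tibble(coded),
    tibble::as_tibble(actual)
  )
}

# run seeded code without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Load a CCRD study dataset
#'
#' Reads a formulation dataset CSV (30-run layout: four factors in actual
#' units plus per-run mean and SD of the four responses) and validates it.
#' The packaged dataset ships with the package; see [nlc_study_data()].
#'
#' Expected columns:
#' `run_id,X1_wt_pct,X2_pct_total_lipid,X3_wt_pct,X4_wt_pct,`
#' `Y1_nm_mean,Y1_nm_sd,Y2_pdi_mean,Y2_pdi_sd,Y3_mV_mean,Y3_mV_sd,`
#' `Y4_ee_pct_mean,Y4_ee_pct_sd,n_replicates`
#'
#' @param path Path to the CSV file.
#' @param factors Factor table used to infer coded values and point classes.
#' @return A tibble with the original columns plus coded factor columns
#'   (`x1`..`x4`) and `point_class`.
#' @export
load_study_dataset <- function(path, factors = nlc_factors()) {
  expected <- c("run_id", "X1_wt_pct", "X2_pct_total_lipid", "X3_wt_pct",
                "X4_wt_pct", "Y1_nm_mean", "Y1_nm_sd", "Y2_pdi_mean",
                "Y2_pdi_sd", "Y3_mV_mean", "Y3_mV_sd", "Y4_ee_pct_mean",
                "Y4_ee_pct_sd", "n_replicates")
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(expected, names(d))
  if (length(missing) > 0) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in expected) {
    bad <- which(!is.finite(d[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric or missing value in column `", col, "`, row ", bad[1],
           call. = FALSE)
    }
  }
  sd_cols <- c("Y1_nm_sd", "Y2_pdi_sd", "Y3_mV_sd", "Y4_ee_pct_sd")
  if (any(unlist(d[sd_cols]) < 0)) stop("negative SD in dataset", call. = FALSE)
  if (any(d$Y2_pdi_mean < 0 | d$Y2_pdi_mean > 1)) {
    stop("PDI outside [0, 1]", call. = FALSE)
  }
  if (any(d$Y4_ee_pct_mean < 0 | d$Y4_ee_pct_mean > 100)) {
    stop("%EE outside [0, 100]", call. = FALSE)
  }
  actual <- as.matrix(d[, c("X1_wt_pct", "X2_pct_total_lipid", "X3_wt_pct",
                            "X4_wt_pct")])
  coded <- actual_matrix_to_coded(actual, factors)
  colnames(coded) <- tolower(factors$symbol)
  d <- dplyr::bind_cols(d, tibble::as_tibble(coded))
  d$point_class <- apply(coded, 1, classify_point, tol = 0.05)
  d
}

#' Packaged 30-run CFE-NLC study dataset
#'
#' The 30-run CCRD formulation dataset (16 factorial + 8 axial + 6 center
#' runs) with replicate means and SDs (n = 3) of particle size (nm), PDI,
#' zeta potential (mV) and %EE.
#'
#' @inheritParams load_study_dataset
#' @return See [load_study_dataset()].
#' @export
nlc_study_data <- function(factors = nlc_factors()) {
  load_study_dataset(
    system.file("extdata", "ccrd_study_dataset.csv", package = "nlcoptim",
                mustWork = TRUE),
    factors = factors
  )
}

# response metadata shared across modules
response_columns <- function() {
  tibble::tibble(
    response = c("Y1", "Y2", "Y3", "Y4"),
    mean_col = c("Y1_nm_mean", "Y2_pdi_mean", "Y3_mV_mean", "Y4_ee_pct_mean"),
    sd_col = c("Y1_nm_sd", "Y2_pdi_sd", "Y3_mV_sd", "Y4_ee_pct_sd"),
    units = c("nm", "", "mV", "%")
  )
}

response_matrix <- function(data) {
  m <- as.matrix(data[, response_columns()$mean_col])
  colnames(m) <- response_columns()$response
  m
}

factor_matrix <- function(data, factors = nlc_factors()) {
  cols <- c("X1_wt_pct", "X2_pct_total_lipid", "X3_wt_pct", "X4_wt_pct")
  if (all(cols %in% names(data))) {
    m <- as.matrix(data[, cols])
  } else if (all(factors$symbol %in% names(data))) {
    m <- as.matrix(data[, factors$symbol])
  } else {
    stop("no actual-unit factor columns found in data", call. = FALSE)
  }
  colnames(m) <- factors$symbol
  m
}
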