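#' Entrapment efficiency
#'
#' Indirect entrapment efficiency from the marker-compound concentration in
#' the whole dispersion (`c_total`, C1) and in the filtrate/supernatant
#' (`c_free`, C2): `%EE = 100 * (C1 - C2) / C1`. Units cancel, so any common
#' concentration unit may be used.
#'
#' @param c_total Total marker concentration in the dispersion (> 0).
#' @param c_free Free marker concentration in the filtrate
#'   (0 <= c_free <= c_total).
#' @return Percentage entrapped, in [0, 100].
#' @export
#' @examples
#' entrapment_efficiency(200, 30.56)  # 84.72
entrapment_efficiency <- function(c_total, c_free) {
  if (any(!is.finite(c_total)) || any(!is.finite(c_free))) {
    stop("concentrations must be finite", call. = FALSE)
  }
  if (any(c_total <= 0)) stop("c_total must be > 0", call. = FALSE)
  if (any(c_free < 0)) stop("c_free must be >= 0", call. = FALSE)
  if (any(c_free > c_total)) {
    stop("assay inconsistency: free concentration exceeds total", call. = FALSE)
  }
  100 * (c_total - c_free) / c_total
}

#' HET-CAM irritation score
#'
#' Irritation score from onset times (seconds) of the three vascular
#' endpoints observed on the chorioallantoic membrane within a 300 s window:
#' `score = 5 (301 - t_H)/300 + 7 (301 - t_L)/300 + 9 (301 - t_C)/300`
#' for hemorrhage, lysis and coagulation respectively. An endpoint that did
#' not occur within the window (`NA`) contributes zero, which reproduces a
#' zero score for the untreated/negative-control membrane. Observed times
#' must lie in [1, 300] s.
#'
#' @param hemorrhage_s,lysis_s,coagulation_s Onset times in seconds, or
#'   `NA` for not observed. Vectorized.
#' @return Numeric score(s) in [0, 21].
#' @export
#' @examples
#' irritation_score(NA, NA, NA)  # 0
#' irritation_score(1, 1, 1)     # 21
irritation_score <- function(hemorrhage_s, lysis_s, coagulation_s) {
  check_time <- function(t, what) {
    bad <- !is.na(t) & (t < 1 | t > 300 | !is.finite(t))
    if (any(bad)) {
      stop("invalid ", what, " onset time: must be in [1, 300] s or NA",
           call. = FALSE)
    }
    t
  }
  term <- function(t, coef) {
    ifelse(is.na(t), 0, coef * (301 - t) / 300)
  }
  term(check_time(hemorrhage_s, "hemorrhage"), 5) +
    term(check_time(lysis_s, "lysis"), 7) +
    term(check_time(coagulation_s, "coagulation"), 9)
}

#' Classify an irritation score
#'
#' Bins the HET-CAM score on the standard scale: nonirritant, mildly,
#' moderately, strongly irritant. The printed scale leaves gaps between
#' bins (0.9 to 1, etc.); classification uses the half-open bins
#' [0, 1), [1, 5), [5, 9), [9, Inf) so every non-negative score classifies.
#'
#' @param score Numeric score(s) >= 0.
#' @return Character vector: `"nonirritant"`, `"mild"`, `"moderate"` or
#'   `"strong"`.
#' @export
#' @examples
#' classify_irritation(c(0, 3.19, 19.49))
classify_irritation <- function(score) {
  if (any(!is.finite(score)) || any(score < 0)) {
    stop("score must be non-negative and finite", call. = FALSE)
  }
  as.character(cut(score, breaks = c(0, 1, 5, 9, Inf), right = FALSE,
                   labels = c("nonirritant", "mild", "moderate", "strong")))
}

#' Score a HET-CAM observation table
#'
#' Applies [irritation_score()] and [classify_irritation()] row-wise to a
#' table of per-egg onset times.
#'
#' @param observations Data frame with columns `sample`, `hemorrhage_s`,
#'   `lysis_s`, `coagulation_s` (`NA` or empty cell = endpoint not
#'   observed).
#' @return The input tibble with `score` and `category` columns added.
#' @export
score_hetcam <- function(observations) {
  needed <- c("sample", "hemorrhage_s", "lysis_s", "coagulation_s")
  missing <- setdiff(needed, names(observations))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(observations)
  out$score <- irritation_score(out$hemorrhage_s, out$lysis_s,
                                out$coagulation_s)
  out$category <- classify_irritation(out$score)
  out
}

#' Load a HET-CAM observation CSV
#'
#' @param path CSV with columns `sample,hemorrhage_s,lysis_s,coagulation_s`;
#'   an empty cell means the endpoint was not observed within 300 s.
#' @return A scored tibble (see [score_hetcam()]).
#' @export
load_hetcam <- function(path) {
  score_hetcam(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}
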