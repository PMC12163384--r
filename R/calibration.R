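#' Fit the linear score calibration
#'
#' Ordinary least squares of the reference-assay score on the raw in-house
#' GIS score: `reference ~ m * raw + b`.  The fitted line aligns the raw
#' score scale with the reference assay before the 42-point HRD threshold is
#' applied.
#'
#' @param raw_score numeric raw GIS scores (training samples).
#' @param reference_score numeric reference-assay scores, same length.
#' @return list of class `calibration_model`: `m` (slope), `b` (intercept),
#'   `n_train`, `residuals`, `residual_sd`, `r_squared`.
#' @examples
#' fit_calibration(c(0, 1, 2), c(0, 1, 4))  # m = 2, b = -1/3
#' @export
fit_calibration <- function(raw_score, reference_score) {
  stopifnot(length(raw_score) == length(reference_score))
  if (length(raw_score) < 2L) stop("need at least 2 training pairs")
  if (stats::var(raw_score) == 0) stop("raw scores are constant; slope undefined")
  fit <- stats::lm(reference_score ~ raw_score)
  co <- stats::coef(fit)
  structure(list(m = unname(co[2L]), b = unname(co[1L]),
                 n_train = length(raw_score),
                 residuals = unname(stats::residuals(fit)),
                 residual_sd = stats::sigma(fit),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> corrected = %.4f * raw + %.4f (n = %d)\n",
              x$m, x$b, x$n_train))
  invisible(x)
}

#' Apply the calibration to a raw score
#'
#' Returns the continuous corrected score `m * raw + b`; classification
#' consumes the unrounded value.  A display value rounded half-away-from-zero
#' to integer is available via `round_display = TRUE`.
#'
#' @param raw_score numeric raw GIS score(s).
#' @param model a [fit_calibration()] model.
#' @param round_display also return the rounded display value.
#' @return numeric corrected score(s), or a data.frame with `corrected` and
#'   `display` when `round_display = TRUE`.
#' @export
apply_calibration <- function(raw_score, model, round_display = FALSE) {
  corrected <- model$m * raw_score + model$b
  if (!round_display) return(corrected)
  data.frame(corrected = corrected,
             display = sign(corrected) * floor(abs(corrected) + 0.5))
}

#' Classify HRD status from a corrected GIS score
#'
#' Positive iff the corrected score is at least the threshold (inclusive;
#' default 42, the clinically accepted ovarian-cancer cutoff).
#'
#' @param corrected_score finite numeric score(s).
#' @param threshold positivity threshold (default 42).
#' @return character vector over `{"POS", "NEG"}`.
#' @export
classify_hrd <- function(corrected_score, threshold = 42) {
  if (any(!is.finite(corrected_score))) stop("non-finite score")
  stopifnot(threshold > 0)
  ifelse(corrected_score >= threshold, "POS", "NEG")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes.
#' @param n number of trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` as fractions in `[0, 1]`.
#' @examples
#' wilson_interval(44, 47)  # c(0.828, 0.978) to 3 decimals
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = max(centre - half, 0), upper = min(centre + half, 1))
}

#' Two-assay agreement statistics from a 2x2 table
#'
#' Computes overall, positive, and negative percentage agreement between a
#' reference assay and the test assay, with Wilson 95% confidence intervals.
#' PPA and NPA are margined on the TEST assay: PPA is the fraction of
#' test-positive samples that the reference also calls positive, and NPA the
#' fraction of test-negative samples the reference also calls negative.
#'
#' @param both_pos reference-positive, test-positive count.
#' @param ref_pos_test_neg reference-positive, test-negative count.
#' @param ref_neg_test_pos reference-negative, test-positive count.
#' @param both_neg reference-negative, test-negative count.
#' @param confidence confidence level for the Wilson intervals.
#' @return list of class `agreement_report`: `counts`, `n`, and for each of
#'   `opa`, `ppa`, `npa` a list with `pct`, `ci_lower_pct`, `ci_upper_pct`
#'   (percentages; `NA` with an absent CI when the margin is zero).
#' @examples
#' agreement(26, 1, 2, 18)  # OPA 93.6%, PPA 92.9%, NPA 94.7%
#' @export
agreement <- function(both_pos, ref_pos_test_neg, ref_neg_test_pos, both_neg,
                      confidence = 0.95) {
  counts <- c(both_pos = both_pos, ref_pos_test_neg = ref_pos_test_neg,
              ref_neg_test_pos = ref_neg_test_pos, both_neg = both_neg)
  if (any(counts < 0)) stop("negative count")
  n <- sum(counts)
  if (n < 1) stop("empty table")
  stat <- function(successes, denom) {
    if (denom == 0) {
      return(list(pct = NA_real_, ci_lower_pct = NA_real_,
                  ci_upper_pct = NA_real_))
    }
    ci <- wilson_interval(successes, denom, confidence)
    list(pct = 100 * successes / denom,
         ci_lower_pct = 100 * ci[["lower"]],
         ci_upper_pct = 100 * ci[["upper"]])
  }
  structure(list(
    counts = counts, n = n,
    opa = stat(both_pos + both_neg, n),
    ppa = stat(both_pos, both_pos + ref_neg_test_pos),
    npa = stat(both_neg, ref_pos_test_neg + both_neg)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  fmt <- function(s, nm) {
    if (is.na(s$pct)) return(sprintf("%s undefined (zero margin)", nm))
    sprintf("%s %.1f%% (95%% CI, %.1f%%-%.1f%%)", nm, s$pct,
            s$ci_lower_pct, s$ci_upper_pct)
  }
  cat("<agreement_report> n =", x$n, "\n ",
      fmt(x$opa, "OPA"), "\n ", fmt(x$ppa, "PPA"), "\n ",
      fmt(x$npa, "NPA"), "\n")
  invisible(x)
}

#' Percentage of a count over a total
#'
#' Small reporting helper used for cohort bookkeeping (e.g. positivity and
#' success rates).
#'
#' @param count numerator.
#' @param total denominator (> 0).
#' @param digits decimals to round to (default 1).
#' @return `100 * count / total`, rounded.
#' @examples
#' percent_of(271, 654)       # 41.4
#' percent_of(280, 286, 2)    # 97.90
#' @export
percent_of <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}
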