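#' Coefficient of determination
#'
#' `r_squared()` computes \eqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 /
#' \sum_i (y_i - \bar y)^2}, the fraction of reference-value variance
#' explained by the predictions. It is scale- and shift-invariant in the
#' sense that applying the same affine map to `y` and `yhat` leaves it
#' unchanged, so it reads identically whether SSC labels are in degrees
#' Brix or min-max scaled.
#'
#' @param y Numeric vector of reference values (length >= 2, not constant).
#' @param yhat Numeric vector of predictions, same length as `y`.
#' @return A single number, at most 1.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
r_squared <- function(y, yhat) {
  check_metric_args(y, yhat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("r_squared() is undefined for constant reference values ",
         "(zero total sum of squares)", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root mean square error
#'
#' @param y Numeric vector of reference values.
#' @param yhat Numeric vector of predictions, same length as `y`.
#' @return RMSE in the units of `y` (degrees Brix if `y` is in degrees Brix).
#' @export
#' @examples
#' rmse(c(0, 0), c(1, 1)) # 1
rmse <- function(y, yhat) {
  check_metric_args(y, yhat, min_n = 1)
  sqrt(mean((y - yhat)^2))
}

#' Residual prediction deviation
#'
#' RPD is the standard deviation of the reference values divided by the
#' RMSE of the predictions on the same set; values above about 2.5 are
#' conventionally taken to indicate a usable quantitative calibration.
#' The SD uses the sample convention (n - 1 denominator).
#'
#' @param y Numeric vector of reference values the RMSE was computed on.
#' @param rmse_value Positive RMSE in the same units as `y`.
#' @return A single positive number.
#' @export
#' @examples
#' rpd(c(10, 12, 14), rmse(c(10, 12, 14), c(10.5, 12, 13.5)))
rpd <- function(y, rmse_value) {
  stopifnot(is.numeric(y), length(y) >= 2)
  if (!is.numeric(rmse_value) || length(rmse_value) != 1 || rmse_value <= 0) {
    stop("rpd() needs a single positive RMSE; got ",
         format(rmse_value), " (RPD is undefined at zero error)",
         call. = FALSE)
  }
  stats::sd(y) / rmse_value
}

check_metric_args <- function(y, yhat, min_n = 2) {
  if (!is.numeric(y) || !is.numeric(yhat)) {
    stop("y and yhat must be numeric vectors", call. = FALSE)
  }
  if (length(y) != length(yhat)) {
    stop("length mismatch: length(y) = ", length(y),
         ", length(yhat) = ", length(yhat), call. = FALSE)
  }
  if (length(y) < min_n) {
    stop("need at least ", min_n, " observations", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate predictions chemometrically
#'
#' Computes the standard chemometric trio (R-squared, RMSE, RPD) for a set
#' of SSC predictions, on the degrees-Brix axis and, when a label scaler is
#' supplied, on the min-max-scaled axis as well. R-squared is identical on
#' the two axes; RMSE is not, and both are reported because the two
#' conventions coexist in the literature.
#'
#' @param y Reference SSC values in degrees Brix.
#' @param yhat Predicted SSC values in degrees Brix.
#' @param label_scaler Optional `c(min, max)` degrees-Brix range used to
#'   scale labels for training; enables `rmse_scaled`.
#' @return A one-row tibble with columns `n`, `r2`, `rmse_brix`,
#'   `rmse_scaled`, `rpd`, `sd_reference`.
#' @export
evaluate_predictions <- function(y, yhat, label_scaler = NULL) {
  r2 <- r_squared(y, yhat)
  rm_brix <- rmse(y, yhat)
  rm_scaled <- NA_real_
  if (!is.null(label_scaler)) {
    stopifnot(length(label_scaler) == 2, diff(label_scaler) > 0)
    span <- label_scaler[2] - label_scaler[1]
    rm_scaled <- rmse((y - label_scaler[1]) / span,
                      (yhat - label_scaler[1]) / span)
  }
  tibble::tibble(
    n = length(y),
    r2 = r2,
    rmse_brix = rm_brix,
    rmse_scaled = rm_scaled,
    rpd = if (rm_brix > 0) rpd(y, rm_brix) else Inf,
    sd_reference = stats::sd(y)
  )
}

#' Split samples into calibration and prediction sets
#'
#' Randomly partitions sample ids at the fruit level into disjoint
#' calibration and prediction sets at the given ratio (default 5:1, so 570
#' ids give 475 calibration and 95 prediction samples). Splitting happens
#' at the fruit level, never at the patch level, so no fruit contributes
#' patches to both sets.
#'
#' @param ids Vector of sample identifiers.
#' @param ratio Integer pair, calibration:prediction (default `c(5, 1)`).
#' @param seed Integer seed for the random partition.
#' @return An object of class `split_plan`: a list with `calibration_ids`,
#'   `prediction_ids`, `ratio` and `seed`.
#' @export
#' @examples
#' split_samples(1:570)
split_samples <- function(ids, ratio = c(5, 1), seed = 1L) {
  stopifnot(length(ratio) == 2, all(ratio >= 1))
  n <- length(ids)
  if (n < sum(ratio)) {
    stop("need at least ", sum(ratio), " ids for a ",
         ratio[1], ":", ratio[2], " split; got ", n, call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  n_cal <- round(n * ratio[1] / sum(ratio))
  cal <- withr::with_seed(seed, sort(sample(seq_len(n), n_cal)))
  structure(
    list(
      calibration_ids = ids[cal],
      prediction_ids = ids[-cal],
      ratio = ratio,
      seed = seed
    ),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", length(x$calibration_ids), " calibration / ",
      length(x$prediction_ids), " prediction (ratio ",
      x$ratio[1], ":", x$ratio[2], ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Summarise reference values Table-style
#'
#' One summary row per the chemometric reporting convention: n, max, min,
#' mean and sample SD (n - 1 denominator, the same convention RPD uses).
#'
#' @param values Numeric vector of reference values (length >= 2).
#' @param dataset Optional label for the row (e.g. "calibration").
#' @return A one-row tibble with columns `dataset`, `n`, `max`, `min`,
#'   `mean`, `sd`.
#' @export
summarize_reference <- function(values, dataset = "all") {
  if (!is.numeric(values) || length(values) < 2) {
    stop("need at least 2 reference values", call. = FALSE)
  }
  tibble::tibble(
    dataset = dataset,
    n = length(values),
    max = max(values),
    min = min(values),
    mean = mean(values),
    sd = stats::sd(values)
  )
}
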