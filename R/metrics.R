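# Prediction-quality metrics: RMSE (deg), per-cycle NRMSE (%) and R2.

#' Root-mean-square error
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return RMSE in the units of `y`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < 1) stop("need at least one sample")
  sqrt(mean((yhat - y)^2))
}

#' Normalised RMSE of one gait cycle
#'
#' RMSE divided by the within-cycle range of the predicted trace (the
#' default) or of the reference trace, as a percentage. A constant
#' denominator trace makes the metric undefined; the cycle is flagged with
#' a warning and `NA` is returned so callers can exclude it from averages.
#'
#' @param y Observed cycle values.
#' @param yhat Predicted cycle values.
#' @param denominator `"prediction"` (default) or `"reference"`.
#' @return NRMSE in percent, or `NA` if undefined.
#' @export
nrmse_cycle <- function(y, yhat, denominator = c("prediction",
                                                 "reference")) {
  denominator <- match.arg(denominator)
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < 2) stop("a cycle needs at least 2 samples")
  d <- if (denominator == "prediction") yhat else y
  rng <- max(d) - min(d)
  if (rng <= 0) {
    warning("constant trace: NRMSE undefined for this cycle")
    return(NA_real_)
  }
  100 * rmse(y, yhat) / rng
}

#' Coefficient of determination
#'
#' R2 = 1 - SS_res / SS_tot with the total sum of squares about the mean
#' of the observed values.
#'
#' @param y Observed values (must not be constant).
#' @param yhat Predicted values.
#' @return R2 (dimensionless, <= 1).
#' @export
r2 <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < 2) stop("need at least 2 samples")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) {
    warning("constant observed values: R2 undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / ss_tot
}
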