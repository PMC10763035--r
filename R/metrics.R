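#' Paired observed/predicted scores
#'
#' Validated container for the validation statistics: equal-length,
#' NA-free observed (`y`) and predicted (`yhat`) score vectors, n >= 2.
#'
#' @param y Observed scores.
#' @param yhat Predicted scores.
#' @return Object of class `promval_paired` with fields `y`, `yhat`, `n`,
#'   `ybar`.
#' @export
paired_scores <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("y and yhat lengths differ", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 paired scores", call. = FALSE)
  if (anyNA(y) || anyNA(yhat)) stop("paired scores must not contain missing values", call. = FALSE)
  structure(list(y = y, yhat = yhat, n = length(y), ybar = mean(y)),
            class = "promval_paired")
}

as_paired <- function(p) {
  if (inherits(p, "promval_paired")) p else paired_scores(p$y, p$yhat)
}

#' Validation R-squared
#'
#' One minus the ratio of residual to total variance,
#' `1 - sum((y - yhat)^2) / sum((y - ybar)^2)`. For an externally validated
#' (not refitted) model this can be negative.
#'
#' @param p A [paired_scores()] object.
#' @return Real number, at most 1, unbounded below.
#' @export
r_squared <- function(p) {
  p <- as_paired(p)
  tot <- sum((p$y - p$ybar)^2)
  if (tot == 0) undefined_metric("R2", "observed scores are constant (total variance 0)")
  1 - sum((p$y - p$yhat)^2) / tot
}

#' Mean absolute error and root mean square error
#'
#' `MAE = sum(|yhat - y|) / n` and `RMSE = sqrt(sum((yhat - y)^2) / n)`
#' (population form, divisor n).
#'
#' @param p A [paired_scores()] object.
#' @return Non-negative real; `RMSE >= MAE` always.
#' @export
mae <- function(p) {
  p <- as_paired(p)
  mean(abs(p$yhat - p$y))
}

#' @rdname mae
#' @export
rmse <- function(p) {
  p <- as_paired(p)
  sqrt(mean((p$yhat - p$y)^2))
}

#' Continuous concordance index
#'
#' The probability that, of two randomly chosen subjects with *distinct*
#' predictions, the one predicted higher is observed higher:
#' `P((yhat_i - yhat_j)(y_i - y_j) > 0 | yhat_i != yhat_j)`. Under the
#' default `"as_printed"` policy a pair whose observed scores tie counts
#' against concordance, exactly as the strict inequality reads;
#' `"half_credit"` awards such pairs 0.5. Pairs tied on the prediction are
#' excluded from the denominator under both policies.
#'
#' @param p A [paired_scores()] object.
#' @param tie_policy `"as_printed"` (default) or `"half_credit"`.
#' @return Value in \[0, 1\].
#' @export
c_index <- function(p, tie_policy = c("as_printed", "half_credit")) {
  p <- as_paired(p)
  tie_policy <- match.arg(tie_policy)
  ct <- pair_counts(p$yhat, p$y)
  denom <- ct[["concordant"]] + ct[["discordant"]] + ct[["tie_y"]]
  if (denom == 0) undefined_metric("c_index", "all predictions are identical")
  num <- ct[["concordant"]] +
    if (tie_policy == "half_credit") 0.5 * ct[["tie_y"]] else 0
  num / denom
}

#' Calibration-in-the-large
#'
#' The intercept of a regression of the observed score with the predicted
#' score as an offset: the systematic offset between observed and predicted
#' scores (0 is perfect). Under `method = "median"` this is the
#' intercept-only LAD fit to the residuals — the (lower) median residual;
#' under `"mean"` it is the mean residual, the ordinary-least-squares
#' analogue.
#'
#' @param p A [paired_scores()] object.
#' @param method `"median"` (default) or `"mean"`.
#' @return Real, score units.
#' @export
calibration_in_large <- function(p, method = c("median", "mean")) {
  p <- as_paired(p)
  method <- match.arg(method)
  r <- p$y - p$yhat
  if (method == "median") {
    lad_fit(matrix(1, p$n, 1), p$y, offset = p$yhat)$coefficients[[1]]
  } else {
    mean(r)
  }
}

#' Calibration slope
#'
#' The slope of the predicted score in a univariable regression of observed
#' on predicted (intercept included, no offset); 1 is perfect, below 1
#' means predictions are too extreme. `"median"` uses LAD (tau = 0.5
#' quantile regression), `"mean"` ordinary least squares.
#'
#' @inheritParams calibration_in_large
#' @return Real slope.
#' @export
calibration_slope <- function(p, method = c("median", "mean")) {
  p <- as_paired(p)
  method <- match.arg(method)
  if (stats::sd(p$yhat) == 0) {
    undefined_metric("CS", "predicted scores are constant")
  }
  X <- cbind(`(Intercept)` = 1, yhat = p$yhat)
  if (method == "median") {
    lad_fit(X, p$y)$coefficients[[2]]
  } else {
    drop(stats::lm.fit(X, p$y)$coefficients[["yhat"]])
  }
}

#' Compute the full validation statistic set
#'
#' Bundles R-squared, calibration-in-the-large, calibration slope, MAE,
#' RMSE and the concordance index for one (domain, timepoint, imputation)
#' cell.
#'
#' @inheritParams calibration_in_large
#' @param tie_policy Passed to [c_index()].
#' @param domain,timepoint,imputation Provenance labels carried through to
#'   pooling.
#' @param undefined `"error"` (default) re-raises undefined-metric errors
#'   with the metric name; `"na"` records `NA` for the offending metric.
#' @return One-row data frame with columns `domain`, `timepoint`,
#'   `imputation`, `calibration_method`, `R2`, `CL`, `CS`, `MAE`, `RMSE`,
#'   `c_index`.
#' @export
compute_metric_set <- function(p, calibration_method = c("median", "mean"),
                               tie_policy = "as_printed",
                               domain = NA_character_, timepoint = NA_character_,
                               imputation = NA_integer_,
                               undefined = c("error", "na")) {
  p <- as_paired(p)
  calibration_method <- match.arg(calibration_method)
  undefined <- match.arg(undefined)
  wrap <- function(expr) {
    if (undefined == "error") expr() else {
      tryCatch(expr(), promval_undefined_metric = function(e) NA_real_)
    }
  }
  data.frame(domain = domain, timepoint = timepoint, imputation = imputation,
             calibration_method = calibration_method,
             R2 = wrap(function() r_squared(p)),
             CL = wrap(function() calibration_in_large(p, calibration_method)),
             CS = wrap(function() calibration_slope(p, calibration_method)),
             MAE = mae(p), RMSE = rmse(p),
             c_index = wrap(function() c_index(p, tie_policy)),
             stringsAsFactors = FALSE)
}

#' Reshape wide metric rows to the long format used by pooling
#'
#' @param wide Rows as returned by [compute_metric_set()].
#' @return Long data frame: `domain`, `timepoint`, `imputation`, `metric`,
#'   `value`.
#' @export
metrics_long <- function(wide) {
  metrics <- c("R2", "CL", "CS", "MAE", "RMSE", "c_index")
  out <- lapply(metrics, function(m) {
    data.frame(domain = wide$domain, timepoint = wide$timepoint,
               imputation = wide$imputation, metric = m, value = wide[[m]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
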