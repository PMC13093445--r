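#' Compute the seven regression evaluation metrics
#'
#' Computes MSE, RMSE, MAE, MedAE, MAPE, MSLE and R2 for a vector of true
#' values and predictions:
#' \itemize{
#'   \item MSE = mean((y - yhat)^2); RMSE = sqrt(MSE)
#'   \item MAE = mean(|y - yhat|); MedAE = median(|y - yhat|)
#'   \item MAPE = mean(|(y - yhat)/y|) over rows with y != 0; rows with
#'     y = 0 are excluded from MAPE only and the exclusion is flagged
#'   \item MSLE = mean((log(1 + y) - log(1 + yhat))^2), defined only when
#'     all 1 + y and 1 + yhat are positive (flagged otherwise)
#'   \item R2 = 1 - SS_res / SS_tot
#' }
#' A domain violation for MAPE or MSLE flags that field rather than
#' failing the whole report; zero variance in `y` makes R2 undefined and
#' is an error.
#'
#' @param y true values.
#' @param yhat predictions, same length.
#' @param scale `"log"` or `"original"`; recorded in the report.
#' @return A [MetricsReport-class].
#' @examples
#' r <- computeMetrics(c(1, 2, 3), c(1, 2, 4), scale = "original")
#' metricsTable(r)  # mse = 1/3, r2 = 0.5
#' @export
computeMetrics <- function(y, yhat, scale = c("log", "original")) {
  scale <- match.arg(scale)
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) {
    stop("length mismatch: ", length(y), " vs ", length(yhat))
  }
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations")
  if (!all(is.finite(y)) || !all(is.finite(yhat))) {
    stop("y and yhat must be finite with no missing values")
  }
  if (stats::sd(y) == 0) {
    stop("R2 is undefined: true values have zero variance")
  }
  flags <- character()
  res <- y - yhat
  mse <- mean(res^2)
  rmse <- sqrt(mse)
  mae <- mean(abs(res))
  medae <- stats::median(abs(res))
  nonzero <- y != 0
  if (all(nonzero)) {
    mape <- mean(abs(res / y))
  } else if (any(nonzero)) {
    mape <- mean(abs(res[nonzero] / y[nonzero]))
    flags <- c(flags, sprintf("mape: %d row(s) with y = 0 excluded",
                              sum(!nonzero)))
  } else {
    mape <- NA_real_
    flags <- c(flags, "mape: undefined, all true values are zero")
  }
  if (all(1 + y > 0) && all(1 + yhat > 0)) {
    msle <- mean((log1p(y) - log1p(yhat))^2)
  } else {
    msle <- NA_real_
    flags <- c(flags, "msle: undefined, values at or below -1 present")
  }
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  new("MetricsReport", mse = mse, rmse = rmse, mae = mae, medae = medae,
      mape = mape, msle = msle, r2 = r2, n = as.integer(n),
      scale = scale, flags = flags)
}

#' @rdname accessors
#' @aliases metricsTable,MetricsReport-method
setMethod("metricsTable", "MetricsReport", function(x) {
  data.frame(mse = x@mse, rmse = x@rmse, mae = x@mae, medae = x@medae,
             mape = x@mape, msle = x@msle, r2 = x@r2, n = x@n,
             scale = x@scale)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s scale, n = %d)\n", object@scale, object@n))
  cat(sprintf("  MSE %.6g  RMSE %.6g  MAE %.6g  MedAE %.6g\n",
              object@mse, object@rmse, object@mae, object@medae))
  cat(sprintf("  MAPE %.6g  MSLE %.6g  R2 %.6g\n",
              object@mape, object@msle, object@r2))
  for (f in object@flags) cat("  note:", f, "\n")
})

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; 1 for perfect prediction, 0 for predicting the
#' mean, negative for worse than the mean.
#'
#' @param y true values (variance must be positive).
#' @param yhat predictions.
#' @return scalar R2.
#' @export
rSquared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R2 is undefined: true values have zero variance")
  1 - sum((y - yhat)^2) / sst
}
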