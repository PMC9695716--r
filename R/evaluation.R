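#' Regression error metrics
#'
#' MAE = mean |y - yhat|; RMSE = sqrt(mean (y - yhat)^2); MAPE =
#' mean |y - yhat| / denom. The MAPE denominator is the predicted value by
#' default — the form this pipeline reports — with a switch to the
#' conventional actual-value denominator for interoperability.
#'
#' @param y actual values.
#' @param yhat predicted values (same non-zero length).
#' @param mape_denominator `"predicted"` (default) or `"actual"`.
#' @return list with `mae`, `mape` (a fraction, not percent), `rmse`.
#' @export
regression_metrics <- function(y, yhat,
                               mape_denominator = c("predicted", "actual")) {
  mape_denominator <- match.arg(mape_denominator)
  if (length(y) == 0 || length(y) != length(yhat))
    stop("y and yhat must have equal non-zero length")
  denom <- if (mape_denominator == "predicted") yhat else y
  if (any(denom == 0))
    stop("MAPE denominator is zero at sample(s) ",
         paste(which(denom == 0), collapse = ", "))
  err <- y - yhat
  list(mae = mean(abs(err)),
       mape = mean(abs(err) / abs(denom)),
       rmse = sqrt(mean(err^2)))
}

#' Signed per-sample error rate (percent)
#'
#' E = (predicted - actual) / actual * 100: the signed relative deviation
#' of the predicted from the measured nitrogen content.
#'
#' @param actual_gkg measured value(s); must be non-zero.
#' @param predicted_gkg predicted value(s).
#' @return signed percent error(s).
#' @export
error_rate <- function(actual_gkg, predicted_gkg) {
  if (any(actual_gkg == 0)) stop("actual value of zero: error rate undefined")
  (predicted_gkg - actual_gkg) / actual_gkg * 100
}

#' Linear fit of predicted versus actual values
#'
#' Ordinary least squares of predicted on actual (predicted on the
#' vertical axis, as in calibration scatter plots), with the fit's
#' R-squared and the Pearson correlation of the pair. A slope near 1 and
#' intercept near 0 indicate an unbiased predictor.
#'
#' @param y actual values (length >= 3, non-zero variance).
#' @param yhat predicted values.
#' @return list with `slope`, `intercept`, `r_squared`, `pearson_r`.
#' @export
linear_fit_report <- function(y, yhat) {
  if (length(y) < 3) stop("need at least 3 points for a linear fit")
  if (stats::var(y) < .Machine$double.eps)
    stop("actual values have zero variance")
  fit <- stats::lm(yhat ~ y)
  r <- stats::cor(y, yhat)
  # univariate OLS: the fit's R-squared is the squared correlation
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r^2,
       pearson_r = r)
}

#' Evaluate a fitted model on a test table
#'
#' Predicts nitrogen for every test row and assembles the full report:
#' MAE/MAPE/RMSE, per-sample signed error rates, and the
#' predicted-vs-actual linear fit. Optionally writes a scatter-and-fit
#' figure (predicted on the vertical axis, the fitted line and the 1:1
#' line overlaid).
#'
#' @param model any model with a `predict` method over the feature columns.
#' @param test data.frame with feature columns and the response column.
#' @param features,response column names.
#' @param mape_denominator passed to [regression_metrics()].
#' @param plot_file optional PNG path for the diagnostic figure.
#' @return an `eval_report` list: `mae_gkg`, `mape_frac`, `rmse_gkg`,
#'   `error_rates_pct`, `fit_slope`, `fit_intercept`, `r_squared`,
#'   `pearson_r`, `n`, `predictions` (per-sample data.frame).
#' @export
evaluate_run <- function(model, test,
                         features = c("area_cm2", "g_mean", "g_var"),
                         response = "nitrogen_gkg",
                         mape_denominator = "predicted",
                         plot_file = NULL) {
  if (!response %in% names(test))
    stop("test table lacks the response column '", response, "'")
  y <- test[[response]]
  yhat <- as.numeric(predict(model, test))
  m <- regression_metrics(y, yhat, mape_denominator = mape_denominator)
  lf <- if (length(y) >= 3 && stats::var(y) > .Machine$double.eps)
    linear_fit_report(y, yhat)
  else list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
            pearson_r = NA_real_)
  preds <- data.frame(sample_id = test$sample_id %||%
                        sprintf("s%04d", seq_along(y)),
                      actual_gkg = y, predicted_gkg = yhat,
                      error_rate_pct = error_rate(y, yhat),
                      stringsAsFactors = FALSE)
  rep <- structure(list(mae_gkg = m$mae, mape_frac = m$mape,
                        rmse_gkg = m$rmse,
                        error_rates_pct = preds$error_rate_pct,
                        fit_slope = lf$slope, fit_intercept = lf$intercept,
                        r_squared = lf$r_squared, pearson_r = lf$pearson_r,
                        n = length(y), predictions = preds),
                   class = "eval_report")
  if (!is.null(plot_file)) plot_eval(rep, plot_file)
  rep
}

plot_eval <- function(report, path) {
  p <- report$predictions
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::plot(p$actual_gkg, p$predicted_gkg,
                 xlab = "measured nitrogen (g/kg)",
                 ylab = "predicted nitrogen (g/kg)",
                 pch = 19, col = "forestgreen",
                 main = sprintf("fit: slope %.3f, R2 %.3f",
                                report$fit_slope, report$r_squared))
  graphics::abline(0, 1, lty = 2, col = "gray50")
  if (is.finite(report$fit_slope))
    graphics::abline(report$fit_intercept, report$fit_slope, col = "red3")
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' Per-sample predictions are embedded so the summary statistics can be
#' recomputed from the file alone.
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(schema = "leafnitro-report-1",
              n = report$n,
              mae_gkg = report$mae_gkg, mape_frac = report$mape_frac,
              rmse_gkg = report$rmse_gkg,
              fit_slope = report$fit_slope,
              fit_intercept = report$fit_intercept,
              r_squared = report$r_squared, pearson_r = report$pearson_r,
              predictions = report$predictions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
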