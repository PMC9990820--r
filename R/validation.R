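#' External-validation coefficient R2_ext
#'
#' `R2_ext = 1 - sum (y_i - yhat_i)^2 / sum (y_i - ybar_train)^2`,
#' comparing test-set prediction errors against the deviation of the
#' test observations from the training-set mean.  At most 1; zero when
#' predictions are no better than always guessing the training mean;
#' unbounded below.
#'
#' @param y_test observed test-set activities.
#' @param y_pred predicted test-set activities (same length).
#' @param y_train_mean mean activity of the training set.
#' @return A single number.
#' @export
r2_ext <- function(y_test, y_pred, y_train_mean) {
  if (length(y_test) != length(y_pred) || length(y_test) < 1) {
    stop("`y_test` and `y_pred` must have equal length >= 1", call. = FALSE)
  }
  den <- sum((y_test - y_train_mean)^2)
  if (den <= 0) {
    stop("undefined R2_ext: every test activity equals the training mean",
         call. = FALSE)
  }
  1 - sum((y_test - y_pred)^2) / den
}

#' Robustness gate on R2_ext
#'
#' A model is deemed robust (statistically predictive on external data)
#' when `R2_ext` strictly exceeds 0.5.
#'
#' @param r2_ext_value finite numeric value.
#' @return `TRUE` or `FALSE`.
#' @export
robustness_gate <- function(r2_ext_value) {
  stopifnot(is.finite(r2_ext_value))
  r2_ext_value > 0.5
}

#' Prediction error summary
#'
#' Root-mean-square error, mean absolute error, and the squared Pearson
#' correlation between observed and predicted values (the "correlation
#' coefficient" convention of QSAR reporting).
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return List with `rmse`, `mae`, `r2`.
#' @export
error_summary <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop("need equal-length vectors of length >= 2", call. = FALSE)
  }
  if (stats::sd(y_pred) == 0 || stats::sd(y_true) == 0) {
    stop("correlation undefined: constant observed or predicted values",
         call. = FALSE)
  }
  list(rmse = sqrt(mean((y_true - y_pred)^2)),
       mae = mean(abs(y_true - y_pred)),
       r2 = stats::cor(y_true, y_pred)^2)
}

#' Assemble a validation report
#'
#' @inheritParams r2_ext
#' @return List of class `validation_report`: `r2_ext`, `r2`, `rmse`,
#'   `mean_abs_error`, `n_test`, `pass_robust`.
#' @export
validation_report <- function(y_test, y_pred, y_train_mean) {
  r2e <- r2_ext(y_test, y_pred, y_train_mean)
  es <- error_summary(y_test, y_pred)
  structure(list(r2_ext = r2e, r2 = es$r2, rmse = es$rmse,
                 mean_abs_error = es$mae, n_test = length(y_test),
                 pass_robust = robustness_gate(r2e)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("External validation (n = %d): R2_ext = %.4f [%s]\n",
              x$n_test, x$r2_ext,
              if (x$pass_robust) "robust" else "not robust"))
  cat(sprintf("  r2 = %.4f  RMSE = %.4f  MAE = %.4f\n",
              x$r2, x$rmse, x$mean_abs_error))
  invisible(x)
}
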