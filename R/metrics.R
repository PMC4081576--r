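#' Pearson correlation between observed and predicted activity
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 3, both
#'   non-constant.
#' @return Pearson product-moment correlation in \[-1, 1\].
#' @export
pearson_r <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 3)
  if (sd(observed) == 0 || sd(predicted) == 0) {
    abort("undefined correlation: constant vector")
  }
  cor(observed, predicted, method = "pearson")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST`, with `SSE = sum((obs - pred)^2)` and
#' `SST = sum((obs - mean(obs))^2)`. Unlike squared Pearson correlation
#' this penalises biased predictors and can be negative.
#'
#' @inheritParams pearson_r
#' @return R-squared (at most 1; 1 iff predictions equal observations).
#' @export
r_squared <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) abort("undefined R-squared: SST is zero")
  1 - sum((observed - predicted)^2) / sst
}

#' Mean absolute error
#' @inheritParams pearson_r
#' @return Mean of absolute residuals.
#' @export
mae <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 1)
  mean(abs(observed - predicted))
}

#' Root mean square error
#' @inheritParams pearson_r
#' @return Square root of the mean squared residual; always >= MAE.
#' @export
rmse <- function(observed, predicted) {
  check_obs_pred(observed, predicted, min_n = 1)
  sqrt(mean((observed - predicted)^2))
}

check_obs_pred <- function(observed, predicted, min_n) {
  if (!is.numeric(observed) || !is.numeric(predicted)) {
    abort("`observed` and `predicted` must be numeric vectors.")
  }
  if (length(observed) != length(predicted)) {
    abort(sprintf("Length mismatch: %d observed vs %d predicted.",
                  length(observed), length(predicted)))
  }
  if (length(observed) < min_n) {
    abort(sprintf("Need at least %d observations.", min_n))
  }
  if (anyNA(observed) || anyNA(predicted)) {
    abort("Missing values in observed or predicted.")
  }
  invisible(TRUE)
}

#' Evaluate predictions with the standard QSAR statistics
#'
#' Computes n, Pearson R, R-squared, MAE, RMSE, SSE and SST in one pass,
#' as a one-row tibble suitable for stacking across datasets or folds.
#'
#' @inheritParams pearson_r
#' @param label Optional character tag (e.g. `"wild_valid"`) recorded in
#'   a `dataset` column.
#' @return One-row tibble with columns `dataset`, `n`, `R`, `R2`, `MAE`,
#'   `RMSE`, `SSE`, `SST`.
#' @export
evaluate_predictions <- function(observed, predicted, label = NA_character_) {
  check_obs_pred(observed, predicted, min_n = 2)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  tibble(
    dataset = label,
    n = length(observed),
    R = if (sd(observed) > 0 && sd(predicted) > 0)
      cor(observed, predicted) else NA_real_,
    R2 = if (sst > 0) 1 - sse / sst else NA_real_,
    MAE = mean(abs(observed - predicted)),
    RMSE = sqrt(mean((observed - predicted)^2)),
    SSE = sse,
    SST = sst)
}

#' Apply a model trained on one inhibitor class to the other class
#'
#' Cross-prediction probes scaffold transferability: a model trained on
#' one chemical class is evaluated on compounds of the other class. A
#' large drop in R relative to within-class performance indicates the
#' learned structure-activity mapping does not transfer.
#'
#' @param model A fitted model from [train_svr()].
#' @param descriptors Descriptor table for the evaluation compounds
#'   (must provide every feature the model uses).
#' @param activity Observed pIC50 vector aligned to `descriptors` rows.
#' @param evaluated_class Optional label for the evaluated class.
#' @return One-row evaluation tibble (see [evaluate_predictions()]) with
#'   extra columns `model_scope` and `evaluated_class`.
#' @export
cross_predict <- function(model, descriptors, activity,
                          evaluated_class = NA_character_) {
  if (nrow(descriptors) == 0) abort("No compounds to evaluate.")
  preds <- predict(model, descriptors)
  evaluate_predictions(activity, preds, label = "cross_prediction") |>
    mutate(model_scope = model$scope %||% NA_character_,
           evaluated_class = evaluated_class)
}
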