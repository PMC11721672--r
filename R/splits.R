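# Rational train/test split constructions and external-prediction
# assessment.

# Stable sort: ascending pec50, ties broken by lexicographic id, so splits
# are deterministic and invariant to input row order.
.rank_records <- function(records) {
  stopifnot(all(c("id", "pec50") %in% names(records)))
  if (anyNA(records$pec50))
    stop("split: records must have finite pec50", call. = FALSE)
  records[order(records$pec50, records$id), , drop = FALSE]
}

.split_obj <- function(records, train_idx, method, train_fraction = NA) {
  tr <- records[train_idx, , drop = FALSE]
  te <- records[-train_idx, , drop = FALSE]
  structure(list(
    train_ids = tr$id, test_ids = te$id, method = method,
    train_fraction = train_fraction,
    summary = data.frame(
      side = c("train", "test"), n = c(nrow(tr), nrow(te)),
      mean_pec50 = c(mean(tr$pec50), mean(te$pec50)),
      sd_pec50 = c(stats::sd(tr$pec50), stats::sd(te$pec50)))),
    class = "potency_split")
}

#' @export
print.potency_split <- function(x, ...) {
  cat(sprintf("Potency split (%s): %d train / %d test\n", x$method,
              length(x$train_ids), length(x$test_ids)))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Alternating potency-matched split
#'
#' Rank-orders the records by pEC50 (ties by id) and alternates them between
#' train and test, so the two sides are matched potency-by-potency: sorted
#' positions 1, 3, 5, ... go to training and 2, 4, 6, ... to test. For odd n
#' the extra member lands in training (a 31-record set gives 16/15).
#'
#' @param records data.frame with columns `id` and `pec50`.
#' @return a "potency_split" object.
#' @export
alternating_potency_split <- function(records) {
  if (nrow(records) < 2)
    stop("alternating_potency_split(): need n >= 2", call. = FALSE)
  r <- .rank_records(records)
  .split_obj(r, seq(1, nrow(r), by = 2), "alternating")
}

#' Every-fifth potency split
#'
#' Rank-orders by pEC50 and, from each consecutive group of five, allocates
#' the first four to training and the fifth to test; a trailing partial
#' group goes entirely to training (31 records give 25/6).
#'
#' @param records data.frame with columns `id` and `pec50`.
#' @return a "potency_split" object.
#' @export
every_fifth_split <- function(records) {
  n <- nrow(records)
  if (n < 5) stop("every_fifth_split(): need n >= 5", call. = FALSE)
  r <- .rank_records(records)
  test_idx <- seq(5, n, by = 5)
  .split_obj(r, setdiff(seq_len(n), test_idx), "every_fifth")
}

#' Potency-ranked (extrapolation) split
#'
#' Rank-orders by pEC50 and puts the least potent `train_fraction` of the
#' records in training and the most potent remainder in test; the count is
#' rounded half away from zero.
#'
#' @param records data.frame with columns `id` and `pec50`.
#' @param train_fraction fraction in (0, 1); the study used 0.8 and 0.6.
#' @return a "potency_split" object.
#' @export
potency_ranked_split <- function(records, train_fraction = 0.8) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("potency_ranked_split(): train_fraction must be in (0, 1)",
         call. = FALSE)
  n <- nrow(records)
  n_train <- floor(train_fraction * n + 0.5)  # round half away from zero
  if (n_train < 1 || n_train >= n)
    stop("potency_ranked_split(): degenerate split (empty side)",
         call. = FALSE)
  r <- .rank_records(records)
  .split_obj(r, seq_len(n_train), "potency_ranked", train_fraction)
}

#' External-prediction assessment
#'
#' Compares predicted against observed pEC50 values on a test set:
#' `r2_pred = 1 - SSE / SS(observed about the training mean)` (which can be
#' negative for predictions worse than the training-mean baseline),
#' `rmse_pred = sqrt(mean squared error)`, the least-squares line of
#' predicted versus observed with and without an intercept, and the mean
#' shift `mean(predicted) - mean(observed)`.
#'
#' @param observed,predicted numeric pEC50 vectors of equal length >= 2.
#' @param train_mean mean pEC50 of the training set used to fit the model.
#' @return list of class "prediction_report": `r2_pred`, `rmse_pred`,
#'   `fit_slope`, `fit_intercept`, `origin_slope`, `mean_shift`, `n`.
#' @export
assess_predictions <- function(observed, predicted, train_mean) {
  if (length(observed) != length(predicted))
    stop("assess_predictions(): length mismatch", call. = FALSE)
  n <- length(observed)
  if (n < 2) stop("assess_predictions(): need n >= 2", call. = FALSE)
  denom <- sum((observed - train_mean)^2)
  if (denom == 0)
    stop("assess_predictions(): all observed equal the training mean; ",
         "r2_pred undefined", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  sxx <- sum((observed - mean(observed))^2)
  slope <- if (sxx > 0)
    sum((observed - mean(observed)) * (predicted - mean(predicted))) / sxx
  else NA_real_
  intercept <- mean(predicted) - slope * mean(observed)
  structure(list(
    r2_pred = 1 - sse / denom,
    rmse_pred = sqrt(sse / n),
    fit_slope = slope,
    fit_intercept = intercept,
    origin_slope = sum(observed * predicted) / sum(observed^2),
    mean_shift = mean(predicted) - mean(observed),
    n = n), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("External prediction (n = %d):\n", x$n))
  cat(sprintf("  R2_pred = %.3f, RMSE_pred = %.3f\n", x$r2_pred, x$rmse_pred))
  cat(sprintf("  best fit: y = %.4fx %+.4f; through origin: y = %.4fx\n",
              x$fit_slope, x$fit_intercept, x$origin_slope))
  cat(sprintf("  mean shift (pred - obs) = %.3f\n", x$mean_shift))
  invisible(x)
}
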