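#' Pooled forecast error metrics
#'
#' RMSE, MAE and MAPE pooled over every forecast point of every evaluated
#' series: `RMSE = sqrt(mean((t - that)^2))`, `MAE = mean(|t - that|)`,
#' `MAPE = mean(|t - that| / t)` (reported as a fraction). With
#' `per_series = TRUE` the metrics are computed per row and averaged instead.
#'
#' @param truth numeric vector or matrix of observed glucose (mmol/L);
#'   strictly positive (MAPE denominator).
#' @param pred predictions, same shape.
#' @param per_series average per-series metrics instead of pooling all points.
#' @return List with `rmse`, `mae`, `mape`, `n_points`.
#' @export
#' @examples
#' compute_metrics(c(4, 6), c(5, 5))  # rmse 1, mae 1, mape ~0.2083
compute_metrics <- function(truth, pred, per_series = FALSE) {
  if (!identical(dim(truth), dim(pred)) || length(truth) != length(pred)) {
    stop_glucluster("truth and pred shapes differ", "shape_error")
  }
  if (any(truth <= 0)) {
    stop_glucluster("truth must be strictly positive for MAPE", "mape_domain_error")
  }
  if (per_series && !is.null(dim(truth))) {
    rows <- lapply(seq_len(nrow(truth)), function(i)
      compute_metrics(as.numeric(truth[i, ]), as.numeric(pred[i, ])))
    return(list(rmse = mean(vapply(rows, `[[`, numeric(1), "rmse")),
                mae = mean(vapply(rows, `[[`, numeric(1), "mae")),
                mape = mean(vapply(rows, `[[`, numeric(1), "mape")),
                n_points = length(truth)))
  }
  e <- as.numeric(truth) - as.numeric(pred)
  list(rmse = sqrt(mean(e^2)),
       mae = mean(abs(e)),
       mape = mean(abs(e) / as.numeric(truth)),
       n_points = length(e))
}

#' Per-step MAE curve
#'
#' Column-wise mean absolute error across evaluated series: the MAE at each
#' forecast step 1..h, the quantity plotted against forecast-step index in
#' per-horizon error curves.
#'
#' @param truth n x h matrix of observed continuations.
#' @param pred n x h matrix of forecasts.
#' @return Numeric vector of length h.
#' @export
per_step_mae <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (!identical(dim(truth), dim(pred))) {
    stop_glucluster("truth and pred shapes differ", "shape_error")
  }
  colMeans(abs(truth - pred))
}
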