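#' Holt double exponential smoothing forecast
#'
#' Level/trend recursions without a seasonal term (nocturnal 6-hour windows
#' carry none): `l_t = alpha*y_t + (1-alpha)*(l_{t-1} + b_{t-1})`,
#' `b_t = beta*(l_t - l_{t-1}) + (1-beta)*b_{t-1}`, initialized with
#' `l_1 = y_1`, `b_1 = y_2 - y_1`. The h-step forecast is
#' `l_T + j*b_T`, j = 1..h.
#'
#' @param prefix numeric glucose vector (length >= 2).
#' @param alpha,beta smoothing weights in (0, 1\].
#' @param h forecast horizon in steps.
#' @return Numeric forecast vector of length `h`.
#' @export
#' @examples
#' holt_forecast(c(5.0, 5.5, 5.3), alpha = 0.5, beta = 0.5, h = 1)  # 5.975
holt_forecast <- function(prefix, alpha, beta, h) {
  st <- holt_state(prefix, alpha, beta)
  st$level + seq_len(h) * st$trend
}

# run the recursions; returns final level/trend and one-step-ahead SSE
holt_state <- function(y, alpha, beta) {
  n <- length(y)
  if (n < 2L) stop_glucluster("Holt needs at least 2 readings", "size_error")
  if (alpha <= 0 || alpha > 1 || beta <= 0 || beta > 1) {
    stop_glucluster("alpha and beta must lie in (0, 1]", "config_error")
  }
  l <- y[1]; b <- y[2] - y[1]; sse <- 0
  for (t in 2:n) {
    pred <- l + b
    sse <- sse + (y[t] - pred)^2
    l_new <- alpha * y[t] + (1 - alpha) * (l + b)
    b <- beta * (l_new - l) + (1 - beta) * b
    l <- l_new
  }
  list(level = l, trend = b, sse = sse)
}

#' Per-series Holt parameter grid search
#'
#' Minimizes the in-sample one-step-ahead squared error of the recursions
#' over a grid of `(alpha, beta)` pairs; ties break to the smaller alpha,
#' then the smaller beta.
#'
#' @param prefix numeric glucose vector.
#' @param grid_alpha,grid_beta candidate values (defaults 0.1, 0.2, ..., 1.0).
#' @return List with `alpha`, `beta`, `sse`.
#' @export
holt_fit <- function(prefix, grid_alpha = seq(0.1, 1, by = 0.1),
                     grid_beta = seq(0.1, 1, by = 0.1)) {
  if (length(grid_alpha) == 0L || length(grid_beta) == 0L) {
    stop_glucluster("empty Holt grid", "config_error")
  }
  best <- NULL
  for (a in sort(grid_alpha)) {
    for (b in sort(grid_beta)) {
      sse <- holt_state(prefix, a, b)$sse
      if (is.null(best) || sse < best$sse) {
        best <- list(alpha = a, beta = b, sse = sse)
      }
    }
  }
  best
}
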