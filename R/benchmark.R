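ALGORITHM_LABELS <- c(
  mtsc = "MTSC", wmtsc = "WMTSC", holt = "Holt",
  rf_cluster = "RF with pre-clustering",
  gbt_cluster = "GBT with pre-clustering",
  rf_global = "RF without pre-clustering",
  gbt_global = "GBT without pre-clustering")

#' Benchmark all forecasting algorithms on split NH groups
#'
#' For each NH group and horizon: clusters the group's training panel (one
#' Ward model per group, shared across horizons and reused by every
#' cluster-based algorithm), fits the requested forecasters, predicts each
#' test series' last `h` readings from its first `72 - h`, and reports pooled
#' RMSE/MAE/MAPE plus per-step MAE curves.
#'
#' @param sets named list of [split_dataset()] results, e.g.
#'   `list(no_NH = ..., NH = ...)` from [preprocess_cohort()].
#' @param algorithms subset of `"mtsc"`, `"wmtsc"`, `"holt"`, `"rf_cluster"`,
#'   `"gbt_cluster"`, `"rf_global"`, `"gbt_global"`.
#' @param horizons_min prediction horizons in minutes (multiples of 5).
#' @param k_range silhouette search interval for the per-group Ward model.
#' @param k_fixed optional named list/vector fixing k per group.
#' @param hyper tree-ensemble hyperparameters (`default_hyperparams()`).
#' @param holt_grid alpha/beta grid for the per-series Holt search.
#' @param stability_reps replicates for the advisory stability score
#'   (0 = skip).
#' @param per_series average per-series metrics instead of pooling points.
#' @param seed master seed; every stage derives its own small offset from it.
#' @return Object of class `benchmark_table`: `table` (data.frame: group,
#'   ph_minutes, algorithm, rmse, mae, mape, n_series, seed), `per_step`
#'   (data.frame: group, ph_minutes, algorithm, step, mae), and
#'   `cluster_models` (per group).
#' @export
run_benchmark <- function(sets,
                          algorithms = c("mtsc", "wmtsc", "holt",
                                         "gbt_global", "rf_cluster",
                                         "gbt_cluster"),
                          horizons_min = c(15L, 30L),
                          k_range = c(2L, 8L), k_fixed = NULL,
                          hyper = default_hyperparams(),
                          holt_grid = seq(0.1, 1, by = 0.1),
                          stability_reps = 0L,
                          per_series = FALSE,
                          seed = 1L) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  bad <- setdiff(algorithms, names(ALGORITHM_LABELS))
  if (length(bad)) {
    stop_glucluster(sprintf("unknown algorithms: %s",
                            paste(bad, collapse = ", ")), "config_error")
  }
  rows <- list(); curves <- list(); cmodels <- list()
  for (gi in seq_along(sets)) {
    group <- names(sets)[gi]
    set <- sets[[group]]
    train <- role_matrix(set, "train")
    test <- role_matrix(set, "test")
    if (nrow(train) < 3L || nrow(test) < 1L) {
      stop_glucluster(sprintf("group %s has too few train/test series", group),
                      "dependency_error")
    }
    kf <- if (!is.null(k_fixed)) k_fixed[[group]] else NULL
    cmodel <- fit_cluster_model(train, k_range = k_range, k = kf,
                                stability_reps = stability_reps,
                                seed = seed + 11L * gi)
    cmodels[[group]] <- cmodel
    L <- set$series_length
    for (mins in horizons_min) {
      h <- as.integer(mins / 5L)
      P <- L - h
      prefixes <- test[, seq_len(P), drop = FALSE]
      truth <- test[, (P + 1L):L, drop = FALSE]
      for (algo in algorithms) {
        algo_seed <- seed + 1000L * gi + 10L * h +
          match(algo, names(ALGORITHM_LABELS))
        pred <- switch(
          algo,
          mtsc = t(apply(prefixes, 1L, mtsc_forecast, model = cmodel, h = h)),
          wmtsc = t(apply(prefixes, 1L, wmtsc_forecast, model = cmodel, h = h)),
          holt = t(apply(prefixes, 1L, function(p) {
            par <- holt_fit(p, holt_grid, holt_grid)
            holt_forecast(p, par$alpha, par$beta, h)
          })),
          rf_cluster = predict_cluster_routed(
            fit_cluster_routed(train, cmodel, "random_forest", h,
                               hyper, algo_seed), prefixes),
          gbt_cluster = predict_cluster_routed(
            fit_cluster_routed(train, cmodel, "gradient_boosting", h,
                               hyper, algo_seed), prefixes),
          rf_global = predict_global(
            fit_global(train, "random_forest", h, hyper, algo_seed), prefixes),
          gbt_global = predict_global(
            fit_global(train, "gradient_boosting", h, hyper, algo_seed),
            prefixes))
        if (h == 1L) pred <- matrix(as.numeric(pred), ncol = 1L)
        m <- compute_metrics(truth, pred, per_series = per_series)
        rows[[length(rows) + 1L]] <- data.frame(
          group = group, ph_minutes = mins,
          algorithm = ALGORITHM_LABELS[[algo]], algo_key = algo,
          rmse = m$rmse, mae = m$mae, mape = m$mape,
          n_series = nrow(test), seed = seed)
        curves[[length(curves) + 1L]] <- data.frame(
          group = group, ph_minutes = mins,
          algorithm = ALGORITHM_LABELS[[algo]], algo_key = algo,
          step = seq_len(h), mae = per_step_mae(truth, pred))
      }
    }
  }
  structure(list(table = do.call(rbind, rows),
                 per_step = do.call(rbind, curves),
                 cluster_models = cmodels),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("Nocturnal glucose forecasting benchmark\n")
  for (group in unique(x$table$group)) {
    for (mins in unique(x$table$ph_minutes)) {
      sub <- x$table[x$table$group == group & x$table$ph_minutes == mins, ]
      if (!nrow(sub)) next
      cat(sprintf("\n%s, PH = %d min\n", group, mins))
      fmt <- function(v) {
        s <- sprintf("%.3f", v)
        s[which.min(v)] <- paste0("*", s[which.min(v)])
        format(s, width = 7, justify = "right")
      }
      out <- data.frame(Algorithm = format(sub$algorithm, width = 27),
                        RMSE = fmt(sub$rmse), MAE = fmt(sub$mae),
                        MAPE = fmt(sub$mape))
      print(out, row.names = FALSE)
    }
  }
  cat("\n(* = column minimum)\n")
  invisible(x)
}

#' Plot per-step MAE curves
#'
#' MAE against forecast-step index, one panel per (group, horizon), one line
#' per algorithm. Requires ggplot2.
#'
#' @param benchmark a [run_benchmark()] result.
#' @return A ggplot object.
#' @export
plot_per_step_mae <- function(benchmark) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_glucluster("ggplot2 is required for plotting", "dependency_error")
  }
  df <- benchmark$per_step
  df$panel <- sprintf("%s, PH %d min", df$group, df$ph_minutes)
  step <- mae <- algorithm <- NULL  # quiet R CMD check; aes() evaluates in df
  ggplot2::ggplot(df, ggplot2::aes(x = step, y = mae,
                                   colour = algorithm)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "forecast step (5 min each)", y = "MAE (mmol/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
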