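#' Nearest-medoid forecast (MTSC)
#'
#' Assigns the observed prefix to its nearest cluster medoid (Euclidean
#' distance on the first `72 - h` readings) and copies the medoid's next `h`
#' readings as the forecast.
#'
#' @param prefix numeric glucose vector of length `L - h`.
#' @param model a [fit_cluster_model()] result fitted on full-length series.
#' @param h forecast horizon in 5-min steps (3 = 15 min, 6 = 30 min).
#' @return Numeric forecast of length `h`.
#' @export
mtsc_forecast <- function(prefix, model, h) {
  L <- ncol(model$medoid_series)
  if (h >= L) stop_glucluster("horizon must be shorter than the series",
                              "range_error")
  P <- L - h
  if (length(prefix) != P) {
    stop_glucluster(sprintf("prefix must have length %d", P), "shape_error")
  }
  a <- assign_nearest_cluster(prefix, model, P)
  as.numeric(model$medoid_series[a$cluster, (P + 1L):L])
}

#' Softmax-weighted medoid forecast (WMTSC)
#'
#' Computes the distance vector d' from the prefix to every medoid prefix,
#' inverts it elementwise (d = 1/d'), turns d into weights with the softmax
#' (`w_i = exp(d_i) / sum_j exp(d_j)`), and returns the weighted sum of all
#' medoids' next-`h` readings. An exact prefix match (d' = 0, where 1/d' is
#' undefined) short-circuits to weight 1 on that medoid (uniform over all
#' exact matches); distances below `eps` count as exact.
#'
#' @inheritParams mtsc_forecast
#' @param eps zero-distance guard (default 1e-12).
#' @param details if `TRUE`, also return the distances and weights.
#' @return Numeric forecast of length `h`, or (with `details`) a list
#'   `forecast`, `distances`, `weights`, `nearest`.
#' @export
wmtsc_forecast <- function(prefix, model, h, eps = 1e-12, details = FALSE) {
  L <- ncol(model$medoid_series)
  if (h >= L) stop_glucluster("horizon must be shorter than the series",
                              "range_error")
  P <- L - h
  if (length(prefix) != P) {
    stop_glucluster(sprintf("prefix must have length %d", P), "shape_error")
  }
  a <- assign_nearest_cluster(prefix, model, P)
  dprime <- a$distances
  w <- wmtsc_weights(dprime, eps)
  cont <- model$medoid_series[, (P + 1L):L, drop = FALSE]
  fc <- as.numeric(crossprod(cont, w))
  if (!details) return(fc)
  list(forecast = fc, distances = dprime, weights = w, nearest = a$cluster)
}

#' Softmax-of-inverse-distance weights
#'
#' @param dprime nonnegative distance vector d'.
#' @param eps distances below this count as exact matches.
#' @return Weight vector: nonnegative, summing to 1.
#' @export
wmtsc_weights <- function(dprime, eps = 1e-12) {
  zero <- dprime <= eps
  if (any(zero)) {
    w <- as.numeric(zero) / sum(zero)
    return(w)
  }
  d <- 1 / dprime
  e <- exp(d - max(d))   # shift-invariant softmax, overflow-safe
  e / sum(e)
}

default_hyperparams <- function() {
  list(rf = list(ntree = 300L),
       gbt = list(nrounds = 300L, max_depth = 3L, eta = 0.1))
}

# One multi-output tree-ensemble learner: a separate forest / boosted model
# per forecast step, mapping the 72-h prefix to each of the h target steps.
fit_learner <- function(X, Y, learner_kind, hyper = default_hyperparams(),
                        seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L) stop_glucluster("empty training set", "model_error")
  models <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    if (learner_kind == "random_forest") {
      set.seed(seed + j)
      models[[j]] <- randomForest::randomForest(
        x = X, y = Y[, j], ntree = hyper$rf$ntree)
    } else if (learner_kind == "gradient_boosting") {
      models[[j]] <- xgboost::xgboost(
        X, Y[, j],
        objective = "reg:squarederror",
        nrounds = hyper$gbt$nrounds,
        max_depth = hyper$gbt$max_depth,
        learning_rate = hyper$gbt$eta,
        nthreads = 1L, seed = seed + j, verbosity = 0)
    } else {
      stop_glucluster(sprintf("unknown learner kind %s", learner_kind),
                      "config_error")
    }
  }
  structure(list(models = models, learner_kind = learner_kind,
                 n_features = ncol(X)),
            class = "step_learner")
}

predict_learner <- function(learner, X) {
  X <- as.matrix(X)
  if (ncol(X) != learner$n_features) {
    stop_glucluster("feature count mismatch", "shape_error")
  }
  out <- vapply(learner$models, function(m) as.numeric(stats::predict(m, X)),
                numeric(nrow(X)))
  matrix(out, nrow = nrow(X))
}

#' Fit one supervised model per cluster (cluster-routed ensemble)
#'
#' For each Ward cluster of the training panel, fits a multi-output tree
#' ensemble (random forest or gradient-boosted trees; one model per forecast
#' step) mapping the first `72 - h` readings of each member series to its
#' last `h` readings. Clusters smaller than `min_cluster_size` fall back to a
#' single global model of the same kind.
#'
#' @param train numeric training matrix (n x 72) — typically
#'   `role_matrix(set, "train")`.
#' @param cluster_model a [fit_cluster_model()] of the same rows.
#' @param learner_kind `"random_forest"` or `"gradient_boosting"`.
#' @param h forecast horizon in steps.
#' @param hyper hyperparameter list, see `default_hyperparams()`.
#' @param seed RNG seed (tree ensembles are seeded per step).
#' @param min_cluster_size clusters below this size use the fallback.
#' @return An object of class `cluster_routed_model`.
#' @export
fit_cluster_routed <- function(train, cluster_model, learner_kind, h,
                               hyper = default_hyperparams(), seed = 1L,
                               min_cluster_size = 10L) {
  train <- as.matrix(train)
  L <- ncol(train); P <- L - h
  stopifnot(length(cluster_model$labels) == nrow(train))
  X <- train[, seq_len(P), drop = FALSE]
  Y <- train[, (P + 1L):L, drop = FALSE]
  sizes <- tabulate(cluster_model$labels, cluster_model$k)
  fallback <- NULL
  if (any(sizes < min_cluster_size)) {
    fallback <- fit_learner(X, Y, learner_kind, hyper, seed)
  }
  learners <- vector("list", cluster_model$k)
  for (cl in seq_len(cluster_model$k)) {
    if (sizes[cl] == 0L) stop_glucluster("empty cluster", "model_error")
    if (sizes[cl] >= min_cluster_size) {
      rows <- cluster_model$labels == cl
      learners[[cl]] <- fit_learner(X[rows, , drop = FALSE],
                                    Y[rows, , drop = FALSE],
                                    learner_kind, hyper, seed + 100L * cl)
    }
  }
  structure(
    list(cluster_model = cluster_model, learners = learners,
         fallback = fallback, learner_kind = learner_kind, h = as.integer(h),
         prefix_length = P),
    class = "cluster_routed_model")
}

#' Forecast with a cluster-routed model
#'
#' Routes each prefix to its nearest medoid (on the first `72 - h` readings)
#' and applies that cluster's learner (or the recorded fallback).
#'
#' @param model a [fit_cluster_routed()] result.
#' @param prefixes numeric vector (one series) or matrix (rows = series) of
#'   length/width `72 - h`.
#' @return Forecast matrix (rows = series, h columns); a vector input gives
#'   a vector.
#' @export
predict_cluster_routed <- function(model, prefixes) {
  one <- is.null(dim(prefixes))
  X <- if (one) matrix(prefixes, 1L) else as.matrix(prefixes)
  if (ncol(X) != model$prefix_length) {
    stop_glucluster(sprintf("prefixes must have %d columns",
                            model$prefix_length), "shape_error")
  }
  routes <- apply(X, 1L, function(p)
    assign_nearest_cluster(p, model$cluster_model, model$prefix_length)$cluster)
  out <- matrix(NA_real_, nrow(X), model$h)
  for (cl in unique(routes)) {
    rows <- which(routes == cl)
    lrn <- model$learners[[cl]] %||% model$fallback
    out[rows, ] <- predict_learner(lrn, X[rows, , drop = FALSE])
  }
  if (one) as.numeric(out) else out
}

#' Fit one global supervised model on all training series
#'
#' Same feature/target construction as [fit_cluster_routed()] but a single
#' model over the whole training panel (the "without pre-clustering"
#' baseline).
#'
#' @inheritParams fit_cluster_routed
#' @return An object of class `global_forecast_model`.
#' @export
fit_global <- function(train, learner_kind, h,
                       hyper = default_hyperparams(), seed = 1L) {
  train <- as.matrix(train)
  L <- ncol(train); P <- L - h
  learner <- fit_learner(train[, seq_len(P), drop = FALSE],
                         train[, (P + 1L):L, drop = FALSE],
                         learner_kind, hyper, seed)
  structure(list(learner = learner, learner_kind = learner_kind,
                 h = as.integer(h), prefix_length = P),
            class = "global_forecast_model")
}

#' Forecast with a global model
#'
#' @param model a [fit_global()] result.
#' @param prefixes vector or matrix of prefixes.
#' @return Forecast matrix (or vector for a single series).
#' @export
predict_global <- function(model, prefixes) {
  one <- is.null(dim(prefixes))
  X <- if (one) matrix(prefixes, 1L) else as.matrix(prefixes)
  out <- predict_learner(model$learner, X)
  if (one) as.numeric(out) else out
}
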