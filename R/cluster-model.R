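#' Mean silhouette score of a labeled partition
#'
#' Mean over points of `(b - a) / max(a, b)` under Euclidean distance, where
#' `a` is the mean distance to the point's own cluster (excluding itself) and
#' `b` the smallest mean distance to any other cluster; members of singleton
#' clusters score 0. Computed via [cluster::silhouette()].
#'
#' @param series numeric matrix (rows = series) or a `dist` object.
#' @param labels integer cluster labels per row; at least 2 clusters.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(series, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop_glucluster("silhouette undefined for a single cluster",
                    "undefined_score_error")
  }
  d <- if (inherits(series, "dist")) series else stats::dist(series)
  if (length(labels) == length(unique(labels))) return(0)  # all singletons
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' Choose the number of clusters by the silhouette criterion
#'
#' Cuts one Ward linkage at every k in `k_range` and returns the k with the
#' highest mean silhouette (ties break to the smallest k), together with the
#' full per-k table for expert inspection.
#'
#' @param series numeric matrix of training series.
#' @param k_range integer interval `c(lo, hi)`, within `[2, n - 1]`.
#' @param history optional precomputed [ward_linkage()] of `series`.
#' @return List with `k` (chosen), `table` (data.frame k, silhouette) and
#'   `history` (the linkage used).
#' @export
select_num_clusters <- function(series, k_range = c(2L, 10L), history = NULL) {
  series <- as.matrix(series)
  n <- nrow(series)
  ks <- seq.int(max(2L, k_range[1]), min(n - 1L, k_range[2]))
  if (length(ks) == 0L) stop_glucluster("empty k range", "range_error")
  if (is.null(history)) history <- ward_linkage(series)
  d <- stats::dist(series)
  sil <- vapply(ks, function(k) silhouette_score(d, cut_to_k(history, k)),
                numeric(1))
  list(k = ks[which.max(sil)],
       table = data.frame(k = ks, silhouette = sil),
       history = history)
}

#' Medoid of each cluster
#'
#' Per cluster, the member series minimizing the sum of Euclidean distances
#' to all members of that cluster; ties break to the lowest row index.
#'
#' @param series numeric matrix of series.
#' @param labels cluster labels per row.
#' @return Integer vector of medoid row indices, one per cluster id 1..k.
#' @export
compute_medoids <- function(series, labels) {
  series <- as.matrix(series)
  labels <- as.integer(labels)
  d <- as.matrix(stats::dist(series))
  vapply(sort(unique(labels)), function(cl) {
    rows <- which(labels == cl)
    sums <- rowSums(d[rows, rows, drop = FALSE])
    rows[which.min(sums)]
  }, integer(1))
}

#' Fit the full cluster model of a training panel
#'
#' Runs [ward_linkage()], picks k by [select_num_clusters()] (unless fixed),
#' cuts, extracts medoids and records the silhouette; optionally runs
#' [stability_assessment()].
#'
#' @param series numeric training matrix (n x 72).
#' @param k_range silhouette search interval; ignored when `k` is given.
#' @param k optional fixed number of clusters.
#' @param stability_reps perturbation replicates for the stability score
#'   (0 skips the assessment).
#' @param stability_noise_sd perturbation sd, mmol/L.
#' @param seed seed for the stability assessment.
#' @return An object of class `cgm_cluster_model`: `k`, `labels`,
#'   `medoid_ids`, `medoid_series` (k x 72 matrix), `metric` ("euclidean"),
#'   `silhouette`, `silhouette_table`, `stability`.
#' @export
fit_cluster_model <- function(series, k_range = c(2L, 10L), k = NULL,
                              stability_reps = 0L, stability_noise_sd = 0.3,
                              seed = 1L) {
  series <- as.matrix(series)
  history <- ward_linkage(series)
  tab <- NULL
  if (is.null(k)) {
    sel <- select_num_clusters(series, k_range, history = history)
    k <- sel$k
    tab <- sel$table
  }
  labels <- cut_to_k(history, k)
  medoid_ids <- compute_medoids(series, labels)
  sil <- if (k >= 2L) silhouette_score(series, labels) else NA_real_
  stab <- if (stability_reps > 0L) {
    stability_assessment(series, k, n_reps = stability_reps,
                         noise_sd = stability_noise_sd, seed = seed)
  } else NA_real_
  structure(
    list(k = as.integer(k), labels = labels, medoid_ids = medoid_ids,
         medoid_series = series[medoid_ids, , drop = FALSE],
         metric = "euclidean", silhouette = sil, silhouette_table = tab,
         stability = stab, history = history),
    class = "cgm_cluster_model")
}

#' @export
print.cgm_cluster_model <- function(x, ...) {
  cat(sprintf("Ward cluster model: k = %d over %d series; silhouette %.3f%s\n",
              x$k, length(x$labels), x$silhouette,
              if (is.na(x$stability)) ""
              else sprintf("; stability %.3f", x$stability)))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Assign a (possibly truncated) series to its nearest medoid
#'
#' Euclidean distance between the prefix and the first `P` readings of each
#' medoid; the nearest cluster is the argmin (ties break to the lowest
#' cluster id).
#'
#' @param prefix numeric glucose vector of length `P <= 72`.
#' @param model a [fit_cluster_model()] result.
#' @param P prefix length (default `length(prefix)`).
#' @return List with `cluster` (id) and `distances` (vector d' over clusters).
#' @export
assign_nearest_cluster <- function(prefix, model, P = length(prefix)) {
  stopifnot(inherits(model, "cgm_cluster_model"))
  if (P > ncol(model$medoid_series)) {
    stop_glucluster("prefix longer than the medoid series", "range_error")
  }
  med <- model$medoid_series[, seq_len(P), drop = FALSE]
  d <- sqrt(rowSums((med - matrix(prefix[seq_len(P)], nrow(med), P,
                                  byrow = TRUE))^2))
  list(cluster = which.min(d), distances = as.numeric(d))
}

#' Noise-perturbation stability of a Ward partition
#'
#' Reclusters `n_reps` independently perturbed copies of the data (iid
#' `N(0, noise_sd)` added to every reading), cuts each at the same k, and
#' averages the adjusted Rand index against the unperturbed partition. A
#' score near 1 means the k-cluster structure survives measurement-scale
#' noise; near 0 means it is an artifact of the particular sample.
#'
#' @param series numeric matrix.
#' @param k number of clusters.
#' @param n_reps perturbation replicates (default 100).
#' @param noise_sd perturbation sd in mmol/L (default 0.3).
#' @param seed RNG seed.
#' @return Mean adjusted Rand index in \[0, 1\] (negative ARIs are possible
#'   in principle but indicate no structure).
#' @export
stability_assessment <- function(series, k, n_reps = 100L, noise_sd = 0.3,
                                 seed = 1L) {
  series <- as.matrix(series)
  if (n_reps < 1L) stop_glucluster("n_reps must be >= 1", "config_error")
  base <- cut_to_k(ward_linkage(series), k)
  set.seed(seed)
  ari <- vapply(seq_len(n_reps), function(r) {
    pert <- series + stats::rnorm(length(series), 0, noise_sd)
    mclust::adjustedRandIndex(base, cut_to_k(ward_linkage(pert), k))
  }, numeric(1))
  mean(ari)
}

#' Persist a cluster model as JSON plus a medoid-matrix CSV
#'
#' @param model a `cgm_cluster_model`.
#' @param json_path output JSON path (k, labels, medoid ids, silhouette,
#'   stability).
#' @param medoids_path output CSV of the k x 72 medoid matrix.
#' @return Invisibly, the two paths.
#' @export
write_cluster_model <- function(model, json_path, medoids_path) {
  stopifnot(inherits(model, "cgm_cluster_model"))
  jsonlite::write_json(
    list(k = model$k, metric = model$metric, labels = model$labels,
         medoid_ids = model$medoid_ids, silhouette = model$silhouette,
         stability = model$stability),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  med <- as.data.frame(model$medoid_series)
  names(med) <- sprintf("g%02d", seq_len(ncol(model$medoid_series)) - 1L)
  utils::write.csv(cbind(cluster = seq_len(model$k), med), medoids_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(json_path, medoids_path))
}
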