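# Independent brute-force oracles and toy fixtures used across test files.

# total within-cluster sum of squared deviations from the mean
sse_of <- function(series, rows) {
  m <- colMeans(series[rows, , drop = FALSE])
  sum(sweep(series[rows, , drop = FALSE], 2, m)^2)
}

# Greedy Ward oracle: at every step evaluates the SSE increase of every
# candidate pair directly from the definition (no recurrence). Ties break to
# the earliest-created pair, leaves in row order. Returns one record per
# merge: the two member sets (ordered by smallest member) and the cost.
brute_ward <- function(series) {
  series <- as.matrix(series)
  n <- nrow(series)
  clusters <- as.list(seq_len(n))
  created <- seq_len(n)
  next_id <- n
  steps <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        cost <- sse_of(series, c(clusters[[a]], clusters[[b]])) -
          sse_of(series, clusters[[a]]) - sse_of(series, clusters[[b]])
        key <- sort(c(created[a], created[b]))
        better <- is.null(best) || cost < best$cost - 1e-12 ||
          (cost <= best$cost + 1e-12 &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))
        if (better) best <- list(a = a, b = b, cost = cost, key = key)
      }
    }
    A <- sort(clusters[[best$a]]); B <- sort(clusters[[best$b]])
    steps[[s]] <- if (min(A) < min(B)) list(a = A, b = B, cost = best$cost)
                  else list(a = B, b = A, cost = best$cost)
    next_id <- next_id + 1L
    clusters[[best$a]] <- c(A, B)
    created[best$a] <- next_id
    clusters[[best$b]] <- NULL
    created <- created[-best$b]
  }
  steps
}

# ward_linkage() output in the same canonical per-merge representation
linkage_steps <- function(lk) {
  members <- vector("list", nrow(lk$merge))
  out <- vector("list", nrow(lk$merge))
  for (s in seq_len(nrow(lk$merge))) {
    get <- function(id) if (id < 0) -id else members[[id]]
    A <- sort(get(lk$merge[s, 1])); B <- sort(get(lk$merge[s, 2]))
    members[[s]] <- sort(c(A, B))
    out[[s]] <- if (min(A) < min(B)) list(a = A, b = B, cost = lk$cost[s])
                else list(a = B, b = A, cost = lk$cost[s])
  }
  out
}

# exhaustive medoid argmin over full Euclidean distance sums
brute_medoids <- function(series, labels) {
  series <- as.matrix(series)
  vapply(sort(unique(labels)), function(cl) {
    rows <- which(labels == cl)
    sums <- vapply(rows, function(r) {
      sum(vapply(rows, function(q) sqrt(sum((series[r, ] - series[q, ])^2)),
                 numeric(1)))
    }, numeric(1))
    rows[which.min(sums)]
  }, integer(1))
}

# hand-built cluster model around given medoid rows (for forecaster tests)
toy_cluster_model <- function(medoid_series) {
  medoid_series <- as.matrix(medoid_series)
  k <- nrow(medoid_series)
  structure(
    list(k = k, labels = seq_len(k), medoid_ids = seq_len(k),
         medoid_series = medoid_series, metric = "euclidean",
         silhouette = NA_real_, silhouette_table = NULL,
         stability = NA_real_, history = NULL),
    class = "cgm_cluster_model")
}

# raw segment with missing readings at the given (1-based) indices
gap_segment <- function(missing_at = integer(0), base = 6, n = 72,
                        patient = "P0001", night = 1L) {
  mask <- rep(FALSE, n)
  mask[missing_at] <- TRUE
  vals <- base + 0.01 * seq_len(n)
  nocturnal_segment(vals, mask, patient_id = patient, night_index = night)
}

# the programmed-gap fixture cohort: 40 segments with hand-known outcomes
# (see test-preprocess.R / acceptance): per block of 8 ->
# complete, 1-gap, 2-gap, 3-gap, 8 scattered, boundary gap, complete, 1-gap
programmed_gap_cohort <- function() {
  patterns <- list(
    integer(0), 10L, c(20L, 21L), c(30L, 31L, 32L),
    c(5L, 9L, 13L, 21L, 33L, 45L, 57L, 69L), 1L,
    integer(0), 40L)
  segs <- list()
  for (block in 1:5) {
    for (p in seq_along(patterns)) {
      segs[[length(segs) + 1L]] <- gap_segment(
        patterns[[p]], base = 5 + 0.1 * block,
        patient = sprintf("P%02d%02d", block, p))
    }
  }
  segs
}
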