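#' Agglomerative Ward linkage of time-series rows
#'
#' Greedy agglomeration in which each step merges the pair of clusters whose
#' union gives the minimum increase in total within-cluster sum of squared
#' Euclidean deviations from cluster means. Implemented with the
#' Lance-Williams recurrence on the Ward merge cost
#' `d(A,B) = |A||B|/(|A|+|B|) * ||mean(A) - mean(B)||^2`
#' (for singletons, half the squared Euclidean distance), which equals that
#' variance increase exactly. Ties break to the pair whose clusters were
#' created earliest (leaves in row order, then merge order), making the
#' sequence fully deterministic.
#'
#' @param series numeric matrix, one series per row; no missing values.
#' @return An object of class `ward_linkage`: `merge` (hclust-convention
#'   (n-1) x 2 matrix: negative entries are leaves, positive entries earlier
#'   merges), `cost` (the nondecreasing variance increase of each merge) and
#'   `n_leaves`. Convert with [as.hclust.ward_linkage()] to plot dendrograms.
#' @export
ward_linkage <- function(series) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 2L) stop_glucluster("need at least 2 series", "size_error")
  if (anyNA(series)) stop_glucluster("series contain missing values",
                                     "precondition_error")
  # Ward merge cost between singletons: ||x - y||^2 / 2
  d <- as.matrix(stats::dist(series))^2 / 2
  diag(d) <- Inf

  active <- rep(TRUE, n)          # slot i alive?
  size <- rep(1L, n)
  node <- -seq_len(n)             # hclust id of the cluster in slot i
  created <- seq_len(n)           # creation order, for the tie rule
  merge <- matrix(0L, n - 1L, 2L)
  cost <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    dm <- d
    dm[!active, ] <- Inf
    dm[, !active] <- Inf
    best <- min(dm)
    cand <- which(dm == best, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # earliest-created pair, first by the earlier member then the later one
    ord <- order(pmin(created[cand[, 1]], created[cand[, 2]]),
                 pmax(created[cand[, 1]], created[cand[, 2]]))
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    if (created[i] > created[j]) { tmp <- i; i <- j; j <- tmp }

    merge[step, ] <- c(node[i], node[j])
    cost[step] <- best

    # Lance-Williams update for the Ward cost of the union (kept in slot i)
    k <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(k)) {
      ni <- size[i]; nj <- size[j]; nk <- size[k]
      newd <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * best) /
        (ni + nj + nk)
      d[i, k] <- newd; d[k, i] <- newd
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    node[i] <- step
    created[i] <- n + step
  }
  structure(list(merge = merge, cost = cost, n_leaves = n),
            class = "ward_linkage")
}

#' @export
print.ward_linkage <- function(x, ...) {
  cat(sprintf("Ward linkage of %d series (%d merges, cost %.4g .. %.4g)\n",
              x$n_leaves, nrow(x$merge), x$cost[1], x$cost[length(x$cost)]))
  invisible(x)
}

#' Convert a Ward linkage to a base-R `hclust` object
#'
#' Heights are the Ward merge costs (within-cluster variance increases); use
#' `sqrt(2 * height)` to match `stats::hclust(method = "ward.D2")` heights.
#'
#' @param x a [ward_linkage()].
#' @param ... unused.
#' @return An `hclust` object suitable for `plot()` or `stats::cutree()`.
#' @export
as.hclust.ward_linkage <- function(x, ...) {
  # dendrogram plotting needs a leaf order without crossings
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(x$merge[id, 1]), expand(x$merge[id, 2]))
  }
  structure(
    list(merge = x$merge, height = x$cost,
         order = expand(nrow(x$merge)),
         labels = NULL, method = "ward", dist.method = "euclidean",
         call = match.call()),
    class = "hclust")
}

#' Cut a Ward linkage into k clusters
#'
#' Undoes the last `k - 1` merges; labels are renumbered 1..k in order of
#' first occurrence along the leaf (row) order.
#'
#' @param history a [ward_linkage()].
#' @param k number of clusters, in `[1, n_leaves]`.
#' @return Integer vector of cluster labels, one per input row.
#' @export
cut_to_k <- function(history, k) {
  stopifnot(inherits(history, "ward_linkage"))
  n <- history$n_leaves
  if (k < 1L || k > n) stop_glucluster("k out of [1, n_leaves]", "range_error")
  lab <- seq_len(n)
  if (n - k >= 1L) {
    members <- vector("list", n - k)   # leaf sets of applied merges
    for (step in seq_len(n - k)) {
      get_members <- function(id) if (id < 0) -id else members[[id]]
      m <- c(get_members(history$merge[step, 1]),
             get_members(history$merge[step, 2]))
      members[[step]] <- m
      lab[m] <- min(lab[m])
    }
  }
  as.integer(factor(lab, levels = unique(lab)))
}
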