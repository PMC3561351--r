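#' Lloyd k-means clustering with seeded restarts
#'
#' Plain Lloyd iteration: each observation is assigned to the cluster with
#' the nearest mean (squared Euclidean distance, ties broken toward the
#' lower cluster id), means are recomputed, and iteration stops when the
#' assignments no longer change.  Each restart initializes the means at k
#' distinct data points sampled with the restart's seed; the best restart
#' by objective is returned.  A cluster emptied during iteration is
#' re-seeded at the point farthest from its current mean.
#'
#' @param points numeric vector (1-D) or matrix (rows = observations)
#' @param k number of clusters, `1 <= k <=` number of distinct points
#' @param seed integer seed
#' @param restarts number of seeded initializations (default 50; 1
#'   reproduces a single random initialization)
#' @param max_iter safety cap on Lloyd iterations per restart
#' @return a `kmeans_fit` list: `assignment` (cluster id per observation),
#'   `centers`, `objective` (sum of squared distances to assigned means),
#'   `iterations`, `seed`, `restarts`
#' @export
kmeans_cluster <- function(points, k, seed = 1L, restarts = 50L,
                           max_iter = 200L) {
  X <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 1)
  if (any(!is.finite(X))) stopf("points contain non-finite values")
  n <- nrow(X)
  n_distinct <- nrow(unique(X))
  if (k < 1 || k != round(k)) stopf("k must be a positive integer")
  if (k > n_distinct) stopf("k = %d exceeds the %d distinct points", k, n_distinct)
  seeds <- child_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- lloyd_once(X, k, seeds[r], max_iter)
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  best$seed <- seed
  best$restarts <- restarts
  class(best) <- "kmeans_fit"
  best
}

lloyd_once <- function(X, k, run_seed, max_iter) {
  n <- nrow(X)
  centers <- with_seed(run_seed, {
    ux <- unique(X)
    ux[sample.int(nrow(ux), k), , drop = FALSE]
  })
  assign_old <- rep(0L, n)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    D2 <- sqdist(X, centers)
    assignment <- max.col(-D2, ties.method = "first")
    # re-seed empty clusters at the globally worst-fitted point
    for (c in seq_len(k)) {
      if (!any(assignment == c)) {
        d_assigned <- D2[cbind(seq_len(n), assignment)]
        far <- which.max(d_assigned)
        assignment[far] <- c
      }
    }
    if (identical(assignment, assign_old) || iters >= max_iter) {
      obj <- sum(sqdist(X, centers)[cbind(seq_len(n), assignment)])
      return(list(assignment = assignment, centers = centers,
                  objective = obj, iterations = iters))
    }
    assign_old <- assignment
    for (c in seq_len(k)) {
      centers[c, ] <- colMeans(X[assignment == c, , drop = FALSE])
    }
  }
}

# n x k matrix of squared Euclidean distances
sqdist <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  outer(xx, cc, "+") - 2 * X %*% t(C)
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat(sprintf("kmeans_fit: k = %d, objective = %.6g, %d iterations\n",
              nrow(x$centers), x$objective, x$iterations))
  invisible(x)
}

#' Classification accuracy rate of a clustering against true groups
#'
#' `100 * max over cluster-to-group bijections of the matched fraction`:
#' since cluster ids from a random initialization are arbitrary, the
#' overlap `sum_i |cluster_i intersect group_i|` is maximized over all
#' bijections between cluster and group labels (exact enumeration; the
#' number of groups is small).  100 means the labelings are identical up
#' to renaming.
#'
#' @param true_groups,est_clusters label vectors over the same
#'   observations, with the same number of distinct labels
#' @return accuracy percentage in `[0, 100]`
#' @examples
#' accuracy_rate(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 100: labels swapped
#' @export
accuracy_rate <- function(true_groups, est_clusters) {
  if (length(true_groups) != length(est_clusters)) {
    stopf("labelings must cover the same observations")
  }
  tg <- as.integer(factor(true_groups))
  ec <- as.integer(factor(est_clusters))
  k <- max(max(tg), max(ec))
  if (k > 8) stopf("more than 8 classes not supported")
  counts <- table(factor(ec, levels = 1:k), factor(tg, levels = 1:k))
  perms <- all_perms(k)
  overlaps <- apply(perms, 1, function(p) sum(counts[cbind(1:k, p)]))
  100 * max(overlaps) / length(tg)
}
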