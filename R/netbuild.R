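#' Build a phase-synchrony weighted functional network
#'
#' Entry (i, j) is the time-averaged phase-synchrony degree of regions i
#' and j ([ps_degree()]); the diagonal is zero (self-synchrony is not
#' considered).  Phases of all regions are extracted once, so the full
#' R x R matrix is computed in one vectorized pass.
#'
#' @param subject a `subject_ts` from [generate_subject()] or
#'   [read_subject_tsv()], or a plain numeric matrix (rows = regions)
#' @param trim,detrend passed to the phase machinery (see [ps_degree()])
#' @return a symmetric R x R `weighted_network` matrix with entries in
#'   `[0, 1]`, zero diagonal, attribute `method = "ps"`
#' @export
build_ps_network <- function(subject, trim = 0.05, detrend = TRUE) {
  X <- subject_matrix(subject)
  R <- nrow(X)
  phases <- matrix(0, R, ncol(X))
  for (i in seq_len(R)) {
    phases[i, ] <- tryCatch(
      as.numeric(analytic_phase(X[i, ], detrend = detrend)),
      error = function(e) stopf("region %d: %s", i, conditionMessage(e))
    )
  }
  idx <- trim_index(ncol(X), trim)
  E <- exp(1i * phases[, idx, drop = FALSE])
  W <- Mod(E %*% Conj(t(E))) / length(idx)
  W <- pmin(pmax(W, 0), 1)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  weighted_network(W, method = "ps")
}

#' Build a Pearson-correlation weighted functional network
#'
#' The conventional comparator: entry (i, j) is the Pearson correlation of
#' the two regional series (raw signed value by default; `absolute = TRUE`
#' takes `|r|`).  Diagonal is zero.
#'
#' @inheritParams build_ps_network
#' @param absolute use `|r|` instead of signed r
#' @return a `weighted_network` with attribute `method = "pearson"`
#' @export
build_pearson_network <- function(subject, absolute = FALSE) {
  X <- subject_matrix(subject)
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) stopf("region %d has zero variance", which(sds == 0)[1])
  W <- cor(t(X))
  if (absolute) W <- abs(W)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  weighted_network(W, method = "pearson")
}

subject_matrix <- function(subject) {
  X <- if (inherits(subject, "subject_ts")) subject$data else subject
  if (!is.matrix(X) || !is.numeric(X)) stopf("subject data must be a numeric matrix")
  if (nrow(X) < 2) stopf("need at least 2 regions")
  if (any(!is.finite(X))) stopf("subject data contain non-finite values")
  X
}

weighted_network <- function(W, method) {
  structure(W, method = method, class = c("weighted_network", class(W)))
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf(
    "weighted_network (%s): %d regions, weights in [%.3f, %.3f]\n",
    attr(x, "method"), nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])
  ))
  invisible(x)
}

#' Binarize a weighted network at a threshold
#'
#' Edge (i, j) is kept iff `weight > T` (strict, so a threshold at the
#' maximum weight yields an empty network; the bigger the threshold, the
#' sparser the matrix).
#'
#' @param W weighted network matrix
#' @param threshold value in (0, 1)
#' @return binary adjacency matrix (0/1), zero diagonal, attribute
#'   `threshold`
#' @export
binarize <- function(W, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stopf("threshold must be a single value in (0, 1)")
  }
  check_square_symmetric(unclass(W), "weighted network")
  A <- (unclass(W) > threshold) * 1
  diag(A) <- 0
  structure(A, threshold = threshold)
}

#' Cost (edge density) of a binary network
#'
#' Number of edges divided by the number of node pairs `R(R-1)/2`.
#'
#' @param A binary adjacency matrix
#' @return value in `[0, 1]`
#' @export
network_cost <- function(A) {
  A <- unclass(A); check_binary(A)
  R <- nrow(A)
  if (R < 2) stopf("need at least 2 nodes")
  sum(A[upper.tri(A)]) / (R * (R - 1) / 2)
}

#' Mean clustering coefficient of a binary network
#'
#' Watts-Strogatz node average of closed-triangle fraction among each
#' node's neighbour pairs; nodes with degree < 2 contribute 0 and stay in
#' the average.
#'
#' @inheritParams network_cost
#' @return value in `[0, 1]`
#' @export
clustering_coefficient <- function(A) {
  A <- unclass(A); check_binary(A)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)          # 2 * triangles at each node
  ci <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  mean(ci)
}

#' Global efficiency of a binary network
#'
#' Mean over unordered node pairs of the inverse shortest-path length,
#' with disconnected pairs contributing 0 (Latora-Marchiori convention),
#' so very sparse and even empty networks remain well defined.
#'
#' @inheritParams network_cost
#' @return value in `[0, 1]`
#' @export
global_efficiency <- function(A) {
  A <- unclass(A); check_binary(A)
  R <- nrow(A)
  if (R < 2) stopf("need at least 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(g)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv[upper.tri(inv)]) / (R * (R - 1) / 2)
}

#' Local efficiency of a binary network
#'
#' Mean over nodes of the global efficiency of the subgraph induced by the
#' node's neighbours (0 for nodes with fewer than 2 neighbours).
#'
#' @inheritParams network_cost
#' @return value in `[0, 1]`
#' @export
local_efficiency <- function(A) {
  A <- unclass(A); check_binary(A)
  vals <- vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}
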