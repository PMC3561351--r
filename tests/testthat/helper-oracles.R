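# Independent brute-force oracles used across the suite.  These are written
# naively (triple loops, exhaustive enumeration) on purpose: they must not
# share code paths with the package implementation they check.

bf_cost <- function(A) {
  n <- nrow(A); e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) e <- e + A[i, j]
  e / (n * (n - 1) / 2)
}

bf_clustering <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in 1:n) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    closed <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && A[nb[a], nb[b]] == 1) closed <- closed + 1
    }
    vals[i] <- closed / choose(length(nb), 2)
  }
  mean(vals)
}

bf_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

bf_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- bf_shortest_paths(A)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  }
  tot / (n * (n - 1) / 2)
}

bf_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in 1:n) {
    nb <- which(A[i, ] == 1)
    if (length(nb) >= 2) vals[i] <- bf_global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

bf_modularity <- function(A, memb) {
  L <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (s in unique(memb)) {
    idx <- which(memb == s)
    l_s <- sum(A[idx, idx]) / 2
    d_s <- sum(deg[idx])
    q <- q + l_s / L - (d_s / (2 * L))^2
  }
  q
}

# all set partitions of n elements as restricted-growth strings
set_partitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(maxid + 1L)) rec(c(prefix, c), max(maxid, c))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive-search maximum modularity over every partition (n <= 8)
exhaustive_best_Q <- function(A) {
  best <- -Inf
  for (p in set_partitions(nrow(A))) {
    q <- bf_modularity(A, p)
    if (q > best) best <- q
  }
  best
}

is_connected_bf <- function(A) {
  all(is.finite(bf_shortest_paths(A)))
}

random_graph <- function(n, p, seed, connected = FALSE) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < p) A[i, j] <- A[j, i] <- 1
    }
    if (!connected || (sum(A) > 0 && is_connected_bf(A))) return(A)
  }
}

# small deterministic cohort specs reused across tests ---------------------

# planted matching on 16 regions, independent base drivers, replacement
# coupling with quadrature lag: strong phase-only "additional network"
planted_spec_replace <- function() {
  cohort_spec(
    n_regions = 16, n_samples = 256, sampling_interval = 2,
    n_base_groups = 16,           # every region its own driver
    base_coupling = 0,
    additional_edges = rbind(c(1, 9), c(2, 10), c(3, 11), c(4, 12)),
    additional_coupling = 0.15, additional_mode = "replace",
    noise_sd = 0.1, seed = 1L
  )
}

# same planted matching, superposed on the base signals
planted_spec_superpose <- function() {
  cohort_spec(
    n_regions = 16, n_samples = 256, sampling_interval = 2,
    n_base_groups = 16, base_coupling = 0,
    additional_edges = rbind(c(1, 9), c(2, 10), c(3, 11), c(4, 12)),
    additional_coupling = 0.15, additional_mode = "superpose",
    noise_sd = 0.1, seed = 1L
  )
}

# exchangeable world: no planted edges, independent drivers
null_spec <- function(n_regions = 16, n_samples = 256) {
  cohort_spec(
    n_regions = n_regions, n_samples = n_samples, sampling_interval = 2,
    n_base_groups = n_regions, base_coupling = 0,
    additional_edges = NULL, noise_sd = 0.1, seed = 1L
  )
}

truth_keys <- function(edges) {
  paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]), sep = "-")
}

matrix_edge_keys <- function(D) {
  idx <- which(upper.tri(D) & D == 1, arr.ind = TRUE)
  paste(idx[, 1], idx[, 2], sep = "-")
}
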