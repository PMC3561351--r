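#' Modularity of a partition of a binary network
#'
#' `Q = sum_s (l_s/L - (d_s/(2L))^2)` where `L` is the total number of
#' edges, `l_s` the number of edges with both endpoints inside community
#' `s`, and `d_s` the sum of degrees of the nodes of `s` (Newman-Girvan).
#' `variant = "edge"` replaces the expectation term with the literal
#' fraction of edges having one or both endpoints inside `s`:
#' `Q = sum_s (l_s/L - ((d_s - l_s)/L)^2)`.
#'
#' The whole graph as one community gives Q = 0; Q is always < 1.
#'
#' @param A binary adjacency matrix with at least one edge
#' @param membership integer community id per node (ids need not be
#'   contiguous)
#' @param variant `"degree"` (default, Newman-Girvan) or `"edge"`
#' @return modularity Q
#' @export
network_modularity <- function(A, membership, variant = c("degree", "edge")) {
  variant <- match.arg(variant)
  A <- unclass(A); check_binary(A)
  n <- nrow(A)
  if (length(membership) != n) stopf("membership must have one id per node")
  deg <- rowSums(A)
  L <- sum(deg) / 2
  if (L == 0) stopf("modularity undefined for an edgeless network")
  Q <- 0
  for (s in unique(membership)) {
    inside <- membership == s
    l_s <- sum(A[inside, inside, drop = FALSE]) / 2
    d_s <- sum(deg[inside])
    Q <- Q + if (variant == "degree") {
      l_s / L - (d_s / (2 * L))^2
    } else {
      l_s / L - ((d_s - l_s) / L)^2
    }
  }
  Q
}

#' Detect communities by seeded modularity maximization
#'
#' Greedy agglomerative merging from singletons (always merging the pair
#' of connected communities with the largest modularity gain, seeded
#' random tie-breaking), recording the best partition at every community
#' count; each recorded partition is then refined by local node moves that
#' keep the community count fixed.  Multiple seeded restarts are pooled,
#' and the partition with the overall maximum Q is returned together with
#' the Q-versus-number-of-communities curve.
#'
#' Isolated (degree-0) nodes are excluded from the optimization and
#' reported in a sentinel community `0`.
#'
#' @param A binary adjacency matrix with at least one edge
#' @param seed integer seed controlling tie-breaks and restarts
#' @param restarts number of seeded agglomerative runs pooled (default 8)
#' @param refine apply local node-move refinement to every recorded
#'   partition (default `TRUE`)
#' @param variant modularity variant, see [network_modularity()]
#' @return a `community_fit` list: `membership` (contiguous ids 1..k for
#'   non-isolated nodes, 0 for isolated ones), `k`, `Q`, `curve` (data
#'   frame of `k` and best `Q` found with exactly `k` communities),
#'   `isolated` (indices), `seed`
#' @export
detect_communities <- function(A, seed = 1L, restarts = 8L, refine = TRUE,
                               variant = c("degree", "edge")) {
  variant <- match.arg(variant)
  A <- unclass(A); check_binary(A)
  deg <- rowSums(A)
  if (sum(deg) == 0) stopf("cannot detect communities in an edgeless network")
  active <- which(deg > 0)
  S <- A[active, active, drop = FALSE]
  n <- length(active)

  best_by_k <- list()   # k -> list(Q, membership)
  consider <- function(memb) {
    memb <- match(memb, unique(memb))
    k <- max(memb)
    q <- network_modularity(S, memb, variant = variant)
    cur <- best_by_k[[as.character(k)]]
    if (is.null(cur) || q > cur$Q + 1e-12) {
      best_by_k[[as.character(k)]] <<- list(Q = q, membership = memb)
    }
  }

  run_seeds <- child_seeds(seed, restarts)
  for (r in seq_len(restarts)) {
    for (memb in agglomerate(S, run_seeds[r])) consider(memb)
  }
  if (refine) {
    for (key in names(best_by_k)) {
      memb <- refine_moves(S, best_by_k[[key]]$membership, variant = variant)
      consider(memb)
    }
  }

  ks <- sort(as.integer(names(best_by_k)))
  curve <- data.frame(
    k = ks,
    Q = vapply(as.character(ks), function(key) best_by_k[[key]]$Q, numeric(1))
  )
  top <- which.max(curve$Q)
  pick <- best_by_k[[as.character(curve$k[top])]]

  membership <- integer(nrow(A))
  membership[active] <- pick$membership
  res <- list(
    membership = membership, k = curve$k[top], Q = pick$Q,
    curve = curve, isolated = which(deg == 0), seed = seed
  )
  class(res) <- "community_fit"
  res
}

#' @export
print.community_fit <- function(x, ...) {
  cat(sprintf("community_fit: k = %d communities, Q = %.4f (%d isolated nodes)\n",
              x$k, x$Q, length(x$isolated)))
  invisible(x)
}

# one greedy agglomerative pass; returns list of memberships, one per k
agglomerate <- function(S, run_seed) {
  n <- nrow(S)
  deg <- rowSums(S)
  L <- sum(deg) / 2
  memb <- seq_len(n)
  # community-level half-edge fractions e[s,t] and degree fractions a[s]
  e <- S / (2 * L)
  a <- deg / (2 * L)
  alive <- rep(TRUE, n)
  snapshots <- vector("list", n)
  snapshots[[n]] <- memb
  with_seed(run_seed, {
    for (step in seq_len(n - 1)) {
      ids <- which(alive)
      # modularity gain of merging s,t: 2 * (e[s,t] - a[s] a[t])
      gain <- 2 * (e[ids, ids, drop = FALSE] -
                     outer(a[ids], a[ids]))
      diag(gain) <- -Inf
      conn <- e[ids, ids, drop = FALSE] > 0
      diag(conn) <- FALSE
      if (any(conn)) gain[!conn] <- -Inf
      mx <- max(gain)
      cand <- which(gain == mx, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      if (nrow(cand) == 0) cand <- which(gain == mx, arr.ind = TRUE)[1, , drop = FALSE]
      pickrow <- cand[sample.int(nrow(cand), 1), ]
      s <- ids[pickrow[1]]; t <- ids[pickrow[2]]
      # merge t into s
      e[s, ] <- e[s, ] + e[t, ]
      e[, s] <- e[, s] + e[, t]
      a[s] <- a[s] + a[t]
      alive[t] <- FALSE
      memb[memb == memb[t]] <- memb[s]
      snapshots[[n - step]] <- memb
    }
  })
  snapshots[!vapply(snapshots, is.null, logical(1))]
}

# local node-move refinement at fixed community count
refine_moves <- function(S, memb, variant = "degree", max_pass = 50) {
  n <- nrow(S)
  deg <- rowSums(S)
  L <- sum(deg) / 2
  k <- max(memb)
  if (k == 1) return(memb)
  size <- tabulate(memb, k)
  d_c <- group_sums(deg, memb, k)
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      s <- memb[i]
      if (size[s] == 1) next   # keep k fixed
      l_ic <- group_sums(S[i, ], memb, k)
      if (variant == "degree") {
        dQ <- (l_ic - l_ic[s]) / L -
          deg[i] * (d_c - d_c[s] + deg[i]) / (2 * L^2)
      } else {
        base <- edge_variant_Q(S, memb, L, deg)
        dQ <- vapply(seq_len(k), function(c) {
          if (c == s) return(0)
          m2 <- memb; m2[i] <- c
          edge_variant_Q(S, m2, L, deg) - base
        }, numeric(1))
      }
      dQ[s] <- 0
      t <- which.max(dQ)
      if (dQ[t] > 1e-12) {
        memb[i] <- t
        size[s] <- size[s] - 1; size[t] <- size[t] + 1
        d_c[s] <- d_c[s] - deg[i]; d_c[t] <- d_c[t] + deg[i]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

# sum x over groups g, returning a length-k vector (zero for empty groups)
group_sums <- function(x, g, k) {
  out <- numeric(k)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

edge_variant_Q <- function(S, memb, L, deg) {
  Q <- 0
  for (s in unique(memb)) {
    inside <- memb == s
    l_s <- sum(S[inside, inside, drop = FALSE]) / 2
    d_s <- sum(deg[inside])
    Q <- Q + l_s / L - ((d_s - l_s) / L)^2
  }
  Q
}
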