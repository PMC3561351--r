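two_triangles <- function() {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 3] <- A[1, 3] <- 1
  A[4, 5] <- A[5, 6] <- A[4, 6] <- 1
  A + t(A)
}

triangle_ring <- function() {
  # four triangles joined into a ring by single edges
  A <- matrix(0, 12, 12)
  tris <- list(1:3, 4:6, 7:9, 10:12)
  for (tr in tris) {
    A[tr[1], tr[2]] <- A[tr[2], tr[3]] <- A[tr[1], tr[3]] <- 1
  }
  A[3, 4] <- A[6, 7] <- A[9, 10] <- A[12, 1] <- 1
  A + t(A)
}

test_that("network_modularity matches the formula", {
  A <- two_triangles()
  expect_equal(network_modularity(A, rep(1, 6)), 0)
  expect_equal(network_modularity(A, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(network_modularity(A, rep(1, 6), variant = "edge"), 0)
  # bounds on random partitions of random graphs
  set.seed(41)
  for (rep in 1:10) {
    G <- random_graph(7, 0.5, seed = 300 + rep, connected = TRUE)
    memb <- sample(1:3, 7, replace = TRUE)
    q <- network_modularity(G, memb)
    expect_lt(q, 1); expect_gte(q, -1)
    expect_equal(q, bf_modularity(G, memb))
  }
  expect_error(network_modularity(matrix(0, 3, 3), c(1, 1, 2)), "edgeless")
})

test_that("detect_communities recovers planted structures", {
  # two disjoint 4-cliques
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  fit <- detect_communities(A, seed = 5)
  expect_equal(fit$k, 2)
  expect_equal(fit$Q, 0.5)
  expect_length(unique(fit$membership[1:4]), 1)
  expect_length(unique(fit$membership[5:8]), 1)
  # complete graph: no partition beats the single community
  K <- 1 - diag(6)
  fitK <- detect_communities(K, seed = 5)
  expect_equal(fitK$k, 1)
  expect_equal(fitK$Q, 0)
  # ring of triangles: the triangles are the communities
  R <- triangle_ring()
  fitR <- detect_communities(R, seed = 5)
  expect_equal(fitR$k, 4)
  for (tr in list(1:3, 4:6, 7:9, 10:12)) {
    expect_length(unique(fitR$membership[tr]), 1)
  }
  expect_error(detect_communities(matrix(0, 4, 4)), "edgeless")
})

test_that("detect_communities attains the exhaustive maximum on small graphs", {
  for (rep in 1:10) {
    n <- 5 + (rep %% 4)
    A <- random_graph(n, 0.45, seed = 500 + rep, connected = TRUE)
    fit <- detect_communities(A, seed = rep)
    expect_equal(fit$Q, exhaustive_best_Q(A), tolerance = 1e-12)
  }
})

test_that("curve and determinism contracts hold", {
  A <- triangle_ring()
  f1 <- detect_communities(A, seed = 9)
  f2 <- detect_communities(A, seed = 9)
  expect_identical(f1, f2)
  # curve covers community counts and its max equals the reported Q
  expect_equal(max(f1$curve$Q), f1$Q)
  expect_true(all(diff(f1$curve$k) > 0))
  # never below the trivial single-community Q = 0
  expect_gte(f1$Q, 0)
  # planted two-module graph has significant structure
  set.seed(42)
  B <- matrix(0, 14, 14)
  B[1:7, 1:7] <- rbinom(49, 1, 0.8); B[8:14, 8:14] <- rbinom(49, 1, 0.8)
  B[1:7, 8:14] <- rbinom(49, 1, 0.05)
  B <- (B + t(B)) > 0; diag(B) <- 0; B <- B * 1
  expect_gt(detect_communities(B, seed = 1)$Q, 0.3)
})

test_that("isolated nodes are sidelined into the sentinel community", {
  A <- two_triangles()
  A2 <- rbind(cbind(A, 0), 0)   # add a degree-0 node
  fit <- detect_communities(A2, seed = 2)
  expect_equal(fit$membership[7], 0)
  expect_equal(fit$isolated, 7L)
  expect_equal(fit$Q, 0.5)
  roles <- node_roles(A2, fit$membership)
  expect_equal(roles$role[7], factor("T6", levels = paste0("T", 1:6)))
  expect_true(roles$isolated[7])
})

test_that("the edge-count modularity variant is available and sane", {
  A <- two_triangles()
  # single community: l = L and w = L, so Q = 0 in both variants
  expect_equal(network_modularity(A, rep(1, 6), variant = "edge"), 0)
  q_edge <- network_modularity(A, c(1, 1, 1, 2, 2, 2), variant = "edge")
  expect_equal(q_edge, 2 * (3 / 6 - (3 / 6)^2))  # w_s = d_s - l_s = 3
  fit <- detect_communities(A, seed = 1, variant = "edge")
  expect_equal(sort(unique(fit$membership[1:3])), fit$membership[1])
})
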