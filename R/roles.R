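#' Within-community degree z-score
#'
#' For node i in community s, `z_i = (kappa_i - mean_s(kappa)) / sd_s(kappa)`
#' where `kappa_i` counts edges from i to other members of s and the
#' statistics run over the nodes of s (population standard deviation).
#' Communities with zero spread (e.g. cliques) give z = 0 for all members.
#' Measures how well-connected a node is inside its own community.
#'
#' @param A binary adjacency matrix
#' @param membership community id per node; nodes with id 0 are treated as
#'   isolated and get z = 0
#' @return numeric z per node
#' @export
within_degree_zscore <- function(A, membership) {
  A <- unclass(A); check_binary(A)
  n <- nrow(A)
  if (length(membership) != n) stopf("membership must have one id per node")
  z <- numeric(n)
  for (s in setdiff(unique(membership), 0)) {
    inside <- which(membership == s)
    kappa <- rowSums(A[inside, inside, drop = FALSE])
    mu <- mean(kappa)
    sdev <- sqrt(mean((kappa - mu)^2))   # population sd
    z[inside] <- if (sdev > 0) (kappa - mu) / sdev else 0
  }
  z
}

#' Inter-community connectivity ratio
#'
#' `r_i = (k_i - kappa_i) / k_i`: the fraction of node i's edges that
#' leave its community.  0 means the node connects only within its own
#' community, 1 means it connects only to other communities.  Isolated
#' nodes (degree 0) get r = 0, flagged in the `isolated` attribute.
#'
#' @inheritParams within_degree_zscore
#' @return numeric r per node in `[0, 1]` with attribute `isolated`
#' @export
inter_community_ratio <- function(A, membership) {
  A <- unclass(A); check_binary(A)
  n <- nrow(A)
  if (length(membership) != n) stopf("membership must have one id per node")
  k <- rowSums(A)
  kappa <- vapply(seq_len(n), function(i) {
    sum(A[i, membership == membership[i]])
  }, numeric(1))
  r <- ifelse(k > 0, (k - kappa) / k, 0)
  structure(r, isolated = which(k == 0))
}

#' Classify nodes into six topological roles
#'
#' Hubs are nodes with `z >= z_c`; the inter-community ratio r splits
#' nodes into backbone (`r >= r_hi`), transfer (`r_lo <= r < r_hi`) and
#' local (`r < r_lo`) bands.  The six classes are T1 backbone hubs,
#' T2 transfer hubs, T3 local hubs, T4 backbone non-hubs, T5 transfer
#' non-hubs, T6 local non-hubs.  The bands partition the (z, r) plane, so
#' every node receives exactly one role.
#'
#' @param z,r numeric vectors from [within_degree_zscore()] and
#'   [inter_community_ratio()]
#' @param z_c hub threshold on z (default 1.0)
#' @param r_lo,r_hi band edges on r, `0 <= r_lo < r_hi <= 1`
#'   (defaults 0.3 and 0.7)
#' @return factor of roles `T1`..`T6`, one per node
#' @export
classify_roles <- function(z, r, z_c = 1.0, r_lo = 0.3, r_hi = 0.7) {
  if (!(r_lo >= 0 && r_lo < r_hi && r_hi <= 1)) {
    stopf("need 0 <= r_lo < r_hi <= 1")
  }
  if (length(z) != length(r)) stopf("z and r must have equal length")
  hub <- z >= z_c
  band <- ifelse(r >= r_hi, 1L, ifelse(r >= r_lo, 2L, 3L))  # backbone/transfer/local
  role <- ifelse(hub, c("T1", "T2", "T3")[band], c("T4", "T5", "T6")[band])
  factor(role, levels = paste0("T", 1:6))
}

#' Full node-role profile for a partitioned network
#'
#' Convenience wrapper combining [within_degree_zscore()],
#' [inter_community_ratio()] and [classify_roles()].  Isolated nodes
#' (membership 0) get z = 0, r = 0 and role T6.
#'
#' @inheritParams within_degree_zscore
#' @inheritParams classify_roles
#' @return data frame with columns `node`, `community`, `z`, `r`, `role`,
#'   `isolated`
#' @export
node_roles <- function(A, membership, z_c = 1.0, r_lo = 0.3, r_hi = 0.7) {
  z <- within_degree_zscore(A, membership)
  r <- inter_community_ratio(A, membership)
  data.frame(
    node = seq_len(nrow(A)),
    community = membership,
    z = z,
    r = as.numeric(r),
    role = classify_roles(z, as.numeric(r), z_c = z_c, r_lo = r_lo, r_hi = r_hi),
    isolated = seq_len(nrow(A)) %in% attr(r, "isolated")
  )
}
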