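#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG seed, restoring global RNG state
#'
#' All randomness in phasenet flows through explicit seeds; no function
#' perturbs the caller's RNG stream.
#' @param seed integer seed
#' @param code code to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream of child seeds below 2^31 from one parent seed
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_square_symmetric <- function(M, what = "matrix", tol = 1e-10) {
  if (!is.matrix(M) || !is.numeric(M)) stopf("%s must be a numeric matrix", what)
  if (nrow(M) != ncol(M)) stopf("%s must be square", what)
  if (max(abs(M - t(M))) > tol) stopf("%s must be symmetric", what)
  if (any(diag(M) != 0)) stopf("%s must have a zero diagonal", what)
  invisible(M)
}

check_binary <- function(A, what = "adjacency") {
  check_square_symmetric(A, what)
  if (!all(A %in% c(0, 1))) stopf("%s must contain only 0/1", what)
  invisible(A)
}

# upper-triangle index pairs of an n x n matrix, as a 2-column matrix (i < j)
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# canonical "i-j" keys (i < j) for unordered region pairs
edge_keys <- function(edges) {
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  paste(lo, hi, sep = "-")
}

# all permutations of 1..k as a matrix (k! rows); k is small (<= 8)
all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  out <- vector("list", k)
  for (pos in seq_len(k)) {
    block <- matrix(0L, nrow(sub), k)
    block[, pos] <- k
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}
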