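#' One-tailed two-sample t-test p-value for a single edge
#'
#' Welch (default) or pooled-variance Student t-test of `mean(a)` versus
#' `mean(b)` in the requested direction.  Degenerate samples (both
#' constant and equal) carry no evidence and report p = 1; both constant
#' but different report p = 0 or 1 according to the observed direction.
#'
#' @param a,b numeric samples (per-subject edge weights), each of length
#'   >= 2
#' @param tail `"greater"` tests mean(a) > mean(b); `"less"` the reverse
#' @param var_equal pooled-variance Student test instead of Welch
#' @return one-tailed p-value
#' @export
edge_ttest <- function(a, b, tail = c("greater", "less"), var_equal = FALSE) {
  tail <- match.arg(tail)
  if (length(a) < 2 || length(b) < 2) stopf("each sample needs >= 2 values")
  res <- welch_stat(
    mean(a), mean(b), var(a), var(b), length(a), length(b),
    var_equal = var_equal
  )
  p_greater <- t_tail_p(res$t, res$df)
  if (tail == "greater") p_greater else 1 - p_greater
}

# t statistic and df for mean1 - mean2; handles zero-variance degeneracies
welch_stat <- function(m1, m2, v1, v2, n1, n2, var_equal = FALSE) {
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- ifelse(
      se2 > 0,
      se2^2 / (ifelse(v1 > 0, (v1 / n1)^2 / (n1 - 1), 0) +
               ifelse(v2 > 0, (v2 / n2)^2 / (n2 - 1), 0)),
      1
    )
  }
  # se = 0 with equal means: no evidence at all -> NaN, mapped to p = 1
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
              ifelse(m1 == m2, NaN, sign(m1 - m2) * Inf))
  list(t = t, df = df)
}

# one-sided upper-tail p; fully degenerate (NaN) statistics report p = 1
t_tail_p <- function(t, df) {
  p <- pt(t, df, lower.tail = FALSE)
  p[is.infinite(t) & t > 0] <- 0
  p[is.infinite(t) & t < 0] <- 1
  p[is.nan(t)] <- 1
  p
}

#' Group statistical difference networks
#'
#' For every unordered region pair, two one-tailed two-sample t-tests
#' compare the per-subject connection weights of the case group against
#' the control group: `D+` collects edges whose mean weight is
#' significantly *greater* in cases, `D-` those significantly *less*.
#' Optionally the per-side p-values are Benjamini-Hochberg adjusted over
#' all pairs before thresholding at `alpha`.
#'
#' @param case_fws,control_fws lists of weighted network matrices, all the
#'   same dimension, >= 2 per group
#' @param alpha significance level (default 0.05)
#' @param correction `"none"` (default) or `"BH"`
#' @param var_equal pooled-variance Student test instead of Welch
#' @return a `diffnet_result` list with binary matrices `d_plus`,
#'   `d_minus`, one-tailed p-value matrices `p_plus`, `p_minus`
#'   (BH-adjusted when requested), `alpha` and `correction`
#' @export
difference_networks <- function(case_fws, control_fws, alpha = 0.05,
                                correction = c("none", "BH"),
                                var_equal = FALSE) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (length(case_fws) < 2 || length(control_fws) < 2) {
    stopf("need >= 2 networks per group")
  }
  R <- nrow(case_fws[[1]])
  all_fw <- c(case_fws, control_fws)
  for (W in all_fw) {
    if (!is.matrix(W) || nrow(W) != R || ncol(W) != R) {
      stopf("all networks must be %d x %d matrices", R, R)
    }
  }
  pairs <- upper_pairs(R)
  flat <- function(fws) t(vapply(fws, function(W) W[pairs], numeric(nrow(pairs))))
  Xa <- flat(case_fws)      # n_case x n_pairs
  Xb <- flat(control_fws)
  n1 <- nrow(Xa); n2 <- nrow(Xb)
  st <- welch_stat(colMeans(Xa), colMeans(Xb),
                   apply(Xa, 2, var), apply(Xb, 2, var),
                   n1, n2, var_equal = var_equal)
  p_plus <- t_tail_p(st$t, st$df)
  p_minus <- 1 - p_plus
  p_minus[is.infinite(st$t) & st$t < 0] <- 0
  p_minus[is.nan(st$t)] <- 1
  q_plus <- if (correction == "BH") stats::p.adjust(p_plus, "BH") else p_plus
  q_minus <- if (correction == "BH") stats::p.adjust(p_minus, "BH") else p_minus
  to_mat <- function(v) {
    M <- matrix(0, R, R)
    M[pairs] <- v
    M + t(M)
  }
  res <- list(
    d_plus = to_mat(as.numeric(q_plus < alpha)),
    d_minus = to_mat(as.numeric(q_minus < alpha)),
    p_plus = to_mat(q_plus),
    p_minus = to_mat(q_minus),
    alpha = alpha,
    correction = correction
  )
  class(res) <- "diffnet_result"
  res
}

#' @export
print.diffnet_result <- function(x, ...) {
  cat(sprintf(
    "difference networks (alpha = %g, correction = %s): |D+| = %d edges, |D-| = %d edges\n",
    x$alpha, x$correction,
    sum(x$d_plus[upper.tri(x$d_plus)]), sum(x$d_minus[upper.tri(x$d_minus)])
  ))
  invisible(x)
}
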