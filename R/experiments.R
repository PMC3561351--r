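#' Per-subject modularity across a binarization threshold grid
#'
#' Builds one weighted network per subject (PS or Pearson), binarizes it
#' at every threshold, runs community detection and records the
#' modularity Q of the detected partition.  Subjects whose binarized
#' network is edgeless at a threshold contribute Q = 0, flagged in the
#' `null_network` matrix.  This table is the shared substrate of the
#' group-Q curve and the classification sweep, so both see exactly the
#' same numbers.
#'
#' @param cohort a `cohort` from [generate_cohort()], or a list of
#'   `subject_ts`
#' @param grid strictly increasing thresholds in (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`
#' @param method `"ps"` (default) or `"pearson"`
#' @param seed integer seed for the community detection
#' @param trim,detrend phase options for `method = "ps"`
#' @return list with `thresholds`, `q` (subjects x thresholds matrix),
#'   `null_network` (logical matrix), `group`, `subject_id`, `method`
#' @export
subject_q_table <- function(cohort, grid = seq(0.05, 0.95, by = 0.05),
                            method = c("ps", "pearson"), seed = 1L,
                            trim = 0.05, detrend = TRUE) {
  method <- match.arg(method)
  subjects <- cohort_subjects(cohort)
  check_grid(grid)
  n <- length(subjects)
  q <- matrix(NA_real_, n, length(grid))
  nullnet <- matrix(FALSE, n, length(grid))
  det_seeds <- child_seeds(seed, n)
  for (i in seq_len(n)) {
    W <- if (method == "ps") {
      build_ps_network(subjects[[i]], trim = trim, detrend = detrend)
    } else {
      build_pearson_network(subjects[[i]])
    }
    for (j in seq_along(grid)) {
      A <- binarize(W, grid[j])
      if (sum(A) == 0) {
        q[i, j] <- 0
        nullnet[i, j] <- TRUE
      } else {
        q[i, j] <- detect_communities(A, seed = det_seeds[i])$Q
      }
    }
  }
  list(
    thresholds = grid, q = q, null_network = nullnet,
    group = vapply(subjects, function(s) s$group, character(1)),
    subject_id = vapply(subjects, function(s) s$subject_id, character(1)),
    method = method
  )
}

cohort_subjects <- function(cohort) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  if (!length(subjects) || !all(vapply(subjects, inherits, logical(1), "subject_ts"))) {
    stopf("cohort must be a cohort object or a list of subject_ts")
  }
  subjects
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) == 0) stopf("threshold grid must be non-empty")
  if (any(grid <= 0 | grid >= 1)) stopf("thresholds must lie in (0, 1)")
  if (any(diff(grid) <= 0)) stopf("thresholds must be strictly increasing")
  invisible(grid)
}

sweep_result <- function(thresholds, per_subject, group, subject_id,
                         metric, method, flags = NULL) {
  per_group_mean <- rbind(
    control = colMeans(per_subject[group == "control", , drop = FALSE]),
    case = colMeans(per_subject[group == "case", , drop = FALSE])
  )
  colnames(per_group_mean) <- thresholds
  structure(
    list(thresholds = thresholds, per_subject = per_subject,
         per_group_mean = per_group_mean, group = group,
         subject_id = subject_id, metric = metric, method = method,
         flags = flags),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: metric = %s (%s), %d subjects, %d thresholds\n",
              x$metric, x$method, nrow(x$per_subject), length(x$thresholds)))
  invisible(x)
}

#' Group-averaged modularity versus binarization threshold
#'
#' For each subject and threshold, Q of the detected community structure
#' of the binarized network; averaged within the case group and within
#' the control group.  An additional network superposed on the case
#' cohort's base structure typically *lowers* the case group's Q at
#' mid-range thresholds (extra inter-community edges), while at high
#' thresholds control networks empty out first and the ordering flips.
#'
#' @inheritParams subject_q_table
#' @return a `sweep_result` with `metric = "modularity"`
#' @export
group_q_curve <- function(cohort, grid = seq(0.05, 0.95, by = 0.05),
                          method = c("ps", "pearson"), seed = 1L,
                          trim = 0.05, detrend = TRUE) {
  tab <- subject_q_table(cohort, grid, method, seed, trim, detrend)
  sweep_result(tab$thresholds, tab$q, tab$group, tab$subject_id,
               metric = "modularity", method = tab$method,
               flags = tab$null_network)
}

#' Group-averaged graph metric versus binarization threshold
#'
#' Same sweep as [group_q_curve()] for cost, clustering coefficient,
#' local or global efficiency.  Edgeless binarized networks contribute 0.
#'
#' @inheritParams subject_q_table
#' @param metric one of `"cost"`, `"clustering"`, `"local_efficiency"`,
#'   `"global_efficiency"`
#' @return a `sweep_result`
#' @export
group_metric_curves <- function(cohort, grid = seq(0.05, 0.95, by = 0.05),
                                metric = c("cost", "clustering",
                                           "local_efficiency",
                                           "global_efficiency"),
                                method = c("ps", "pearson"),
                                trim = 0.05, detrend = TRUE) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  subjects <- cohort_subjects(cohort)
  check_grid(grid)
  fn <- switch(metric,
    cost = network_cost,
    clustering = clustering_coefficient,
    local_efficiency = local_efficiency,
    global_efficiency = global_efficiency
  )
  n <- length(subjects)
  vals <- matrix(NA_real_, n, length(grid))
  flags <- matrix(FALSE, n, length(grid))
  for (i in seq_len(n)) {
    W <- if (method == "ps") {
      build_ps_network(subjects[[i]], trim = trim, detrend = detrend)
    } else {
      build_pearson_network(subjects[[i]])
    }
    for (j in seq_along(grid)) {
      A <- binarize(W, grid[j])
      flags[i, j] <- sum(A) == 0
      vals[i, j] <- fn(A)
    }
  }
  sweep_result(grid, vals,
               vapply(subjects, function(s) s$group, character(1)),
               vapply(subjects, function(s) s$subject_id, character(1)),
               metric = metric, method = method, flags = flags)
}

#' Subject classification accuracy versus binarization threshold
#'
#' At each threshold the per-subject modularity Q (shared with
#' [group_q_curve()] via [subject_q_table()]) is the one-dimensional
#' feature; subjects are split into two clusters by seeded Lloyd k-means
#' and the accuracy rate against the true case/control labels is
#' recorded.  Thresholds where fewer than two distinct Q values remain
#' fall back to the single-cluster accuracy (majority-group fraction),
#' flagged in `degenerate`.
#'
#' @inheritParams subject_q_table
#' @param restarts k-means restarts per threshold (default 50)
#' @param q_table optional precomputed [subject_q_table()] result (must
#'   match `cohort`, `grid` and `method`); avoids recomputation when the
#'   group-Q curve is also needed
#' @return list with `thresholds`, `accuracy` (percent per threshold),
#'   `max_accuracy`, `argmax_threshold`, `degenerate`, `method`,
#'   `q_table`
#' @export
classification_sweep <- function(cohort, grid = seq(0.05, 0.95, by = 0.05),
                                 method = c("ps", "pearson"), seed = 1L,
                                 restarts = 50L, trim = 0.05,
                                 detrend = TRUE, q_table = NULL) {
  method <- match.arg(method)
  tab <- if (is.null(q_table)) {
    subject_q_table(cohort, grid, method, seed, trim, detrend)
  } else q_table
  groups <- tab$group
  if (!all(c("case", "control") %in% groups)) {
    stopf("both groups must be non-empty")
  }
  km_seeds <- child_seeds(seed + 1L, length(tab$thresholds))
  acc <- numeric(length(tab$thresholds))
  degen <- logical(length(tab$thresholds))
  for (j in seq_along(tab$thresholds)) {
    qj <- tab$q[, j]
    if (length(unique(qj)) < 2) {
      degen[j] <- TRUE
      acc[j] <- 100 * max(table(groups)) / length(groups)
    } else {
      fit <- kmeans_cluster(qj, k = 2, seed = km_seeds[j], restarts = restarts)
      acc[j] <- accuracy_rate(groups, fit$assignment)
    }
  }
  best <- which.max(acc)
  list(
    thresholds = tab$thresholds, accuracy = acc,
    max_accuracy = acc[best], argmax_threshold = tab$thresholds[best],
    degenerate = degen, method = method, q_table = tab
  )
}
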