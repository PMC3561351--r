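# small cohorts keep the sweep tests inside the time budget
coarse_grid <- seq(0.1, 0.9, by = 0.1)

clone_cohort <- function(data, groups) {
  subjects <- lapply(seq_along(groups), function(i) {
    structure(list(subject_id = sprintf("s%02d", i), group = groups[i],
                   data = data, sampling_interval = 2),
              class = "subject_ts")
  })
  structure(list(subjects = subjects, truth = list(planted_edges = NULL)),
            class = "cohort")
}

test_that("identical subjects give zero between-group difference", {
  spec <- cohort_spec(n_regions = 8, n_samples = 128, n_base_groups = 2,
                      base_coupling = 0.5)
  data <- generate_subject(spec, "control", 17)$data
  coh <- clone_cohort(data, c("control", "control", "case", "case"))
  gq <- group_q_curve(coh, coarse_grid, seed = 4)
  expect_equal(gq$per_group_mean["control", ], gq$per_group_mean["case", ])
  gm <- group_metric_curves(coh, coarse_grid, metric = "global_efficiency")
  expect_equal(gm$per_group_mean["control", ], gm$per_group_mean["case", ])
})

test_that("sweeps are deterministic and share per-subject Q exactly", {
  spec <- planted_spec_replace()
  coh <- generate_cohort(spec, 4, 4, seed = 6)
  g1 <- group_q_curve(coh, coarse_grid, seed = 11)
  g2 <- group_q_curve(coh, coarse_grid, seed = 11)
  expect_identical(g1, g2)
  cs <- classification_sweep(coh, coarse_grid, seed = 11, restarts = 10)
  expect_identical(cs$q_table$q, g1$per_subject)
  # a precomputed q_table is used as-is
  cs2 <- classification_sweep(coh, coarse_grid, seed = 11, restarts = 10,
                              q_table = cs$q_table)
  expect_identical(cs$accuracy, cs2$accuracy)
})

test_that("sweep bookkeeping invariants hold", {
  spec <- cohort_spec(n_regions = 6, n_samples = 64, n_base_groups = 2,
                      base_coupling = 0.3)
  coh <- generate_cohort(spec, 3, 3, seed = 1)
  sw <- group_metric_curves(coh, coarse_grid, metric = "cost")
  for (g in c("control", "case")) {
    expect_equal(
      unname(sw$per_group_mean[g, ]),
      unname(colMeans(sw$per_subject[sw$group == g, , drop = FALSE]))
    )
  }
  expect_error(group_metric_curves(coh, numeric(0)), "non-empty")
  expect_error(group_metric_curves(coh, c(0.5, 0.4)), "increasing")
  expect_error(group_q_curve(coh, c(0, 0.5)), "in \\(0, 1\\)")
})

test_that("saturated thresholds give cost 1 and null networks give Q = 0", {
  # near-perfectly synchronous cohort: every weight close to 1
  spec <- cohort_spec(n_regions = 5, n_samples = 128, n_base_groups = 1,
                      base_coupling = 0, noise_sd = 0.01)
  coh <- generate_cohort(spec, 2, 2, seed = 9)
  sw <- group_metric_curves(coh, c(0.05, 0.95), metric = "cost")
  expect_equal(unname(sw$per_subject[, 1]), rep(1, 4))
  # white-phase cohort at a high threshold: all networks edgeless
  spec0 <- cohort_spec(n_regions = 6, n_samples = 128, n_base_groups = 1,
                       base_coupling = 20, noise_sd = 0.1)
  coh0 <- generate_cohort(spec0, 2, 2, seed = 9)
  gq <- group_q_curve(coh0, 0.9, seed = 2)
  expect_true(all(gq$flags))
  expect_equal(unname(gq$per_subject[, 1]), rep(0, 4))
})

test_that("planted enhancement raises case cost at every threshold", {
  spec <- planted_spec_replace()
  coh <- generate_cohort(spec, 15, 15, seed = 3)
  gc <- group_metric_curves(coh, coarse_grid, metric = "cost")
  dc <- gc$per_group_mean["case", ] - gc$per_group_mean["control", ]
  expect_true(all(dc >= 0))
})

test_that("cross-module additional coupling lowers case-group modularity", {
  # base world of four tight modules; cases gain superposed cross-module
  # drivers, so control mean Q exceeds case mean Q over the low-to-mid
  # threshold range (the ordering inverts only when controls empty out)
  spec <- cohort_spec(
    n_regions = 16, n_samples = 256, sampling_interval = 2,
    base_communities = list(1:4, 5:8, 9:12, 13:16), base_coupling = 0.4,
    additional_edges = rbind(c(1, 5), c(2, 9), c(6, 13), c(10, 14)),
    additional_coupling = 0.15, additional_mode = "superpose",
    noise_sd = 0.1, seed = 1L
  )
  coh <- generate_cohort(spec, 10, 10, seed = 2)
  gq <- group_q_curve(coh, seq(0.1, 0.4, by = 0.1), seed = 2)
  d <- gq$per_group_mean["control", ] - gq$per_group_mean["case", ]
  expect_true(all(d > 0))
})

test_that("degenerate thresholds fall back to majority accuracy", {
  spec <- cohort_spec(n_regions = 5, n_samples = 128, n_base_groups = 1,
                      base_coupling = 0, noise_sd = 0.01)
  coh <- generate_cohort(spec, 3, 2, seed = 5)
  # threshold above every weight: all Q = 0, fewer than 2 distinct features
  cs <- classification_sweep(coh, c(0.989), seed = 1, restarts = 5)
  expect_true(cs$degenerate[1])
  expect_equal(cs$accuracy[1], 100 * 3 / 5)
})
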