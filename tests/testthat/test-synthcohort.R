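test_that("cohort_spec validates its fields by name", {
  expect_error(cohort_spec(n_regions = 1), "n_regions")
  expect_error(cohort_spec(n_samples = 10), "n_samples")
  expect_error(cohort_spec(sampling_interval = 0), "sampling_interval")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(driver_freq_band = c(0.01, 0.4)), "Nyquist")
  expect_error(cohort_spec(n_regions = 8, additional_edges = rbind(c(1, 1))),
               "self-pairs")
  expect_error(cohort_spec(n_regions = 8, additional_edges = rbind(c(1, 9))),
               "out-of-range")
  expect_error(
    cohort_spec(n_regions = 8, base_communities = list(1:3, 5:8)),
    "partition"
  )
})

test_that("zero-noise single-driver subjects are phase-locked copies", {
  spec <- cohort_spec(n_regions = 4, n_samples = 128, n_base_groups = 1,
                      base_coupling = 0, noise_sd = 0)
  s <- generate_subject(spec, "control", subject_seed = 5)
  # every pair of rows differs only by a fixed phase offset; the estimated
  # PS degree sits at 1 up to Hilbert edge effects on a wandering carrier
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gt(ps_degree(s$data[i, ], s$data[j, ]), 0.99)
  }
})

test_that("generation is deterministic and seed-sensitive", {
  spec <- cohort_spec(n_regions = 6, n_samples = 64, n_base_groups = 2)
  a <- generate_subject(spec, "case", 9)
  b <- generate_subject(spec, "case", 9)
  expect_identical(a$data, b$data)
  c <- generate_subject(spec, "case", 10)
  expect_false(identical(a$data, c$data))
  # RNG state of the session is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_subject(spec, "case", 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generate_cohort assembles labelled cohorts", {
  spec <- cohort_spec(n_regions = 4, n_samples = 64, n_base_groups = 2)
  coh <- generate_cohort(spec, n_control = 27, n_case = 21, seed = 2)
  expect_length(coh$subjects, 48)
  grp <- vapply(coh$subjects, function(s) s$group, character(1))
  expect_equal(sum(grp == "control"), 27)
  expect_equal(sum(grp == "case"), 21)
  expect_error(generate_cohort(spec, 5, 0), "at least one")
  coh2 <- generate_cohort(spec, n_control = 27, n_case = 21, seed = 2)
  expect_identical(
    lapply(coh$subjects, function(s) s$data),
    lapply(coh2$subjects, function(s) s$data)
  )
})

test_that("huge phase jitter drives pairwise PS to the null level", {
  # independent-driver oracle: same world with no shared structure at all
  spec_jit <- cohort_spec(n_regions = 6, n_samples = 400, n_base_groups = 1,
                          base_coupling = 20, noise_sd = 0.05)
  spec_ind <- cohort_spec(n_regions = 6, n_samples = 400, n_base_groups = 6,
                          base_coupling = 0, noise_sd = 0.05)
  mean_ps <- function(spec, seeds) {
    mean(vapply(seeds, function(sd) {
      W <- build_ps_network(generate_subject(spec, "control", sd))
      mean(W[upper.tri(W)])
    }, numeric(1)))
  }
  m_jit <- mean_ps(spec_jit, 1:6)
  m_ind <- mean_ps(spec_ind, 101:106)
  # jittered-to-death coupling is indistinguishable from independence
  expect_lt(abs(m_jit - m_ind), 0.05)
  expect_lt(m_jit, 0.25)
})

test_that("planted edges raise PS on exactly those pairs (replace mode)", {
  spec <- planted_spec_replace()
  s <- generate_subject(spec, "case", 3)
  W <- build_ps_network(s)
  planted <- truth_keys(spec$additional_edges)
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  keys <- paste(pairs[, 1], pairs[, 2], sep = "-")
  w_planted <- W[upper.tri(W)][keys %in% planted]
  w_rest <- W[upper.tri(W)][!keys %in% planted]
  expect_gt(min(w_planted), max(w_rest))
  # control subjects carry no such structure
  s0 <- generate_subject(spec, "control", 3)
  W0 <- build_ps_network(s0)
  w0_planted <- W0[upper.tri(W0)][keys %in% planted]
  expect_lt(mean(w0_planted), mean(w_planted) - 0.3)
})

test_that("cohort TSV round-trip preserves data", {
  spec <- cohort_spec(n_regions = 5, n_samples = 64, n_base_groups = 2,
                      additional_edges = rbind(c(1, 4)))
  coh <- generate_cohort(spec, 2, 2, seed = 4)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  back <- read_cohort(manifest)
  expect_length(back$subjects, 4)
  expect_equal(back$subjects[[1]]$group, "control")
  expect_equal(back$subjects[[4]]$group, "case")
  expect_equal(back$subjects[[2]]$data, coh$subjects[[2]]$data,
               tolerance = 1e-9)
  expect_equal(back$subjects[[3]]$sampling_interval, 2)
  expect_equal(unname(back$truth$planted_edges[1, ]), c(1L, 4L))
})
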