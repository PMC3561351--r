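#' Specification of a synthetic two-cohort phase-oscillator study
#'
#' Describes the stated world that the generator emulates: N regional
#' signals per subject, T samples at a fixed sampling interval, regions
#' organized into driver groups whose slowly wandering phases live inside
#' a low-frequency band, per-region phase jitter, amplitude noise, and —
#' in the case cohort only — a planted "additional network": a set of
#' region pairs that share extra phase drivers and therefore show enhanced
#' pairwise phase synchrony.  Defaults mirror a resting-state acquisition:
#' 116 regions, 197 samples at 2 s, drivers in 0.01–0.08 Hz, six base
#' driver groups.
#'
#' @param n_regions number of regions (>= 2)
#' @param n_samples samples per signal (>= 32)
#' @param sampling_interval seconds between samples (> 0)
#' @param base_communities list of integer vectors partitioning
#'   `1:n_regions` into driver groups; `NULL` splits the regions into
#'   `n_base_groups` contiguous blocks
#' @param n_base_groups used only when `base_communities` is `NULL`
#'   (default 6)
#' @param base_coupling sd (radians) of the independent per-sample phase
#'   jitter around the group driver; larger = weaker within-group
#'   synchrony
#' @param additional_edges 2-column matrix of unordered region pairs
#'   planted in cases only (no self-pairs); `NULL` for none
#' @param additional_coupling phase-jitter sd (radians) around the extra
#'   shared driver(s)
#' @param additional_mode `"superpose"` (default: the extra driver's
#'   sinusoid is added to the base signal and the sum rescaled) or
#'   `"replace"` (incident regions are driven by the extra driver alone,
#'   leaving amplitude statistics identical to controls)
#' @param additional_lag phase lag (radians) applied between successive
#'   members of a planted component (default `pi/2`, which makes the
#'   planted coupling invisible to Pearson correlation in `"replace"`
#'   mode)
#' @param noise_sd amplitude noise sd (>= 0; default 0.1)
#' @param driver_freq_band `c(low, high)` in Hz, inside (0, Nyquist)
#' @param seed integer seed stored with the spec
#' @return a validated `cohort_spec` list
#' @export
cohort_spec <- function(n_regions = 116, n_samples = 197,
                        sampling_interval = 2,
                        base_communities = NULL, n_base_groups = 6,
                        base_coupling = 1.0,
                        additional_edges = NULL,
                        additional_coupling = 0.2,
                        additional_mode = c("superpose", "replace"),
                        additional_lag = pi / 2,
                        noise_sd = 0.1,
                        driver_freq_band = c(0.01, 0.08),
                        seed = 1L) {
  additional_mode <- match.arg(additional_mode)
  if (!is.numeric(n_regions) || n_regions < 2) stopf("n_regions must be >= 2")
  if (!is.numeric(n_samples) || n_samples < 32) stopf("n_samples must be >= 32")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stopf("sampling_interval must be > 0")
  }
  if (base_coupling < 0) stopf("base_coupling must be >= 0")
  if (additional_coupling < 0) stopf("additional_coupling must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  nyq <- 1 / (2 * sampling_interval)
  if (length(driver_freq_band) != 2 ||
      !(driver_freq_band[1] > 0 && driver_freq_band[2] > driver_freq_band[1] &&
        driver_freq_band[2] < nyq)) {
    stopf("driver_freq_band must lie inside (0, Nyquist = %g) Hz", nyq)
  }
  if (is.null(base_communities)) {
    g <- max(1L, min(as.integer(n_base_groups), as.integer(n_regions)))
    base_communities <- split(seq_len(n_regions),
                              sort(rep_len(seq_len(g), n_regions)))
  }
  members <- sort(unlist(base_communities))
  if (!identical(as.integer(members), seq_len(as.integer(n_regions)))) {
    stopf("base_communities must partition 1..n_regions")
  }
  if (!is.null(additional_edges)) {
    additional_edges <- as.matrix(additional_edges)
    if (ncol(additional_edges) != 2) stopf("additional_edges must have 2 columns")
    if (any(additional_edges < 1 | additional_edges > n_regions)) {
      stopf("additional_edges contain out-of-range region indices")
    }
    if (any(additional_edges[, 1] == additional_edges[, 2])) {
      stopf("additional_edges must not contain self-pairs")
    }
  }
  spec <- list(
    n_regions = as.integer(n_regions), n_samples = as.integer(n_samples),
    sampling_interval = sampling_interval,
    base_communities = lapply(base_communities, as.integer),
    base_coupling = base_coupling,
    additional_edges = additional_edges,
    additional_coupling = additional_coupling,
    additional_mode = additional_mode,
    additional_lag = additional_lag,
    noise_sd = noise_sd,
    driver_freq_band = driver_freq_band,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

# slowly wandering driver phase whose instantaneous frequency stays in band
driver_phase <- function(n, dt, band) {
  f0 <- runif(1, band[1], band[2])
  width <- band[2] - band[1]
  wander <- cumsum(rnorm(n, 0, width / (8 * sqrt(n))))
  f <- pmin(pmax(f0 + wander, band[1]), band[2])
  2 * pi * cumsum(f) * dt + runif(1, 0, 2 * pi)
}

# connected components of the planted edge set -> list of member vectors
planted_components <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  g <- igraph::graph_from_edgelist(cbind(as.character(edges[, 1]),
                                         as.character(edges[, 2])),
                                   directed = FALSE)
  comps <- igraph::components(g)
  lapply(seq_len(comps$no), function(c) {
    sort(as.integer(igraph::V(g)$name[comps$membership == c]))
  })
}

#' Generate one synthetic subject
#'
#' Each region's signal is the sine of its driver group's wandering phase
#' plus a fixed per-region offset plus independent wrapped-Gaussian phase
#' jitter (sd `base_coupling`), plus amplitude noise.  For `group =
#' "case"`, every region incident to the planted edges additionally (or
#' instead, in `"replace"` mode) follows a shared per-component extra
#' driver with jitter `additional_coupling` and a deterministic
#' `additional_lag` stagger between component members.  Bit-reproducible
#' given `(spec, group, subject_seed)`.
#'
#' @param spec a [cohort_spec()]
#' @param group `"case"` or `"control"`
#' @param subject_seed integer seed for this subject
#' @param subject_id optional id string
#' @return a `subject_ts` list: `subject_id`, `group`, `data`
#'   (regions x samples matrix), `sampling_interval`
#' @export
generate_subject <- function(spec, group = c("control", "case"),
                             subject_seed = 1L, subject_id = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  R <- spec$n_regions; Tn <- spec$n_samples; dt <- spec$sampling_interval
  X <- with_seed(subject_seed, {
    X <- matrix(0, R, Tn)
    for (g in seq_along(spec$base_communities)) {
      theta <- driver_phase(Tn, dt, spec$driver_freq_band)
      for (i in spec$base_communities[[g]]) {
        psi <- runif(1, 0, 2 * pi)
        jit <- if (spec$base_coupling > 0) rnorm(Tn, 0, spec$base_coupling) else 0
        X[i, ] <- sin(theta + psi + jit)
      }
    }
    if (group == "case") {
      for (comp in planted_components(spec$additional_edges)) {
        theta_e <- driver_phase(Tn, dt, spec$driver_freq_band)
        for (pos in seq_along(comp)) {
          i <- comp[pos]
          jit <- if (spec$additional_coupling > 0) {
            rnorm(Tn, 0, spec$additional_coupling)
          } else 0
          extra <- sin(theta_e + (pos - 1) * spec$additional_lag + jit)
          X[i, ] <- if (spec$additional_mode == "replace") {
            extra
          } else {
            (X[i, ] + extra) / sqrt(2)
          }
        }
      }
    }
    if (spec$noise_sd > 0) X <- X + matrix(rnorm(R * Tn, 0, spec$noise_sd), R, Tn)
    X
  })
  structure(
    list(
      subject_id = if (is.null(subject_id)) sprintf("%s_%d", group, subject_seed)
                   else subject_id,
      group = group, data = X, sampling_interval = dt
    ),
    class = "subject_ts"
  )
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("subject_ts %s (%s): %d regions x %d samples, dt = %g s\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$sampling_interval))
  invisible(x)
}

#' Generate a full two-cohort study
#'
#' Draws per-subject seeds deterministically from `seed` and generates
#' `n_control` control and `n_case` case subjects under `spec`.
#'
#' @param spec a [cohort_spec()]
#' @param n_control,n_case cohort sizes (>= 1; 27 and 21 mirror the
#'   reference study)
#' @param seed integer master seed
#' @return a `cohort` list: `subjects` (list of `subject_ts`), `truth`
#'   (list with `planted_edges` and a `subject_seeds` data frame)
#' @examples
#' spec <- cohort_spec(n_regions = 8, n_samples = 64, n_base_groups = 2)
#' coh <- generate_cohort(spec, n_control = 3, n_case = 2, seed = 7)
#' length(coh$subjects)
#' @export
generate_cohort <- function(spec, n_control, n_case, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_control < 1 || n_case < 1) stopf("need at least one subject per cohort")
  n <- n_control + n_case
  seeds <- child_seeds(seed, n)
  groups <- c(rep("control", n_control), rep("case", n_case))
  ids <- c(sprintf("control%02d", seq_len(n_control)),
           sprintf("case%02d", seq_len(n_case)))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_subject(spec, groups[i], seeds[i], ids[i])
  }
  structure(
    list(
      subjects = subjects,
      truth = list(
        planted_edges = spec$additional_edges,
        subject_seeds = data.frame(subject_id = ids, group = groups,
                                   seed = seeds, stringsAsFactors = FALSE)
      )
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  gr <- vapply(x$subjects, function(s) s$group, character(1))
  cat(sprintf("cohort: %d subjects (%d control, %d case), %d planted edges\n",
              length(x$subjects), sum(gr == "control"), sum(gr == "case"),
              if (is.null(x$truth$planted_edges)) 0L
              else nrow(x$truth$planted_edges)))
  invisible(x)
}
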