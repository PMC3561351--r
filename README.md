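# phasenet

Functional brain networks from **phase synchrony** instead of Pearson
correlation, with the downstream machinery to ask whether a patient group
carries an *additional network* of enhanced couplings on top of the normal
one — and to classify subjects from it.

## Who this is for

Researchers working with regional time series (typically resting-state
fMRI series extracted on the 116-region AAL parcellation, but any
regions × samples matrix works) who want to:

1. quantify pairwise coupling by **phase locking** rather than linear
   correlation,
2. test edge-wise group differences between a case and a control cohort,
3. characterize the resulting difference network's community structure
   and node roles, and
4. classify individual subjects with k-means on a network statistic.

Everything is testable offline: a coupled-phase-oscillator cohort
generator with a *planted* additional network provides ground truth for
every stage.

## The statistics at the core

**Phase-synchrony degree.** For signals `x_i`, `x_j`, the instantaneous
phase `phi(t)` is the argument of the analytic signal `x + iH[x]`
(Hilbert transform). The connection strength is the phase-locking value

    rho_ij = | (1/T) * sum_t exp( i * (phi_i(t) - phi_j(t)) ) |,

which lies in [0, 1], equals 1 exactly when the phase difference is
constant, and decays like `sqrt(pi)/(2*sqrt(T))` for independent phases.
The R×R matrix of `rho_ij` (zero diagonal) is the weighted functional
network; thresholding at `T` with a strict `>` gives binary networks for
graph analysis (cost, clustering coefficient, local/global efficiency).

**Difference networks.** For each region pair, two one-tailed two-sample
t-tests (Welch by default, optional Benjamini–Hochberg correction)
compare case versus control weights: `D+` holds edges significantly
*stronger* in cases, `D-` those significantly *weaker*.

**Communities and roles.** Modularity
`Q = sum_s ( l_s/L - (d_s/(2L))^2 )` is maximized by seeded greedy
agglomeration with node-move refinement, recording the best Q at every
community count. Nodes get a within-community degree z-score `z`, an
inter-community connectivity ratio `r = (k - kappa)/k`, and one of six
roles (backbone/transfer/local × hub/non-hub).

**Classification.** Per binarization threshold, each subject's Q is the
feature for Lloyd k-means (k = 2, seeded restarts); accuracy is the
best-bijection match between clusters and true groups, in percent.

## Worked example

A synthetic study: 16 regions, independent base oscillators, and an
additional network of four phase-coupled pairs planted in the 12 case
subjects only (quadrature lag, so Pearson correlation sees nothing):

```r
library(phasenet)

spec <- cohort_spec(n_regions = 16, n_samples = 256, sampling_interval = 2,
                    n_base_groups = 16, base_coupling = 0,
                    additional_edges = rbind(c(1,9), c(2,10), c(3,11), c(4,12)),
                    additional_coupling = 0.15, additional_mode = "replace",
                    noise_sd = 0.1)
coh <- generate_cohort(spec, n_control = 12, n_case = 12, seed = 1)

fws <- lapply(coh$subjects, build_ps_network)
grp <- vapply(coh$subjects, function(s) s$group, character(1))
dn  <- difference_networks(fws[grp == "case"], fws[grp == "control"],
                           correction = "BH")
dn
#> difference networks (alpha = 0.05, correction = BH): |D+| = 4 edges, |D-| = 0 edges

which(upper.tri(dn$d_plus) & dn$d_plus == 1, arr.ind = TRUE)
#>      row col
#> [1,]   1   9
#> [2,]   2  10
#> [3,]   3  11
#> [4,]   4  12

detect_communities(dn$d_plus, seed = 1)
#> community_fit: k = 4 communities, Q = 0.7500 (8 isolated nodes)

cs <- classification_sweep(coh, method = "ps", seed = 1)
sprintf("max accuracy %.1f%% at threshold %.2f", cs$max_accuracy, cs$argmax_threshold)
#> "max accuracy 100.0% at threshold 0.75"
```

`D+` is exactly the planted additional network and `D-` is empty (the
coupling is one-directional enhancement); its four components are the
four detected communities (`Q = 4 × (1/4 − 1/16) = 0.75`); and the
per-subject modularity separates the cohorts perfectly at mid-to-high
thresholds. The same sweep with `method = "pearson"` stays near chance,
because the planted coupling lives in phase, not amplitude.

The bundled 116-region anatomical table is available via
`load_region_table()` / `region_lookup()`; a command-line pipeline
(`simulate`, `fw`, `diffnet`, `communities`, `roles`, `sweep`,
`classify`) is exposed through `phasenet_cli()` and `inst/cli/phasenet`.

## Documentation

The methods vignette (`vignettes/phase-synchrony-networks.Rmd`) explains
the model, the generator's stated world, numerical choices and
limitations.
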