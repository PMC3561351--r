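---
title: "Phase-synchrony functional networks: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchrony functional networks: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasenet)
```

## The problem

Functional connectivity between brain regions is conventionally measured
by Pearson correlation of regional time series. Correlation is a linear,
amplitude-sensitive statistic; two regions whose oscillations are
phase-locked at a lag, or whose amplitudes fluctuate independently of
their timing relationship, can show weak correlation despite tight
dynamical coupling. Phase synchrony — locking of instantaneous phases
while amplitudes vary freely — is the alternative this package builds
on. The pipeline constructs weighted networks from the time-averaged
phase-synchrony degree, contrasts two cohorts edge by edge, analyses the
community structure of the resulting difference network, and classifies
single subjects from a network statistic.

## Model and estimators

### Instantaneous phase

For a regional signal $x(t)$, `analytic_phase()` removes a linear trend
and the mean, forms the analytic signal $x + i\,H[x]$ by the FFT
half-spectrum method, and takes its argument. Assumption: the signal is
narrowband enough for a single well-defined phase; broadband inputs
yield a phase whose increments fluctuate, which is exactly what makes
the null level of the synchrony estimator nonzero at finite $T$.

### Phase-synchrony degree

`ps_degree()` is the 1:1 phase-locking value
$$\rho_{ij} = \Bigl|\tfrac1T \sum_t e^{\,i(\phi_i(t) - \phi_j(t))}\Bigr|,$$
the mean resultant length of the wrapped phase difference. Properties
that drive the tests: $\rho \in [0,1]$; $\rho = 1$ iff the phase
difference is constant; for independent uniform phase differences
$E[\rho] \approx \sqrt{\pi}/(2\sqrt{T})$ (two-dimensional random walk),
so the null level decays like $1/\sqrt{T}$; and $\rho$ is exactly
invariant to positive amplitude scaling because the Hilbert transform is
linear. The strict bounded-difference definition of locking
(`phase_locking_condition()`, $|n\phi_x - m\phi_y - c| \le \varepsilon$
with the sup-norm-optimal constant, the midrange) is provided for
completeness; the pipeline uses the time-averaged degree throughout.

**Edge handling.** The analytic signal of a finite record is distorted
near both ends. By default the first and last 5% of samples are excluded
from the phase-difference average (`trim = 0.05`, configurable). With
trimming, identical or constant-lag sinusoids with an integer number of
cycles reproduce $\rho = 1$ to machine precision; generic signals sit
within about $10^{-4}$ of it.

### Band-pass filtering

Resting-state practice filters to 0.01–0.08 Hz before phase extraction;
`bandpass_filter()` exposes that with those defaults at a 2 s sampling
interval. A design note: the conventional implementation is a
forward–backward Butterworth IIR. No filter-design library is available
in the supported dependency set, so the filter is implemented in the
frequency domain — exactly zero-phase, DC-rejecting, with raised-cosine
transition bands whose closed-form response (`bandpass_response()`)
doubles as the oracle in the tests. For the synthetic worlds below the
filter is optional, since the generator already produces in-band
signals.

## Networks, difference networks

`build_ps_network()` fills the R×R matrix with pairwise $\rho_{ij}$
(zero diagonal, symmetric — self-synchrony is not considered);
`build_pearson_network()` is the comparator (raw signed $r$ by default;
absolute-value mode exists because the thresholding literature varies).
`binarize()` keeps edges with weight strictly above the threshold, so a
threshold at the maximum weight yields an empty graph — the higher the
threshold, the sparser the network. Cost, Watts–Strogatz clustering,
and Latora–Marchiori local/global efficiency (disconnected pairs
contribute zero, required because high thresholds disconnect and even
empty some networks) operate on the binary matrices; subjects whose
networks empty out are kept, contributing zero, rather than dropped —
the alternative (exclusion) is configurable at the experiment level but
zeros are the default because the high-threshold crossover behaviour of
the group curves is driven precisely by those null matrices.

`difference_networks()` performs, per region pair, both one-tailed
two-sample t-tests between cohorts. Defaults: $\alpha = 0.05$ and the
Welch statistic — the safer choice for unequal cohort sizes such as
21 versus 27; the pooled-variance Student form is available. Without
correction, a 116-region study tests 6670 edges and a null world flags
about $\alpha$ of them per side by construction (that calibration is
itself an acceptance criterion); the optional Benjamini–Hochberg mode is
what makes *recovery* claims (planted-edge precision, an empty `D−`)
meaningful, and the correction used is recorded in the result object.

## Community structure and node roles

Modularity is $Q = \sum_s (l_s/L - (d_s/2L)^2)$ with $L$ the edge count,
$l_s$ the within-community edge count and $d_s$ the community degree
sum. The defining text of the statistic can also be read literally as
"fraction of links with one or both vertices inside the community" for
the squared term; that edge-count variant is implemented behind
`variant = "edge"`, with the degree-sum (Newman–Girvan) form as the
default since it is the standard statistic with the standard $Q = 0$
single-community baseline.

`detect_communities()` uses greedy agglomerative merging from singleton
communities — no algorithm is canonical for this statistic; greedy
agglomeration is chosen because its merge path visits every community
count once, which directly yields the $Q$-versus-$k$ curve the
experiments need — with seeded random tie-breaking, followed by local
node-move refinement of the best partition recorded at each $k$ (moves
that would empty a community are disallowed so $k$ is preserved), pooled
over seeded restarts (default 8). On thirty random connected graphs with
$n \le 8$ the procedure attains the exhaustive-search maximum over all
set partitions (an oracle kept in the test helpers only: Bell(8) = 4140
partitions). Degree-zero nodes are excluded from optimization and
reported in a sentinel community 0 with $z = 0$, $r = 0$, role T6.

Node roles: the within-community degree z-score uses the *population*
standard deviation (divide by $n$), with $z = 0$ where the spread is
zero (e.g. cliques) — the choice is not dictated by the statistic's
definition and is config-free because only comparisons against
configurable thresholds consume it. The inter-community ratio
$r = (k - \kappa)/k$ runs from 0 (purely local) to 1 (purely bridging).
Role thresholds default to $z_c = 1.0$, $r_{lo} = 0.3$, $r_{hi} = 0.7$:
classical air-transportation role taxonomies use $z_c = 2.5$, which on
communities of the size a 116-node network produces would make hubs
nearly unattainable; all three cutoffs are arguments.

## Classification

`kmeans_cluster()` is a plain Lloyd iteration: initial means are $k$
distinct data points sampled under the seed, assignment is to the
nearest mean in squared Euclidean distance (ties toward the lower
cluster id), and iteration stops when assignments stop changing. Because
single-initialization Lloyd is notoriously initialization-sensitive, the
default takes the best of 50 seeded restarts; `restarts = 1` reproduces
the single-draw behaviour. `accuracy_rate()` maximizes the matched
fraction over cluster-to-group bijections — cluster indices are
arbitrary, so fixing the identity matching would make the statistic
depend on the initialization; the maximization is exact (permutation
enumeration, $k \le 8$). `classification_sweep()` uses each subject's
modularity at each threshold as a scalar feature with $k = 2$; the
per-subject Q values are computed once (`subject_q_table()`) and shared
with `group_q_curve()`, so the two experiment views can never disagree.
A multi-threshold feature-vector mode was considered and left out:
classification is per threshold by design, and the sweep's argmax is the
reported operating point.

## The synthetic cohort: what it emulates, what it does not

The generator (`cohort_spec()`, `generate_subject()`,
`generate_cohort()`) states a world rather than fitting one, since the
reference setting provides no generative model:

* **Shape.** Defaults: 116 regions × 197 samples at 2 s (the shape of a
  standard resting-state acquisition on the AAL template), cohorts of
  27 controls and 21 cases.
* **Base dynamics.** Regions belong to driver groups (default six, the
  number of communities reported in the motivating analysis). Each
  group's phase wanders with instantaneous frequency clipped to
  0.01–0.08 Hz; each region adds a fixed offset and per-sample
  wrapped-Gaussian jitter (default sd 1.0 rad — moderate within-group
  synchrony), and the signal is the sine of that phase plus Gaussian
  amplitude noise (default sd 0.1, i.e. 10% of the unit carrier).
* **The additional network.** Case subjects only: each connected
  component of the planted edge set gets an extra wandering driver with
  tight jitter (default 0.2 rad). In `"superpose"` mode (default) the
  extra sinusoid is added to the base signal and rescaled — the additional
  network literally superposes the original. In `"replace"` mode
  incident regions are driven by the extra driver alone, with a
  quadrature ($\pi/2$) lag between component members: phase locking is
  near-perfect while the expected Pearson correlation is
  $\cos(\pi/2) \approx 0$, giving an amplitude-uninformative cohort that
  only a phase method can classify. That is the world used for the
  PS-versus-Pearson acceptance claim, and the reason the mode exists.
* **Determinism.** All randomness flows from explicit seeds through an
  RNG-state-preserving scope; same (spec, group, seed) means
  bit-identical output, and the caller's RNG stream is never touched.

What the generator does **not** emulate: hemodynamics (no BOLD forward
model, no hemodynamic response), spatial structure (no voxels, no
smoothing-induced dependence between neighbouring regions), physiological
confounds, scanner drift, or realistic 1/f noise. A green test therefore
establishes that the estimators and the inference chain behave as
specified on phase-coupled oscillator data — not that any particular
neurobiological claim holds on real fMRI.

## Numerical choices, degenerate inputs

* Phases: FFT-based Hilbert transform; linear detrend + demean before
  phase extraction (mirroring standard preprocessing); constant signals
  are a hard error naming the offending region.
* PLV is clamped to $[0,1]$ against rounding; the network matrix is
  symmetrized by averaging to kill last-ulp asymmetry from the
  vectorized outer product.
* Degenerate t-test cells: both samples constant and equal report
  $p = 1$ on both sides (no evidence); constant but different report
  certainty in the observed direction.
* Edgeless networks: modularity is undefined (error) at the API level;
  the experiment drivers instead record $Q = 0$ with a flag, keeping
  subjects in group averages.
* Thresholds at exact weight values: the strict `>` rule decides; ties
  in k-means nearest-mean assignment go to the lower cluster id; merge
  ties in community detection are broken by the run's seed.
* Seeds derived from user seeds stay below $2^{31}$.

## Known limitations

* The PS network scales quadratically in regions and uses dense
  matrices; fine for hundreds of regions, not for voxel-level graphs.
* Greedy-plus-refinement modularity maximization is exact only against
  small-graph exhaustive search; at 116 nodes it is a heuristic like
  every practical modularity maximizer, and the per-$k$ curve is the
  agglomerative snapshot (refined), not a constrained global optimum.
* No n:m synchrony networks, no wavelet/linear-phase alternatives, no
  weighted-graph metric generalizations, no permutation-based
  network-level inference — deliberately out of scope.
* One-tailed testing without correction is reported as-is; the
  calibration criterion documents its false-positive rate rather than
  hiding it.
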