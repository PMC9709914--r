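---
title: "Radial and diametral threshold clustering of molecular conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial and diametral threshold clustering of molecular conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmsdclust)
```

## The problem

A molecular-dynamics trajectory delivers thousands of configurations of the
same molecule. To talk about *conformers* — structural states the molecule
visits repeatedly — one partitions the configurations into clusters using a
pairwise similarity metric, almost always the root-mean-squared difference
(RMSD) of selected atomic Cartesian coordinates after optimal rigid-body
superposition. `rmsdclust` implements the two classic iterative
maximal-neighborhood algorithms used for this purpose, together with the
metric layer they consume and diagnostics for choosing the one quantity that
really matters: the threshold.

## The two algorithms

Both algorithms scan a precomputed symmetric RMSD matrix. At iteration $m$,
every configuration still unassigned ("available") acts as a candidate
*seed* proposing a *tentative cluster*; the largest proposal is promoted to
be cluster $m$ and its members are removed. Iteration stops when nothing is
available or the newest cluster falls below `min_size` (the undersized
winner is not emitted; whatever remains is reported as unassigned). Ties
between equally large proposals are resolved by an injectable rule `f`,
by default the lowest seed index.

The algorithms differ only in how a seed $k$ proposes members:

* **RTC (radial threshold)**: the proposal is the seed's radial
  neighborhood $\{i : \mathrm{rmsd}_{ki} < \theta_r\}$. Membership is a
  relation to the seed only, so transitivity is not guaranteed: two members
  can be up to (but never reach) $2\theta_r$ apart.
* **QTC (quality/diametral threshold)**: the proposal is grown greedily
  from the seed; at each step the available configuration whose inclusion
  increases the cluster *diameter* (largest pairwise RMSD) the least is
  added, provided the diameter stays strictly below $\theta_d$. Every
  member pair therefore satisfies the threshold and the final diameter is
  guaranteed below $\theta_d$.

Strict inequalities are used throughout; a distance exactly equal to the
threshold excludes the candidate. Exact ties during greedy growth (two
candidates yielding the same resulting diameter) go to the lower frame
index; floating-point values are compared exactly, without an epsilon,
which keeps runs bit-reproducible.

Two implementation notes. First, the greedy growth only ever inspects the
seed's radial neighborhood at $\theta_d$: a configuration at
$\mathrm{rmsd} \ge \theta_d$ from the seed can never join a set of diameter
$< \theta_d$ containing the seed, so this restriction is a pure
optimization (the test suite checks it against an unrestricted-pool
re-simulation). Second, the diameter is maintained incrementally — adding
candidate $c$ updates it to $\max(\text{current}, \max_j
\mathrm{rmsd}_{cj})$ — and the tests compare this against from-scratch
recomputation.

### Properties worth knowing

* With `min_size = 1` the clusters always partition the frames.
* RTC cluster sizes never increase with rank: the winning proposal is a
  maximum over a pool that only shrinks. For QTC this can fail: greedy
  growth from a seed can be derailed by configurations that an earlier
  cluster later removes, so a later cluster may outgrow an earlier one.
  It is rare in practice; the test suite scans random instances until it
  observes such an inversion and keeps it as a regression case.
* An RTC cluster's diameter is bounded by $2\theta_r$, but on simulation
  data it stays well short of that bound. The `pair_sum_angle()`
  diagnostic shows why: pairs of members whose seed-distances sum to
  nearly $2\theta_r$ almost never sit at an angle near 180 degrees in
  coordinate space.
* On dense data with few voids, RTC at $\theta_r = \theta/2$ and QTC at
  $\theta_d = \theta$ produce *closely* matched leading cluster sizes. In
  our experiments on structureless 2-D fixtures (uniform disk, broad
  Gaussian, correlated-walk clouds) the leading QTC clusters run a few
  elements (roughly 3–10%) larger than their RTC counterparts,
  systematically: the diametral constraint pins only the diameter, so the
  effective search region may sit off-center from the seed, while the
  radial ball is anchored on a data point. Exact size equality should
  therefore not be expected on continuous data — only on data whose
  density islands are captured whole by both algorithms.

## The metric layer

`superpose()` computes the optimal least-squares rigid superposition
(Kabsch, via singular value decomposition) restricted to proper rotations
— the determinant sign of the rotation is corrected so mirror images are
never matched by reflection. The residual is evaluated explicitly rather
than through the singular-value identity, which cancels catastrophically
near zero RMSD. Degenerate inputs (single atom, collinear atoms) return a
valid minimizer. `pairwise_rmsd_matrix()` offers two modes:

* `pairwise_fit` (default): every pair is superposed independently;
* `prealigned`: RMSDs are taken on the stored coordinates, appropriate for
  trajectories already fitted to a common reference and for abstract point
  clouds (where the "RMSD" is just Euclidean distance scaled by
  $1/\sqrt{n_a}$).

`pairwise_fit` entries can never exceed `prealigned` ones. RMSD is
mass-unweighted — every selected atom counts equally — and all lengths are
nanometres; PDB and DCD coordinates (angstrom) are divided by 10 on read.

## Choosing a threshold

The threshold is the scientific decision, and the package formalizes one
defensible heuristic rather than a trial-and-error loop. Query the space
first: take the seeds of the most populated clusters from a first, rough
radial clustering, and look at each seed's full RMSD distribution to all
other frames (`seed_profile()`, a row of the matrix). Such profiles
typically show a first layer of close neighbors, then a trough where the
probability density collapses — a shell of conformational transition —
before the rest of the ensemble appears.

`suggest_radial_threshold()` locates that trough: the density histogram
(default bin width 0.005 nm, chosen to resolve structure at the scale of
typical backbone-RMSD distributions) is smoothed with a 3-bin moving
average, the first mode is found, and the trough is the first later bin
whose density drops below 5% of the mode's peak or sits in a strict local
minimum; if neither happens the end of the support is used. All three
knobs (`bin_width`, `smooth_window`, `drop_frac`) are arguments. The
consensus over several profiles is the **maximum** of the per-profile
troughs — the smallest radius at which *no* profile's density has
recovered — which is one concrete formalization of picking a value where
the density "has not yet come back" across all panels; other reasonable
consensus rules (median, mean) differ little on clean profiles. Note that
this information is radial in nature: it yields a value for $\theta_r$,
not for $\theta_d$.

```{r threshold-demo}
fix <- generate_planted_ensemble(3, 100, n_atoms = 5, intra_spread = 0.02,
                                 min_separation = 0.5, rng_seed = 1)
m <- pairwise_rmsd_matrix(fix$ensemble, "prealigned")
profiles <- lapply(c(1, 101, 201), function(s) seed_profile(m, s))
suggest_radial_threshold(profiles)
```

## Cluster geometry diagnostics

For each cluster the package reports its diameter (`cluster_diameter()`),
its radius of gyration, the seed-to-centroid RMSD, and the within-cluster
RMSD distribution (`intra_cluster_distribution()`, where a split/bimodal
shape flags a cluster that merged two populations). The centroid needs a
frame convention: members are least-squares fitted onto the *seed* — the
one configuration every member already relates to — before coordinate-wise
averaging (`fit = FALSE` skips this for prealigned or point-cloud data).
The radius of gyration is the population (divide-by-$|C|$) RMS deviation of
members from that centroid, in RMSD units, so for an isotropic Gaussian
cluster with per-coordinate spread $\sigma$ it converges to
$\sigma\sqrt{3}$.

A practical warning these diagnostics quantify: the seed is *not* the
cluster's geometric center. QTC seeds especially tend to sit near the
cluster boundary, because greedy growth is steered by the local point
distribution around the seed and proceeds in eccentric layers away from
it. On planted fixtures the seed-to-centroid distance of QTC clusters
exceeds that of matched RTC clusters in the large majority of cases —
the suite asserts this as a majority vote over 25 planted clusters, not
per-cluster, since individual clusters can tie or reverse.

`coverage_report()` summarizes the ranking's upper end: for each size
cutoff, how many clusters reach it and what share of all frames they hold.

## Synthetic fixtures

Everything above is exercised without external data by two generators,
both driven by an explicit integer seed of R's Mersenne-Twister (with
inversion sampling for normals), restoring the caller's RNG state —
identical seeds give bit-identical output.

* `generate_planted_ensemble()` plants `k` well-separated Gaussian
  clusters: centers are rejection-sampled in a hypercube until every pair
  is at least `min_separation` apart *in RMSD units* (the hypercube side is
  four times the Euclidean separation, roomy enough that rejection rarely
  triggers in three or more dimensions); members are isotropic Gaussian
  draws with per-coordinate spread `intra_spread`; optionally the first
  member of each cluster is the exact center. Ground-truth labels are
  returned for recovery scoring. Intra-member RMSDs then concentrate
  around `intra_spread * sqrt(6)` and cross-cluster RMSDs around
  `min_separation`, so any threshold inside that gap recovers the planted
  partition exactly (adjusted Rand index 1) — the acceptance suite uses
  spread 0.02 nm, separation 0.5 nm, three clusters of 100.
* `generate_2d_mixture()` produces desk-scale planar point sets — a
  uniform disk (dense, structureless; defaults: 1501 points, radius 10,
  matching the scale at which thresholds around 1–2 distance units give
  clusters of a few dozen points), a broad Gaussian, or Gaussian blobs —
  wrapped by `points_ensemble()` as single-atom frames so the prealigned
  "RMSD" is planar Euclidean distance.

What these fixtures do **not** emulate: molecular structure (bonds,
excluded volume), Boltzmann weighting, and the temporal correlation of
real trajectories. Passing recovery tests on planted Gaussians therefore
says the algorithms and thresholds behave as specified on clean geometry,
not that any particular biomolecular ensemble will show so clean a gap;
on real data the seed-profile trough is the empirical stand-in for the
planted gap.

`project_to_2d()` (fit every frame to a reference, keep one atom's x, y)
and `subsample()` (every `stride`-th frame from `start`) mirror how such
planar examples are extracted from real trajectories; a 6001-frame
trajectory subsampled 1-in-4 from the first frame gives 1501 points.

## The tau-polypeptide benchmark

`reproduce_tau()` runs the full pipeline on the publicly available
6001-frame tau-polypeptide trajectory (BitQT example files): backbone N,
H, CA, C, O atoms of residues 2–11 (50 atoms), pairwise-fitted matrix,
RTC at 0.12 and 0.17 nm and QTC at 0.20 and 0.25 nm, with `min_size = 1`
so all 6001 frames are assigned (the minimum-size rule these analyses used
is not documented; 1 is the only choice that assigns every frame). It
reports total cluster counts, first-cluster diameters and coverage at the
10- and 100-member cutoffs. The trajectory itself is several megabytes of
binary data and is not shipped; the corresponding acceptance test states
where to place the files. Since the distributed trajectory is pre-aligned,
`mode = "prealigned"` is also meaningful and the harness exposes the
choice.

## Numerical and design choices

* Thresholds and RMSDs are `double`; ties are exact floating-point
  equality. Seeds are evaluated in ascending frame order, but outputs
  depend on that order only through the tie rule `f`.
* The clustering loops are small C++ kernels (the greedy growth is
  quadratic per seed); a pure-R driver handles non-default `f`. Both are
  cross-checked against independent plain-R re-simulations.
* The matrix cache stores the upper triangle with a header (N, atom
  count, mode, selection); the binary variant round-trips bit-exactly,
  the text variant at full `%.17g` precision.
* Human-readable tables use 1-based frame numbers (stated in their
  headers); rank 0 denotes unassigned frames.
* Problem sizes in the tests and acceptance script (matrices up to
  N = 60, 1000 oracle instances at N ≤ 12, 1501-point planar fixtures,
  300-frame planted ensembles) were chosen as the smallest scales at
  which every property is non-trivially exercised.

## Limitations

* No periodic-boundary treatment, no mass/occupancy weighting, no
  internal-coordinate metrics; superposition is plain least squares.
* XTC trajectories are not read (PDB and DCD are); convert externally.
* The greedy growth is one member of the family of diametral selection
  procedures; alternatives (time-sequence growth, maximal-subset search)
  satisfy the same diameter guarantee but produce different clusters and
  are not implemented, though the per-iteration API (`qtc_grow`,
  `qtc_iteration`) makes experimenting straightforward.
* The trough heuristic assumes the profiles actually show a first layer
  and a gap; on featureless profiles it falls back to the end of support
  and the suggestion should be treated as an upper bound, not an answer.
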