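# rmsdclust

Conformational clustering of molecular-structure ensembles — for example
the frames of a molecular-dynamics (MD) trajectory — using the pairwise
root-mean-squared difference (RMSD) of selected atomic Cartesian
coordinates as the similarity metric. The package is aimed at people who
analyze simulation ensembles and need clusterings whose geometry they can
defend: which algorithm was run, with which threshold, and why that
threshold is physically meaningful.

## What it implements

Both classic iterative maximal-neighborhood algorithms over an RMSD
matrix, exactly and reproducibly:

* **RTC — radial threshold clustering.** At each iteration every
  still-unassigned frame proposes its radial neighborhood
  {i : rmsd(seed, i) < θ_r}; the largest proposal becomes the next
  cluster and is removed. Membership is a relation to the seed only, so
  cluster diameters can approach (never reach) 2·θ_r.
* **QTC — quality (diametral) threshold clustering.** Each candidate
  seed grows a tentative cluster greedily, always adding the frame that
  extends the cluster *diameter* (largest pairwise RMSD) the least while
  the diameter stays strictly below θ_d; the largest grown set wins.
  Every member pair satisfies the threshold, so the diameter is
  guaranteed below θ_d.

Ties between equally large proposals are broken by an injectable rule
(default: lowest frame index), iteration stops when frames run out or a
new cluster falls under `min_size`, and all runs are bit-reproducible.

Around the algorithms:

* optimal least-squares (Kabsch) superposition restricted to proper
  rotations, and pairwise RMSD matrices (`pairwise_fit` or `prealigned`
  mode) with a documented text/binary cache format;
* threshold diagnostics: per-seed RMSD distributions and a consensus
  "trough" detector that turns them into a radial threshold;
* cluster geometry: diameter, radius of gyration, seed-to-centroid RMSD,
  seed-pair distance/angle records, within-cluster RMSD distributions,
  coverage statistics;
* reproducible synthetic generators (planted Gaussian clusters with
  ground-truth labels; structureless 2-D point sets);
* PDB/DCD reading with residue/atom-name selection (angstrom converted
  to nm on read), a `run_pipeline()` orchestrator writing TSV artifacts,
  and a thin command-line front end (`exec/rmsdclust`) with subcommands
  `matrix`, `cluster`, `suggest-threshold`, `diagnose`, `simulate`.

## Worked example

Plant three well-separated Gaussian clusters, let the package propose a
radial threshold from the seeds' RMSD profiles, and cluster at it:

```r
library(rmsdclust)

fix <- generate_planted_ensemble(3, 100, n_atoms = 5, intra_spread = 0.02,
                                 min_separation = 0.5, rng_seed = 1)
mat <- pairwise_rmsd_matrix(fix$ensemble, mode = "prealigned")

profiles <- lapply(c(1, 101, 201), function(s) seed_profile(mat, s))
suggest_radial_threshold(profiles)
#> suggested radial threshold: 0.0575 nm (consensus of 3 profiles)
#>  seed trough   peak peak_density
#>     1 0.0575 0.0325     16.72241
#>   101 0.0575 0.0325     15.38462
#>   201 0.0575 0.0325     17.39130

res <- cluster_rmsd(mat, 0.0575, kind = "radial")
res
#> RTC clustering: 300 frames, threshold 0.0575 (radial), min_size 1
#>   3 clusters, 0 unassigned
#>   sizes: 100 100 100
```

The profiles' first density mode (intra-cluster RMSDs, peaking at
0.0325 nm ≈ `intra_spread * sqrt(6)`) collapses into an empty trough at
0.0575 nm, well before the cross-cluster distances near 0.5 nm; clustering
at the suggested radius recovers the planted partition exactly. Geometry
of the first cluster:

```r
cluster_diameter(mat, res$clusters[[1]])
#> [1] 0.08017865
radius_of_gyration(fix$ensemble, res$clusters[[1]], fit = FALSE)
#> [1] 0.03435568   # ~ intra_spread * sqrt(3)
```

For real data, replace the generator with
`load_ensemble("topology.pdb", "trajectory.dcd", residues = c(2, 11),
atoms = c("N", "H", "CA", "C", "O"))` and use the default
`pairwise_fit` matrix mode; `reproduce_tau()` bundles exactly that
workflow for the public 6001-frame tau-polypeptide trajectory.

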