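# bindscape

Trajectory analysis for receptor–ligand association simulations, built
around the two-site recognition model of chemokine-family receptors: a
chemotactic protein ligand (chemerin) first engages the receptor's
N-terminal recognition site (CRS1) and subsequently docks onto the
extracellular-loop site (CRS2).  The package provides the complete
analysis chain used to characterise such binding from coarse-grained or
atomistic trajectories, together with synthetic-trajectory generators
whose ground truth is known exactly, so every stage is testable without
any simulation engine or download.

## What it computes

**Collective variables.** The smooth coordination number
`c = Σ_{i∈A} Σ_{j∈B} s(r_ij)` with the rational switching function

    s(r) = (1 − x^n) / (1 − x^m),   x = (r − d0)/r0

(defaults `d0 = 0`, `r0 = 0.9` nm, `n = 6`, `m = 12`, continuous at
`x = 1` via the analytic limit `n/m`), centre-of-mass and minimum
interchain distances, N-terminus–N-terminus distance, and inter-chain
orientation angles.

**Free-energy landscapes.** 2D probability histograms over
(distance, coordination), Boltzmann-inverted as `F = −k_B T ln P`
(in kT or kJ/mol), with masked empty bins, depth-based basin detection,
per-basin frame extraction, and basin free-energy differences
`ΔF = −k_B T ln(p_i/p_j)`.

**Binding kinetics.** Bound/unbound segmentation under the 5 Å
criterion, per-region residue-contact traces, z-scored time-lag
cross-correlation (negative peak lag ⇒ CRS1 precedes CRS2), and
persistence-filtered first-engagement calls.

**Clustering.** GROMOS neighbour-count clustering of structures under a
pairwise-RMSD cutoff (Kabsch superposition on a fit selection), and
density-peak clustering in collective-variable feature space with a
decision-graph centre rule.

**Contact maps.** Residue–residue contact frequencies (strict cutoffs:
4 Å atomistic / 5 Å coarse-grained), persistence thresholding,
signed Δ-contact maps between conformational ensembles, and hotspot
extraction.

**Fluctuations.** RMSD with subset fitting, two-pass per-residue RMSF,
and centre-of-mass tracking of the ligand core over uniformly sampled
(optionally bound-only) frames.

**Ensemble comparison.** Per-frame global descriptors (COM distance,
total contacts, orientation angle) embedded by pooled standardised PCA;
ensembles compared by centroid Euclidean distance and Jensen–Shannon
divergence (base-2, range [0, 1]) over shared 2D histograms.

**Variant triage.** Pathogenicity-score binning
(benign ≤ 0.33 / ambiguous 0.34–0.564 / pathogenic ≥ 0.565), ΔΔG
harmonisation across predictor sign conventions (FoldX/MutaBind2
positive-destabilising vs DynaMut2/DDMut-PPI negative-destabilising,
±2 kcal/mol thresholds), interface-membership flags from thresholded
contact maps, and residue contact-network centralities (degree,
betweenness, closeness).

**Synthetic generators.** A membrane-anchored toy receptor (N-terminal
arm = CRS1, loop ring = CRS2) with a rigid ligand: an i.i.d. pose
mixture with chosen weights (exact stationary ground truth) and a gated
two-site Langevin binder with an induced-fit handover (temporal ground
truth with a first-contact event log).

## Worked example

Sample a mixture of two designed bound poses (weights 0.6 and 0.3) plus
a diffuse unbound state (0.1), build the landscape, and recover the
designed free-energy gap:

```r
library(bindscape)

cx    <- toy_complex()
poses <- default_poses(cx)
spec  <- mixture_spec(poses, c(A = 0.6, B = 0.3), unbound_weight = 0.1,
                      n_frames = 20000, seed = 42)
sim   <- sample_mixture(spec, cx)

d   <- com_distance(sim$trajectory, cx$regions, "RECEPTOR", "LIGAND")
co  <- coordination_number(sim$trajectory, cx$regions, "RECEPTOR", "LIGAND")
fel <- build_fel(d, co, bins = c(60, 60), temperature = 303)
basins <- find_basins(fel, depth = 3)
basins
#> fel_basins: 3 basins (depth 3)
#>  basin    f_min n_bins n_frames probability
#>      1 0.000000      3    11796     0.58980
#>      2 1.110725      4     6001     0.30005
#>      3 4.211292     21     2001     0.10005

basin_delta_f(fel, basins, 1, 2)
#> [1] -0.6758344
```

Basins 1 and 2 are the two bound poses, basin 3 the diffuse unbound
state; the recovered gap −0.676 kT matches the designed
`−ln(0.6/0.3) = −0.693` kT within the multinomial sampling error at
20 000 frames.  The bound fraction recovers the designed 0.9:

```r
md <- min_interchain_distance(sim$trajectory, "R", "L")
classify_bound(md)
#> bound_segmentation: 20000 frames, bound fraction 0.900 (< 0.5 nm), 3565 segments
```

Engagement order on a gated Langevin run:

```r
run <- simulate_langevin(langevin_spec(seed = 7), cx)
t1  <- contact_trace(run$trajectory, cx$regions, "LIGAND", "CRS1")
t2  <- contact_trace(run$trajectory, cx$regions, "LIGAND", "CRS2")
engagement_order(t1, t2)$xcorr
#> lag_correlation: peak 0.325 at lag -1250 -> CRS1_first
#>    negative peak lag => trace1 (CRS1) precedes trace2 (CRS2)
```

`run_pipeline(run_config(...))` chains the stages
(simulate → CVs → landscape → contact map) and writes CSV/JSON outputs
plus a manifest with parameters, seeds and MD5 hashes.

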