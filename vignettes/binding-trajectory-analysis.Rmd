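---
title: "Methods: two-site binding trajectory analysis"
author: "bindscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-site binding trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindscape)
```

## The scientific problem

Atypical chemokine-family receptors such as CCRL2 bind their protein
ligand (chemerin) through a two-site mechanism: the receptor's flexible
N-terminal segment — chemokine recognition site 1 (CRS1) — makes the
first contact, and the ligand subsequently docks onto the extracellular
loops (ECL1–3) that form recognition site 2 (CRS2).  Association
simulations of such systems produce long bead- or atom-resolution
trajectories, and the scientific questions are statistical: where on
the (distance, contact) plane does the complex spend its time, how many
distinct bound poses exist and with what relative stability, which
residue pairs carry the interface, in what order do the recognition
sites engage, and which naturally occurring missense variants fall on
that interface.

bindscape implements that analysis chain as composable R functions over
a plain data model (a particle table plus an `n x 3 x n_frames`
coordinate array, nm units throughout), and pairs it with synthetic
trajectory generators whose ground truth is exact.  The generators are
first-class, tested code: every downstream claim the package makes is
validated by recovering a designed quantity from generated data.

## Collective variables

The coordination number between particle selections A and B is the
smooth contact count

$$c = \sum_{i \in A}\sum_{j \in B} s(r_{ij}), \qquad
  s(r) = \frac{1 - x^n}{1 - x^m}, \quad x = \frac{r - d_0}{r_0},$$

with defaults $d_0 = 0$, $r_0 = 0.9$ nm, $n = 6$, $m = 12$ — the
standard rational switch used in biased-sampling engines.  $s$ is
continuous and differentiable; at $x = 1$ the removable singularity is
evaluated by the analytic limit $n/m$ (a guarded first-order expansion
inside $|x - 1| < 10^{-6}$ avoids 0/0 at machine level), distances
below $d_0$ clamp to 1, and the implementation is verified against a
brute-force double loop at $10^{-10}$ tolerance.  Pairing it with the
centre-of-mass distance disambiguates "spatially close" from "actually
in contact": distance alone cannot distinguish an adjacent but weakly
interacting ligand from a formed interface.

Centres of mass are unweighted geometric centres: coarse-grained beads
carry no masses here, and backbone-only selections make uniform
weighting the faithful choice.  No periodic minimum-image convention is
applied by default — the synthetic systems are unwrapped, and silent
imaging corrupts distances; trajectories from other sources should be
unwrapped before analysis.  The orientation angle between two chains is
the angle between their N→C anchor-vector axes, in degrees.

## Free-energy landscapes

The 2D histogram of (distance, coordination) is normalised to a
probability $P$ and Boltzmann-inverted, $F = -k_B T \ln P$, shifted so
the lowest occupied bin is zero.  Three numerical choices matter:

* **No smoothing.**  The free-energy difference between any two
  occupied bins is then *exactly* $-k_B T \ln$ of their count ratio,
  which is what the recovery tests assert.
* **Masked empty bins.**  An unvisited bin is unknown, not zero-energy;
  it is `NA` in the grid and acts as an infinite barrier for basin
  connectivity.
* **Binning.**  Default 60×60 bins over the observed ranges padded by
  5%: fine enough to separate designed basins, coarse enough for
  trajectory-length series.  Compared ensembles should share bin edges
  (pass `edges`).

Basins are detected by a depth rule: local minima are occupied bins no
higher than any occupied 8-neighbour; each basin is the connected
occupied component within `depth` (default 3 kT) of its minimum, and
touching components merge into the deeper minimum.  Basin free-energy
differences use total basin probability mass rather than minimum bin
energy — the population ratio is the quantity with exact mixture ground
truth, and it is robust to how the jitter cloud spreads over bins.
Energies are reported in kT by default or kJ/mol with
$k_B = 0.008314\ \mathrm{kJ\,mol^{-1}K^{-1}}$ (303 K for the
coarse-grained profile, 300 K atomistic).

## Bound classification and engagement order

A frame is bound iff the minimum interchain particle distance is
strictly below 0.5 nm (the 5 Å criterion; 0.4 nm for atomistic
contacts).  Strict inequalities are used at every cutoff and threshold
in the package, and the boundary behaviour is unit-tested.

Region engagement traces count (ligand residue, region residue) pairs
within the cutoff, once per pair per frame.  Two ordering statistics
are provided:

* `first_engagement()`: the first frame at which a trace stays positive
  for `persistence` consecutive frames (default 5 — enough to
  de-emphasise single-frame brushes at the trace resolution without
  hiding genuine short dwells); earlier engagement wins.
* `lagged_xcorr()`: both traces are z-scored and correlated at lags
  $\ell \in [-L, L]$ with per-lag overlap normalisation $1/(N-|\ell|)$,
  an unbiased comparison across lags.  The sign convention is fixed and
  recorded in the output: a negative peak lag means trace 1 (CRS1)
  precedes trace 2 (CRS2).

`engagement_order()` combines the two.  Its one open parameter is the
lag window $L$: the package defaults to the maximal legal window
$\lfloor (N-1)/2 \rfloor - 1$.  The reason is structural: in two-step
binding the CRS1 trace is often a transient *pulse* (the ligand hands
over to CRS2 and leaves CRS1 range) while the CRS2 trace is a late
plateau, so the correlation maximum sits at a lag comparable to the
gap between pulse and plateau — windows sized to the engagement delay
truncate it and can leave only spurious structure in range.  With the
maximal window the peak-lag sign matched the generator's event-log
ordering in 70/70 benchmark runs across four seed families.

## Conformational clustering

**GROMOS mode.**  Every frame is superposed on a common reference
(frame 1) over a *fit selection*, pairwise RMSD is computed over a
*measure selection*, and the greedy neighbour-count algorithm runs:
repeatedly take the frame with most neighbours within the cutoff as a
centre (ties → lowest index), assign centre + neighbours, remove,
repeat.  Fitting on the receptor core and measuring on the ligand makes
the RMSD a *relative pose* metric, which is what separates binding
orientations of a two-chain complex; mutual pair-by-pair fitting is
available behind `mutual_fit = TRUE` for single-chain use.  The
implementation is tested label-for-label against an independent greedy
reference on 200-frame sets.

**Density-peak mode.**  Features (e.g. coordination and COM distance)
are standardised; local density $\rho_i$ is a Gaussian kernel sum at
scale $d_c$ (the 2nd percentile of pairwise distances), $\delta_i$ is
the distance to the nearest higher-density item.  Centres are chosen by
the decision graph: sort $\gamma = \rho\,\delta$ descending and cut at
the largest multiplicative gap (examining at most `max_centers`
candidates).  A fixed percentile threshold on $\rho$ was rejected after
testing: when two pose basins have unequal spread, the sparser basin's
peak falls below any global density cut and the rule either misses it
or fragments the denser basin.  The gap rule selects the designed
number of centres automatically in both equal and unequal mixtures;
explicit `rho_percentile`/`delta_percentile` thresholds remain
available.  Remaining items join their nearest higher-density
neighbour's cluster in decreasing density order.

## Contact maps and variants

Contact frequencies divide per-pair contact-frame counts by all frames
(default; persistent-fraction interpretation) or by bound frames only —
both denominators are exposed because different questions need
different baselines, and bound-frame frequencies are never smaller.
Thresholding (10% coarse-grained, 25% atomistic profiles) zeroes
entries `<= tau`; Δ-maps subtract two thresholded maps (positive ⇒
enriched in the first ensemble) and are antisymmetric by construction.

Variant triage is rule-based: pathogenicity scores round to three
decimals and bin as benign (≤ 0.33), ambiguous (0.34–0.564), pathogenic
(≥ 0.565), with the residual 0.331–0.339 gap resolved to the nearer
edge; ΔΔG predictions are unified to the positive-destabilising
convention before the ±2 kcal/mol thresholds.  The residue contact
network of a structure excludes sequence-adjacent pairs
(|Δindex| < 2), so centralities reflect tertiary organisation;
betweenness and closeness are normalised within each connected
component and isolated residues score zero.  The network edge cutoff
defaults to 0.5 nm (configurable — published contact-atlas tools do not
state theirs).

## The synthetic generators

The toy complex is a bead model (one backbone bead per residue): a
static receptor — infinite friction, mimicking a membrane-embedded
receptor with restrained termini — with a 31-residue N-terminal arm
(CRS1) above a three-ring helical-bundle stand-in whose top ring is the
loop site (CRS2), and a rigid 40-bead ligand with labelled subregions
(β1-like, loop3-like, C-terminal).  Two generators cover the two kinds
of ground truth, because no single toy model gives both cheaply and
exactly:

**Pose mixture (`sample_mixture`).**  Each frame independently draws a
designed bound pose or a diffuse unbound state (uniform in a spherical
shell outside the receptor's reach) and adds per-bead Gaussian jitter
(σ = 0.03 nm, small against the 0.5 nm contact cutoff).  Defaults
follow the reference study conditions used throughout the tests: pose
weights 0.6/0.3 and unbound weight 0.1, so the bound fraction is 0.9
and the pose free-energy gap is exactly $-k_B T\ln 2$.  Pose A presents
the ligand's β1 face to the loop ring (the dominant-interface
analogue), pose B presents the C-terminal face to the N-terminal arm;
their designed contact pairs are disjoint, which is what the Δ-map and
hotspot tests exploit.

**Gated Langevin binder (`simulate_langevin`).**  Overdamped rigid-body
dynamics of the ligand COM,
$x \leftarrow x - D\,\nabla U\,\mathrm{d}t + \sqrt{2D\,\mathrm{d}t}\,\xi$
(energies in kT), with small random rigid rotations, reflecting walls,
and a soft-core repulsion around every receptor bead.  The potential
implements induced-fit two-step binding:

1. a wide, weak capture funnel (5 kT, 3.5 nm) draws the ligand to the
   CRS1 arm;
2. a narrow docking well (12 kT, 0.7 nm) at a point flanking the arm
   holds it in persistent bead contact — a single wide well cannot,
   because its curvature over the contact shell is a fraction of kT;
3. once docking is confirmed by a 25-step contact streak, a countdown
   of `gate_delay` steps (default 2000) models the conformational
   transition; when it elapses the CRS2 well (14 kT, 0.8 nm) activates
   at a point flanking the loop ring, the CRS1 dock releases, and the
   capture funnel recentres on CRS2 — without the recentring, transfer
   is purely diffusive and occasionally takes thousands of frames;
4. until the transition, a reflecting floor above the loop ring makes
   CRS2 contact geometrically impossible, so the CRS1-before-CRS2
   contact order holds *by construction* (the docked CRS2 position is
   also placed out of CRS1's contact range, so the two sites' traces
   are cleanly separated in time).

The event log records the true first-contact step for each site
regardless of which wells are active.  Numerical safeguards: the time
step (0.02 ns at D = 0.1 nm²/ns) keeps per-step displacements far below
half the repulsion radius (exceeding it in more than 0.1% of steps
raises an instability error), and a hard projection floor at 90% of the
repulsion radius enforces the no-overlap invariant exactly — a spring
stiff enough to do that alone is not integrable explicitly at any
useful time step.

All stochastic operations take explicit seeds; `derive_seed()` expands
one master seed into per-component streams below $2^{31}$.

## Ensemble comparison

Per-frame descriptors (COM distance, total intermolecular residue
contacts, orientation angle) are pooled across all compared ensembles,
z-standardised with pooled mean and SD, and projected on the top two
eigenvectors of the pooled covariance; each component's sign is fixed
by making its largest-magnitude loading positive, so embeddings are
deterministic.  Zero-variance features are dropped with a warning.
Ensembles are compared by the Euclidean distance between their PC
centroids and by the Jensen–Shannon divergence over a shared 2D
histogram (default 30×30 over the pooled range).  The base-2 logarithm
makes JSD range over [0, 1] — the only base on which divergences above
$\ln 2 \approx 0.69$ are possible at all, which published values above
0.7 imply.  Note the finite-sample bias of histogram JSD
(order bins/frames): replicate ensembles of a few thousand frames show
JSD of a few hundredths, not zero.  The joint 2D histogram is the
default; per-axis 1D histograms would discard the correlation structure
that distinguishes binding modes.

## What the tests do and do not show

Passing recoveries on the generators demonstrate that every estimator
is computed correctly and recovers designed stationary and temporal
structure at its expected statistical error (binomial / multinomial
standard errors at 2×10⁴–5×10⁴ frames; problem sizes were chosen as
typical desk-scale analyses: 200-frame clustering sets, 10⁴-frame
ensembles, ten binding replicas).  They do not certify behaviour on
real trajectories: the toy model has a rigid ligand and static
receptor (no internal dynamics, no RMSF structure beyond imposed
jitter), isotropic jitter instead of correlated thermal motion, no
membrane or solvent, pose basins that are well separated relative to
their width, and unwrapped coordinates.  On real data the user owns the
choice of regions, cutoffs (Å quoted values convert via
`angstrom_to_nm()`), bin counts, and basin depth; the shipped `"cg"`
and `"aa"` profiles centralise the conventional defaults.

## Known limitations

* Contact definitions are purely geometric; interaction typing
  (hydrogen bonds, π-stacking, salt bridges) is out of scope.
* No reweighting or kinetic modelling on the landscape; the FEL is a
  population map of the sampled ensemble.
* GROMOS clustering is O(N²) in frames; subsample long trajectories.
* The variant module ingests predictor outputs; it never runs the
  predictors, and solvent accessibility is accepted only as an
  optional external column.
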