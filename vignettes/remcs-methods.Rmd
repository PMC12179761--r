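---
title: "Microcluster identification and weighting: methods and defaults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microcluster identification and weighting: methods and defaults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind the `remcs` pipeline, the default
parameter choices and why they were made, and the design of the synthetic
fixture used for validation.

## The model

The pipeline treats a solvated-solute MD trajectory as a mixture of a small
number of *microcluster states*: recurring geometries of the solute plus its
tightly bound first-shell solvent molecules. The goal is to identify those
states without manual inspection and to attach a statistical weight (the
fraction of simulation time spent in each) so that per-state spectra can be
combined into an ensemble spectrum.

Key assumptions:

* **Stationarity.** Frame weights estimate state probabilities only if the
  trajectory samples a stationary distribution. `convergence_check` splits
  the trajectory into blocks and compares per-block basin weights; large
  deviations flag insufficient sampling rather than a pipeline failure.
* **Fixed composition after extraction.** Essential dynamics needs the same
  number of coordinates in every frame. EMCS and rEMCS therefore keep a
  fixed *count* of solvent molecules per frame (slots), even though the
  *identity* of the molecules filling the slots changes from frame to frame.
  Slot coordinates are ordered deterministically (metric rank for EMCS;
  center order, then distance rank, for rEMCS) so that equivalent geometries
  map to nearby points in coordinate space.
* **Separable solute and shell dynamics.** The roto-translational fit uses
  the solute atoms, so the essential eigenvectors describe solvent motion
  relative to the solute frame (plus internal solute motion if present).

## Stage-by-stage description

### EMCS: ellipsoid extraction

Per frame, the solute's gyration tensor is diagonalized; its eigenvectors
are the ellipsoid axes and the square roots of its eigenvalues set the shape.
The semi-axes are scaled up (if necessary) so every solute atom is enclosed,
then a padding is added to each semi-axis. Solvent molecules are ranked by
the ellipsoid metric of their center of geometry — `m(x) < 1` is inside —
and the `M` smallest-metric molecules are kept. Exact ties break toward the
lower molecule id. With a periodic box, minimum-image convention is applied
relative to the solute center before ranking, and the stored coordinates are
the wrapped images.

* **padding = 3 Å.** Approximately one water diameter beyond the solute
  surface: the ellipsoid then covers the first solvation shell without
  reaching deep into the second. For a solute with a degenerate gyration
  axis (planar or linear), the padding alone sets that semi-axis, which
  keeps the ellipsoid well defined.
* **scale = 1.** The enclosing expansion is a hard guarantee, not a tuning
  knob; anisotropy handling comes from the tensor itself.
* **`M`.** The number of retained molecules is a study decision, not a
  fitted quantity. `determine_M` reports the median (or mode/min) of the
  per-frame inside counts as a starting point; extraction itself is purely
  rank-based, so `M` may be set explicitly to any feasible value.

### rEMCS: reduction to aggregation centers

Aggregation centers are small solute atom groups expected to bind solvent
strongly (for a zwitterionic amino acid: the two carboxylate oxygens as one
center, the ammonium nitrogen as another). Per frame, every (center,
solvent) distance is computed — minimum atom–atom distance by default, or
centroid–centroid with `distance_mode = "com"` — all pairs are sorted
globally in ascending order, and molecules are assigned greedily to at most
one center until each center holds its `n_retain` molecules. The global
sort resolves conflicts deterministically: when one molecule is nearest to
two centers, the closer center wins and the other takes the next available
molecule. Ties break by center order, then slot order.

The greedy pass is not guaranteed to minimize the *total* assigned distance
in adversarial geometries, but it is deterministic, order-independent, and
coincides with the exhaustive optimum whenever the shells around different
centers are spatially separated — the regime the method is intended for.
The test suite checks both properties (scan-oracle equivalence everywhere,
exhaustive-optimum equivalence on separated fixtures).

### Essential dynamics

Frames are Kabsch-fitted (SVD with reflection correction, so the rotation is
always proper) on the solute atoms onto the first frame, the population
covariance (1/N) of the fitted Cartesian coordinates is diagonalized, and
frames are projected onto the eigenvectors. Eigenvalues below 1e-12 are
clipped to zero; each eigenvector's sign is fixed so its largest-magnitude
component is positive, making results reproducible across LAPACK builds.

* **Variance fraction 0.6.** `essential_count` reports the smallest number
  of eigenvectors whose cumulative variance fraction reaches 60 %
  (boundary inclusive) — the usual working rule for calling a subspace
  "essential". The landscape stage uses the first one or two eigenvectors
  directly and does not depend on this threshold.

The central empirical claim — rEMCS *steepens* the eigenvalue spectrum
relative to the unreduced EMCS cluster — follows from removing the loosely
bound molecules whose diffusive motion spreads variance over many modes. On
the synthetic study fixture the first two eigenvectors carry about 95 % of
the reduced cluster's variance versus about 26 % for the `M = 10` EMCS
cluster.

### Free-energy landscape and basins

Projections on the chosen essential eigenvectors (first two by default) are
histogrammed; the range is expanded by 2.5 % per side so extreme frames do
not sit on the boundary. Bin free energies are ΔG = −kT ln(n/n_max), with
empty bins capped at (max occupied ΔG) + 1 kT. Basins are found by
steepest descent on the bin grid (plateaus resolve toward the lower linear
index); basins separated by saddles shallower than `min_depth` merge.
Frames in bins above `g_cut` are excluded, and basin probabilities are
either fractions of all frames or renormalized over retained frames.

* **n_bins = 64 per dimension.** At the study scale (10⁴–10⁵ frames, 1–2
  dimensions) this resolves well-separated minima while keeping occupied
  bins populated enough for stable Boltzmann inversion.
* **min_depth = 1 kT.** A barrier below thermal energy does not separate
  states on the trajectory timescale, so sub-kT saddles merge their basins.
* **g_cut = 4 kT.** Frames more than 4 kT above the global minimum
  (relative population < e⁻⁴ ≈ 2 %) are transition-region noise; excluding
  them stabilizes the representative-structure choice. `renormalize = TRUE`
  restores a probability distribution over the retained frames.
* **Representative frame.** The member frame nearest the basin's mode-bin
  center — an actually sampled geometry, not an average, so it can be fed
  directly to quantum-chemistry input generation.

### Spectra

Stick spectra (signed rotational strengths at wavenumbers) are broadened
with Gaussian profiles defined by their **1/e half-width** Δ:
I(ν₀ ± Δ) = I(ν₀)/e, so one band integrates to R·Δ·√π. The default
Δ = 7 cm⁻¹ reproduces typical solution-phase VCD linewidths in the
1200–1500 cm⁻¹ region. Composite spectra are probability-weighted sums on
a common grid; `normalize_spectrum` rescales to max |I| = 100, and
`spectrum_rmsd` linearly resamples both spectra onto the comparison window,
normalizes each, and returns the root-mean-square difference — making the
score independent of absolute intensity calibration.

### QM glue

`build_constraints` expresses each retained solvent molecule in a
mass-weighted solute body frame: spherical coordinates (r, θ, φ) of the
solvent center of mass, three orientation torsions built from the two
nearest solute anchor atoms, and optional solvent-internal torsions given as
local atom indices (mapped to global indices per slot). Freezing these
coordinates in a partial optimization preserves the MD solvation geometry
while the intramolecular degrees of freedom relax — the usual preparation
for per-cluster VCD calculations.

## The synthetic fixture

`synthetic_spec` / `generate_trajectory` produce a ground-truth ensemble:

* A rigid 13-atom alanine-zwitterion-like solute (so the solute contributes
  nothing to the covariance and all signal is solvent rearrangement).
* Four (by default) bound-water *arrangements* with target weights
  0.15/0.25/0.40/0.20. Each arrangement places 4 waters near the
  carboxylate group and 3 near the ammonium group, stacked outward at radii
  2.3 + 0.8·(i − 1) Å — the 0.8 Å stagger keeps distance ranks stable
  under noise — and the arrangements differ by an out-of-plane tilt of
  0.35·(a − 1) rad (carboxylate waters tilt toward +z, ammonium toward
  −z), giving geometrically distinct, linearly separated states.
* 20 bulk waters uniformly distributed in a 9–13 Å shell, far enough that
  the `M = 10` EMCS extraction keeps all 7 bound waters plus the 3 nearest
  bulk ones.
* Per frame: an arrangement is drawn by its weight, every water gets
  independent rigid-translation noise of σ = 0.15 Å, and the true label is
  stored in `attr(traj, "labels")`. The seed is mandatory; there is no
  unseeded generation.

What the fixture demonstrates: end-to-end recovery of the planted number of
states and their weights (within ±0.02 at 50,000 frames), the steepening
inequality, split convergence, and exact worked-example counts (EMCS
`M = 10` → rEMCS `k = 4 + 3 = 7`). What it does **not** demonstrate:
realistic water–water correlations, exchange kinetics between bound and bulk
water, solute flexibility, or the accuracy of any quantum-chemical spectrum
— the stick spectra used in tests are themselves synthetic. Conclusions
about real systems still require converged MD and reliable VCD calculations.

## Pipeline and CLI

`run_pipeline(config)` executes input → EMCS → rEMCS → ED → landscape/basins
→ constraints → (optional) spectrum assembly from a single list or YAML
config, writing a `report.json`, landscape table, per-basin representative
structures and constraint files, and a run log. The installed script

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "shellpick.R", package = "remcs"))')" run config.yml
```

exposes `run`, `convert`, `synth` and `spectrum` subcommands.
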