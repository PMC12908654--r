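---
title: "Methods: analysing confined-water dynamics with confinedwater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing confined-water dynamics with confinedwater}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confinedwater)
```

Water inside a narrow protein pore — the cavity and selectivity filter of
an ion channel, say — behaves very differently from bulk water: it dwells
longer in constrictions, its dipoles align with the pore axis, its
hydrogen-bond network couples to the pore-lining residues, and its
hindered rotations (librations) sit in the terahertz band, where an
external oscillating field can drive them selectively. `confinedwater`
packages the analyses needed to quantify all of this from simulation
trajectories, together with synthetic-trajectory generators whose
statistical structure is known exactly, so every estimator can be
validated against ground truth before it is pointed at real data.

## Units and data model

Everything internal is nm / ps / amu / elementary charge / kJ mol⁻¹.
Readers convert on ingest (PDB and XYZ are Å-based, GRO is nm-based).
Conversion constants are fixed once in `cw_constants`: 1 kcal = 4.184 kJ,
1 amu Å² = 1.66053906660e-47 kg m², Avogadro 6.02214076e23, and the
electric factor 138.935458 kJ mol⁻¹ nm e⁻² so that two unit charges 1 nm
apart interact with exactly that energy.

A `cw_topology` carries per-atom metadata (name, residue, mass, charge,
LJ ε/σ, donor/acceptor flags, donor-attached hydrogens) plus the (O, H1,
H2) triplets of rigid three-site waters, detected from residue names
(SOL/TIP3/HOH/WAT) and conventional atom names, overridable in the
parameter file. A `cw_trajectory` binds an `n_atoms × 3 × n_frames`
coordinate array, per-frame orthorhombic box edges, and strictly
increasing, evenly spaced time stamps (tolerance 1e-6 ps; a single frame
has an `NA` interval).

Atom indices are 1-based throughout — the native R convention, shared by
the installed structural packages — while residue ids keep the 1-based
file convention. Coordinates are stored exactly as the source provides
them (unwrapped stays unwrapped); minimum-image corrections and wrapping
happen on demand inside each analysis, so residence episodes never break
spuriously at a box boundary. Region membership tests wrap into the
primary box first; this wrapped convention is the documented default
because slab regions are defined in box coordinates.

Parameter files are human-readable YAML keyed by (residue name, atom
name), with glob patterns on atom names. Only the quantities the
pairwise analysis equations need are carried — q, ε, σ, mass, donor and
acceptor flags — deliberately avoiding any force-field file parsing.

## Residence statistics

The central object is the *occupancy episode*: a maximal run of
consecutive frames in which a water's oxygen (the conventional water
centre) stays inside a region. Re-entry starts a new episode. Durations
use the inclusive convention `(end − start + 1) × dt`, so a one-frame
visit counts `dt`. Episodes touching either end of the trajectory are
*censored*: their true length is unknown, so they are excluded from means
(which would otherwise be biased downward) but reported separately. A
slab with no uncensored episode gets an `NA` mean, never a silent zero.

`residence_profile()` tiles the axis with 0.1 nm slabs by default — the
standard slicing for pore-axis residence profiles — and reports per-slab
means, episode counts and time-averaged occupancy density.

Retention around a reference site uses the *continuous-survival*
convention: a water counts as retained at lag τ only if it has stayed
within the cutoff sphere (default 1.0 nm around the per-frame centroid of
the reference selection) at every intermediate frame since the time
origin; curves are averaged over multiple origins. The intermittent
variant (present at origin and at lag, excursions ignored) is available
behind `mode = "intermittent"` and bounds the survival curve from above.
`mean_residence_from_retention()` integrates R(τ) by the trapezoid rule —
for an exponential curve this converges to the time constant — and flags
the result as right-censored (a lower bound) when R at the longest lag
still exceeds 0.05. An exponential-fit estimator is provided as an
alternative because "average residence time from a retention curve" is a
genuine convention split; the integral is the default as it assumes no
functional form.

`frequency_response()` merges labelled runs into a mean-residence-vs-
frequency table with replicate standard errors, with frequency 0 as the
required field-free baseline; the extremum frequencies are reported over
the field rows (the baseline is not a "frequency" in the sweep sense).
Weighting is per episode, not per molecule.

## Orientation statistics

The water dipole μ = Σ qᵢrᵢ of a three-site water lies along the H–O–H
bisector, pointing from O toward the hydrogens; its angle to the pore
axis (+z) is reported in [0, 180]°, not folded, so parallel and
antiparallel alignment are distinguishable. Angular spread uses a
circular statistic — the angular deviation √(2(1−R̄)), bounded by √2 rad
≈ 81.03° — rather than a naive SD, because angles wrap at 0/360.

The H–H vector (H1→H2, minimum-imaged, length ≈ 0.1514 nm for the rigid
geometry) diagnoses rotational freedom. Since the H1/H2 labelling is
arbitrary, each vector is oriented so its first plotted component is
non-negative before histogramming; the per-axis standard deviation of the
components is the broadening proxy (no canonical broadening metric exists
for these distributions, so this choice is documented rather than
derived). One geometric fact worth knowing when interpreting the
histograms: a *wag* rotation happens about the H–H axis itself and
therefore leaves the H–H vector exactly invariant — rock and twist are
the modes the H–H plane distribution can see.

## The librational mode model

Rigid three-site water (O–H 0.9572 Å, H–O–H 104.52°, masses
15.9994/1.008 amu) has three principal moments of inertia through its
centre of mass, assigned to the librational modes by rotation axis:

* **rock** — about the normal to the molecular plane (largest moment),
* **twist** — about the H–O–H bisector,
* **wag** — about the in-plane axis perpendicular to the bisector
  (smallest moment).

For any planar body the perpendicular-axis identity
I_rock = I_twist + I_wag holds exactly, and the package computes the
moments from the geometry (≈ 1.770 / 1.155 / 0.615 amu Å²) rather than
tabulating them. With an orientational well depth E_b the harmonic
oscillator model E_b = ½ I (2πf)² gives mode frequencies
f = (1/2π)√(2E_b/I); E_b is supplied per mole (default 19 kcal/mol,
treated as a plain classical parameter) and converted to joules per
molecule via Avogadro's number. The defaults give ≈ 15.1, 18.7 and
25.6 THz for rock, twist and wag — squarely in the experimental
librational band.

The driven rotor is deliberately a 1-D caricature, not an MD surrogate:
one angular coordinate with inertia I, stiffness k = 2E_b (so the well
depth at 1 rad equals E_b, matching the mode model), viscous damping γ
and torque μ_c·E₀·cos(2πft). In the package's amu/nm/ps/kJ·mol⁻¹ units
the natural frequency √(k/I)/2π comes out directly in THz. The default
damping gives a quality factor of ~10 so the resonance is clearly visible
within tens of picoseconds of simulated time. Integration uses `lsoda`
(rtol 1e-8); the steady-state amplitude is √2 × RMS of the final 40% of
the trajectory (exact for a sinusoid), and every simulation also returns
the closed-form linear-response amplitude
A(ω) = (M₀/I)/√((ω₀²−ω²)² + (γω)²) for cross-checking. The drive must be
resolved by at least 20 steps per period or the call is refused. The
model is noise-free and has no mode coupling or anharmonicity.

## Interactions

Hydrogen bonds use the geometric criterion: donor–acceptor distance
≤ 0.35 nm and angle ≤ 30° with the vertex at the donor (H–D–A), the
convention of the common trajectory-analysis tools; the hydrogen-vertex
variant is a config option since the verbal form of the criterion is
ambiguous. Coulomb and Lennard-Jones group–group energies are bare
pairwise sums with minimum-image distances — mesh electrostatics and
switching functions belong to the simulation engine, not the analysis —
with an optional plain cutoff (full sum by default on analysis-sized
systems). LJ pairs combine by Lorentz–Berthelot (arithmetic σ, geometric
ε), equivalent to the A/B coefficient form with A = 4εσ¹², B = 4εσ⁶.
Whether residue–water energies should be distance-capped is left
configurable with the full sum as the documented default.

The RDF normalises the pair-distance histogram by the ideal-gas shell
expectation at the target's mean density in the full box (bulk
convention), so uncorrelated points give g(r) = 1; a confined-volume
normalisation would change the scale, which is why comparisons should
hold the convention fixed. `r_max` may not exceed half the shortest box
edge (minimum-image validity).

## What the synthetic generators emulate — and what they do not

The generators exist so that every estimator has a recovery target with
known truth; they are pure functions of (parameters, seed).

* **Jump process** (`generate_jump_trajectory`). Each water dwells in a
  0.1 nm z-slab for a geometric number of frames with per-frame exit
  probability dt/τ_s — the discrete-time exponential analogue whose mean
  episode duration under the inclusive convention is *exactly* τ_s — then
  hops to an adjacent slab, cyclically in z (consistent with the periodic
  box; cyclic adjacency keeps the stationary slab occupancy uniform,
  which reflecting ends would not). A continuous-time exponential dwell
  sampled on the frame grid would bias the episode estimator upward by
  about 12% at τ = 0.43 ps and dt = 0.1 ps, which is why the discrete
  realisation is the right generative model for frame-based episode
  statistics. Positions are redrawn uniformly in the slab cylinder each
  frame and orientations are redrawn per frame from the slab's tilt
  field: rotation is deliberately decoupled from translation because the
  two are analysed by separate statistics.
* **Exchange process** (`generate_exchange_trajectory`). Waters leave the
  1 nm sphere around a static reference site permanently with per-frame
  probability 1−exp(−k·dt), so the survival retention curve is exactly
  e^(−kτ) in expectation — the analytic target for the retention
  estimator.
* **Brownian mode** (`generate_brownian_trajectory`). Overdamped Gaussian
  steps with per-slab diffusivity and reflecting walls, for
  Einstein-relation checks and "realistic-motion" smoke tests.
* **Orientation fields** (`generate_orientations`). Dipole polar angles
  are drawn from a von Mises distribution about the configured tilt,
  folded to [0, 180]°, azimuth and roll uniform — an axial
  von Mises(-Fisher style) choice made here because no canonical scatter
  law exists for confined-water tilt; κ = ∞ pins the tilt exactly and
  κ = 0 gives the isotropy-like draw with zero mean axial cosine.
* **Libration** (`add_libration`). A rigid-body rotation of angle
  A·sin(2πft + φ) about the mode axis through each molecule's centre of
  mass, with a random phase per molecule to avoid ensemble coherence.
  Bond lengths and the H–O–H angle are untouched by construction.

What passing tests on these synthetics shows is that the *estimators*
are correct and unbiased at realistic sampling densities. What they do
not show is anything about real channel water: the generators have no
forces, no thermostat, no field coupling (the driven rotor demonstrates
frequency selectivity separately), no protein geometry, and translation
and rotation are independent by construction. Headline effects measured
on real membrane-protein trajectories — percentage changes in
hydrogen-bond counts, residence reductions, retention ratios — appear
here only as configured recovery targets for the estimators, not as
predictions.

## Numerical choices and degenerate inputs

* Minimum-image displacements map each component into (−L/2, L/2];
  orthorhombic boxes only.
* Collinear water geometry makes the dipole direction undefined (error in
  `water_dipoles`) and zeroes one principal moment (warning in
  `principal_inertias`).
* A residence mean below dt cannot be resolved by frame sampling and is
  refused by the jump generator; Brownian steps larger than a slab width
  warn.
* Ties at slab boundaries follow half-open bins [z_lo, z_hi).
* The von Mises sampler is the standard rejection scheme (batch
  vectorised); κ < 1e-8 short-circuits to uniform, κ = ∞ to a point mass.
* `orientation_spread` requires n ≥ 2; identical samples give exactly 0;
  balanced antipodal angle sets give the maximal value √2 rad.

## Problem sizes

The test-suite fixtures are sized for thorough statistics at interactive
cost: the slab-recovery checks use ~1.5×10⁵ episodes (60 waters ×
12 000 frames at dt = 0.1 ps), making the 5% recovery bands several
standard errors wide; retention checks use 1 500 molecules (binomial 99%
bands at three canonical lags, single time origin since multiple origins
share molecules and are correlated); oracle-equivalence checks run 20
random 40-water fixtures against brute-force all-pairs references. The
full suite runs in well under a minute on one CPU.

## Reproducibility

Every generator takes an explicit seed and is byte-reproducible;
`run_synthesize`/`run_analyze` record the artifact version, the MD5 of
the run config and the seed in every output header and in a run
manifest, and identical (config, seed) pairs reproduce identical output
bytes end to end.

## Known limitations

Orthorhombic boxes only; no triclinic support. No Ewald/PME
electrostatics, tapering or polarisable models in the analysis energies.
No rotational autocorrelation spectra or spectral decomposition of
librations from trajectories. The donor-hydrogen attachment rule links
every hydrogen of a residue to each donor heavy atom of that residue —
exact for waters and simple pseudo-residue sites, too permissive for
large multi-donor residues. The H–H spread metric is a proxy, not a
standardised observable.
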