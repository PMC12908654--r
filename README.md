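# confinedwater

Analysis of confined-water dynamics in molecular-simulation trajectories.

Water confined in the narrow pore of a membrane protein — the cavity and
selectivity filter of an ion channel — is nothing like bulk water. It
dwells longer where the pore constricts, its dipoles align with the pore
axis, its hydrogen bonds to the pore-lining residues set the energetics
of permeation, and its hindered rotations (the rock, twist and wag
librational modes) fall in the terahertz band, where an oscillating
electric field can couple to them mode-selectively. `confinedwater` is
an R package for quantifying all of this from trajectories, aimed at
simulators and biophysicists who have (or synthesize) frame data and
want validated, reproducible estimators rather than one-off scripts.

## What it computes

* **Residence statistics** — occupancy episodes of water oxygens in 0.1 nm
  axial slabs (or cylinders/spheres), per-slab mean residence times with
  censoring handled explicitly, axial density profiles, retention
  (survival) curves `R(τ)` around a reference site with the mean
  residence `τ̄ = ∫R(τ)dτ`, and frequency-response tables across
  field-labelled runs.
* **Orientation statistics** — dipole angle profiles along the pore axis
  (`μ = Σqᵢrᵢ`, angle to +z in [0, 180]°, circular spread), H–H vector
  plane histograms with a head–tail sign convention and per-axis spread.
* **Interactions** — geometric hydrogen-bond detection (D–A ≤ 0.35 nm,
  H–D–A ≤ 30°), radial distribution functions with ideal-gas
  normalisation, group–group Coulomb (`f·Σqᵢqⱼ/rᵢⱼ`,
  `f = 138.935458 kJ·mol⁻¹·nm·e⁻²`) and 12-6 Lennard-Jones
  (`Σ4εᵢⱼ[(σᵢⱼ/r)¹² − (σᵢⱼ/r)⁶]`, Lorentz–Berthelot) energies,
  per-residue energy tables, field-minus-baseline differences, and local
  hydration counts within 0.5 nm.
* **The librational mode model** — principal inertias of rigid three-site
  water assigned to rock/twist/wag by rotation axis, harmonic mode
  frequencies from `E_b = ½I(2πf)²`, and a driven damped rotor
  demonstrating resonant frequency selectivity against the closed-form
  linear response.
* **Synthetic generators** — seed-reproducible jump-process, exchange and
  Brownian trajectories with known ground truth (slab residence means,
  tilt fields, exchange rates, librational oscillation), emitted together
  with GRO/XYZ/PDB files, a YAML parameter file and a ground-truth record
  so the whole pipeline runs from files alone.

## Worked example

Generate a pore with a slow constriction and a strong dipole tilt, then
recover both from the trajectory:

```r
library(confinedwater)

librational_table()
#> Librational modes of rigid water (E_b = 19 kcal/mol)
#>   mode I (amu A^2) f (THz)
#>   rock      1.7697    15.1
#>  twist      1.1551    18.7
#>    wag      0.6146    25.6

pore  <- pore_model(z_max = 0.8, slab_width = 0.1, radius = 1)
truth <- ground_truth(slab_residence = c(rep(0.43, 4), rep(0.54, 4)),
                      slab_tilt_deg = 80, slab_kappa = 12)
g  <- generate_jump_trajectory(pore, truth, n_waters = 40,
                               n_frames = 2500, seed = 7)
residence_profile(g$traj, c(0, 0.8))
#> <cw_residence_profile> 8 slabs of 0.1 nm; mean residence 0.482 ps (defined bins)
#>   z_nm   mean_ps n_episodes n_censored density
#> 1 0.05 0.4233911       2595          9  44.112
#> 2 0.15 0.4242991       2568         10  43.748
#> 3 0.25 0.4361686       2563         13  44.932
#> 4 0.35 0.4353906       2560          9  44.668
#> 5 0.45 0.5314161       2521          6  53.752
#> 6 0.55 0.5308356       2549         11  54.340
#> 7 0.65 0.5268348       2657         15  56.372
#> 8 0.75 0.5439144       2662          7  58.076
```

The first four slabs were configured with a 0.43 ps mean residence and
the last four with 0.54 ps; the profile recovers both within a few
percent from ~21 000 episodes, with censored episodes counted apart. The
dipole profile likewise returns the configured 80° tilt:

```r
head(as.data.frame(dipole_angle_profile(g$traj, c(0, 0.8))), 3)
#>   z_nm mean_deg spread_deg     n
#> 1 0.05 79.81988   16.63362 11028
#> 2 0.15 80.11097   16.63512 10937
#> 3 0.25 80.14352   16.62326 11233
```

Exchange kinetics around a reference site, with `R(τ) = e^(−kτ)` as the
analytic target:

```r
rc    <- generate_exchange_trajectory(k = 0.5, n_waters = 800,
                                      n_frames = 80, seed = 3)
curve <- retention_curve(rc$traj, "resname REF", cutoff = 1.0, max_lag = 4)
mean_residence_from_retention(curve)
#> $mean_ps
#> [1] 1.64278
#> $censored
#> [1] TRUE
```

The integral over a 4 ps window is flagged censored — a lower bound on
the true 1/k = 2 ps, exactly as a finite observation window demands.

End-to-end runs (synthesize → analyze → TSV reports with version, config
hash and seed in every header) go through `run_synthesize()` /
`run_analyze()` / `run_sweep_report()` with a YAML run config, or the
thin CLI at `inst/cli/confinedwater.R`
(`synthesize | analyze | librational-table | sweep-report`).

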