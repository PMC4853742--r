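---
title: "A hard-sphere model of transverse ionic currents past single amino acids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hard-sphere model of transverse ionic currents past single amino acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionseqsim)
```

## The physical picture

A polypeptide is pulled, unfolded, through a longitudinal nanochannel of
radius R (35 Å by default). A second, transverse channel crosses it, and an
electric field drives K⁺ and Cl⁻ ions (1 M KCl) through that crossing. The
residue sitting in the intersection blocks part of the conducting
cross-section — the plane y = 0 perpendicular to the transverse flow — so
the measured ionic current carries a geometric and electrostatic signature
of that residue. Because each of the 20 proteinogenic side chains excludes
ions differently, a block of repeated current measurements can identify the
residue, and a sequence of such blocks reads the protein.

`ionseqsim` simulates this device end to end: residue geometry, the ionic
atmosphere around each residue, a hard-sphere reduction of that atmosphere,
Monte Carlo current distributions, and maximum-likelihood identification
error.

## From ion atmospheres to one number per species: the effective radius

The ionic environment of a residue is summarized by proximal radial
distribution functions (pRDFs): the local concentration `g(r)` of each ion
species on 0.5 Å shells, as a function of the perpendicular distance `r`
from the residue's van der Waals surface (the union of its atoms' vdW
spheres, Bondi radii). Using surface distance rather than center distance
keeps the features sharp for irregular shapes. Profiles relax to the bulk
value `g_b` = 1 M by roughly 15 Å.

Ions near the surface also move slower: the transverse flow ratio
`v(r)/v_b` is modeled as a parabola with no-slip at the molecular surface
and at the wall, pinned at its maximum of exactly 1 at
`r_b = (R − r_o)/2`, where `r_o` is the residue's mean surface radius.
Only these three facts — parabolic form, maximum at `r_b`, bulk beyond —
are used; the symmetric parabola is the unique parsimonious choice
consistent with them.

The hard-sphere model replaces the full profile with a single per-species
**effective radius** `r_eff` added to every atomic vdW radius. It is fixed
by an area balance in the measurement plane: writing `A(r)` for the area
that the shell at surface-distance `r` occupies in the plane y = 0, the
excluded area must equal the velocity-weighted ion deficit,

$$\int_{r_\mathrm{eff}}^{r_b} A(r)\,dr \;=\;
  \int_{0}^{r_b} \frac{g(r)}{g_b}\,\frac{v(r)}{v_b}\,A(r)\,dr .$$

Both sides are discretized on the pRDF's own 0.5 Å shell grid (rectangle
rule) and solved by monotone bisection with linear interpolation inside the
bracketing shell (tolerance 10⁻³ Å; ties resolved to the smallest root —
the least-exclusion convention). Degenerate cases are exact: a profile at
bulk everywhere with unit velocity ratio gives `r_eff = 0`; an empty
profile gives `r_eff = r_b`; a profile denser than bulk everywhere is
flagged `overdense` and reported as 0. Because the velocity ratio vanishes
at the surface, even a bulk-level profile yields a substantial effective
radius — concentration structure far from the surface matters more than
tightly bound spikes.

For the packaged LYS fixture the balance gives `r_eff` ≈ 5.2 Å for the
attracted Cl⁻ and ≈ 7.2 Å for the repelled K⁺, the ordering and few-Å
magnitude expected for a positive residue.

## Geometry engine

All areas and volumes are grid computations on deterministic,
origin-centered lattices (no random offsets, so results are bit
reproducible):

* **Shell volumes** (for pRDF estimation from ion frames) count 0.1 Å
  cells by signed surface distance `min_i(|p − c_i| − vdW_i)`.
* **Plane areas** count 0.05 Å cells of the y = 0 plane; the free
  cross-section is the disk of radius R/2, clipped to a z window, outside
  every circle cut by the plane from the inflated atomic spheres. The
  Monte Carlo loop uses an exact row/interval counting kernel (Rcpp) that
  gives cell-identical results to the direct single-structure measurement.
* **The z window** `|z| ≤ terminal_z_extent + 1.9 Å` discards the part of
  the cross-section that neighboring residues (ideal spacing 3.8 Å) would
  dominate. A z slab was chosen over a cone about ±z: the limitation is
  described only qualitatively in terms of half the inter-residue spacing,
  and the slab is the simplest geometry consistent with that. The window
  is re-derived for every sampled conformation from its own terminal
  extent.
* **Mean surface radius** `r_o` averages, over ~10⁵ quasi-uniform
  (Fibonacci) directions, the distance from the origin to the outermost
  crossing of the union-of-spheres surface.

Residue templates are single amino acids with N-terminal H and C-terminal
OH caps in an extended reference conformation, canonicalized with the
backbone centroid at the origin and the N→C direction along +z; they were
built from ideal Chemical Component Dictionary coordinates and are
packaged as plain-text PDB with a JSON sidecar of Bondi radii, so the
radii set is explicit and test-stable. Backbone dihedrals are applied as
rigid rotations relative to the template: the N-side cap hydrogens rotate
about N–Cα by (φ − 180°), the carboxyl group about Cα–C by (ψ − 180°),
then the whole residue rotates about z by the azimuth. Tilt is fixed at 0
(rigid peptide bond).

## Monte Carlo current distributions

Each draw samples (φ, ψ) from a discretized Ramachandran density and an
azimuth uniform on [0°, 360°). The packaged density represents a chain
straightened by a 250 pN pulling force: a two-component truncated-Gaussian
mixture on 10° bins, dominated by the extended-β region (centered near
φ = −151°, ψ = 153°, σ ≈ 12°) with a minor polyproline-II component
(−75°, 150°, σ ≈ 10°), stored as CSV so a measured density can be
substituted. Both ion species share each conformation draw — one physical
configuration yields one current measurement — and the observable is the
summed current

$$I = \sum_{i \in \{K^+, Cl^-\}} q\, g_b\, v_b\, \bar A_i,$$

with `q` the elementary charge, `g_b` converted to number density
(1 M = 6.022 × 10²⁶ m⁻³), `v_b` = 77.23 m/s (a configurable parameter;
its hydrodynamic derivation is not re-done here), and `Ā_i` the free plane
area outside the species-specific effective surface. A point-free window
carries ≈ 143 nA; realistic residues land in the tens of nA. Currents are
histogrammed (100 bins by default) and interpolated with a natural cubic
spline, clipped at zero and renormalized, giving an evaluable PDF plus an
inverse-CDF sampler. Distributions are typically multimodal with the
highest peaks at the ends of the range, because the current is roughly
sinusoidal in the uniformly distributed azimuth.

## Identification error and the sequencing protocol

Identification uses the maximum-likelihood rule on blocks of M independent
measurements: candidate Y's score is the product of its spline-PDF
densities at the M currents, and the block is assigned to the highest
product. The error estimator draws J realizations per true residue and
counts a realization as an error when any wrong candidate scores at least
as high as the truth — a tie counts as an error (Heaviside convention
H(0) = 1, the conservative reading). Densities are evaluated as spline
PDFs, not bin masses; a measurement outside a candidate's support zeroes
that candidate's product, which is exactly the mechanism that makes the
error collapse at large M: with bounded, residue-specific supports, 175
draws almost surely include a value impossible under every wrong
candidate.

At a 100 kHz measurement frequency, M = 175 per residue yields
`floor(100000/175)` = 571 residues/s, and with a 3.8 Å residue spacing a
maximum pulling speed of 3.8 Å × (100000/175) ≈ 217 nm/s.

## What the synthetic pRDF generator emulates — and what it does not

The generator produces smooth profiles
`g(r) = (g_b + attraction peak − depletion well) · contact(r) + noise`:
a Gaussian attraction peak (position ~3 Å, width ~1.3 Å), an exponential
depletion well (decay 1.6–4.2 Å), a universal contact-exclusion factor
`1 − exp(−(r/1.5)²)` that drives every profile to zero at the surface
(real ion atmospheres cannot touch the vdW surface), and small seeded
Gaussian noise (σ = 0.02 M) damped away from the surface so profiles
relax cleanly to bulk well before 15 Å. Signs follow the charge class:
negative residues attract K⁺ and deplete Cl⁻, positive residues the
reverse, hydrophobic residues deplete both, and polar residues are
near-neutral with a weak cation preference (half-weight K⁺ attraction,
0.6-weight Cl⁻ depletion) reflecting their oxygen-rich side chains.

The packaged parameter table (one row per residue and species) was
calibrated so the 20 resulting current distributions are **mutually
distinct**: per-residue depletion depths were solved so that mean currents
are maximally separated (a max-min optimization with credit for width
dissimilarity), subject to the qualitative orderings the physics dictates —
ARG carries the largest currents and GLU smaller currents than the
similar-sized VAL; GLU and ASP sit near their maximum exclusion; large
residues (ARG, PHE, TRP, TYR) produce the broadest distributions purely
through their geometry. One honest consequence of prioritizing
distinctness: within the hydrophobic class some calibrated depletion
depths exceed those of charged residues; this is a fixture-design choice,
not a claim about hydration strength. The fixtures preserve the
phenomenology of molecular-dynamics pRDFs — they do not reproduce any
particular simulation's numbers, so downstream results characterize the
method under realistic, controlled conditions rather than any specific
force field. Passing tests demonstrate the pipeline's correctness and the
method's behavior class (error collapsing below 0.1% by M = 175), not a
guarantee for experimentally measured atmospheres.

## Numerical choices and problem sizes

* Concentration unit mol/L externally, ions/Å³ internally
  (1 M = 6.02214076 × 10⁻⁴ ions/Å³); currents in nA, areas internally m².
* Grid steps: 0.1 Å for 3-D shell volumes, 0.05 Å for plane areas (both
  first-order convergent; halving the step changes results by less than
  the previous refinement).
* The effective-radius integration bound defaults to `r_b`, where the
  velocity profile reaches bulk; the solution is stable to halving the
  shell thickness (< 0.05 Å change).
* Default production scale is 10⁵ Monte Carlo draws per residue and
  J = 1000 error realizations. The test suite exercises the full 20-residue
  pipeline at 2 × 10⁴ draws per residue — distribution supports and the
  M = 175 error are already stable at that size — and smaller geometries
  elsewhere; the acceptance script runs the full 10⁵.
* All randomness flows through named seeds (one per pipeline stage,
  derived from the master seed); artifacts are stamped with an md5 config
  hash, and identical configurations produce byte-identical outputs.
* Configuration files are YAML (or JSON) mirroring `run_config()`
  arguments.

## Known limitations

* Single isolated residues only: no inter-residue sterics, no PRO-neighbor
  dihedral coupling, no solvent structure beyond what pRDFs encode, no
  convolution of neighboring residues' signals.
* The velocity profile's symmetry about `r_b` is an assumption; the exact
  Stokes solution could be skewed by the cylindrical geometry.
* Measurements within a block are treated as independent; real
  measurement autocorrelation would lower the effective M.
* Channel cross-sections are circular; other shapes are expected to
  improve selectivity but are not modeled.
* `v_b` = 77.23 m/s is taken as a parameter, not re-derived.
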