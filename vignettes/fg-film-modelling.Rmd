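---
title: "Modelling NTR uptake by grafted FG-nucleoporin films"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling NTR uptake by grafted FG-nucleoporin films}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

The permeability barrier of the nuclear pore complex is built from
intrinsically disordered nucleoporin domains rich in phenylalanine–glycine
(FG) motifs, grafted at high density to the walls of the central channel.
Planar films of end-grafted FG domains are a tractable bottom-up mimic: one
can titrate nuclear transport receptors (NTRs) over decades of
concentration and measure both the bound amount (an areal density
$\Gamma_{NTR}$, pmol/cm²) and the film thickness. `fgfilm` implements the
two halves of the analysis of such experiments — phenomenological isotherm
fitting, and a coarse-grained equilibrium model of the film with its
calibration against the measurements — plus a seeded synthetic-data
generator so that every stage is testable without access to instrument
data.

## Isotherm analysis

Binding curves are fitted with the Langmuir isotherm
$\Gamma = \Gamma_{max}\, c /(K_{0.5}+c)$ and with the Hill isotherm
$\Gamma = \Gamma_{max}\, c^\alpha/(K_{0.5}^\alpha + c^\alpha)$. A Hill
coefficient $\alpha < 1$ means negative cooperativity: the average binding
strength decreases as the film fills. Fits are unweighted nonlinear least
squares on the linear $\Gamma$ scale (a log-scale option exists; nothing in
the standard treatment prescribes weighting), over the window 0.05–10 µM
where the Hill form describes the data; duplicate concentrations are
averaged first. `two_stage_hill_fit()` implements the two-stage procedure
for curve families: free-$\alpha$ fits to the curves covering the full
window, then the remaining (truncated) curves refitted with $\alpha$ fixed
at the stage-1 mean rounded to two decimals, which stops the limited data
from scattering the other parameters.

Below 0.05 µM binding is independent and $\Gamma/c = PC \times d$ defines a
partition coefficient; `partition_coefficient()` forces the low-c linear
fit through the origin (zero binding at zero concentration is physical) and
uses the mean recorded thickness over the window as $d$ — the data do not
single out another choice. `master_curve_collapse()` overlays
$(c/K_{0.5},\ \Gamma/\Gamma_{max})$ and scores the collapse by the RMS
across-curve dispersion in logarithmic concentration bins.
`motif_stoichiometry()` divides the film's FG-motif content (33 motifs per
Nsp1 domain, 39 per Nup98-glyco, 16 per reg-FSFG) by the bound amount at
10 µM, extrapolated through the Hill fit where that concentration was not
measured.

## The film model

The film model treats an FG domain as a freely jointed chain of beads of
diameter and bond length 0.76 nm — twice the contour length of an amino
acid, so each bead represents two residues, the Kuhn length is 0.76 nm and
the persistence length 0.38 nm, mirroring unfolded polypeptides. Chain
lengths are 300, 260 and 155 beads for Nsp1, Nup98-glyco and reg-FSFG
(matching half the construct length within 5%). NTRs are hard spheres —
4.0 nm for the NTF2 homodimer, 6.0 nm for Importin β — exchanging with an
ideal reservoir whose activity is the bulk number density of the stated
molar concentration (at micromolar concentrations bulk crowding is
negligible). Chains are grafted at 5.5 pmol/cm² (3.3 per 100 nm²) to the
bottom of a cylinder of 100 nm diameter and 120 nm height, with
zero-density boundary conditions at the side walls, hard top/bottom walls
for the polymer, and periodic boundaries in z for the colloids.

Two contact energies control the physics: the FG–FG cohesiveness
$\varepsilon_{pp}$ and the NTR–FG attraction $\varepsilon_{pc}$ (the
colloid–colloid attraction is zero). Attractions have the generic
exponential form $-\varepsilon\, e^{-(r-r_c)/\lambda}$ with a 1 nm decay
length beyond hard contact at $r_c$.

The equilibrium solver is a self-consistent mean-field (density-functional)
treatment assembled from three ingredients:

* **Connectivity** — the exact freely-jointed-chain propagator: each bond
  averages the chain weight over a spherical shell of radius 0.76 nm
  (precomputed interpolation weights on the (r,z) grid; in the laterally
  uniform configuration the shell projects to a uniform distribution over
  $\pm$ one bond length in z). The first bead is confined to the first grid
  layer, laterally uniform.
* **Hard cores** — a local-density Boublík–Mansoori (BMCSL) hard-sphere
  mixture excess free energy over the bead and colloid densities, capped at
  a packing fraction of 0.65 (with a linear penalty beyond) to keep the
  iteration stable.
* **Attractions** — mean-field convolutions of the pair tails with the
  partner densities. The attraction is continued at $-\varepsilon$ through
  the core region (the van der Waals convention). This matters: a
  local-density convolution with $g(r)=1$ and the tail zeroed inside the
  core underweights the contact-shell attraction so strongly that no
  colloid absorption occurs anywhere near the experimentally relevant
  parameter window; with the core continuation the polymer–colloid binding
  onset sits near 0.32 kBT while the polymer–polymer cohesion scale is
  essentially unchanged (the core adds 3.6% to that kernel integral).

Self-consistency is reached by adaptively damped Picard iteration on the
two species potentials (default tolerance $10^{-6}$ kBT on the maximum
potential change, mixing parameter adapted between $10^{-3}$ and 0.25). The
solver is deterministic for a fixed grid and tolerance; the polymer mass is
conserved exactly by construction (canonical normalization). Solutions warm
start from previous fields; a radially uniform solution can seed a full
cylinder solve.

Two grid configurations are used. Isotherm and calibration scans run in the
laterally uniform configuration (one radial cell, no side walls), which
represents the macroscopically planar experimental films and is cheap
enough for parameter scans; the full cylinder (default radial spacing
2.5 nm, 5 nm in the acceptance runs; z-spacing 0.75 nm, height 90 nm in the
study-scale runs) is used for the wall-sensitive observables: the
full-vs-central bound-density comparison and the packing-fraction maps.
These problem sizes are the package's working choices; finer grids change
the reported observables by a few percent (see the grid-refinement
property test).

## Observables

`film_thickness()` defines the local thickness at each radius as the
largest height where the polymer packing fraction still reaches 1%, 5% or
10% of its global maximum, and averages over the cylinder cross-section
with the 2πr weight; the 5% threshold is the working definition and the
three are always ordered. `bound_colloid_density()` integrates the colloid
excess over bulk along z — experiments measure a surface excess — averaged
either over the full 100 nm cross-section or the central 50 nm, whose
comparison quantifies side-wall artifacts. `axial_profiles()` gives the
radially averaged packing-fraction profiles. `contact_energy_estimate()`
is a deliberately rough count of beads touching an embedded colloid: bead
density times the volume of a shell of one bead *radius* beyond hard
contact. (A shell of a full bead diameter — the other obvious recipe —
overcounts by more than a factor of two relative to the published
order-of-magnitude figures of ~26 beads for the 4 nm and ~53 for the 6 nm
colloid, which the half-diameter shell reproduces; only factor-two accuracy
is claimed either way.)

## Calibration

The model is matched to measurements in two steps. `calibrate_epp()`
inverts a cubic interpolation of the computed thickness-per-amino-acid
versus $\varepsilon_{pp}$ (grid 0–0.05 kBT by default) at the measured
NTR-free value; thickness decreases monotonically with cohesion, so the
inversion is unique, and the measured error band propagates through the
same interpolation. Switching the thickness threshold from 5% to 1% or 10%
moves the study-scale estimate by less than 10%. `calibrate_epc()` scans
$\varepsilon_{pc}$ (0.1–0.5 kBT in 0.02 steps, refined to 0.01 near the
optimum) and minimizes $\sum[\log\Gamma_{model}-\log\Gamma_{exp}]^2$ over
13 (9 in the faster acceptance configuration) log-spaced concentrations in
0.025–10 µM, representing the measured curve as a linear law through the
origin below 0.05 µM and the Hill fit above — the same
interpolation/extrapolation used when matching such models to titration
data. Grid points where the film shows no uptake, or where the solver does
not converge, score as infinitely bad; the final estimate interpolates the
objective quadratically around its minimum and quotes half the fine grid
step as the uncertainty.

`sensitivity_scan()` probes the interaction balance at a calibrated
baseline: a 25% reduction of $\varepsilon_{pc}$ at 1.4 µM (fold-reduction
of binding), $\pm 0.01$ kBT bracketing curves, and a 33% increase of
$\varepsilon_{pp}$ followed through an absorption indicator — the mean
colloid excess inside the film (below the 5% thickness) over the peak
excess in the one-colloid-diameter band above it.

## Synthetic data and pseudo-measurements

`generate_isotherm_dataset()` emulates a titration table: the 12-step
concentration grid (0.0025–10 µM), bound amounts following a Hill law with
$\alpha = 0.71$ times lognormal noise of unit mean (optical areal densities
carry roughly constant relative error; 5% is the default), and a thickness
column rising linearly with the bound amount from a 30 nm baseline by 20%
at saturation — inside the 5–35% range such films show. Families draw
$\Gamma_{max}$ from 0.5–5 pmol/cm² and $K_{0.5}$ from 0.3–3 µM
(log-uniform), grafting densities from 4–11 pmol/cm², and truncate three of
ten curves below 0.2 µM. All generators are seeded and leave the global RNG
untouched.

The generator emulates the *statistical* structure of titration tables —
Hill-shaped means, multiplicative noise, truncated ranges — not raw
instrument output (no ellipsometric or acoustic signals), and its curves
are exactly Hill by construction. Tests passing on synthetic families
therefore demonstrate the analysis machinery, not the biology of real
films.

Because the original titration tables are not redistributed here,
calibration correctness is demonstrated by round-trip recovery:
`synthetic_thickness_measurement()` and `synthetic_isotherm_measurement()`
generate pseudo-measurements *from the model itself* at the published
reference parameters (`reference_interactions()`: $\varepsilon_{pp}$ 0.024
kBT for Nsp1, 0.030 for Nup98-glyco and reg-FSFG; $\varepsilon_{pc}$ for
NTF2 0.34/0.36/0.40, for Importin β on Nsp1 0.40), and the calibration
machinery must recover them. These are labelled synthetic throughout: they
validate the inversion, not the functional.

## Monte Carlo oracle

`mc_oracle()` samples the identical physical model — freely jointed
hard-sphere chains with quenched anchor points, grand-canonical colloids,
the same pair tails — by Metropolis Monte Carlo (crankshaft moves for
interior beads, sphere resampling for chain ends, insertion/deletion at
the reservoir activity), restricted to small systems (≤ 20 chains of ≤ 60
beads). It is the independent check on the mean-field solver: phantom
chains reproduce the closed-form end-to-end distance, an empty cylinder
holds an ideal colloid gas at the activity, and on small hard-sphere
brushes the axial density profiles agree with the mean field within 15%
above the anchoring layers (z > 1 nm). In the first two layers the methods
differ systematically by 15–20%: the MC's quenched point anchors and
hard-wall contact correlations have no counterpart in a local-density mean
field with a smeared graft layer, so the comparison region excludes them.

## Known limitations

* The local-density functional produces a colloid isotherm far steeper
  than the measured Hill curves: a film-filling transition sits just above
  the calibrated $\varepsilon_{pc}$, i.e. the mean field shows *positive*
  cooperativity at onset where the experiments show negative
  cooperativity. Calibrated values are therefore least-squares compromises,
  and observables evaluated at the best match sit close to a transition and
  inherit its sensitivity. One consequence: the central-region bound
  density exceeds the full-cylinder average by a factor ~4 (the
  wall-depleted outer annulus underbinds by orders of magnitude), rather
  than the factor < 2 a softer isotherm yields.
* The insertion cost of the hard-sphere colloid grows roughly with its
  volume while the smeared attraction grows with its surface, so the 6 nm
  colloid's binding onset (~0.44 kBT) sits markedly above the 4 nm one's
  (~0.32 kBT) — a stronger size dependence than the measurements imply.
  Its attraction is therefore calibrated on a grid extended to 0.6 kBT.
* Calibrated cohesion for a measured 30 nm Nsp1-like film comes out near
  0.044 kBT; functionals differing in their excess free energy shift this
  scale substantially, so only orderings across constructs, not absolute
  contact energies, transfer between functionals.
* Side-wall boundary conditions are a numerical convention inherited from
  cylindrical-geometry algorithms; the laterally uniform configuration is
  the better mimic of planar films and is used for all isotherm work.
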