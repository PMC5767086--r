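---
title: "Methods: coarse-grained membrane simulation and free-energy analysis with cgmemb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained membrane simulation and free-energy analysis with cgmemb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmemb)
```

## The model

`cgmemb` implements an implicit-solvent coarse-grained (CG) representation
of peptides in lipid bilayers. A peptide is a chain of backbone beads at
the alpha-carbon positions with up to four sidechain beads per residue,
each bead carrying one of five protein site types (`p`, `ap`, `pos`,
`neg`, and the legacy `ca` backbone type used by force-field version 1).
Lipids carry nine types covering choline, phosphate, glycerol, ester and
tail groups. All nonbonded physics lives in *tabulated* pair potentials —
one table per site-type pair, truncated at 1.2 nm — which fold
electrostatics and dispersion into a single distance-dependent function;
there is no explicit water and no long-range electrostatics by
construction. Bonded terms are harmonic bonds, fourth-order polynomial
angle potentials, GROMOS-96 cosine-harmonic restraint angles and harmonic
torsions.

Site-type assignment is version-resolved in the residue templates
(`sidechain_template()`). Version 2.4 makes the backbone polar (`p`)
except for alanine, whose single bead is apolar (`ap`), and reassigns
several sidechain sites relative to version 1: a polar Cδ for Phe, polar
Cγ and Cε for Tyr, a polar Cγ for Trp, polar Cβ for Gln, Arg, Lys, Asp and
Glu, a single polar Asn site on a lengthened 0.26 nm bond, an apolar Cys
site, and a second apolar site for Val. Version 2.3's retired Lys
(p.p.pos), Trp (ap-p-ap-p) and Asn (p-p) descriptions are kept selectable
for comparison. Where the original parameter files would specify exact
atom groupings, the templates are user-overridable; the printed
reassignments above are encoded as defaults.

## Units and key parameters

All quantities use kJ/mol, nm, ps and amu (so 1 amu·nm²/ps² = 1 kJ/mol).
The defaults that matter:

| parameter | default | meaning |
|---|---|---|
| `kT` | 2.24 kJ/mol | effective temperature reproducing liquid-phase bilayer structure |
| `gamma` | 0.5 ps⁻¹ | Langevin friction (implicit solvent) |
| `dt` | 0.005 ps | integration step |
| `cutoff` | 1.2 nm | nonbond truncation, U(cutoff) = 0, no switching |
| umbrella `k` | 350 (sidechain) / 650 (peptide) kJ/mol/nm² | z-restraint between solute and bilayer mass centers |
| windows | 21 at 0.2 nm spacing | sidechain insertion layout, optional duplicate copy 3.7 nm away |
| WHAM bins | 400 | histogram resolution |
| bulk region | \|z\| in [3.2, 3.7] nm | zero reference beyond the head groups |
| helix restraints | θ₀ = 89°, kθ = 2000; φ₀ = 50°, kφ = 2000/rad² | ideal right-handed α-helix |
| regions | 1.0 / 1.8 / 2.8 nm | tail / ester / head boundaries on \|z\| |
| anchors | z = 0, 1.3, 1.7 nm | cyclohexane-, octanol- and interface-like depths |

Bonded force constants and most bond lengths are properties of a fitted
parameter set rather than printed constants; the templates carry generic
defaults (20000 kJ/mol/nm² bonds, 0.38 nm backbone spacing, 0.20 nm
Cα–Cβ) plus the lengths that are structurally meaningful: the short
0.16 nm Cβ–Cγ bond of Leu/Val versus 0.25 nm for Met/Ile, and Asn's
0.26 nm single-site bond. Callers with fitted parameters should override
per term.

## Numerical choices

**Interpolation.** Pair tables are resampled onto a uniform grid (spacing
at most 0.002 nm) ending exactly at the cutoff, shifted so U(cutoff) = 0,
and evaluated through the natural cubic spline of `stats::splinefun`.
Forces are always the analytic spline derivative, never stored, so
F = −dU/dr holds to machine precision; `validate_forcefield()` verifies
this with a central-difference sweep. Below the first grid point the
spline extrapolates linearly, giving a well-defined repulsive wall.

**Integration.** The engine uses BAOAB splitting with an exact
Ornstein–Uhlenbeck velocity substep. The discretization of the original
stochastic-dynamics routine this emulates is not part of the contract —
statistical equivalence is: with γ = 0 the scheme reduces to velocity
Verlet (energy drift below 0.1 % of mean kinetic energy over 10⁴ steps of
a bonded chain in the tests), and with γ > 0 the sampled kinetic
temperature and configurational variances match kT to within the
statistical resolution of the tests. `langevin_step()` applies the
B-A-O-A substeps with the caller's forces; `run_simulation()` completes
each step's trailing half-kick after recomputing forces.

**Random numbers.** A run seeds R's generator once from the protocol seed
and restores the caller's RNG state afterwards; trajectories are exactly
reproducible for a given seed. The engine is single-threaded, so no
counter-based scheme is needed.

**Neighbor search.** A cell list (minimum three cells per dimension,
half-shell offsets) is rebuilt every step and falls back to a vectorized
all-pairs sweep for small systems; the two paths return identical pair
sets and the tests assert it. Exclusions are all 1-2 and 1-3 pairs derived
from the bond graph.

**WHAM.** The self-consistent equations are iterated until the largest
change in any window free energy is below 10⁻⁸ kJ/mol. The window-overlap
precondition is enforced on sampled ranges (adjacent windows must
overlap), not on every histogram bin being occupied — single ragged empty
bins at window edges are benign at finite sampling. A single unbiased
window degenerates exactly to −kT ln(histogram). Split-half errors follow
the workflow's convention: WHAM is run independently on two halves of the
data (the duplicate solute copies where present, otherwise the two time
halves), both halves are zeroed over a common region, and the per-bin
error is half the absolute difference; the *largest error over the bins*
is the summary statistic. Profile symmetrization averages the two leaflet
profiles after reflection and combines errors in quadrature.

**Angle fitting.** `fit_angle_potential()` histograms angles into 90 bins
over (0, π), converts occupied bins to energies by U = −kT ln p̂, and fits
the quartic by least squares weighted by bin counts (the variance of a
log-histogram energy scales as 1/count, so sparse tail bins must not
dominate). Empty bins are excluded, never imputed. No sin θ Jacobian is
applied by default — the distribution is fitted as observed — but
`jacobian = TRUE` removes the solid-angle factor first, since the original
parameterization's convention is not recorded.

**Orientation statistics.** Helix tilt is folded to [0°, 90°] because
leaflet orientation is arbitrary; depths are reported in Å relative to the
per-frame bilayer center of mass (so slow drift of the whole system is
harmless); spreads are population standard deviations over frames, since
they describe the trajectory rather than an inference beyond it.

## The synthetic-data generators

The fixtures module makes every stage testable with no external inputs,
and its defaults are the study conditions:

* `make_toy_pair_table()` builds flat, harmonic or truncated 12-6 tables
  with U(cutoff) = 0 — analytically known landmarks (minimum at 2^{1/6}σ,
  force −k(r−r₀)) for parser and engine tests.
* `build_ideal_helix()` places Cα beads with 0.15 nm rise, 100° twist and
  0.23 nm radius — standard α-helix Cα geometry, chosen so consecutive
  beads sit 0.38 nm apart and backbone torsions fall within 5° of the
  +50° restraint target (the angles sit near 90°, within the restraint
  well around 89°).
* `build_bilayer_slab()` builds two lattice leaflets with tails inward and
  ester beads at ±1.45 nm, so the ester–ester thickness is 29 Å by
  construction; bead depths, chain offsets and template bond lengths are
  mutually consistent, giving a strain-free start in which no two sites
  begin closer than ≈0.4 nm. The builder is deterministic. The slab's
  bonded terms include chain-straightening and ester-splay angles — the
  minimal stiffness that keeps a lipid from folding onto itself — with
  default k = 10 kJ/mol/rad².
* `sample_boltzmann_1d()` draws from exp(−U/kT) by Metropolis walk
  (exact stationary distribution; used for inversion round trips) or by
  overdamped Euler–Maruyama Brownian dynamics (time-ordered paths usable
  as umbrella series; a small step-size bias ∝ dt·U″/γ is kept below the
  statistical noise at the default settings used in the tests). Walkers
  leaving a ±1000 nm domain raise a divergent-potential error. Every
  fixture is a pure function of its arguments plus an explicit seed.

What the toy potentials do **not** emulate: the chemistry-specific shapes
of fitted CG tables, lipid electrostatic screening, or the real DOPC
liquid structure. Passing engine tests on toy tables demonstrates
mechanical correctness (forces, integration, sampling, estimators), not
force-field accuracy; reproducing published PMF features additionally
requires the fitted parameter tables and equilibrated coordinates
distributed with the force field, which are inputs to — not products of —
this package.

## Problem sizes in the tests

The test suite and `scripts/acceptance.R` size their simulations for a
single CPU: 16-lipid slabs run for 1000–1500 steps (temperature control
and stability checks), 125 free or tethered particles for a few thousand
steps (equipartition, fluctuation–dissipation), 15 umbrella windows of
1500 thinned Brownian samples (WHAM recovery), and 10⁵-sample
Metropolis chains (Boltzmann inversion). These sizes were chosen so each
statistical assertion has comfortable resolution — for instance the
equipartition check resolves kT to ~2 % and tests it at 3 standard
errors — while the whole suite runs in about a minute.

## Known limitations

* The tabulated-potential *derivation* (force matching from atomistic
  ensembles) is out of scope; tables are inputs.
* The engine is pure R and vectorized per step; it is sized for desk-scale
  validation (hundreds of sites, 10³–10⁵ steps), not for microsecond
  production runs of 256-lipid boxes.
* Pressure coupling is absent by design (the bilayer model runs NVT).
* `extract_features()` reports every local minimum below −0.5 kJ/mol;
  on noisy profiles adjacent bins can register as separate shallow minima,
  so feature extraction is best applied to converged or smoothed profiles.
* The shipped hydrophobicity table is a synthetic stand-in transcribed
  from primary literature values; analyses intended for publication should
  load the curated experimental table instead.
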