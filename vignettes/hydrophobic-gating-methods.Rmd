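---
title: "Methods: quantifying hydrophobic gating in channel pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying hydrophobic gating in channel pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregate)
```

## The problem

Narrow hydrophobic stretches of an ion-channel pore can close the channel
without any steric occlusion: confined water in the constriction
stochastically evaporates to a vapour-like state, and the resulting dry
zone is an energetic barrier to ion permeation ("hydrophobic gating" or a
"vapour lock"). In K2P potassium channels such as TWIK-1, a ring of leucine
side chains deep in the inner pore — a hydrophobic cuff a few Angstrom
below the selectivity filter — shows exactly this behaviour in molecular
dynamics (MD) simulations, and polar substitutions in the cuff (e.g.
leucine to asparagine) keep the pore wet.

`poregate` quantifies this phenomenon from MD output. It computes:

* **water occupancy** of the gate region over time — the count nH2O of
  water oxygens in an axial slab, its time average mu, the fraction of dry
  frames, dry/wet dwell episodes, and the mutant-minus-WT difference
  delta-mu;
* **normalized water density** on a regular 3D grid (1 = bulk water), the
  standard way to visualize a dewetted zone as a hole in the 0.5-isovalue
  surface;
* **pore radius profiles** in the HOLE maximal-sphere sense, to verify that
  dewetting is not explained by steric closure;
* **1D potentials of mean force** (PMF) for an ion along the pore axis,
  reconstructed from umbrella-sampling windows by WHAM, and WT-vs-mutant
  barrier differences.

Because production MD trajectories are large and rarely redistributable,
the package also ships a synthetic-data module that generates pore
structures, wetting/dewetting trajectories and umbrella windows with
analytically known ground truth. Every analysis stage is validated against
those known answers.

## Coordinate conventions

All analyses work in a pore-aligned frame: z = 0 at the centroid of a
reference selection (for TWIK-1-like channels, the threonines of the S4
ion-binding site, residues 117 and 225 on both chains), z increasing toward
the selectivity filter, the cytoplasmic vestibule at negative z. The axis
is the lab z-axis by default (`axis_mode = "fixed_z"`); for tilted systems
the principal axis of a pore-lining selection can be used instead, with a
hard error when that selection is nearly isotropic. Which atoms of the
reference residues define z = 0 is configurable; the default is the
centroid of all their atoms.

Atom indices are 1-based everywhere inside the package, matching R's
native indexing; file formats keep their own conventions at the I/O
boundary. Coordinates are Angstrom, times ns, energies kJ/mol or kT as
stated.

## Water occupancy of the gate slab

The gate region is the axial slab 5–10 Angstrom below the S4 reference.
The bounds are implemented half-open, `-10 <= z < -5`, so adjacent slabs
tile the axis without double counting. By default only the z bounds define
the region; a cylindrical `radial_cutoff` is available for open simulation
boxes where bulk water would otherwise be counted at gate-slab heights.
Input coordinates are assumed pre-wrapped (periodic imaging is not
applied).

`occupancy_series()` recomputes the pore frame at every frame and counts
water oxygens in the slab; `occupancy_histogram()` normalizes pooled counts
(multiple runs are pooled by concatenation); `summarize_occupancy()`
reports mu, the dry fraction, and dwell episodes — maximal runs of dry
(count 0) or wet frames times the frame interval, with episodes touching
either end of the series flagged as censored. With a partner series it also
reports `delta_mu = mu(self) - mu(partner)`; calling it with the mutant as
`self` gives the conventional mutant-minus-WT sign.

## The synthetic wetting model

The generator emulates the observed two-state switching with the simplest
process that has it: a continuous-time two-state Markov (telegraph) chain
with dewetting rate `k_dry` (wet to dry) and rewetting rate `k_wet` (dry to
wet), sampled exactly at the frame interval (default 0.1 ns, matching the
usual analysis stride). In wet frames the gate slab holds
Poisson(`lambda_full`) water oxygens placed uniformly in the slab volume;
in dry frames it holds none. The default `lambda_full = 12` is the
hydrated inner-pore count of the wet starting structure used for mutant
PMFs. The rest of the pore lumen and a bulk box above the pore carry a
constant background at bulk density (0.0334 molecules per cubic Angstrom),
so density-grid normalization has a known truth. The total atom count is
fixed (unused slab waters are parked on a reservoir plane far below the
pore), which keeps trajectories writable in fixed-atom formats.

What this emulates: bimodal occupancy, exponential-ish dwell times,
Poisson occupancy noise, a known stationary dry fraction
`k_dry / (k_dry + k_wet)`. What it does not emulate: water-water
correlations, partial-wetting intermediates, coupling between pore
geometry fluctuations and wetting, and any force-field physics. Passing
the recovery tests therefore demonstrates the correctness of the
*estimators*, not the realism of any particular MD setup. The rates are
free parameters: dwell-time distributions of the real channel are not
characterized quantitatively in the source experiments, so the defaults
used in tests (rates of order 1/ns) are round values in the range that
produces visible switching on a 100-ns trajectory.

### Recovering telegraph parameters

A state sequence observed every `dt` is the exact discrete skeleton of the
chain. Naive dwell-time estimates (mean observed run length times `dt`)
carry an O(`dt`) discretization bias — up to ~20% at rates of 2/ns and
`dt` = 0.1 ns. `fit_telegraph()` instead inverts the skeleton in closed
form: with self-transition probabilities `p_ww` and `p_dd`,

```
lambda = -log(p_ww + p_dd - 1) / dt
pi_dry = (1 - p_ww) / (1 - (p_ww + p_dd - 1))
k_dry  = pi_dry * lambda,   k_wet = lambda - k_dry
```

which is asymptotically unbiased. Standard errors come from the delta
method on the binomial transition counts; the SE of the time-average dry
fraction uses the chain's autocorrelation `exp(-lambda dt)`. Occupancy
counts can stand in for states because misclassifying a wet frame as dry
requires a Poisson(12) zero (probability ~6e-6).

## Density grids

`water_density_grid()` deposits one count per selected oxygen into its
containing voxel (nearest-voxel binning; the kernel smoothing of common
visualization plugins is unspecified, and plain binning keeps an exact
conservation law: binned deposits + overflow tally = frames x selected
atoms, asserted in the tests). Per-frame-average counts are divided by
voxel volume times bulk density (default 0.0334 per cubic Angstrom), so 1
means bulk water. The default 0.5-Angstrom spacing matches standard
practice; the reported `iso_voxels` is the size of the voxel set at or
above the 0.5 isovalue used for dewetting surfaces. Grids export to
OpenDX scalar fields (z-fastest value order, the OpenDX convention, so
files load in VMD/PyMOL).

## Pore radius profiles

The radius at slice z is the HOLE-style maximal-sphere radius: the largest
`min over atoms (3D distance - vdW radius)` over probe centers constrained
to the slice plane. Spheres are tested with true 3D distances; the slice
only constrains the probe center. Van der Waals radii are assigned by
element (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80; unknown elements
1.70 with a warning) and are configurable — the radius set behind published
HOLE profiles is typically unstated, so the table is deliberately
force-field-agnostic.

The in-plane maximization runs simulated annealing seeded from the
previous slice's optimum (2,000 proposals, initial step 0.5 Angstrom,
step and temperature cooled by 0.9 every 100 proposals, uphill always
accepted), followed by a deterministic Nelder-Mead polish of the best
point. The polish makes the result insensitive to the final annealing step
size, which is what gives rigid-motion equivariance to ~1e-3 Angstrom and
agreement with a dense grid search to <0.05 Angstrom on test pores. The
whole search is seeded and reproducible; ties between equal maxima resolve
to the first encountered under the seeded proposal stream. Off-axis,
curved pore pathfinding is out of scope — the inner pores this targets,
and all synthetic fixtures, are near-axial.

Classification against the conventional 1.2-Angstrom threshold is strict:
`r < 1.2` is `sub_threshold`, `r >= 1.2` is `open` (a radius of exactly
1.2 is open). 1.2 Angstrom is well below the hydrophobic-gating regime
(dewetting occurs at radii below ~6 Angstrom in apolar pores); the point
of the profile here is to show a pore is *not* sterically closed even
while dry.

### Wall-atom placement in the generator

Synthetic pores place wall pseudo-atoms on rings of radius
`r(z) + vdW` so the inscribed probe radius equals the requested wall
radius `r(z)`. Ring discretization adds a small positive bias between
rings (~(spacing/2)^2 / 2R, about 0.02 Angstrom at the defaults) and
sloped walls add a small negative cone bias (~R m^2/2 for slope m); test
fixtures use gentle slopes (|m| <= 0.15) so both effects stay within the
0.1-Angstrom end-to-end tolerance.

## Umbrella sampling and WHAM

Windows are harmonically biased, `U_i(z) = 0.5 k (z - z_i)^2`, with the
reference protocol of 25 windows spaced 1 Angstrom at
k = 10 kJ/mol/Angstrom^2. The restraint is interpreted as acting on the z
coordinate only. kT defaults to 310 K x 0.0083145 = 2.577 kJ/mol;
the temperature is configurable and recorded, since production runs exist
at both 310 K and 323 K.

`wham()` iterates the standard 1D self-consistency equations,

```
P(z_b)        =  sum_i n_i(z_b) / sum_i N_i exp((F_i - U_i(z_b)) / kT)
exp(-F_i/kT)  =  sum_b P(z_b) exp(-U_i(z_b) / kT)
```

with gauge F_1 = 0, renormalizing P every sweep (asserted), until
`max |delta F_i| < 1e-6` kJ/mol or an iteration cap (1e5; hitting it
returns the best iterate flagged non-converged with a warning). The
0.1-Angstrom default bin width over-resolves the 1-Angstrom window spacing
without producing empty-bin pathologies at the sample sizes used here.
Empty bins interior to the sampled range are masked with a warning; a
window whose histogram shares no bin with any other window is a hard error
naming the window, since its free energy would be undetermined.

`to_pmf()` converts to `G(z) = -ln P(z)` in kT. Three zero conventions are
offered: `bulk_end` (G = 0 at the most cytoplasmic sampled bin — the
barrier-relative-to-bulk reading, and the default), `bulk_mean` (zero mean
over the lowest 2 Angstrom of sampled bins), and `minimum`. For
*differences* between two independently reconstructed profiles, use
`bulk_mean`: referencing each profile to a single 0.1-Angstrom edge bin
injects that bin's counting noise (easily ~0.3 kT at the edge of the
sampled range) as a rigid offset into every Delta-G value — ten-fold
amplified in a 10-Angstrom area integral — whereas averaging over 2
Angstrom of bulk suppresses it.

`compare_pmfs()` reports `Delta G(z) = G_a - G_b` (linear re-binning when
the grids differ), the peak Delta-G in a region, and the rectangle-rule
integral of positive Delta-G over the region (kT Angstrom). With the WT
profile as `a` and the mutant as `b`, positive area is the additional
barrier experienced by the WT ion.

### Synthetic windows

`gen_umbrella_samples()` draws i.i.d. samples from the exact biased
Boltzmann density by inverse-CDF lookup on a 0.01-Angstrom grid. The CDF
is accumulated at cell edges (midpoint-rule mass per cell), which keeps
the sampler unbiased to O(step^2); i.i.d. sampling was chosen over MCMC so
WHAM validation is free of autocorrelation confounds. An optional Gaussian
AR(1) copula (`rho`) adds MD-like autocorrelation while preserving the
marginal, for stress-testing. Analytic profile forms: harmonic, Gaussian
barrier, double well, or any user function of z (kT units).

No autocorrelation correction or bootstrap is applied by default (none is
standard in the source protocol); the estimators here are validated on
i.i.d. windows where none is needed.

## File formats

PDB is read and written through `bio3d`; GRO is parsed directly
(fixed-column, nm converted to Angstrom). Note GRO stores nm to three
decimals, i.e. 0.01-Angstrom quantization — cross-format agreement is
limited accordingly. Trajectories use the DCD format (CHARMM layout,
single-precision coordinates, orthogonal unit cells, frame interval kept
in the header so times survive round trips); the package carries both the
writer and a header-aware reader, and the reader is cross-checked against
`bio3d::read.dcd` in the tests. XTC is not supported. Umbrella windows are
two-column TSV (time_ps, z_A) with a YAML sidecar carrying center, force
constant and kT. Density grids are OpenDX text.

## Pipeline and reproducibility

`run_hydration()`, `run_pmf()` and `run_compare()` orchestrate the stages
from a YAML/list config describing either file inputs or a synthetic
block, and write only diffable text artifacts (TSV, JSON, DX) with fixed
numeric formatting. Every run writes a provenance block (config hash,
seed, package and R versions). All stochastic components take explicit
seeds and restore the caller's RNG state; rerunning any pipeline with the
same config and seed reproduces every artifact byte-for-byte, which the
test suite enforces. A thin command-line front end
(`inst/cli/poregate.R`) exposes the same functions as subcommands.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script size their simulations for
tight statistical checks at interactive runtimes: 1,000 randomized
counting fixtures; 49-slice profiles on cylinder and hourglass pores;
nine 10,000-frame telegraph runs over a 3x3 rate grid (rates 0.5, 1,
2 /ns); a 267-water, 60-frame uniform bulk box for density normalization;
25-window WHAM problems at 10,000 exact samples per window (3-kT and 5-kT
Gaussian barriers, recovered within 0.3 kT) plus a 100,000-sample
Boltzmann-inversion check (RMSE < 0.15 kT); and a WT/mutant pair built
with a known uniform 4-kT plateau difference, recovered as peak 4 +/- 0.5
kT and area 40 +/- 5 kT Angstrom over the 10-Angstrom comparison region.
Statistical checks are stated as 3-standard-error bands derived from the
generators' analytic laws.

## Known limitations

* Occupancy counting trusts pre-wrapped coordinates; no periodic imaging.
* The slab count has no radial bound by default; use `radial_cutoff` when
  the simulation box is open at gate-slab heights.
* The profiler does not follow curved pore paths.
* WHAM here is strictly 1D, no MBAR, no replica exchange, and windows must
  share a temperature.
* The synthetic generator is phenomenological: it validates estimators,
  not force fields, and its defaults (rates, lambda, 0.1-ns stride) are
  study conditions, not fitted quantities.
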