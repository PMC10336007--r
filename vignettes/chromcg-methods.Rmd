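---
title: "Coarse-graining chromatin from contact maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-graining chromatin from contact maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chromcg)
```

## The fine-grained model

`chromcg` represents chromatin at nucleosome resolution: a chain of N
spherical "nucleosome + linker" (NL) beads, each covering 200 bp, with

* harmonic chain bonds between successive beads
  (`chain_k` = 100 kBT/sigma^2, rest length 1 sigma),
* excluded volume via the purely repulsive WCA potential
  (Lennard-Jones truncated and shifted at its minimum, eps = 1 kBT), and
* per-configuration harmonic *constraint springs*
  (`constraint_k` = 50 kBT/sigma^2, rest length 1 sigma) that encode the
  contact map.

All internal computation is in reduced units (bead diameter sigma = 1,
kBT = 1, unit mass). A `unit_system()` carries the conversion to physical
units. The default sigma = 21 nm follows from geometry: a nucleosome core
is ~11 nm wide, a straight 50 bp linker adds 50 x 0.34 = 17 nm, so two
bonded neighbours can be up to 28 nm apart while non-neighbours can
approach to ~11 nm; an effective diameter of ~20 nm sits between these
bounds (`estimate_nl_bead_geometry()`). kBT = 4.1 pN nm, so
1 kBT/sigma^2 is ~9.3 pN/um.

### Why constraint springs are assigned in two steps

Bonding every pair independently with probability `P_ij` would both miss
the strong, actively formed loops (present in nearly every cell) and place
springs between pairs that happen to be far apart in a given
configuration, distorting the chain. The two-step scheme avoids both:

1. **Prominent contacts** — entries at least one standard deviation above
   the mean of their genomic-separation stratum — are bonded first, with
   an independent uniform draw `r_n < P_ij` per configuration
   (`find_prominent_contacts()`, `assign_step1_bonds()`). The stratum
   statistics use the population standard deviation (a stratum is a
   complete enumeration, not a sample), and a zero-variance stratum
   yields no prominent contacts: equal entries carry no outlier signal.
   Separations 0 and 1 are excluded; those pairs are already chain-bonded.
2. After equilibrating each configuration, **every** pair `(i, j)` with
   `j - i >= 2` is bonded in the `round(P_ij * n_configs)` configurations
   (round-half-even, so the rounding is unbiased over many pairs) in which
   its 3D distance is currently smallest (`assign_step2_bonds()`). Spatially
   close pairs thus get priority for forming a contact, mimicking
   protein-mediated bridging. Quotas come from a single snapshot of the
   step-1 distances, so pair processing order cannot matter; exact distance
   ties resolve to the lower configuration index; pairs with
   `P_ij < 1/n_configs` have a zero quota and are skipped. Step-1 bonds are
   retained and count toward the quota.

The system is equilibrated again and the final snapshot of every
configuration forms the ensemble (`build_ensemble()`). Whether contact
distances should be time-averaged rather than taken from the end-of-stage
snapshot is not determined by the construction; the snapshot is used
because it keeps the assignment exactly reproducible.

## The Langevin engine

Equilibration uses an embedded BAOAB discretization of Langevin dynamics
(Rcpp, linked-cell neighbour search; trajectories are bitwise reproducible
given a seed). The contract is distributional — correct Boltzmann sampling,
verified in the tests by equipartition on a single bond and by a two-body
closed-form check — not trajectory equivalence with any particular MD
package. Defaults: dt = 0.005 tau, friction 1/tau, temperature 1 kBT.

Numerical choices worth knowing:

* **Stability margin.** A warning fires when
  `dt > 0.1 / sqrt(k_max)`, a tenth of the stiffest bond's angular period —
  the usual rule of thumb for stochastic Verlet-family integrators.
* **`build_ensemble()` runs at dt = 0.002.** After step 2 a configuration
  carries on the order of 5-10 constraint springs per bead; the stiffest
  collective modes are then several times stiffer than a single bond and
  dt = 0.005 is no longer safely inside the margin (it shows up as
  stretched chain bonds and non-settling Rg).
* **Force cap.** Pair forces are capped at 1e4 kBT/sigma (counted and
  reported); only near-coincident beads under a steep pair term can reach
  the cap. Capping regularizes the first steps of an unlucky initial
  placement without affecting equilibrium statistics.
* **Equilibration detection.** The recorded Rg series is split into
  windows; the burn-in ends at the first window whose mean changes by
  less than 2% to the next (`detect_equilibration()`). Configurations
  that never stabilize, or whose chain bonds stretch beyond 3 r0, are
  dropped with a warning rather than silently kept.
* **Initial configurations.** Random-walk growth with unit steps,
  retrying steps that land within 0.8 sigma of an existing bead (1000
  retries, then a compact serpentine lattice fallback). Collapsed-globule
  controls start directly from the serpentine layout: local packing
  equilibrates quickly, whereas waiting for a full coil-globule collapse
  would dominate the runtime.

## Coarse-grained observables

`cg_trace()` maps a conformation to CG-bead centres. Two window modes are
used deliberately: per-genomic-position *profiles* (e.g. `rg_profile()`)
use a sliding window, because the profile is a function of position along
the contour; polymer quantities of the CG chain itself (bond lengths,
angles, dihedrals, `K_cg`, the overlap parameter; `cg_observables()`) use
the blocked partition of disjoint consecutive windows, because they
describe the CG chain an actual simulation would integrate.

Conventions:

* `theta_cg = pi - acos(l̂_i · l̂_{i+1})`, in [0, 180] degrees: a straight
  chain scores 180, a complete fold-back 0. Cosines are clamped to
  [-1, 1]; angles at a zero-length CG bond (coincident centroids of
  overlapping soft beads — possible by construction) are excluded with a
  count rather than raised as errors.
* Dihedrals use the right-handed atan2 construction on three successive
  bond vectors, in (-180, 180], cis = 0, trans = 180.
* Angle histograms default to 36 bins of 5 degrees. The sine-corrected
  density `P̃ = P/sin(theta)` removes the solid-angle measure; it is
  evaluated with the sine of the bin centre and the two outermost bins are
  masked, since dividing by sin -> 0 there amplifies noise without bound.
* Effective potentials are `V = -kBT ln(density)` on occupied bins only;
  empty bins stay masked (no extrapolation) and the minimum is shifted
  to 0. The bond-angle potential inverts `P̃` (the measure-free density);
  the dihedral potential inverts `P` directly.
* `K_cg = kBT / Var(l_cg)` uses the population variance: the definition
  involves distribution moments, not a bias-corrected sample estimate.
* The two-Gaussian deconvolution is a least-squares fit to the binned
  `P(theta)` (not `P̃`), with five fixed starting points and post-fit
  ordering of the component means; the bending-stiffness fit
  `V = (k_b/2)(1 + cos(theta - theta0)) + c` carries a free offset because
  a Boltzmann-inverted potential has an arbitrary zero.

A useful exact identity ties the scales together: for any conformation and
any blocked `n_b`, `Rg^2(chain) = Rg^2(CG trace) + mean(within-block
Rg^2)`. The tests verify it to 1e-10; it also explains why the Rg of a
coarse-grained trace is systematically slightly below the fine-grained Rg.

## Iterative Boltzmann inversion

For each coarse-graining scale the non-bonded pair potential of the CG
chain (harmonic bonds at the measured `l_cg`, `K_cg`) is refined by

    V_{i+1}(r) = V_i(r) + alpha(r) kBT ln(P_i(r) / P_target(r)),
    alpha(r) = 0.2 exp(-r^2 / 2),

starting from V = 0 (`run_ibi()`). `P_i` is the distance distribution over
non-bonded pairs (contour separation >= 2) measured by simulating the CG
chain with the current tabulated potential. The Gaussian damping keeps the
update short-ranged; `r` inside `alpha` is taken in units of the CG bond
length, the natural reduced unit of the CG chain, and both the prefactor
and the width are exposed in the interface. Convergence is monitored as
`KL(P_target || P_i)` — this direction penalizes missing probability mass
where the target has support — with an additive 1e-10 regularization on
both histograms, and the best-KL iterate is returned. Further numerical
guards: bins where either distribution is below the sampling floor leave
the potential unchanged (no update from unsampled regions), an optional
3-point moving average (on by default, recorded in provenance) suppresses
bin-to-bin noise, and the potential is re-anchored to zero at the cutoff
after every update.

One genuine limitation, measured on a self-generated target (a 50-bead CG
chain with a known soft potential): the KL criterion converges quickly
(below 1e-3 within ~25 iterations at the test's sampling effort), and the
recovered potential matches the truth to better than 0.2 kBT across the
attractive well, but the steep repulsive core (where V exceeds ~1 kBT) is
visited so rarely at thermal energies that the damped update cannot pin it
down at comparable effort. This is inherent to structure-based inversion:
the data only constrain the potential where configurations sample it. The
tests therefore check pointwise recovery over the well and the location of
the minimum, alongside the KL criterion.

### The parametric soft form

The converged tabulated potential is summarized by a bounded soft-core
form: a finite repulsive branch `V0 [1 - (r/r_m)^eta1]^eta2 - eps` below
the minimum `r_m`, a cosine attractive branch
`(eps/2)[cos(mu r^2 + nu) - 1]` between `r_m` and the cutoff `r_c`, and 0
beyond. `solve_attractive_phase()` gives the unique phase pair
`mu = pi/(r_c^2 - r_m^2)`, `nu = pi - mu r_m^2` for which the attractive
branch hits -eps at `r_m` and 0 at `r_c` with zero slope at both ends, so
the assembled potential is C1 whenever `eta2 >= 1` (which the fit
enforces: it also makes the repulsive branch meet the minimum with zero
slope). `fit_soft_potential()` reads `r_m`, `eps` and `r_c` directly off
the table (argmin, depth, first zero crossing) and fits only `V0`, `eta1`,
`eta2` by least squares on the repulsive branch. Softness is reported as
the inverse of the maximal repulsive force, `1/F_max`; depth and softness
can be tuned independently, which is the point of the form — unlike a
Lennard-Jones core, the potential stays finite at contact, reflecting that
a "bead" of chromatin is a penetrable polymer blob, not a hard particle.

## Map similarity

Reconstructed maps (`ensemble_contact_map()`, contact when `r_ij < 2`
sigma — the cutoff must exceed the constraint-spring rest length so bonded
pairs register; it is exposed and reported with every comparison) are
scored against the input with the stratum-adjusted correlation
coefficient in the HiCRep construction: 2D mean-filter smoothing
(half-width h = 1 by default, reported alongside every value), Pearson
correlation per genomic-separation stratum, and the weighted combination
`sum(N_s sd_A sd_B rho_s) / sum(N_s sd_A sd_B)` over strata 2..max
(default `min(50, n_bins/3)`). Zero-variance strata are skipped; stratum
correlation is undefined there.

## The synthetic-data generator and what the tests show

`generate_synthetic_map()` emulates the statistical structure of a
nucleosome-resolution contact map: `P_ij = clip(A s^-gamma B_ij eta_ij)`
with unit diagonal, a power-law decay, TAD-like blocks (`B_ij` =
`tad_boost` within a block) and optional multiplicative log-normal noise
with unit median (positivity- and symmetry-preserving). The defaults — 200
bins, gamma = 1, A = 0.9, three equal blocks boosted 3x, no noise — are the
package's standard test condition. The generator does **not** produce
compartment (checkerboard) structure, loop anchors/corner peaks, or
coverage biases of real Micro-C maps; passing the self-tests therefore
shows that the construction, measurement and inversion machinery is
correct, not that any particular biological conclusion transfers to a
given locus. Real maps are accepted through `read_contact_map()` (dense
TSV, the supported on-disk format) and flow through the identical code
path.

Controls: the ideal chain is sampled exactly (independent Gaussian bond
vectors with `<step^2> = b^2`) rather than simulated, so control baselines
carry no integrator error; its angle distribution is the half-sine law
`P(theta) = sin(theta)/2` with flat `P̃`, and its Rg obeys
`<Rg^2> -> N b^2/6`. The SAW control (WCA chain) shows the ~0.6
window-Rg scaling exponent and non-overlapping CG beads (O < 1); the
eps = 1 kBT Lennard-Jones globule collapses, pushes the bond-angle mode
to ~60 degrees (three beads in mutual contact form near-equilateral
triangles) and shows O > 1.

## Problem sizes used by the tests and the acceptance script

The self-contained runs use 20 chains of 350 beads for the SAW control
(40000 steps each), 10 chains of 300 beads for the globule (20000 steps),
200 configurations of a 200-bin map for the reconstruction check (6000
steps per stage at dt = 0.002), and 8 chains of 50 CG beads per IBI
iteration. These sizes give stochastic observables whose run-to-run
variation is comfortably inside the stated tolerances (e.g. the scaling
exponent fluctuates by ~0.01 across seeds) while keeping a full run on a
single CPU in the minutes range.

## Known limitations

* Soft potentials permit chain crossing; dynamics (as opposed to ensemble
  statistics) from such a model needs separate topology control.
* The two-step construction targets the contact map; it does not impose
  loop-extrusion kinetics, nucleosome positioning variability, or
  epigenetic-state-specific interactions.
* Maps are stored densely and limited to 5000 bins; the pipeline is a
  desk-scale tool, not a cluster workflow.
* The ensemble is an equilibrium of a constrained homopolymer: per-cell
  heterogeneity enters only through the constraint draw, not through any
  dynamic process.
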