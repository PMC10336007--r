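# chromcg

Systematic coarse-graining of chromatin polymers from contact probability
maps.

## The problem

Chromatin is routinely simulated as a coarse-grained bead-spring polymer,
with one bead standing for anywhere between 1 kb and 1 Mb of the genome —
but the physical parameters of that polymer (bead diameter, bond length,
stretching spring constant, bending stiffness, the shape of the non-bonded
pair potential) are usually guessed or fitted ad hoc. Nucleosome-resolution
contact data (Micro-C, ~200 bp bins) makes a bottom-up alternative
possible: build a fine-grained chain of "nucleosome + linker" (NL) beads
whose ensemble reproduces the measured contact probabilities `P_ij`, then
measure every coarse-grained quantity directly on that ensemble.

`chromcg` implements this pipeline end to end for anyone who wants
principled, scale-dependent parameters for chromatin polymer models:

1. **Constrained ensemble construction.** Each configuration of an N-bead
   chain (harmonic bonds, WCA excluded volume) receives harmonic constraint
   springs in two steps: *prominent* contacts — entries at least one
   standard deviation above the mean of their `|i - j|` stratum — are bonded
   with probability `P_ij` (uniform draw `r_n < P_ij`); then every pair
   `(i, j)` is bonded in the `P_ij` fraction of configurations where its 3D
   distance is smallest. Equilibration uses an embedded BAOAB Langevin
   integrator (Rcpp).
2. **Coarse-grained observables.** For windows of `n_b` consecutive beads:
   radius of gyration `Rg`, CG bond length `l_cg`, bond angle
   `theta_cg = pi - acos(l̂_i · l̂_{i+1})`, signed dihedral `phi_cg`, the
   overlap parameter `O = 2<Rg>/<l_cg>`, the spring constant
   `K_cg = kBT / Var(l_cg)`, sine-corrected angle densities
   `P̃(theta) = P(theta)/sin(theta)`, Boltzmann-inverted effective
   potentials `V = -kBT ln P`, two-Gaussian angle deconvolution, and a
   cosine bending-stiffness fit `V = (k_b/2)(1 + cos(theta - theta0))`.
3. **Soft non-bonded potential by iterative Boltzmann inversion.**
   `V_{i+1}(r) = V_i(r) + alpha(r) kBT ln(P_i(r)/P_target(r))` with
   `alpha(r) = 0.2 exp(-r^2/2)`, convergence tracked by the KL divergence,
   plus a parametric bounded soft-core form whose softness (`1/F_max`) and
   depth (`eps`) are independently tunable.
4. **Validation.** Stratum-adjusted correlation coefficient (SCC, the
   HiCRep construction) between input and reconstructed maps; KL
   divergence between distance distributions; `Rg` comparisons between
   fine-grained and coarse-grained ensembles.

A synthetic-map generator (power-law decay plus TAD-like blocks) and exact
ideal-chain / SAW / globule controls make the whole pipeline testable with
no external data.

## Worked example

```r
library(chromcg)

# a 200-bin synthetic contact map: P(s) = 0.9 s^-1, three TAD blocks
# boosted 3x
cm <- generate_synthetic_map(synthetic_map_spec(seed = 1))

# two-step constrained ensemble, 50 configurations
ens <- build_ensemble(cm, n_configs = 50, seed = 1)

# does the ensemble reproduce the map?
recon <- ensemble_contact_map(ens, cutoff = 2)
scc(cm, recon, h = 1, max_stratum = 50)
#> [1] 0.8816662

# coarse-grained observables at 1 kb (n_b = 5)
obs <- cg_observables(ens, 5)
l <- obs$value[obs$quantity == "l_cg"]
rg <- obs$value[obs$quantity == "rg"]
overlap_parameter(mean(rg), mean(l))
#> [1] 1.184679
k <- spring_constant(l)
attr(k, "k_lcg2")
#> [1] 11.80167
```

The overlap parameter above 1 says neighbouring 5-bead CG beads
interpenetrate — they are soft, not hard spheres — and the effective spring
constant (~12 kBT/l_cg²) quantifies the bond-length fluctuation a CG
simulation should reproduce. Lengths are in units of the NL bead diameter
`sigma`; `sigma_to_nm()` and `spring_constant_pn_per_um()` convert to
physical units (default `sigma` = 21 nm, kBT = 4.1 pN nm).

The methods vignette (`vignettes/chromcg-methods.Rmd`) documents the model,
every tunable parameter, the numerical choices, and what the synthetic
controls do and do not establish.

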