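# ppsucg

Coarse-grained simulation and analysis of dipolar sulfone homopolymer
self-assembly.

Poly(propylene sulfone) (PPSU) is a single-component homopolymer that
self-assembles in DMSO–water mixtures: every repeat unit carries a
strong dipole (6.534 D at the all-atom level), and raising the water
fraction switches on noncovalent electrostatic "sulfone–sulfone bonds"
that cross-link chains into networks, which further hydration collapses
into compact nanogels. The *hydration history* — many small water
additions versus one large one — selects the morphology (elongated
bundles vs spherical gels). `ppsucg` is a desk-scale model of this
system for people who want to probe those mechanisms computationally:
polymer-physics and soft-matter researchers, and method developers who
need a small, fully reproducible dipolar bead–spring engine.

## The model in brief

Each monomer is a charge-neutral three-site unit: backbone site `+q`,
two oxygen sites `-q/2`, with `q` calibrated so the unit dipole is
6.534 D. Chains of N monomers (default 20) are bead–spring polymers
with a harmonic bending stiffness `k_bend` calibrated so the chain's
persistence length in implicit DMSO matches the all-atom value of 9.2
monomer units. Non-bonded interactions are the Weeks–Chandler–Andersen
excluded volume plus a sharply truncated Coulomb sum
`u(r) = (λ_B/σ) q_i q_j / (ε_r r)` for `r ≤ 8 σ`, where the solvent
enters only through its dielectric constant ε_r (47 = DMSO, 80 =
water). Langevin (BAOAB) dynamics propagates the system; stepwise
hydration is a piecewise-constant dielectric schedule
`ε_r = 47 + φ_w (80 − 47)` driven by added water volumes.

Analyses: persistence length from bond-vector correlations, backbone
end-to-end distances, cluster formation (union-find over a chain
contact graph), gyration-tensor shape metrics (asphericity, relative
shape anisotropy κ², principal-axis ratio), dipole moments of
charge-neutral units, dipolar pair energies, and surface oxygen
enrichment of aggregates.

## Worked example

```r
library(ppsucg)

# the calibrated monomer: charge from the 6.534 D dipole target
g <- monomer_geometry()
g
#> CG sulfone monomer geometry
#>   d_SO      : 0.3972 sigma (1.430 A)
#>   theta_OSO : 119.30 deg
#>   charges   : S+ +1.8827 e, O- -0.9413 e each
#>   net dipole: 6.5340 D

# the unit-conversion check: rigid three-site water
w <- tip3p_water()
dipole_moment(w$positions, w$charges)
#> [1] 2.346968

# six 20-mers in implicit water, 100k Langevin steps
sys  <- build_system(6, 20, density = 0.02, seed = 1)
traj <- run_dynamics(sys, force_field(dielectric_eps_r = 80),
                     integrator_config(n_steps = 100000,
                                       save_every = 10000, seed = 1))
cluster_analysis(traj)
#> cluster report (cutoff 1.5 sigma): 4 cluster(s), sizes 3, 1, 1, 1

# shape of the largest aggregate
shape_metrics(largest_cluster_sites(traj)$positions)
#> shape: Rg 5.760, asphericity 11.263, kappa^2 0.144, axis ratio 4.61
```

The cluster report says that after 500 τ three of the six chains have
associated into one aggregate; its relative shape anisotropy κ² ≈ 0.14
marks a fairly compact object (a perfect sphere has κ² = 0, a thin rod
κ² = 1).

A hydration history, following the one-shot laboratory recipe (200 µL
DMSO solution + 800 µL water in one addition, so φ_w = 0.8 and
ε_r = 73.4):

```r
sch <- hydration_schedule(200, 800, hold_steps = 48000,
                          initial_hold = 6000)
hh  <- run_hydration_history(sys, force_field(),
                             integrator_config(save_every = 3000,
                                               seed = 1), sch)
hh$table[, c("plateau", "phi_w", "eps_r", "largest_size", "largest_Rg",
             "kappa2")]
```

one row per plateau: cluster growth and compaction along the schedule.

## Command line

A thin CLI over the package functions lives at `inst/cli/ppsucg.R`
(subcommands `build`, `run`, `hydrate`, `scan-stiffness`,
`scan-length`, `analyze`, `calibrate`), driven by a YAML config; see
the methods vignette (`vignettes/ppsucg-methods.Rmd`) for the model,
its assumptions, parameter choices and limitations.
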