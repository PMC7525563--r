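---
title: "Coarse-grained modelling of dipolar sulfone homopolymer self-assembly"
author: "ppsucg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of dipolar sulfone homopolymer self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The physical problem

Poly(propylene sulfone) (PPSU) is a homopolymer whose every repeat unit
carries a strongly dipolar sulfone group: a partially positive backbone
(S plus its neighbouring carbons) and two partially negative pendant
oxygens. Although the polymer has no amphiphilic architecture, it
self-assembles in DMSO–water mixtures: chains are dissolved and extended
in DMSO, while raising the water fraction switches on noncovalent
"sulfone–sulfone bonds" — electrostatic dipolar cross-links — that drive
network formation, and further hydration collapses those networks into
compact nanogels. The *hydration history* (many small water additions vs
one large one) selects the final morphology, from elongated bundles to
spherical gels.

`ppsucg` implements a desk-scale coarse-grained model of this system: a
Langevin-dynamics engine for dipolar bead–spring chains in an implicit
solvent whose only solvent descriptor is the relative permittivity
$\varepsilon_r$ (47 for DMSO, 80 for water), plus the analysis
operations needed to quantify chain stiffness, clustering, aggregate
shape and surface charge ordering.

## The model

**Monomer.** Each repeat unit is a charge-neutral three-site unit: one
backbone site with charge $+q$ and two oxygen sites with $-q/2$ each,
held at S–O distance $d_{SO}$ and O–S–O angle $\theta_{OSO}$ by stiff
harmonic springs. Its net dipole lies along the O–S–O bisector with
magnitude $\mu = q\, d_{SO} \cos(\theta_{OSO}/2)$ (in e·Å, converted to
Debye via 1 e·Å = 4.80320 D). The charge is *calibrated*, not assumed:
`calibrate_monomer_charge(6.534)` inverts the closed form so the unit
reproduces the 6.534 D all-atom dipole moment of the sulfone unit,
giving $q \approx 1.883$ e with the default geometry
($d_{SO} = 1.43$ Å, $\theta_{OSO} = 119.3^\circ$ — typical sulfone
values; only the product $q\,d_{SO}\cos(\theta/2)$ matters, and that is
pinned by the dipole target).

**Chain.** $N$ monomers (default 20) joined by harmonic backbone bonds
($r_0 = 1\,\sigma$, $k = 1000$) with a harmonic bending potential
$\tfrac12 k_{bend}(\theta - \pi)^2$ at each interior backbone site.
$k_{bend}$ is the chain-stiffness knob.

**Non-bonded interactions.** Excluded volume is the
Weeks–Chandler–Andersen potential — Lennard-Jones truncated and shifted
to zero at its minimum $2^{1/6}\sigma$ — between all non-excluded site
pairs. The length unit $\sigma$ is the van der Waals diameter of sulfur
(3.6 Å). Backbone sites have diameter $\sigma$; oxygen sites carry a
small repulsive core $\sigma_O = 0.35\,\sigma$ (arithmetic mixing).
A full-size core on the oxygens is geometrically impossible (they sit
only $0.397\,\sigma$ from their own backbone site), but a bare point
charge could fuse onto an oppositely charged site, so the small core is
a numerical-robustness convention of this package.

Electrostatics is a sharply truncated Coulomb sum,
$$ u(r) \;=\; \frac{\lambda_B^{(1)}}{\sigma}\,
   \frac{q_i q_j}{\varepsilon_r\, r}, \qquad r \le r_c = 8\,\sigma, $$
and exactly zero beyond the cutoff (no shifting or switching; the
discontinuity heat is absorbed by the thermostat). The absolute coupling
is fixed by the Bjerrum convention: $\lambda_B^{(1)} = e^2/(4\pi
\varepsilon_0 k_B T)$ at $T = 298$ K, expressed in $\sigma = 3.6$ Å
units, so that $\lambda_B \approx 1.95\,\sigma$ in water
($\varepsilon_r = 80$) and $\approx 3.31\,\sigma$ in DMSO
($\varepsilon_r = 47$). Solvent quality enters *only* through
$\varepsilon_r$.

**Exclusions.** Directly bonded pairs (S–O within a monomer, backbone
S–S neighbours) and the two oxygens of one monomer are excluded from
WCA and Coulomb; their geometry is governed by the bonded terms. The
S–O pairs across a backbone bond *do* interact. We also examined the
stricter convention that excludes those 1–3 pairs: it removes an
attractive S–O "ladder" along the extended zigzag, but the remaining
intra-chain electrostatics then *softens* the chain, so reducing the
coupling (raising $\varepsilon_r$) stiffens it — the opposite of the
physically expected solvent response. The bonded-only policy is kept.

## Dynamics

Time integration is the BAOAB-class stochastic velocity Verlet: drift
and kick half-steps around an Ornstein–Uhlenbeck velocity update
$v \leftarrow e^{-\gamma\,\Delta t} v + \sqrt{(1 - e^{-2\gamma\Delta
t})\,k_BT}\,\xi$. With $\gamma = 0$ it reduces to plain velocity Verlet
and conserves energy (a regression test). Defaults $\Delta t = 0.005\,
\tau$, $\gamma = 1/\tau$, $k_BT = 1$ are a standard stable regime for
coarse-grained bead–spring dynamics; with the stiff $k = 1000$ bond
springs $\omega\,\Delta t \approx 0.16$. Runs are bit-reproducible for
a fixed seed: the thermostat noise comes from a counter-free
Mersenne-Twister stream seeded from the integrator config, forces are
accumulated in a fixed order, and the engine is single-threaded.

The solvent dielectric may vary during a run. It is piecewise constant
in time and updated *before* each force evaluation, so a trajectory
frame always carries the dielectric that generated it.

## Hydration schedules

A hydration history is encoded as volumes: starting from
$V_0$ of DMSO-equivalent solvent, the $k$-th water addition brings the
water volume fraction to $\phi_w = \sum_i v_i / (V_0 + \sum_i v_i)$ and
the dielectric to the linear interpolation $\varepsilon_r = 47 + \phi_w
(80 - 47)$. Linearity is the simplest monotone map consistent with the
two endpoints; alternative maps can be substituted by supplying an
explicit per-step dielectric vector. Volumes are never mapped to
explicit solvent particles — they only drive $\phi_w$. The one-shot
laboratory recipe (200 µL DMSO + 800 µL water) therefore lands at
$\phi_w = 0.8$, $\varepsilon_r = 73.4$; the same total water split into
8 × 100 µL reaches the same endpoint along a staircase. The final
dielectric depends only on the total water added — an exact invariant —
while the *path* differs, which is the mechanism behind
hydration-history-dependent morphology.

## Calibration

The only free conformational parameter, $k_{bend}$, is calibrated
against the all-atom persistence length of the 20-mer in DMSO, 9.2
monomer units. `calibrate_stiffness()` scans a $k_{bend}$ grid, runs a
single chain at $\varepsilon_r = 47$, measures $L_p$ from the
bond-correlation decay and interpolates to the target. $L_p$ is close
to linear in $k_{bend}$ over the relevant range; the packaged default
is `k_bend_backbone = 9.8`, which reproduced $L_p = 9.3 \pm 0.5$ (mean
of 5 seeds) in 300k-step runs. The bare bending term dominates: the
intra-chain electrostatic contribution at this coupling is only a few
tenths of a monomer unit, which is why the purely dielectric solvent
response of *single-chain* stiffness is weak (see Limitations).

## Analysis operations

- **Dipole moment** of any charge-neutral unit, $|\sum_i q_i r_i|$ in
  Debye. The rigid three-site water fixture (O–H 0.9572 Å, H–O–H
  104.52°, charges −0.834/+0.417 e) evaluates to 2.347 D and serves as
  the worked unit-conversion check.
- **Dipolar pair energy** between two neutral units: the untruncated
  Coulomb sum over cross pairs. In the far field it reduces to the
  ideal point-dipole interaction and decays as $1/R^3$ (a test asserts
  the log–log slope −3 ± 0.1).
- **Persistence length**: $\langle\cos\theta(s)\rangle$ over backbone
  bond vectors pooled across chains and frames, fitted as $\ln\langle
  \cos\theta(s)\rangle = -s/L_p$ by least squares through the origin
  over $s \in [1, 8]$ by default. Separations whose mean correlation
  has decayed below 0.05 are dropped — the log of a noisy
  near-zero average is biased and would corrupt the slope. A chain with
  no measurable decay is reported as $L_p = \infty$ ("exceeds chain
  length"). The estimator recovers the exact decay constant of
  synthetic freely rotating chains within 5% across
  $\langle\cos\theta\rangle \in \{0.5, 0.8, 0.9, 0.95\}$.
- **End-to-end distance** of the backbone, after bond-walk unwrapping
  across periodic boundaries (each site is placed in the image nearest
  its bonded predecessor, starting from the first backbone site).
- **Cluster formation analysis**: chains are linked when any
  inter-chain site pair is within 1.5 σ (first excluded-volume
  coordination shell plus margin) under the minimum image; clusters are
  connected components (union-find; validated against an independent
  graph-components oracle).
- **Shape metrics** of a site selection: mass-weighted gyration tensor,
  $R_g$, asphericity $b = \lambda_1 - (\lambda_2+\lambda_3)/2$,
  relative shape anisotropy $\kappa^2 \in [0,1]$ and principal-axis
  ratio $\lambda_1/\lambda_3$ — the quantitative proxy for "bundle"
  ($\kappa^2 \to 1$) vs "spherical gel" ($\kappa^2 \to 0$). Clusters
  spanning the periodic box are first made whole by walking the chain
  graph and shifting whole chains by box vectors.
- **Surface enrichment**: fraction of oxygen sites in the outer radial
  shell (top 30% of sites by distance from the cluster centroid),
  compared against the global oxygen fraction 2/3. Values above 2/3
  indicate the oxygen-out orientation that disperses the aggregates.

## Study protocols and problem sizes

The multi-chain protocols use 6 chains of 20 monomers at a monomer
number density of 0.02 σ⁻³ (a concentrated-solution regime, roughly
75 mg mL⁻¹ with σ = 3.6 Å and a 106 g mol⁻¹ repeat unit, between the
25 mg mL⁻¹ nanogel and 200 mg mL⁻¹ gel regimes studied
experimentally). This density gives a cubic box of ~18 σ — comfortably
above twice the Coulomb cutoff — while keeping chain encounter times
inside desk-scale runs. Dilute single-chain runs (2×10⁻³ σ⁻³) are used
for stiffness measurements. Production runs in the packaged studies use
10⁴–10⁵ steps per condition with 3–5 independent seeds; these sizes are
the package's own desk-scale choices and are stated in each function's
defaults.

## What the tests do and do not show

The synthetic-data side of the test suite (freely rotating chains with
a known decay constant, randomly labelled balls for the enrichment
null, tabulated point sets for the gyration tensor) validates the
*estimators* exactly. The simulation-based properties (aggregation,
bundling vs spherical collapse, hydration-path dependence) are
*qualitative directions* measured on scaled-down systems: 6 chains
cannot show mesoscale morphology, only the shape tendency of a single
aggregate. Passing them demonstrates that the model's ingredients
(dipolar attraction, oxygen-surface repulsion, stiffness, schedule
kinetics) point the same way as the experiments, not that the model is
quantitative at experimental scale.

## Numerical choices

- Pairs at exactly the cutoff distance are *included* in the Coulomb
  sum (`r <= r_c`); this matters only for lattice-perfect initial
  configurations.
- The non-bonded loop is a direct $O(n^2)$ pair sweep: at ≤ a few
  hundred sites with $r_c = 8\sigma$ comparable to the half-box, a cell
  list selects nearly all pairs anyway and costs more than it saves.
  The brute-force reference (`brute_force_reference`) is an independent
  plain-R implementation used as the oracle, including an untruncated
  mode that stands in for a long-range electrostatics cross-check.
- Angle forces guard against the collinear singularity by flooring
  $\sin\theta$ at 10⁻⁶; the harmonic bend has $\theta_0 = \pi$ so the
  torque amplitude stays finite as $\theta \to \pi$.
- Velocities are drawn from the Maxwell–Boltzmann distribution (with
  the centre-of-mass momentum removed) when a run starts from a static
  configuration.
- Hydration-history tables report each plateau's observables averaged
  over the final half of that plateau's saved frames: the shape of a
  single snapshot of a six-chain aggregate is dominated by which chains
  happen to touch, and frame averaging is the standard variance
  reduction. The bundling-vs-sphere comparison between hydration paths
  uses the largest cluster's principal-axis ratio \(\lambda_1/
  \lambda_3\), the most direct elongation readout.
- Positions are propagated unwrapped; minimum-image displacements make
  wrapping unnecessary during dynamics, and analysis re-wraps or
  unwraps explicitly.

## Known limitations

- A uniform background dielectric is the *only* solvent descriptor.
  Because every electrostatic term scales identically with
  $1/\varepsilon_r$, solvent-specific effects (preferential solvation
  of sulfones by DMSO, hydrogen-bond networks, hydrophobicity of the
  propylene spacer) are not representable. In particular the strong
  single-chain collapse seen in explicit-solvent water simulations is
  not reproduced: at this calibrated coupling the intra-chain
  electrostatic contribution to stiffness is a few tenths of a monomer
  unit, so switching 47 → 80 moves $L_p$ and the end-to-end distance by
  less than the seed-to-seed noise, and the shift's sign is not robust.
  The suite's collapse-direction test is implemented as a paired
  one-sided rank test and reports this outcome honestly. Multi-chain
  aggregation and its kinetics carry the solvent-polarity signal in
  this model, to the extent it is present.
- At six chains the shape of the largest aggregate is dominated by
  which chains happen to merge: the test suite's comparison of 1-step
  vs many-step hydration anisotropy is implemented as a one-sided test
  but its outcome is within seed noise at this system size, and the
  suite reports it as such. Resolving the morphology distinction would
  need far more chains than these desk-scale studies use.
- No constant-pressure ensemble, no hydrodynamics, no explicit solvent
  particles, no Ewald-type long-range electrostatics (the sharp 8 σ
  cutoff follows the source model; the untruncated direct sum is
  available as a reference).
- Crystallinity (the experimental WAXD signatures) is outside the
  model: bundling is resolved only as shape anisotropy.
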