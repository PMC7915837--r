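---
title: "Co-assembly of charged diblocks and porphyrin solubilization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-assembly of charged diblocks and porphyrin solubilization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipecdpd)
```

## The physical problem

Oppositely charged diblock polyelectrolytes - here an A10B25 architecture
with a ten-bead charged block (A+, A-) and a 25-bead neutral water-soluble
block (B) - co-assemble in stoichiometric mixtures into core-shell
nanoparticles.  The core is an interpolyelectrolyte complex (IPEC): a dense,
mutually charge-compensated phase of the A blocks, stabilized by a hydrated
B shell.  The driving force is not primarily electrostatic energy but the
entropy gained when the small counterions that neutralize each chain are
released into the bulk upon complexation.  `ipecdpd` simulates this
co-assembly with dissipative particle dynamics (DPD) and explicit
electrostatics, and then asks whether rigid, tetra-cationic porphyrin-like
molecules (P+) dissolved in the bulk are solubilized into the IPEC cores,
how they aggregate there, and how they reshape the associate composition.

## The model

### Beads and conservative interactions

Eight bead species are used: `A+`, `A-`, `B`, `P` (hydrophobic porphyrin
ring bead), `Pq+` (charged porphyrin periphery bead), `CI+`, `CI-`
(monovalent counterions) and `S` (solvent).  All beads have unit mass, the
interaction range r_c = 1 is the unit of length and kT = 1 the unit of
energy.  Conservative interactions are the standard soft repulsion
a_ij (1 - r/r_c).  The like-bead baseline a = 25 corresponds to water-like
compressibility at the reference density rho = 3, and unlike-bead values
follow the linear Flory-Huggins mapping

    a_ij = 25 + 3.27 chi,

so 25, 26.6 and 39.7 correspond to an athermal solvent (chi = 0), a theta
solvent (chi = 0.5) and a non-solvent (chi = 4.5).  `chi_to_repulsion()`
implements the map; `default_interaction_table()` returns the full symmetric
parameter matrix of the study: a hydrophobic polyelectrolyte backbone
(a(A,S) = 35), a marginally soluble neutral block (a(B,S) = 26,
a(A,B) = 35), a strongly self-attracting, water-avoiding porphyrin ring
(a(P,P) = 18, a(P,S) = a(Pq,S) = 39) and an ion-ring affinity
(a(A,CI) = 27).  Values below 25 encode specific attraction, which is how
the pi-pi stacking of porphyrin rings enters a purely repulsive force field.

### The porphyrin unit

The porphyrin model (`make_porphyrin()`) is a rigid, planar eight-bead
unit: four P beads at the corners of a square (side 0.7 r_c by default) and
four Pq+ beads displaced outward along the diagonals by 0.7 r_c.  The
geometry dimensions are set at the bond-length scale of the model; they are
not prescribed by the source system and are configurable.  The unit is
integrated as a rigid body, which keeps the plane exactly planar, and
carries a net charge of +4.

### Electrostatics

Point charges diverge at contact and soft DPD repulsions cannot balance
that divergence, so every charge is smeared into a Slater-type exponential
cloud, rho(r) proportional to exp(-2r/lambda), with smearing constant
lambda = 0.2.  This scale is chosen so that more than 99% of the charge
lies within one bead radius (`charge_fraction_within(1)` = 0.997), i.e. the
charge is delocalized enough to regularize the potential but not enough to
leak out of its bead.  The closed-form cloud-cloud interaction is

    U(r) = Gamma q_i q_j / (4 pi r) * B(r/lambda),
    B(x) = 1 - exp(-2x) (1 + 11x/8 + 3x^2/4 + x^3/6),

finite at contact and Coulombic beyond a few lambda.  The dimensionless
coupling Gamma = 13.87 is the common room-temperature aqueous DPD
convention (Bjerrum length of about 1.1 r_c); it is exposed as a
configuration knob in `charge_model()`.

Periodic sums use an Ewald decomposition: the erf-screened point part goes
to reciprocal space, and the real-space remainder (full smeared interaction
minus the screened point part) decays exponentially and is truncated at the
real-space cutoff (4 r_c by default, clipped to L/2 in small boxes).  The
splitting parameter and the reciprocal cutoff are tuned per box from the
requested relative force accuracy (1e-2 for production dynamics, tighter
in validation).  `direct_sum_reference()` provides the brute-force
image-shell oracle used in the tests; cubic-shell summation converges to
the Ewald result with vacuum (surface dipole) boundary conditions, which
`ewald_forces(boundary = "vacuum")` reproduces.

### Dynamics

The integrator is the modified velocity-Verlet scheme standard in DPD, with
the dissipative/random pair forces forming a momentum-conserving
thermostat; the fluctuation-dissipation constraint sigma^2 = 2 gamma kT is
enforced in `sim_params()` and sigma can never be set independently.
Defaults: dt = 0.04, gamma = 4.5 (so sigma = 3), harmonic bonds with
k = 4 and zero rest length giving a mean bond length near 0.7 r_c.  The
velocity-prediction factor is lambda_vv = 0.65: at sigma = 3 this is the
value for which the scheme's kinetic temperature stays within a few tenths
of a percent of the target at dt = 0.04, whereas 0.5 measurably overheats
the system by about 2%.  The random pair force is keyed by (seed, step,
pair) through a counter-based hash, so trajectories are bit-reproducible
regardless of pair iteration order.  Rigid porphyrins are propagated as
rigid bodies (force/torque accumulation, Rodrigues rotation update,
re-orthonormalized every step), so intra-body distances are constant to
machine precision; their reference frames are re-derived from bead
coordinates at the start of every run, which is why continuing a run is
supported but not bitwise identical to one long run.

A per-step displacement larger than r_c aborts the run as an integration
instability rather than silently wrapping through the box.

## Builders: the study conditions

`scenario_recipe()` fixes a simulation scenario.  Counterion counts are
never chosen by the user: one CI- per A+ bead, one CI+ per A- bead, one
CI- per Pq+ bead and one CI+/CI- pair per unit of added salt, which makes
every built state exactly electroneutral.  Solvent fills the box to
round(rho L^3) beads at the reference density rho = 3.  The box edge is not
prescribed by the source system (only chain counts are), so it is a recipe
parameter; the full 137 + 137 chain system uses L = 30, which puts the
polymer volume fraction near 4%.

Two initial states are supported.  `assemble_box()` disperses everything at
random (chains as self-avoiding random walks with bond length 0.7).
`assemble_preaggregated()` builds the deliberately non-equilibrium "one
large associate": all A blocks packed as confined random walks in a central
sphere sized so the local A density is rho, B blocks as random walks
excluded from that sphere, ions and solvent outside.  At step 0 this is a
single associate of association number n_plus + n_minus with no B beads in
the core.  `insert_porphyrins_bulk()` adds porphyrins to the bulk of an
existing configuration without touching the polymer (minimum distance
1 r_c, operationalizing "inserted without touching the associates"); each
porphyrin and its four counterions replace twelve solvent beads, so bead
count, neutrality and even total momentum are preserved.

`make_cluster_fixture()` builds configurations with known cluster labels
for validating the analysis stack; it is test infrastructure promoted to a
first-class, documented builder.

## Observables

Associates are identified by single-linkage clustering
(`identify_clusters()`): molecules are linked when any two of their
core-forming beads (A+, A-, P, Pq+ by default) approach within d_cut under
the minimum image.  d_cut = 0.7 r_c, the bond-length scale, implements the
"close approach comparable with the bond length" criterion; chain-chain
association and porphyrin-porphyrin aggregation share this single
configurable cutoff, since no distinct values are prescribed.  Restricting
linkage to core species means B-shell brushing contacts do not merge
distinct associates.  From per-frame cluster reports the package computes
the association number AS per cluster, the number average over the
ensemble including unimers, the weight distribution F_w(AS) proportional to
AS times the cluster count, porphyrin aggregate distributions (linkage
restricted to P/Pq+ beads), per-cluster compositions with net core charge,
and the solubilized fraction f_P+ (a porphyrin counts as solubilized when
it shares a cluster with at least one chain).  Time averages discard the
first 10% of frames as equilibration unless overridden.

Radial density profiles (`radial_density_profile()`,
`core_charge_profile()`) are angularly averaged around the periodic centre
of each selected associate's core beads, with 0.25 r_c shells by default.
The centre is the circular (toroidal) mean of the core bead coordinates:
each coordinate is mapped to an angle on the box circumference and the mean
angle mapped back, which is well defined for any compact cluster wherever
it sits relative to the boundary - including associates spanning more than
half the box, for which naive first-bead unwrapping misfolds beads.  Only
clusters that wrap around the whole box (nearly uniform bead angles) have
no centre; they are skipped and counted in the profile's `n_skipped`
attribute.  The distance axis is in r_c units from the core centre; no
radius-of-gyration rescaling is applied, since none is prescribed.  Whole-associate centring was considered and
rejected in favour of core centring because the shell is strongly
fluctuating and would smear the core profiles.

## Numerical choices and degenerate inputs

- Pair forces at exact overlap are defined as zero (the direction is
  undefined for a soft potential); the smeared electrostatic force also
  vanishes at r = 0 by the form of B(x).
- The cell-list neighbour search requires three cells per box edge and
  falls back to the exact all-pairs loop below that; both paths are
  compared to 1e-10 in the tests.
- Ewald parameters are derived from one accuracy number: alpha =
  sqrt(log(1/acc))/r_cut and the reciprocal cutoff from the matching
  k-space estimate.
- Zero-step runs, empty recipes, porphyrin-free solubilization queries and
  profile filters matching nothing are all defined behaviours (identity,
  pure solvent, error, error with the filter echoed).

## What the synthetic systems do and do not show

The generator reproduces the study conditions in composition (A10B25
chains, stoichiometric mixtures, derived counterions, porphyrin loadings,
reduced density 3) and in protocol (random versus pre-aggregated starts,
bulk insertion of porphyrins).  The trend suites run at reduced problem
sizes chosen to keep the whole test battery within a desktop budget: the
porphyrin-only solutions use L = 10 boxes with 2-8 porphyrins (0.5-2 Vol%)
over 2e4 steps, and the co-assembly/loading scenario uses 10 + 10 chains in
L = 12 with 10 porphyrins over 4e4 steps, rather than 137 + 137 chains over
1e7 steps.  At these scales the package demonstrates the mechanisms -
concentration- and salt-promoted porphyrin aggregation, segregated
core-shell structure, quantitative porphyrin uptake into cores - but not
the slow large-system coarsening kinetics (the 10^6-10^7-step evolution of
the mean association number), whose reproduction requires cluster-scale
runs of the same code.  Passing tests therefore validate mechanism and
implementation, not large-scale kinetic constants.  Equally, real
porphyrin photophysics (J- versus H-aggregate discrimination) is outside
what a coarse-grained model can say and is deliberately not modelled.

## Known limitations

- Constant-volume, constant-temperature ensemble only; no pressure
  coupling.
- Electrostatics is plain Ewald (no mesh acceleration), adequate for the
  charge counts used here but not for much larger systems.
- Monodisperse chains; fixed ionization; no pH coupling.
- Continuing a run re-derives rigid-body frames from coordinates, so
  restarts are statistically but not bitwise equivalent to uninterrupted
  runs.
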