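---
title: "Methods: conformational statistics, MM/PBSA energetics and dynamic networks in trajan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational statistics, MM/PBSA energetics and dynamic networks in trajan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajan)
```

trajan is a post-simulation analysis toolkit for molecular-dynamics
trajectories of proteins and their complexes — the kind of analysis battery
used to characterize how a post-translational modification (for instance
dual phosphorylation of the switch regions of a small GTPase such as
K-Ras4B) changes conformational equilibria, binding energetics with
regulator and effector proteins, and allosteric communication. This
vignette is the package's own account of the models it implements, the
tunable parameters that matter, and the choices made where the underlying
methods leave room.

## 1. Trajectory model and geometric primitives

A trajectory is an `N × 3 × F` array of Cartesian coordinates (Å) bound to
a per-atom topology table (identity, residue membership, and parameters:
partial charge in e, Lennard-Jones σ in Å and ε in kcal/mol, and a radius
in Å used for both the Poisson–Boltzmann dielectric boundary and solvent
accessibility). Multi-model PDB and binary DCD (CHARMM/X-PLOR dialect,
little-endian) are read and written natively; PDB coordinates are
fixed-precision (3 decimals), DCD stores 32-bit floats, and round-trip
tests assert exactly those precisions.

**Superposition.** `superpose()` computes the Kabsch least-squares
rotation/translation per frame (SVD of the cross-covariance, with the
determinant sign corrected so no reflection is ever applied). The default
reference is the first frame — the analysis convention of aligning to the
initial crystal structure. Fewer than three or collinear fit atoms are
rejected rather than silently producing a non-unique rotation.

**RMSF.** Fluctuations are measured about each atom's time-mean position.
The contract assumes the caller has already superposed the trajectory;
`refit = TRUE` additionally performs a two-pass alignment to the mean
structure (fit, recompute mean, fit again), which is common practice when
no external reference exists. The default is no refit so that the
statistic matches its definition exactly on synthetic fixtures — with a
refit, 6 rigid-body degrees of freedom out of 3N are absorbed, which for
small test systems (N ≈ 5) would bias the χ-distribution check by several
percent.

**Contacts and salt bridges.** Contact persistence is the fraction of
frames with distance ≤ cutoff; every threshold in the package is
*inclusive* so that programmed boundary cases are well defined. In
salt-bridge mode the distance is the minimum over charged-group heavy
atoms (Asp/Glu carboxylate oxygens, Lys NZ, Arg guanidinium nitrogens, His
ring nitrogens, phosphotyrosine phosphate oxygens) and the default cutoff
is 4.0 Å; the source analyses never define their salt-bridge criterion, so
this is an explicit, documented default.

**SASA.** Shrake–Rupley with a deterministic golden-angle spiral point set
(no RNG; 960 points and a 1.4 Å probe by default). For an isolated atom
the quadrature is exact up to point-set uniformity; the suite asserts ≤ 1%
error against 4π(r + 1.4)². Statistical testing of per-frame quantities
uses Welch's unequal-variance t test (the flavour is pinned because the
source analyses say only "t-test"); frames are treated as independent,
which overstates the effective sample size of autocorrelated MD data — a
caveat that applies to the original analyses as much as to this
reimplementation.

## 2. Free-energy landscapes and conformational clustering

`pmf_2d()` bins two collective variables (for the Ras systems: the
distances d₁ = G60 Cα–GTP P<sub>β</sub> and d₂ = T35 Cα–GTP P<sub>β</sub>)
and converts occupancies to free energies by Boltzmann inversion,
G = −k<sub>B</sub>T ln(n/n<sub>max</sub>), k<sub>B</sub> = 0.0019872
kcal·mol⁻¹·K⁻¹, T = 300 K by default. The most-occupied bin defines G = 0;
empty bins are *undefined* (`NA`), never zero. The default grid is 50 × 50
bins spanning the observed range padded by 5% of the span per side — the
binning is not stated in the source, so it is an explicit parameter.

`segment_basins()` labels connected components (4-neighborhood) of bins
with G ≤ cutoff, ordered by ascending minimum G, and frames inherit their
bin's basin. How the C1–C4 basin boundaries were drawn is never stated in
the source analyses, so the cutoff (default 1.0 kcal/mol) is explicit
configuration rather than a baked-in constant.

`cluster_average_linkage()` superposes frames on the selection, builds the
pairwise RMSD matrix, and runs agglomerative average-linkage clustering
(delegated to `stats::hclust`, verified in the tests against a brute-force
agglomeration oracle). Representatives are medoids — the member frame
minimizing summed RMSD to its cluster, ties broken by lowest frame index
for determinism.

## 3. MM/PBSA binding energetics

The binding free energy is assembled per frame under the
single-trajectory protocol (receptor and ligand conformations cut from
complex frames):

ΔG_binding = ΔE_MM + ΔG_solv,  ΔE_MM = ΔE_vdW + ΔE_ele + ΔE_int,
ΔG_solv = ΔE_PB + ΔE_nonpolar,

with the entropy term −TΔS omitted (recorded as such in every report) and
ΔE_int ≡ 0 because identical conformers are used bound and unbound. The
molecular-mechanics difference therefore reduces exactly to
receptor–ligand cross terms: Coulomb with k = 332.0636 kcal·Å·mol⁻¹·e⁻²
and 12-6 Lennard-Jones with Lorentz–Berthelot combining, summed without
any distance cutoff (cutoffs are an MD-engine concern, not an analysis
one).

**Polar solvation** is a finite-difference Poisson solver (linearized
Poisson–Boltzmann when ionic screening is enabled; off by default):

- dielectric boundary = union of atom spheres at their PB radii, ε_in = 1
  inside, ε_out = 80 outside; no Stern layer, no reentrant molecular
  surface. The face dielectric is the harmonic average weighted by the
  *exact* chord fraction of each inter-node edge inside the spheres
  (per-atom chords combined by maximum — exact for non-overlapping
  spheres, a mild underestimate where spheres overlap). Harmonic
  averaging is what makes convergence in grid spacing smooth; with naive
  midpoint assignment the Born-ion error oscillates with grid alignment.
- charges are spread trilinearly; the potential is solved by red-black
  SOR with Dirichlet boundaries from (screened) monopoles; non-convergence
  within the iteration cap is an error reporting the residual, never a
  silent partial result.
- ΔE_PB = ½ Σ qᵢ(φ_solv − φ_ref) with the reference run using ε_in
  everywhere on the *identical* grid with identical charge spreading, so
  the grid self-energy cancels.

On the Born ion (q = 1 e, R = 2 Å) the solver lands within 0.2% of the
analytic −81.98 kcal/mol at 0.25 Å spacing, converging monotonically
across spacings 1.0/0.5/0.25 Å. In `mmpbsa_binding()` all three systems
(complex, receptor, ligand) are solved in the complex's grid box so that
discretization noise partially cancels in the difference — a deliberate
deviation from codes that re-grid each system, chosen for lower variance
and determinism at desk scale.

**Nonpolar solvation** is the linear SASA model ΔE_nonpolar = γ·SASA + b
with γ = 0.00542 kcal·mol⁻¹·Å⁻² and b = 0.92 kcal/mol. In a binding
difference the offset enters once as −b.

**Per-residue decomposition** attributes each cross pair's MM energy half
to each partner's residue; the polar term per atom is
½qᵢ(φ_RF,complex − φ_RF,own); the nonpolar term is γ times the per-atom
SASA change, with the constant −b spread uniformly over complex residues.
That last choice is arbitrary but conservative: it makes residue sums
reproduce every component total exactly (asserted to 10⁻⁶ kcal/mol),
which a "drop the constant" convention would not.

The source analyses do not state grid spacing, interior dielectric,
snapshot counts, or replica pooling for their MM/PBSA tables, and the
underlying microsecond trajectories are not deposited — so printed table
values are not reproducible in absolute terms. All of these are exposed
configuration with the defaults above, and verification is by exact
identities, analytic limits and oracles instead.

## 4. Dynamic cross-correlation networks

`dccm()` computes C_ij = ⟨Δrᵢ·Δrⱼ⟩ / √(⟨Δrᵢ²⟩⟨Δrⱼ²⟩) over displacement
vectors from time-mean positions (trajectory superposed first; an
immobile atom is an error naming the atom, not a NaN). `mask_dccm()`
implements the display convention that |C| < 0.3 is blanked — the
inequality is strict, so 0.3 itself survives; the boundary is asserted in
the tests from both sides.

`build_network()` makes each residue a node (at its Cα) and draws an edge
when the residues stay within 4.5 Å for at least 75% of frames — both
thresholds inclusive, both verified by programmed contact schedules with
*exact* frame counts (the generator rounds half-up, so 0.750 of 1000
frames is exactly 750). Residue contact uses the minimum heavy-atom
distance (Cα–Cα pairs almost never approach 4.5 Å), and sequence-adjacent
pairs are excluded — standard dynamic-network practice, flagged here as an
interpretation of ambiguous wording in the source. Edge weights are
d_ij = −ln |C_ij|:

- the natural log is the convention of the network-analysis literature
  this follows; optimal paths are base-invariant, but the suboptimal
  tolerance is not, so the base is pinned;
- the absolute value makes anti-correlations carry information (the
  formula as usually printed is undefined for negative C);
- |C| is floored at 10⁻⁶ so fully uncorrelated contacts get a large but
  finite length.

**Communities** come from divisive Girvan–Newman clustering: repeatedly
remove the edge of highest shortest-path betweenness (lengths d_ij;
igraph supplies the betweenness primitive; ties broken by lexicographic
edge order for determinism) and keep the nested partition maximizing
weighted modularity with |C_ij| as edge strengths. Using correlation
magnitudes as strengths — rather than the d_ij lengths — is the package's
choice: modularity rewards grouping strongly correlated residues, while
path lengths reward short graph distances; the two roles are distinct and
are kept so. Intercommunity connectivity is the summed full-graph
betweenness of edges joining each community pair. The suite checks a
planted two-clique bridge (brute-forced over all 2-partitions) and a
two-domain synthetic trajectory whose communities must separate the
domains.

**Paths.** All-pairs shortest distances come from an own Floyd–Warshall
implementation (cross-checked against igraph's shortest paths); the
optimal source→sink path is reconstructed from the next-hop matrix, and
all simple paths within the tolerance δ of the optimal length are
enumerated by depth-first search pruned with exact distances-to-sink. The
source method states suboptimal paths "within 20 Å"; edge weights are
dimensionless −ln |C|, so the 20 is taken as 20 edge-weight units — a
units slip in the original, resolved the way suboptimal-path tools
conventionally do. Enumerated path sets are verified against exhaustive
enumeration on random graphs of ≤ 8 nodes.

## 5. The synthetic-data generators: what a green test establishes

Microsecond explicit-solvent trajectories of Ras systems cannot be
regenerated at desk scale, so verification runs on generators with known
ground truth:

- `sample_correlated_trajectory()` adds zero-mean Gaussian displacements
  with a prescribed inter-atom covariance (symmetric eigenfactorization;
  the same covariance applied independently to x, y, z, making the
  displacement-vector correlation exactly the normalized covariance).
  Sample DCCMs must recover it at the CLT rate 3/√F.
- `sample_two_state_cv()` draws (d₁, d₂) from a Gaussian mixture with
  prescribed occupancies — the truth generator for landscapes; an 80/20
  split at 300 K must give ΔG = 0.826 kcal/mol within binomial error.
- `sample_contact_schedule()` places residue pairs at the contact
  distance in exactly round(f·F) frames (half-up), making the 75%/4.5 Å
  edge rule testable with *no* sampling error.
- `build_toy_system()` lays out protein-like toys (charge ±1 e scale,
  σ ≈ 3.4 Å, ε ≈ 0.1 kcal/mol, radius 1.9 Å) that keep LJ/PB arithmetic
  well conditioned.

All generators are bit-reproducible under a fixed seed. What a green test
does *not* establish: physical realism. The generators have no solvent,
no bonded structure, no force-field realism, and Gaussian statistics;
they validate the *estimators* (that DCCM recovers a known correlation,
that the PMF recovers known occupancies, that the network gate fires at
exactly its thresholds), not any claim about real Ras dynamics. Headline
numbers from the original microsecond study (RMSD/SASA means, binding
tables, the seven-community decomposition) depend on those trajectories
and are out of reach by construction; the package's accountable outputs
are the printed model constants and threshold conventions, which it
reproduces exactly.

## 6. Numerical choices and degenerate inputs

- Coordinates in Å, energies in kcal/mol, residue numbering 1-based,
  frame indices 1-based (R convention; the data model is frame-count
  agnostic), all thresholds inclusive.
- Histogram bin width for distance distributions defaults to 0.1 Å (not
  stated in the source; configurable).
- Medoid ties, Girvan–Newman betweenness ties, and path ordering are all
  broken lexicographically (lowest index first) for bitwise determinism.
- Degenerate inputs error loudly with the offending entity named:
  truncated PDB records cite the line, corrupt DCD blocks cite the frame,
  zero-variance atoms in `dccm()` and missing radii in SASA/PB cite the
  atom, angle degeneracies are flagged per frame rather than dropped.
- The pipeline derives per-stage seeds from the global seed by fixed
  offsets, so toggling one stage never changes another stage's
  randomness; every applied default is visible in the written artifacts.

## 7. Known limitations

- The PB solver uses a sphere-union dielectric boundary (no reentrant
  surface), the linearized equation, and modest grids — adequate for toy
  complexes and analytic validation, not a production MM/PBSA replacement.
- No quasi-harmonic or normal-mode entropy (deliberately omitted, as in
  the protocol this package follows), no generalized-Born alternative, no
  nonlinear PB.
- No periodic-boundary imaging; trajectories are assumed unwrapped.
- Suboptimal-path enumeration is exponential in the worst case; a
  configurable cap (default 10⁵ paths) guards runaway enumerations and
  warns when hit.
- Whether the original analyses pooled replicas for DCCM/landscapes is
  unstated; the pipeline pools by default and can be run per replica.
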