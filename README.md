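# trajan

Post-simulation analysis of molecular-dynamics trajectories of proteins and
protein complexes, in R. The package bundles the analysis battery used to
study how a perturbation (a mutation, a post-translational modification such
as phosphorylation of a GTPase's switch regions) shifts conformational
equilibria, binding energetics with partner proteins, and allosteric
communication — without requiring the MD engine itself:

- **Geometry & statistics** — Kabsch superposition, per-frame RMSD, per-atom
  RMSF, distances/angles with probability-density histograms,
  contact and salt-bridge persistence, Welch's *t* test,
  Shrake–Rupley solvent-accessible surface area (deterministic spiral
  quadrature).
- **Free-energy landscapes** — 2D potentials of mean force over collective
  variables, G = −k_B T ln(n/n_max) (k_B = 0.0019872 kcal·mol⁻¹·K⁻¹,
  300 K default), basin segmentation, and average-linkage conformational
  clustering with medoid representatives.
- **MM/PBSA energetics** — single-trajectory protocol
  ΔG_binding = ΔE_MM + ΔG_solv (−TΔS omitted; ΔE_int ≡ 0), Coulomb/LJ cross
  terms (k = 332.0636 kcal·Å·mol⁻¹·e⁻²), a finite-difference
  Poisson–Boltzmann solver validated against the Born ion, the γ·SASA + b
  nonpolar model (γ = 0.00542 kcal·mol⁻¹·Å⁻², b = 0.92 kcal/mol), and
  per-residue decomposition that conserves every component total.
- **Dynamic networks** — cross-correlation matrices
  C_ij = ⟨Δr_i·Δr_j⟩/√(⟨Δr_i²⟩⟨Δr_j²⟩), display masking at |C| < 0.3,
  persistence-gated networks (edge iff contact ≤ 4.5 Å in ≥ 75% of frames)
  weighted by d_ij = −ln|C_ij|, Girvan–Newman community detection, and
  optimal plus suboptimal path enumeration (Floyd–Warshall + pruned DFS).
- **Synthetic trajectories with exact ground truth** — Gaussian
  displacement fields with prescribed correlation, multi-basin CV series
  with prescribed occupancies, and contact schedules with *exact* per-pair
  contact fractions, so every stage above is verifiable at desk scale.
- **I/O** — multi-model PDB and binary DCD, plain-text parameter tables,
  a JSON-configured pipeline (`run_pipeline()`, with a thin Rscript wrapper
  in `inst/scripts/run_pipeline.R`).

Everything user-facing speaks tibbles: results pipe into dplyr/ggplot2, and
fitted objects have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

A toy receptor–ligand complex (2 + 1 residues, partial charges ±0.4/0.3 e,
σ = 3.4 Å, ε = 0.1 kcal/mol, PB radius 1.9 Å, ligand 5 Å from the receptor
edge):

```r
library(trajan)
top <- md_topology(tibble::tibble(
  name = "CA", element = "C",
  resid = c(1, 2, 1), resname = "GLY", chain = c("R", "R", "L"),
  charge = c(0.4, -0.4, 0.3), sigma = 3.4, epsilon = 0.1, radius = 1.9))
complex <- md_trajectory(top, rbind(c(0, 0, 0), c(3.8, 0, 0), c(8.8, 0, 0)))

report <- mmpbsa_binding(complex, receptor_sel = 1:2, ligand_sel = 3,
                         grid = pb_grid_spec(spacing = 0.6, padding = 6),
                         frame_stride = 1)
report
#> <binding_report> 1 frame(s); entropy omitted (-TdS set to 0)
#> # A tibble: 8 × 3
#>   component     mean    sd
#>   <chr>        <dbl> <dbl>
#> 1 e_vdw      -0.0370     0
#> 2 e_ele      -3.44       0
#> 3 e_int       0          0
#> 4 e_pb        3.43       0
#> 5 e_nonpolar -1.10       0
#> 6 e_mm       -3.48       0
#> 7 g_solv      2.33       0
#> 8 g_binding  -1.14       0
```

Reading the ledger: the attractive Coulomb cross term (−3.44 kcal/mol,
dominated by the +0.3 e ligand facing the −0.4 e receptor atom) is mostly
paid back by desolvation (ΔE_PB = +3.43); burying interface area is
favourable under the γ·SASA + b model (−1.10, which includes the −b
offset); the internal term is exactly zero under the single-trajectory
protocol, and the net ΔG_binding = ΔE_MM + ΔG_solv = −1.14 kcal/mol — the
identity holds to 10⁻¹⁰ by construction, not by rounding.

Correlation recovery and a two-basin landscape from the synthetic
generators:

```r
sys <- build_toy_system(synthetic_spec(n_residues = 6))
cov <- diag(0.25, 6); cov[1, 2] <- cov[2, 1] <- 0.6 * 0.25
traj <- sample_correlated_trajectory(sys, cov, n_frames = 50000, seed = 1)$trajectory
round(unclass(dccm(traj))[1, 2], 3)
#> [1] 0.6

out <- sample_two_state_cv(rbind(c(4, 6), c(9, 11)), 0.3, c(0.8, 0.2),
                           n_frames = 100000, seed = 1)
grid <- pmf_2d(out$series$cv1, out$series$cv2, bins = 40)
glance(segment_basins(grid, 1.0))
#> # A tibble: 1 × 5
#>   n_frames n_bins_occupied max_G temperature n_basins
#>      <int>           <int> <dbl>       <dbl>    <int>
#> 1   100000             234  5.13         300        2
```

The prescribed 0.6 correlation is recovered to three decimals at 50,000
frames, and the 80/20 two-basin mixture yields exactly two basins at a
1 kcal/mol depth cutoff.

## Acceptance script

`scripts/acceptance.R` re-derives, from scratch against the installed
package, the network-construction boundary conventions: it programs
synthetic contact schedules across a fine scan of contact fractions and of
fixed separations, builds the dynamic network at default settings for each
point, and reports the smallest persistence and the largest contact
distance that still produce an edge, plus the display-mask boundary of the
cross-correlation matrix located by bisection. Run it as:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/trajan-methods.Rmd`) documents the models
and their assumptions, every tunable parameter with units and defaults,
what the synthetic generators do and do not emulate, numerical choices
(tolerances, tie-breaks, degenerate inputs), and known limitations.
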