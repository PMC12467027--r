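# fragdock

Fragment-map free-energy docking, binding-site hotspot identification, and
receptor trajectory metrics — with a synthetic-data module that makes the
whole chain testable against known ground truth.

## What it is for

Cosolvent simulation methods summarize a protein's functional-group
preferences as voxelized **grid free energy (GFE) fragment maps** on a 1 Å
lattice, `GFE_v = -kB T ln(n_v / n_bulk)`, one map per functional-group
class (APOLAR, GEHC, HBDON, HBACC, MAMN, ACEC, MEOO, FORC) plus an
exclusion map of forbidden space. A ligand pose is scored by classifying
each non-hydrogen atom to a map type through a rule table and summing the
per-atom map values — the **ligand GFE (LGFE)**, its predicted binding
strength; atoms overlapping the exclusion map add a 1000 kcal/mol penalty.

This package provides, for people studying ligand binding sites and
allosteric modulation (e.g. bile acids acting on a GPCR):

* **gridmaps** — GFE/exclusion containers, the occupancy→GFE Boltzmann
  transform, Boltzmann-weighted map overlap coefficients, DX-format I/O;
* **ligand model & scoring** — atom classes, rotatable-torsion derivation,
  rigid and torsional Monte-Carlo moves, LGFE with per-atom breakdown and
  a documented intramolecular surrogate;
* **mc_docking** — the three-stage Metropolis MC + simulated-annealing
  protocol (10,000 / 10,000 / 40,000 steps; move caps 1 Å/180°/180°,
  0.2 Å/9°/60°, 0.2 Å/9°/9°; 300→0 K cooling; up to 1000 cycles with a
  0.03 kcal/mol top-3 convergence check every 100 cycles), in compiled
  code, seed-reproducible end to end;
* **hotspots** — cubic-block partitioning of the search space, per-block
  docking of a ligand panel, two-round leader clustering (per ligand, then
  across ligands), ranking by average LGFE;
* **trajectory_metrics** — Kabsch superposition RMSD, per-residue RMSF and
  site distributions, COM distance traces, heavy-atom close-contact
  fractions (3 Å), the ionic-lock vs NPxxY-RMSD activation plane, block
  moving averages (15 ns), linear mutual information maps with
  inter-domain region detection at the 0.625 threshold;
* **synthetic_data** — planted Gaussian wells, geometric exclusion masks,
  schematic steroid-like ligand templates (acid / glycine / taurine
  tails), a labeled seven-helix receptor fixture, and Gaussian
  trajectories with closed-form RMSF (`sigma*sqrt(3)`) and LMI (`rho`)
  ground truth.

## Worked example

Dock a probe atom into a planted −5 kcal/mol Gaussian well and compare
with exhaustive voxel enumeration; then recover fluctuation and
correlation ground truth from a synthetic trajectory:

```r
library(fragdock)

spec <- grid_spec(dims = c(20, 20, 20))
fm <- make_fragmap_set(list(planted_well(c(10, 10, 10), -5, 2, "APOLAR")), spec)
dr <- dock(make_ligand("probe_atom"),
           start_region(center = c(10, 10, 10), radius = 9), fm, seed = 7)
dr
#> <docking_result: best LGFE -5.000 kcal/mol, 100 cycles, converged, 46 distinct poses>
min(fm$maps$APOLAR$values)   # exhaustive enumeration oracle
#> [1] -5

cs <- covariance_spec(12, 0.5, domains = list(A = 1:4, B = 5:8),
                      block_pairs = list(list("A", "B", 0.8)))
mt <- make_trajectory(cs, 10000, seed = 7)
mean(rmsf(mt$trajectory, fit = FALSE))   # truth: 0.5 * sqrt(3) = 0.8660
#> [1] 0.8667
lm <- lmi_matrix(mt$trajectory, fit = FALSE)
round(lm[1, 5], 3)                       # planted inter-domain rho = 0.8
#> [1] 0.8
high_correlation_regions(lm, 0.625, mt$truth$domain_map)
#>   domain_i domain_j n_pairs   max_lmi residues_i residues_j
#> 1        A        B      16 0.8029364        1-4        5-8
```

The docking result converged (the deduplicated top poses agree within
0.03 kcal/mol) at the exact voxel optimum; the trajectory estimators hit
their closed-form targets (0.8667 vs 0.8660 Å RMSF; LMI 0.800 vs 0.8) and
the region detector reports exactly the planted domain pair.

## Layout

```
R/                  implementation (grids, ligands, scoring, docking,
                    hotspots, trajectory metrics, synthetic data, I/O)
src/                compiled Metropolis MC/SA inner loop (Rcpp)
tests/testthat/     unit, property, and end-to-end recovery tests
vignettes/          methods vignette: models, parameters, design choices
scripts/            acceptance.R (validation re-run, JSON output)
```
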