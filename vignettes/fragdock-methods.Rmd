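---
title: "Fragment-map docking and trajectory metrics: models, parameters, and validation design"
author: "fragdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-map docking and trajectory metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdock)
```

## The problem this package addresses

Cosolvent molecular-dynamics methods map where small functional groups like
to sit around a protein. Binning selected solute atoms onto a 1 Å voxel
grid, normalizing by the fragment's bulk occupancy, and Boltzmann-
transforming yields *grid free energy* (GFE) fragment maps,

$$\mathrm{GFE}_v \;=\; -k_B T \,\ln\!\frac{n_v}{n_\mathrm{bulk}},$$

one map per functional-group class. Eight classes are carried here: four
generic (hydrophobic APOLAR, heterocycle carbon GEHC, hydrogen-bond donor
HBDON, hydrogen-bond acceptor HBACC) and four specific (methylammonium
nitrogen MAMN, acetate carboxyl carbon ACEC, methanol hydroxyl oxygen MEOO,
formamide carbon FORC), plus an *exclusion map* marking solute- and
water-forbidden space.

Against such maps, a ligand pose is scored by classifying each non-hydrogen
atom to a map type through a rule table and summing the per-atom map values
— the *ligand GFE* (LGFE), the predicted binding strength. A non-hydrogen
atom overlapping the exclusion map contributes a 1000 kcal/mol penalty to
the LGFE. Monte-Carlo docking samples poses against this landscape;
two-round pose clustering over a ligand panel turns pose ensembles into
ranked candidate binding sites (hotspots); and a set of trajectory metrics
(RMSD, RMSF, center-of-mass distances, contact fractions, the ionic-lock /
NPxxY activation plane, linear mutual information) quantifies what bound
modulators do to receptor dynamics.

This package implements that full analysis chain as reusable, tested code,
and — because real cosolvent simulations are out of desk-scale reach — a
synthetic-data module that generates every input with *known ground truth*:
planted Gaussian free-energy wells, geometric exclusion masks, schematic
steroid-like ligands, a toy seven-helix receptor, and multivariate Gaussian
trajectories with closed-form fluctuation and correlation targets. Every
headline claim of the package is validated by parameter recovery against
those analytic truths.

## Grid maps

`grid_spec()` defines the lattice: `origin` is the center of the first
voxel, spacing defaults to 1 Å. Point lookups (`gfe_at()`,
`is_excluded()`) use nearest-voxel semantics: fractional grid coordinates
are rounded half-up, so a point exactly midway between two centers belongs
to the higher-index voxel. Points outside the grid read as bulk (GFE 0,
not excluded) — maps cover the region of interest and everything else is
solvent. Trilinear interpolation is available (`mode = "trilinear"`) and
agrees with nearest-voxel lookup at voxel centers; the docking engine uses
nearest-voxel lookup, matching the voxel-binned provenance of the maps.

`occupancy_to_gfe()` clamps output to ±`cap` (default 3 kcal/mol): a
never-visited voxel has infinite apparent free energy, and the clamp keeps
scores finite and bounded. Synthetic planted-well maps use a nominal large
cap (1000) since their values are constructed directly in energy units.

Map convergence between two runs is measured by `overlap_coefficient()`:
each grid is turned into a Boltzmann probability
$p_v \propto e^{-\mathrm{GFE}_v/k_BT}$ normalized over the grid, and the
overlap is $\sum_v \min(p_v^{(a)}, p_v^{(b)}) \in [0,1]$. The statistic's
name and its >0.7 convergence convention are standard; the precise formula
(Boltzmann-weighted voxel probabilities at the set's temperature) is this
package's documented choice.

Grids travel in DX format (`read_dx()`/`write_dx()`), written with the
z-index varying fastest as is conventional for that format.

## Ligands, scoring, and the intramolecular surrogate

A `ligand()` is atoms (element, scoring class, hydrogen flag), bonds, and
rotatable dihedrals derived from the bond graph: a torsion is rotatable iff
its central bond is a non-ring single bond with at least one heavy atom on
each side beyond the bond — terminal torsions are excluded, and ring bonds
are detected by connectivity (removing the bond leaves its endpoints
connected). Only non-hydrogen atoms are scored; unmapped heavy atoms
contribute zero in permissive mode (the scoring rule table deliberately
covers *selected* atoms, not all).

The shipped rule table (`default_rules()`) covers the synthetic templates:
aliphatic carbon → APOLAR, heterocycle carbon → GEHC, donor nitrogen →
HBDON, carbonyl/anionic oxygen → HBACC, protonated amine → MAMN,
carboxylate carbon → ACEC, hydroxyl oxygen → MEOO, amide carbon → FORC;
sulfur is carried for geometry only. These are honest schematic stand-ins,
not a force-field atom-typing.

Monte-Carlo acceptance needs an intramolecular term alongside the LGFE so
that torsional moves cannot fold the ligand through itself. Full
force-field internal energies are deliberately out of scope; the surrogate
used is

* a 3-fold cosine barrier $\tfrac{V}{2}(1+\cos 3\phi)$ per rotatable
  torsion (default $V = 2$ kcal/mol), and
* a harmonic soft-sphere clash penalty
  $\tfrac{k}{2}(d_c - r)^2$ for nonbonded heavy-atom pairs (beyond 1-2 and
  1-3 connectivity) closer than $d_c = 2$ Å (default $k = 50$
  kcal/mol/Å²).

It depends only on internal coordinates (rigid-motion invariant, verified
to 1e-9) and is isolated behind `scoring_config()` so a richer energy can
replace it. This surrogate is the package's largest acknowledged fidelity
gap relative to force-field-based scoring.

## The docking protocol

`docking_protocol()` defaults to the canonical three-stage exhaustive
protocol: 10,000 Metropolis steps at 300 K with moves up to 1 Å / 180° /
180° (translation / rigid rotation about the center of mass / torsion),
then 10,000 local steps at 300 K with caps 0.2 Å / 9° / 60°, then 40,000
simulated-annealing steps with caps 0.2 Å / 9° / 9° and the temperature
cooled from 300 K to 0 K. Choices the protocol's description leaves open,
fixed here:

* *Cooling schedule*: linear in step index, reaching exactly 0 K at the
  last step; at 0 K uphill moves are rejected outright (verified on
  per-step logs).
* *Move sampling*: move kind uniform over available kinds (torsions only
  for flexible ligands); translation = uniform random direction with
  magnitude uniform in [0, cap]; rotation = uniform random axis, angle
  uniform in [−cap, cap].
* *Initial placement*: uniform random center of mass in the start region
  (sphere or box), uniform random orientation (quaternion method).
* *Cycle bookkeeping*: each cycle (stage 1 → 2 → 3) retains its best-LGFE
  pose seen, which is more robust than the final SA state and in practice
  equal to it. Metropolis acceptance uses LGFE + intramolecular energy
  (unit weights, configurable); ranking and the incumbent best use LGFE
  alone, the protocol's stated selection score.
* *Convergence*: up to 1000 cycles; every 100th cycle the retained poses
  are deduplicated (center-of-mass distance < 0.5 Å keeps the lower LGFE,
  so near-copies cannot trivially satisfy the test) and sampling stops
  when the LGFE spread between rank 1 and rank 3 falls below 0.03
  kcal/mol. When deduplication leaves fewer than three distinct poses the
  spread is taken over the poses available: a single-funnel landscape
  legitimately collapses to one distinct pose, and demanding three would
  make convergence unattainable exactly when sampling is most decisive.
  The top-3 window is global across all cycles (not per check window).

The per-step loop (propose, score, accept) runs in compiled code and draws
from R's RNG, so `set.seed()`/`seed =` arguments give bit-identical
trajectories end to end.

On a planted single-well map, a probe atom docks to the exhaustive
voxel-enumeration optimum within 1e-6 kcal/mol; that equivalence is the
engine's primary correctness oracle.

## Hotspot identification

`identify_hotspots()` globally scans a search box: the box is tiled with
cubic blocks (default edge 12 Å, overlap 3 Å; lower corners on a stride
lattice, the last block may extend past the box face so coverage is
guaranteed), each panel ligand is docked per block, and the pose pools go
through two clustering rounds — per ligand (local sites), then across
ligands (common sites) — using iterative leader clustering: the pose with
the most neighbors within the cluster radius (default 3.5 Å
center-of-mass distance) becomes a center, its neighborhood is removed,
repeat; neighbor-count ties resolve to the lower-LGFE pose. Final clusters
are scored by the mean over member ligands of each ligand's best member
LGFE and ranked ascending.

Design choices worth knowing:

* Block docking uses a reduced protocol by default (step counts scaled to
  10%, 20-cycle budget) because the full protocol across dozens of blocks
  is a cluster-scale computation; the full protocol is a drop-in argument.
* Sampling is *not* confined to a block (the chain may diffuse out), so
  the default pose pool keeps every distinct cycle pose
  (`pool_poses = "all"`); keeping only each block's best would silently
  lose shallower sites that sit within diffusion reach of a deeper one.
* Two filters separate binding-site evidence from sampling debris: a pose
  must be at least half as favorable as its own ligand's best pose
  (`lgfe_keep_frac = 0.5`, scale-free), and a final cluster must contain a
  majority of the panel (`min_ligands`) — the cross-ligand round exists
  precisely to find *common* sites. Both are configurable and reported in
  the output's metadata attribute.
* Ligands absent from a cluster do not penalize its average; the mean runs
  over ligands present (per-ligand columns expose the composition).

On a two-site synthetic fixture (site depths −3.5 and −2 kcal/mol per map,
24 Å apart), the scan returns exactly two hotspots, ranked deeper-first,
with centers within the cluster radius of the planted centers.

## Trajectory metrics

All metrics run on a frames × atoms × 3 `trajectory()` with a per-atom
residue table.

* `kabsch_superpose()` — SVD-based least-squares rigid superposition with
  the determinant correction (always a proper rotation); degenerate
  (<3-atom or collinear) selections are rejected. Verified against a dense
  rotation-grid search oracle.
* `rmsf()` — per-atom $\sqrt{\langle|\mathbf r-\langle\mathbf
  r\rangle|^2\rangle}$ aggregated per residue; `fit = TRUE` superposes
  every frame onto the mean structure first, removing global rigid motion.
* `contact_fraction()` — per residue, the percentage of frames in which
  any non-hydrogen ligand atom is within the cutoff (default 3 Å) of any
  non-hydrogen residue atom; a distance exactly at the cutoff counts. The
  criterion is applied literally per frame, with no smoothing.
* `activation_trace()` — the two-dimensional activation metric: per-frame
  center-of-mass distance between the ionic-lock partner selections
  against the NPxxY-motif RMSD relative to the inactive reference, with
  marker values computed from both reference structures.
* `moving_average()` — non-overlapping block means ("calculated every
  15 ns" read as block averages; a sliding variant would smear block
  boundaries); the trailing partial block averages over its actual length.
* `lmi_matrix()` — linear mutual information between per-residue 3D
  displacement vectors under the Gaussian estimator,
  $I_{ij} = \tfrac12(\ln\det C_i + \ln\det C_j - \ln\det C_{ij})$,
  normalized to a correlation-like scale by
  $r_{ij} = \sqrt{1 - e^{-2I_{ij}/3}}$ — the generalized-correlation
  convention. One representative point per residue (the first selected
  atom, conventionally the alpha-carbon). `high_correlation_regions()`
  collects off-diagonal entries above a threshold (default 0.625) between
  distinct named domains and reports contiguous residue runs per domain
  pair.

A practical note on the `fit` flag and LMI: superposition absorbs part of
any *collective* motion into the removed rigid-body degrees of freedom, so
fitting attenuates planted collective correlations (the fit-based estimate
is still exactly invariant under imposed global rigid motion, which is
what the flag is for). Parameter-recovery validation therefore generates
displacement trajectories with no rigid drift and analyzes them with
`fit = FALSE`.

Frames are assumed pre-imaged; no periodic-boundary unwrapping is
performed.

## The synthetic-data module and what it does (not) emulate

* **Maps**: isotropic Gaussian free-energy wells,
  $\mathrm{GFE}(\mathbf r) = d\, e^{-|\mathbf r-\mathbf c|^2/2w^2}$, plus
  optional i.i.d. Gaussian voxel noise. Wells are planted directly in free
  energy (not occupancy) because that is the landscape the docking engine
  sees, so ground truth for docking is exact by construction. Real maps
  have anisotropic, multimodal structure; nothing here validates against
  that.
* **Ligands**: united-atom schematic templates. The steroid-like core is
  four linearly fused hexagons (18 carbons) with a ring hydroxyl; the
  acid, glycine-conjugate and taurine-conjugate templates share it
  identically and differ only in the tail, mirroring how bile-acid
  conjugation extends the acidic tail. Geometry is schematic by design —
  there is no claim of conformational realism, only of correct topology
  (ring detection, rotatable-torsion count, class coverage).
* **Trajectories**: i.i.d. frames of Gaussian residue displacements about
  fixed helical mean positions, axes independent, per-axis standard
  deviation σ. Closed forms follow: RMSF $= \sigma\sqrt3$; for a planted
  per-axis correlation ρ between two residues, the normalized LMI equals
  exactly ρ. A block pair (A, B, ρ) sets correlation ρ between *all*
  distinct residues of A ∪ B — compound symmetry, which keeps the
  covariance positive definite (checked by Cholesky at construction) while
  preserving the inter-domain closed form. i.i.d. frames mean no
  autocorrelation, so nothing about moving-average behavior on correlated
  data is validated by them; an AR(1) mode exists for that purpose and
  carries no LMI claim.
* **Receptor**: a CA-only seven-helix bundle with labeled stand-ins for
  the ionic-lock partners (ARG 123 on TM3, GLU 360 on TM6), the TM7 NPxxY
  motif (residues 410–414) and two intracellular groove sites (TM3/TM4 and
  TM5/TM6). The "active" state displaces the TM6 intracellular half
  outward and distorts the motif — the geometric signature the activation
  trace measures — with no pretense of structural realism beyond that.

Passing recovery tests on these fixtures demonstrates that the *estimators
and search procedures* are correct; it does not demonstrate that the
pipeline's conclusions transfer to real cosolvent maps or microsecond MD,
which have rugged landscapes, anisotropy, and autocorrelation the
generators deliberately omit.

## Validation problem sizes

The shipped validation suite uses sizes chosen to make every check sharp
but desk-scale: 20³–40×20×20-voxel grids; probe docking with the full
default protocol (5 seeds); steroid well recovery with default stages and
a 100-cycle budget (20 seeds; the planted well width, 4 Å, is set
comparable to the template's radius of gyration so the pocket can
physically accommodate the ligand, and well depth −3 kcal/mol per map
type); two-site hotspot scans with the reduced block protocol (10 seeds);
10⁵ Metropolis trials; 10,000-frame trajectories for RMSF/LMI recovery
(tolerances 2% and ±0.02 against the closed forms). `scripts/acceptance.R`
re-runs exactly these computations from scratch and writes the measured
quantities as JSON.

## Known limitations

* The intramolecular energy is a surrogate, not a force field; relative
  LGFEs of highly flexible ligands inherit its crudeness.
* Convergence by the 0.03 kcal/mol top-3 spread is a demanding criterion
  on landscapes with continuous orientational degeneracy (distinct
  deduplicated poses then differ by curvature-scale energies); runs that
  exhaust their cycle budget without the flag still return the best pose
  found, and the flag's absence is informative rather than fatal.
* Atom classes are inputs; there is no chemical perception (aromaticity,
  protonation).
* No receptor flexibility beyond what the exclusion map encodes; no
  periodic-boundary handling; no hydrogen-bond geometry analysis or
  secondary-structure assignment.
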