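---
title: "Docking and hotspot mapping with dockmapr: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking and hotspot mapping with dockmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockmapr)
```

## What this package computes

`dockmapr` implements two closely related grid-correlation workflows from
structure-based modelling:

1. **Rigid-body protein-protein docking.** The receptor is held fixed, a
   quasi-uniform set of ligand rotations is swept, and for each rotation
   every integer grid translation is scored at once by multi-channel FFT
   cross-correlation. The lowest-energy poses across all rotations are
   retained (1000 by default), clustered greedily by ligand RMSD, and the
   cluster representatives are relaxed by rigid-body energy minimization.
   Clusters are ranked by population: the premise, inherited from the
   server methodology this package emulates, is that the broadest
   low-energy basin — not the single lowest-energy pose — marks the most
   probable binding mode.

2. **Whole-surface solvent mapping.** Sixteen small organic probe
   molecules of varying size, shape and polarity are each swept over the
   entire protein surface with the same FFT engine (no pocket prior).
   For each probe type the best grid placements are retained, minimized
   off-grid with a continuous energy, and clustered; clusters of
   different probe types that co-locate are merged into *consensus
   sites* (binding hotspots). A site's population — the number of probe
   clusters it contains — measures its importance: a site with 16 or
   more probe clusters is called *strong* and marks a druggable pocket,
   and nearby hotspots are merged into predicted binding sites.

A third, smaller utility scores predicted complex models by the mean
predicted aligned error (PAE) over interface residue pairs (residues
within 10 Å of the partner chain), the selection score used when
docking inputs come from a structure predictor.

## The scoring model

### Grid channels

A parameterized structure (per-atom radius *r*, partial charge *q*,
coarse type) is rasterized at spacing *h* into:

* `core` — indicator of voxel centers inside any atom sphere shrunk by
  the overlap tolerance δ (default 0.5 Å). Shrinking implements the
  rigid-docking requirement of tolerating moderate overlaps.
* `surface` — indicator of the shell (r − δ, r + σ] around atoms, with
  core voxels removed; σ is the shell width.
* `charge` — trilinearly spread partial charges.
* `pair` — one trilinear unit-density channel per coarse atom type
  (C_aliph, C_arom, N_don, O_acc, S, P), contracted with a packaged
  symmetric contact matrix ε (negative = attractive) in the score.

The score of a relative translation *t* at one rotation is

    E(t) =  w_rep · corr(core, core)(t)
          − w_attr · corr(surface, surface)(t)
          + w_elec · corr(charge, charge)(t)
          + w_pair · Σ_ij ε_ij · corr(pair_i, pair_j)(t)

with every correlation computed by zero-padded FFTs (padded to
receptor-dims + ligand-dims − 1, so no translation in the reported range
aliases). A direct-summation oracle (`brute_force_correlate`) implements
the identical contract and the equivalence of the two paths on random
grids is the module's central test.

### Why the repulsive weight is large

The published coefficient sets are named but not printed in the source
methodology, so the numeric values here are this package's own
documented choice. One choice needs explanation: in the `balanced` set
the attraction, electrostatic and pair coefficients keep conventional
ratios (1, 0.6, 1), but `w_rep` is far larger. With indicator channels
at h = 1 Å, one atom's shrunk core covers roughly 10 voxels while its
surface shell covers roughly 240; a clashing atom pair therefore
overlaps only 1–3 core voxels, yet the extra burial it buys can add tens
of shell-overlap voxels of spurious reward. For clashes to be *always*
penalized — the invariant the coefficient sets must satisfy — each core
voxel must cost more than that purchasable gain; measurements on the
planted-pose fixtures put the break-even near 6 units per core voxel;
the shipped value (8) sits just above it. Much larger values were also
tried and are counterproductive: they evict mildly-overlapping
near-native poses from the retention funnel, which is exactly the
moderate-overlap tolerance rigid-body docking relies on, and
cluster-population ranking degrades. The same reasoning is why
published FFT-docking potentials weight their repulsive cores orders of
magnitude above their attractive terms.

### Grid margin

The grids only need to cover the structure plus the surface-shell
support (about 4 Å), because zero-padding already makes every relative
translation alias-free; padding the receptor by the full ligand
diameter, as one might when correlating at receptor-sized transforms,
would only inflate the FFT size several-fold. The default margin is 5 Å
and is configurable.

### The off-grid (refinement) energy

Retained poses are relaxed rigidly (translation + rotation) under a
soft-core 12-6 potential plus screened Coulomb:

    E = Σ_pairs e0 [ (s/ρ)^12 − 2 (s/ρ)^6 ] + 332 q_i q_j e^{−κ r} / (ε_d ρ)

with ρ = sqrt(r² + soft²) and s = contact_scale · (r_i + r_j). The
contact scale (0.87) shifts the contact optimum inward by about the same
overlap tolerance the grids apply through δ, keeping the on-grid and
off-grid energy worlds consistent; without it, refinement pushes snugly
docked poses back out of their pockets. The minimizer combines a projected
steepest descent on the rigid-body manifold (net force for translation,
net torque for rotation, backtracking line search) with a deterministic
multi-start Nelder-Mead search over the six rigid parameters: descent
alone can jam against the displacement cap when it starts from a clashed
pose, while the simplex restarts can hop such barriers. Whatever the
route, three hard guarantees are enforced on return: the continuous energy
never increases, the clash count never increases, and the pose never
moves more than 3 Å RMSD from its input; if no candidate satisfies all
three, the input pose is returned flagged `unchanged`.

## The docking funnel

Per rotation, the best `per_rotation_keep` translations are retained —
*diversely*: translations must be at least 3 voxels apart, so a single
wide flat well cannot stack near-duplicates and distort the later
population counts. Candidates across rotations are pooled and the
`retained` (default 1000) lowest-energy poses survive. Distance
restraints, when supplied, mask infeasible translations *before*
retention, so the funnel always delivers feasible poses (and errors
explicitly if no translation anywhere satisfies them). Restraint
semantics are k-of-n within a group and AND across groups.

Greedy clustering then repeatedly picks the pose with the most
neighbors within the RMSD radius (ties: lower energy, then input
order), removes the cluster, and repeats; clusters are ranked by
population. Ligand RMSD is computed with the receptor frame fixed — no
re-superposition — which is the docking convention: two poses are the
same binding mode only if they overlap in the receptor's frame. The
default radius (9 Å) matches the cited server methodology for
protein-sized ligands; the toy fixtures are about one-third that scale,
so the fixture-based tests pass a proportionally smaller radius
(4–5 Å). The cluster representative is its maximum-neighbor member (the
density peak), not the lowest-energy member, because population is the
model-selection principle.

## The mapping hierarchy

For each of the 16 probes: FFT sweep over rotations × all surface
translations → retain K (default 2000) grid poses → rigid off-grid
minimization → greedy clustering on probe centers (default radius 3 Å),
keeping at most 6 clusters per probe ranked by *average* minimized
energy. Probe clusters of all types are then merged greedily within the
consensus radius (default 4 Å center-to-center; the seed is the cluster
with most neighbors); every probe cluster ends up in exactly one
consensus site, so site populations always sum to the number of input
clusters. Sites are ranked by population (ties: lower mean energy) and
classed `strong` (≥ 16 probe clusters), `intermediate` (> 10) or
`weak` — the strong threshold is the published druggability anchor, and
the package counts probe *clusters*, consistent with the definition of
consensus-site population. `predict_sites` merges hotspot centers by
single linkage within 8 Å and annotates each merged site with the
receptor residues within 4 Å of any member probe pose.

The consensus-distance and per-probe retention constants are not printed
in the source papers; the shipped values follow the cited methodology
papers and are all exposed in `map_params()`.

## Synthetic fixtures: what they emulate and what they do not

`make_toy_complex` builds a pseudo-atom receptor around an L-shaped
pseudo-atom ligand with a fixed clearance, so the receptor cavity is the
ligand's exact complement, then presents the ligand displaced by a
recorded pure translation. Three design points matter:

* **Packing density.** Pseudo-atoms are packed at 2.0 Å minimum
  separation — much denser than a CA trace — so the union of shrunk
  atom cores is solid on the grid. Real proteins are solid because all
  heavy atoms are present; a sparse pseudo-atom interior is porous and
  becomes spuriously attractive to the surface channel.
* **Shape asymmetry.** A round blob fits a round cavity in any
  orientation. The two unequal arms of the L make the planted
  orientation the unique complementarity optimum, which is what the
  recovery tests actually exercise.
* **Pure-translation plant.** The presented ligand differs from the
  bound pose by translation only, so the identity rotation (always the
  first element of the rotation set) can represent the native
  orientation exactly and recovery accuracy is limited by grid spacing,
  not by rotation-set resolution.

The constructors self-validate (zero core overlap at the plant; the
plant beats every 5 Å axis displacement) and raise an error rather than
return a defective fixture. `make_toy_pocket` is a dense pseudo-atom
ball with one spherical concavity (radius 4.5 Å) opening to the
surface, with the cavity-lining residues recorded.

A green recovery test on these fixtures establishes that the funnel,
clustering, ranking and refinement interact correctly on a system whose
ground truth is known by construction. It does *not* establish docking
accuracy on real proteins: the fixtures have no side-chain flexibility,
no desolvation, a single nitrogen class, and a stand-in contact
potential where the servers use calibrated statistical potentials.

## Numerical choices and degenerate inputs

* Voxel ownership is half-open (`floor((x − origin)/h)`), voxel centers
  at `origin + (i + 0.5) h`; origins snap to multiples of *h* so that
  translating a structure by exactly *h* shifts every channel by one
  voxel index.
* FFT sizes are rounded up to 5-smooth integers.
* Greedy tie-breaks everywhere are (more neighbors, lower energy, lower
  input index), making all clusterings invariant to input order.
* Quaternions are canonicalized to the w ≥ 0 hemisphere; q and −q are
  the same rotation.
* Empty selections, empty interfaces, infeasible restraint sets, and
  probe grids larger than the receptor grid raise explicit errors
  naming the offending stage or selection.
* Altloc resolution keeps the highest occupancy (ties → altloc A);
  hydrogens and waters are dropped on input (heavy-atom model).

## Known limitations

* The pairwise contact matrix and charge templates are documented
  stand-ins, not a reconstruction of the servers' statistical
  potentials; absolute energies are not comparable to server scores.
* Refinement is rigid-body only; no side-chain or backbone relaxation.
* The pair channels use point (trilinear) densities, so the pair term
  acts only at near-contact range on the grid.
* Mapping of NMR/MD ensembles, cryptic-site analysis, and web-service
  features of the reference servers are out of scope.
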