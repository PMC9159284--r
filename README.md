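# dockmapr

FFT rigid-body protein–protein docking and whole-surface computational
solvent mapping (binding-hotspot detection), in R.

## Who this is for

Structural bioinformaticians who want a transparent, scriptable,
fully offline implementation of the two classic grid-correlation
workflows used by the ClusPro/PIPER family of docking servers and the
FTMap/FTSite family of hotspot-mapping servers:

* **Docking**: sample all rotations × translations of a ligand protein
  against a fixed receptor, score each placement as a sum of channel-wise
  grid cross-correlations computed with FFTs, keep the 1000 lowest-energy
  poses, cluster them greedily by ligand RMSD, rank clusters by
  population, and relax the cluster representatives by rigid-body energy
  minimization. Pairwise distance restraints (k-of-n groups, AND across
  groups) can confine the search.
* **Mapping**: sweep 16 small organic probe molecules (ethanol …
  N,N-dimethylformamide) over the *entire* protein surface, minimize and
  cluster each probe's poses, merge clusters of different probe types
  into consensus sites (hotspots), classify druggability (a site with
  ≥ 16 probe clusters is a strong, druggable hotspot), and assemble
  nearby hotspots into predicted binding sites.
* **Model metrics / predicted complexes**: ligand RMSD, CAPRI-style
  interface RMSD, and the mean interface-PAE score (interface = residues
  within 10 Å of the partner) for ranking predicted complex models.

The core score of a relative translation `t` of the ligand grid against
the receptor grid, at one ligand rotation, is

```
E(t) =  w_rep  · corr(core_R,  core_L)(t)
      − w_attr · corr(surf_R,  surf_L)(t)
      + w_elec · corr(chg_R,   chg_L)(t)
      + w_pair · Σ_ij ε_ij · corr(pair_R,i, pair_L,j)(t)
```

computed for every `t` at once by zero-padded FFTs, and verified in the
test suite against a direct-summation oracle (`brute_force_correlate`).

## Worked example

```r
library(dockmapr)

# a synthetic receptor-ligand pair whose true bound pose is known
tc <- make_toy_complex(seed = 1)

out <- run_docking_pipeline(
  tc$receptor, tc$ligand,
  dock_params(n_rotations = 500, per_rotation_keep = 10, seed = 17),
  cluster_p = cluster_params(radius = 4))

length(out$models)                                  # up to 10 ranked models
ligand_rmsd(out$models[[1]], tc$planted_pose, tc$ligand)

# whole-surface mapping of a designed pocket
tp <- make_toy_pocket(seed = 1)
mp <- run_mapping_pipeline(tp$receptor,
                           map_params(K = 400, n_rotations = 24, seed = 7))
hotspot_table(mp$sites)
mp$druggability$strongest
sqrt(sum((mp$sites[[1]]$center - tp$cavity_center)^2)) < tp$cavity_radius
```

On the mapping run above the rank-1 consensus site sits inside the
designed cavity (the last line is `TRUE`), `hotspot_table()` lists the
sites with their populations and strength classes, and the druggability
verdict is driven by the strongest site's population against the ≥ 16
threshold. For the docking run, the rank-1 (most populous) cluster's
refined model lands within 2 Å ligand-RMSD of the planted pose.

A worked druggability classification with published hotspot populations:

```r
il2 <- lapply(c(18, 12, 5, 3), consensus_site)   # IL-2 interface hotspots
druggability_report(il2)$druggable               # TRUE  (strongest = 18)
zipa <- lapply(c(8, 3, 2), consensus_site)       # ZipA interface hotspots
druggability_report(zipa)$druggable              # FALSE (strongest = 8)
```

## Command line

```sh
inst/cli/dockmap dock REC.pdb LIG.pdb --rotations 500 --seed 17 --out run/
inst/cli/dockmap ftmap PROT.pdb --seed 7 --out mapdir/
inst/cli/dockmap restraints generate --pair A.85:C.119 --dmin 2 --dmax 10 --required 1
inst/cli/dockmap afscore MODEL.pdb PAE.json --chains-a A --chains-b B
```

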