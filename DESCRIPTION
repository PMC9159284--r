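Package: dockmapr
Title: FFT Rigid-Body Protein-Protein Docking and Computational Solvent
    Mapping of Binding Hotspots
Version: 0.1.0
Authors@R: person("dockmapr", "developers", role = c("aut", "cre"),
    email = "dockmapr@example.org")
Description: Exhaustive rigid-body protein-protein docking by multi-channel
    grid correlation computed with fast Fourier transforms, with pairwise
    distance-restraint filtering (k-of-n group semantics), greedy RMSD pose
    clustering ranked by population, and rigid-body energy refinement.  Also
    implements whole-surface computational solvent mapping with a library of
    16 small organic probe molecules: probe poses are swept over the entire
    surface, minimized off-grid, clustered per probe type by average energy,
    and merged across probe types into consensus sites (binding hotspots)
    that are classified for druggability and assembled into predicted
    binding sites.  Includes interface-RMSD and ligand-RMSD model metrics,
    an average interface predicted-aligned-error (PAE) score for ranking
    predicted complex models, and deterministic synthetic fixtures
    (planted-pose complexes, designed pockets) that make every stage
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
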