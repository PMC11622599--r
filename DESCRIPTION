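Package: chemsa
Title: Chemical Space Annealing for Fragment-Based Molecular Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A global optimizer over synthesizable chemical space. A fixed-size
    bank of molecules is evolved by BRICS-rule virtual synthesis (retrosynthetic
    fragmentation into single-attachment-point fragments and recombination of
    compatible fragment pairs) under a conformational-space-annealing style
    update rule: a niching radius in Tanimoto-distance space is annealed from
    broad to narrow, and trial molecules replace either their nearest bank
    neighbour or the worst bank member depending on that radius. Includes a
    self-contained SMILES/molecular-graph layer with canonicalization and
    circular (Morgan-type) fingerprints, pluggable objective functions
    (synthetic accessibility, QED, logP, similarity to a target, external
    commands), a sphere-intersection shape-overlap score for pre-aligned 3D
    conformers, and diversity metrics (pairwise Tanimoto distance
    distributions, #Circles sphere packing).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
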