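Package: gibbsmotif
Title: Gibbs-Sampling Discovery of Conserved Local Motifs in Protein 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple local alignment of protein 3D structures by Markov chain
    Monte Carlo Gibbs sampling over C-alpha distance geometry. Starting from
    amino-acid triplet fingerprints, the sampler bootstraps three-residue seed
    alignments across all structures, stochastically extends them to a target
    width, refines the worst-aligned columns, and reports alignments ranked by
    average pairwise superposition RMSD with greedy overlap filtering.
    Includes a quaternion characteristic-polynomial (QCP) superposition RMSD
    with an SVD-based Kabsch cross-check, contact-map utilities, a
    planted-motif synthetic benchmark generator, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
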