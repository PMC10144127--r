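Package: barrelmetry
Title: Geometry and Topology Analysis of Beta-Barrel Membrane Protein Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of beta-barrel membrane protein
    conformers, built around the VDAC (voltage-dependent anion channel) fold.
    Reads PDB and mmCIF coordinate models (experimental structures or folding
    engine predictions), detects backbone hydrogen bonds with a
    Kabsch-Sander-style energy criterion, segments beta-strands, builds the
    strand-pairing sheet graph, fits the barrel axis, and measures pore
    diameter, ellipticity, the gap between N- and C-terminal strands, strand
    tilt, sheet twist handedness, stretched hydrogen bonds and N-terminal
    segment contacts. Each structure is classified into a five-class topology
    taxonomy (closed barrel, partial barrel, disrupted sheet, left-twisted
    barrel, collapsed sheet). Includes a deterministic generator of idealized
    beta-barrel coordinates and distorted archetypes with known ground truth,
    and a builder for systematically modified VDAC sequence constructs
    (deletions, insertions, tandem repeats).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
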