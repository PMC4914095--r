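Package: kturnlab
Title: Classification and Sequence Analysis of RNA Kink-Turn Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural and sequence analysis of RNA kink-turn
    (k-turn) motifs. Implements the geometric classification of k-turn cores
    into the N3 and N1 conformational classes from hydrogen-bond acceptor
    geometry at the conserved 2b adenine, C1'-C1' helix-width statistics for
    the 2b/2n, 3b/3n and 4b/4n basepairs, a simplified Leontis-Westhof
    basepair-family assignment for the 3b,3n pair, a 4x4 rule table mapping
    the 3b,3n sequence to conformation and ion-induced foldability, and a
    population-scale profiler that projects multiple sequence alignments onto
    the rule table. A synthetic-data generator produces minimal k-turn
    coordinate sets and alignments with known properties so that the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bp-family.R'
    'geometry.R'
    'kturnlab-package.R'
    'pipeline.R'
    'rules.R'
    'seqprofile.R'
    'structure-io.R'
    'synthetic.R'
    'utils.R'
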