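Package: fintegrate
Title: Integrating Presence/Absence Trait Data with Species-Level Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling ontology-derived presence/absence character
    matrices and integrating them with large, possibly unresolved species-level
    phylogenies. Implements asymmetric ontology-based inference of anatomical
    presence and absence, assembly of provenance-tagged supermatrices,
    taxonomic propagation of genus- and family-level character data to member
    species, two-pass taxon name reconciliation (external identifiers, then
    exact name matching), and unordered (Fitch-Hartigan) parsimony ancestral
    state reconstruction on multifurcating trees with exact counting of most
    parsimonious reconstructions, exact per-transition-type bounds, uniform
    MPR sampling, and random polytomy-resolution replicates. A synthetic-data
    generator with planted trait histories makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
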