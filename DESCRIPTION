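Package: pyrenoid
Title: Annelation Patterns, Clar Sextets, and Strain in Pyrene-Based
    Polybenzenoid Hydrocarbons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph-theoretic analysis of pyrene-based polybenzenoid
    hydrocarbons (PBHs). Represents benzenoids as hexagon assemblies on an
    axial lattice with a direction-annotated dualist graph (helicenic
    winding supported), detects the pyrene core and classifies molecules
    into the eight a/b annelation patterns, enumerates Kekule structures
    and Clar sextet placements to compute fixed and migrating sextet counts
    (Delta-Clar), detects bay/cove/fjord perimeter motifs and scores
    torsional strain (n_strain), and fits the pattern-level linear model
    relating relative isomer energy to strain and Delta-Clar. Includes an
    exhaustive enumerator of the pyrene-cored chemical space with purely
    cata-condensed attachments and a simulator of property tables for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ChemmineR,
    jsonlite,
    optparse
Config/testthat/edition: 3
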