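Package: alphastrand
Title: Alpha-Strand Detection and Topological Water Network Analysis for
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics trajectories of
    amyloidogenic proteins such as alpha-synuclein. Classifies backbone
    phi/psi dihedrals into right- and left-handed helical quadrants, detects
    alpha-strands (runs of residues alternating between the alpha-R and
    alpha-L conformations) and reports their occupancy and first-appearance
    time, detects peptide-plane flip events, scans static structures for
    alpha-strand motifs, and analyses the topological water network around
    selected residues (TIP3P pair energies, hydrogen-bond graph, counts of
    three-membered water rings). A synthetic-trajectory generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
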