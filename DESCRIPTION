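Package: kinomeSR
Title: Reliability Scoring, Differential Phosphorylation and Surface
    Similarity for Peptide-Array Kinome Profiles
Version: 0.1.0
Authors@R: person("kinomeSR", "Developers", email = "kinomesr@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for tyrosine-kinome peptide microarray
    (PamChip-style) experiments that compare cellular responses to
    different culture substrates, such as modified titanium implant
    surfaces.  Spots are filtered by a 1-6 spot-reliability (SR) score
    built from two per-spot statistics, the coefficient of variation
    (sd/mean) and a mean/median skew ratio; reliable spots common to two
    groups are quantile normalized and tested for differential
    phosphorylation with Student's t-test and fold change; surfaces are
    compared with a chi degree-of-similarity statistic.  Also included:
    undirected protein-protein interaction network utilities (degree,
    betweenness and closeness centrality, top-decile comparison), a
    formatter for kinase-substrate prediction input, and a synthetic
    chip-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
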