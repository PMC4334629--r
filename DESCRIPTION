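Package: complexnest
Title: Detection and Characterization of Nested Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to enumerate and characterize nested groups of protein
    complexes in complex catalogs. A nested group is a maximal complex
    together with all catalog complexes whose subunit sets are subsets of
    its subunit set, including sub-subcomplexes and overlapping
    subcomplexes. The package reads complex catalogs (TSV and a
    MITAB-style complex dialect), computes pairwise meet-min and Jaccard
    set similarities with sparse all-pairs matrices, enumerates nested
    groups via a subset DAG and depth-first search, expands complexes into
    protein-level graphs under spoke and matrix models with four
    multi-membership views, and characterizes groups by node centralities,
    shared versus nonshared protein comparisons, hypergeometric enrichment,
    GO-style term counting with a Monte Carlo baseline, GO homogeneity,
    connected 3-5-node motif censuses against a degree-preserving rewiring
    null, and community-detection evaluation with Newman-Girvan modularity.
    A seeded synthetic-catalog generator with planted nesting, provenance
    and annotations supports end-to-end testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
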