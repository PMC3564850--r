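Package: reoccur
Title: Criteria-Based Filtering, Integration and Reoccurrence Ranking of
    Gene Lists and Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Qualitative integration of heterogeneous tabular data sources
    for candidate gene prioritization and composite network construction.
    List sources (one identifier column plus optional attribute columns) and
    network sources (two node columns plus optional attributes) are filtered
    with per-source, user-defined criteria on value (numeric) and label (tag)
    attributes, merged across sources, and ranked by reoccurrence -- the
    number of distinct sources supporting each element or edge. Includes
    cumulative node-degree and edge-reoccurrence statistics, provenance
    preserving tab-delimited reports importable into Cytoscape, a
    hypergeometric overrepresentation test, deterministic force-directed
    network rendering to PNG or TIFF, synthetic fixture generators with
    planted candidates, and a declarative YAML run configuration with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
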