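Package: lymphgraph
Title: Graph-Based Detection and Classification of Lymphocytic Infiltrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and characterizes lymphocytic infiltrates from single-cell
    coordinates in immunostained tissue sections. Builds circumradius-filtered
    Delaunay neighborhood graphs over T- and B-cell positions, decomposes them
    into infiltrates and single-phenotype compartments, computes a per-infiltrate
    feature suite including the tertiary-lymphoid-organ organization score
    kappa(a), calibrates the circumcircle-radius cutoff against pathologist
    annotations, and classifies infiltrates into four organization classes with
    a radial-kernel support vector machine under stratified cross-validation.
    A synthetic point-pattern generator emulating the four infiltrate classes
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
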