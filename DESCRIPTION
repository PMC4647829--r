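Package: essalign
Title: Alignment of Enzymatic Step Sequences from Metabolic Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Transforms KGML metabolic pathway maps into linear Enzymatic
    Step Sequences (ESS) of 3-level Enzyme Commission numbers via
    breadth-first search over the directed enzyme graph, aligns all sequence
    pairs with a global dynamic-programming algorithm minimising an
    EC-hierarchy substitution cost, assesses significance against shuffled
    null databases, and derives functional-conservation classes, metabolic
    map clusters and enzyme-recruitment scans. Includes deterministic
    generators of synthetic KGML fixtures and planted-structure sequence
    databases for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'align.R'
    'clustering.R'
    'conservation.R'
    'ec.R'
    'ess.R'
    'essalign-package.R'
    'fixtures.R'
    'io.R'
    'kgml.R'
    'pipeline.R'
    'scan.R'
    'significance.R'
    'utils.R'
    'weightMatrix.R'
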