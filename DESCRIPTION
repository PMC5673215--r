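Package: chosda
Title: Chitooligosaccharide Deacetylation Analysis and CE4 Deacetylase Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying carbohydrate esterase family 4 (CE4) chitin
    deacetylases and the chitooligosaccharide (CHOS) products they generate.
    Provides exact mass arithmetic for GlcNAc/GlcN oligomers with optional
    2-aminoacridone (AMAC) reducing-end labels, MS2 fragment-ladder
    enumeration and acetylation-pattern ranking for AMAC-labeled CHOS,
    a motif-based candidate-selection funnel for CE4 deacetylases in protein
    collections, reconstruction of acetate-release activity metrics
    (ASAR, deacetylation degree, release rate, apparent rate constant),
    and stochastic simulators of position-biased sequential deacetylation
    together with synthetic spectrum and protein-collection generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
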