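Package: homoplasr
Title: Sliding-Window Phylogenies and Homoplasy Inference for Yeast Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting independent allele-emergence events
    (homoplasy) in panels of resequenced microbial strains. Local
    neighbor-joining phylogenies are rebuilt in a sliding window of
    variants around every locus so that admixture and mosaicism do not
    masquerade as parallel mutation, and a parsimony-style
    ancestral-genotype reconstruction counts how many times each
    alternate allele arose. Companion forward simulators generate
    admixed mosaic populations with a ground-truth mutation log,
    balanced ancestral polymorphism, neutral variant placement on a
    tree, and inbred F6 crosses with planted causal variants; a
    forward-selection QTL mapper with in-silico allele-swap fine
    mapping, a directional (sign-coherence) test for selection, and an
    ecological-niche enrichment permutation test complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
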