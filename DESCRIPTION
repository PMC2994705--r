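Package: chromsim
Title: Stochastic Micromodel of Histone Modification and DNA Methylation Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled dynamics of histone modifications, DNA
    methylation and transcription on a chain of promoter/gene blocks. Histone
    tails of the five core types (H1, H2A, H2B, H3, H4) evolve over enumerated
    combinatorial modification state spaces, one chemical change per time-step,
    with shift probabilities modulated by the block's DNA-methylation level.
    Promoter methylation gates downstream transcription, and the acetylation/
    methylation balance of the histones feeds back into the methylation level.
    Includes state-space enumeration and neighbour graphs, seeded random
    shift-probability tables, most-probable-path queries, a fast compiled
    simulation core, occupancy statistics, and scripted regime experiments
    (pinned low/high methylation, transcription-methylation curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
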