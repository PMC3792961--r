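Package: alnrefine
Title: Short-Read Alignment Refinement, Threshold Variant Calling, and
    Genome Mutation Simulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing of short-read alignments to improve SNP and
    indel calling accuracy: local realignment of mismatched reads around
    catalogued indels, base-quality and allele-frequency driven error
    correction of aligned reads (including pooled samples discriminated
    by read group), and filtering of mismatch-heavy, discordant, and
    degenerate reads. Includes a threshold-based SNP/indel caller
    operating on pileup data or directly on alignments, a reference
    genome mutation simulator with an empirical transition/transversion
    and indel-length model, a truth-set evaluator computing true and
    false positive rates, and a synthetic read generator for hermetic
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
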