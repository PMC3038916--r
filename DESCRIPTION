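Package: seqem
Title: Sequencing Error Assessment and Mitigation for Low-Coverage Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies sequencing error in low-coverage (~2x) genome
    assemblies by comparison with high-quality reference sequence, and
    mitigates it in multiple alignments. Reads MAF alignments augmented
    with per-base phred quality lines, tabulates draft-versus-reference
    differences by quality bin with a polymorphism correction based on
    the highest-quality bases, and models the relationship between
    average read coverage and assembly error under Poisson read depth.
    Error mitigation includes quality-threshold base masking, an
    optional logistic-regression classifier that combines quality
    scores with a phylogenetic error log-odds score computed by
    Felsenstein pruning, and parsimony-based imputation of spurious
    lineage-specific indels via exact min-sum message passing over
    indel presence/absence states. A truth-tracked synthetic-data
    generator reproduces the statistical structure the methods assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
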