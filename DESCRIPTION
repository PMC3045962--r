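Package: cdr3err
Title: Sequencing-Error Profiling and Filtering for TCR CDR3 Amplicon Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising and removing sequencing errors in
    high-throughput T cell receptor (TCR) CDR3-beta amplicon data. Provides a
    ground-truth read simulator with position-, substitution-, lane- and
    direction-specific error rates and quality-correlated errors; strict CDR3
    extraction (exact V/J flank identity, frame, stop-codon and conserved-motif
    criteria) with phred-cutoff filtering; descriptive error profiling
    (position-by-substitution rate matrices, lane coefficients of variation,
    per-cell one-way ANOVA); analytic error models (independence expectation
    for multi-substitution reads, exact-binomial read-direction boundaries,
    binomially adjusted low-count culling thresholds); single-nucleotide
    mismatch clonotype culling for monoclonal and polyclonal repertoires; and
    abundance-based coverage (ACE) richness estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
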