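Package: genomepam
Title: Characterization of CRISPR-Cas PAM Preferences from Genomic Repeat Protospacers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines protospacer-adjacent motif (PAM) preferences of CRISPR-Cas
    nucleases from cleavage evidence at highly repetitive genomic protospacers.
    Provides a k-mer census with repeat-candidate filters and flank-diversity
    summaries, Hamming-neighborhood enumeration of candidate targets, matching of
    cleavage events to protospacer-aligned sites, read-weighted position frequency
    matrices, PAM cleavage values (PCV) against a genomic background, an iterative
    seed-extension motif table with chi-square enrichment tests, cross-enzyme
    activity/specificity and read-downsampling metrics, chromosomal window
    cleavage profiles, and a synthetic-data generator with planted PAM activity
    models for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
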