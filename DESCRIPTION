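Package: hgtscreen
Title: Contamination-Aware Screening of Horizontal Gene Transfer in Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes genuine horizontal gene transfer (HGT) from
    assembly contamination in annotated genome assemblies. Implements
    per-gene taxonomy-scope classification from annotation evidence,
    scaffold-level contaminant removal by taxonomic gene composition,
    donor/recipient-database HGT candidate screening with flanking-gene
    validation, cross-species HGT presence summaries from best-hit tables,
    and quartile-based gene-family expansion/contraction calls. Includes a
    synthetic-assembly generator with planted truth labels so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
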