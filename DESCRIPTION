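Package: editaudit
Title: Auditing of In Vivo Base-Editing Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to audit the outcomes of in vivo CRISPR base-editor
    treatment from sequencing data: multi-caller variant consensus with
    tissue triangulation and known-variant exclusion, nucleotide conversion
    spectra, guide-RNA/PAM constrained edit-distance homology scanning
    around candidate variants, amplicon editing metrics (repaired fraction,
    bystander edits and their codon consequences, indel rates), delta-PSI
    rescue classification of alternative-splicing events, and a
    single-nucleus gene-set activity score with threshold scanning. A
    synthetic-data module generates every pipeline input with known ground
    truth so that each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
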