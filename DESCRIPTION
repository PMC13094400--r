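Package: hlakit
Title: Standards-Conformant Exchange of HLA Genotyping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exchanging clinical HLA genotyping results in
    standardised, machine-readable form. Parses and serialises WHO HLA
    nomenclature allele names and GL Strings (the delimiter-based grammar for
    allele-, haplotype-, genotype- and locus-level ambiguity) together with
    their GL String Code reference context; expands NMDP Multiple Allele
    Codes against a pluggable code table; validates and generates
    19-character checksummed GRID donor identifiers; reads, writes and
    losslessly converts a minimal histoimmunogenetics markup language (HML)
    message profile between XML and JSON; and evaluates messages against a
    tiered (Minimal/General/Optional) catalog of data-exchange compliance
    rules, emitting auditable JSON reports. Seeded generators produce
    synthetic GL Strings, GRIDs and HML messages, including single-defect
    mutants for negative testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
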