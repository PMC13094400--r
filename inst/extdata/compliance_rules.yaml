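# Tiered compliance rule catalog. Tiers nest: General expands on Minimal,
# Optional on General. Severities are configurable per deployment; rules
# whose standing is contested in practice (MAC presence is tolerated by
# registries but discouraged for interoperable exchange) default to
# "warning" so implementers can re-map without code changes. The check
# predicates live in the package, keyed by rule id; this file owns tier,
# severity and the audit texts.
catalog_version: "1.0.0"
rules:
  - id: M1
    tier: Minimal
    severity: error
    description: Every sample carries a patient identifier (patient-ref property).
    corrective_action: Add a <property name="patient-ref" value="..."/> element
      to each sample.
  - id: M2
    tier: Minimal
    severity: error
    description: Every sample carries center identifiers, lab-ref (typing center)
      and tc-ref (transplant center).
    corrective_action: Add lab-ref and tc-ref properties identifying the typing
      and transplant centers.
  - id: M3
    tier: Minimal
    severity: error
    description: Every allele assignment declares the reference database and a
      parseable release version.
    corrective_action: Set allele-db and a major.minor.patch allele-version on
      each allele-assignment.
  - id: M4
    tier: Minimal
    severity: error
    description: Every allele assignment carries a GL String that parses under
      the genotype-list grammar.
    corrective_action: Supply a syntactically valid GL String in each
      allele-assignment.
  - id: M5
    tier: Minimal
    severity: error
    description: Only official WHO nomenclature allele names are used (no
      unofficial little-g group forms).
    corrective_action: Replace little-g designations with official WHO G/P group
      names or fully specified alleles.
  - id: G1
    tier: General
    severity: error
    description: Each typing includes a machine-readable typing method
      description.
    corrective_action: Add a typing-method block with at least a description of
      the method used.
  - id: G2
    tier: General
    severity: error
    description: The gene family declared on the typing is consistent with the
      loci named in its GL String, and no locus block mixes genes.
    corrective_action: Align the typing gene-family attribute with the loci in
      the GL String and split mixed-locus blocks.
  - id: G3
    tier: General
    severity: error
    description: Every fully specified allele name resolves in the declared
      reference catalog release.
    corrective_action: Re-call or re-name alleles against the declared
      IPD-IMGT/HLA release, or correct the declared allele-version.
  - id: O1
    tier: Optional
    severity: error
    description: Raw data is reported alongside the assignment as a consensus
      sequence.
    corrective_action: Attach the consensus sequence supporting each allele
      assignment.
  - id: O2
    tier: Optional
    severity: warning
    description: The GL String payload is free of legacy NMDP Multiple Allele
      Codes.
    corrective_action: Expand Multiple Allele Codes to explicit allele lists
      before exchange.
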