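# hlakit

Tools for exchanging clinical HLA genotyping results in standardised,
machine-readable form.

Histocompatibility laboratories report HLA typings to transplant centers and
donor registries, and those results drive donor selection. The exchange
formats of the field have precise structure that ad hoc pipelines routinely
get wrong: WHO nomenclature allele names (`HLA-A*01:01:01:01`), the GL
String grammar for typing ambiguity, the HML message standard, NMDP Multiple
Allele Codes, and the 19-character checksummed GRID donor identifier.
`hlakit` implements each of these as a parser/validator pair, plus a tiered
compliance engine that audits messages against Minimal / General / Optional
data-exchange recommendations and emits JSON reports suitable for
accreditation evidence. It is aimed at laboratory bioinformaticians and LIMS
integrators who need standards-conformant import, export and validation
without a registry-scale software stack.

## What is implemented

* **Nomenclature** — `parse_allele_name()` splits a WHO allele designation
  into locus, 1-4 numeric fields (field count = typing resolution), an
  optional expression suffix (`N/L/S/C/A/Q`) and official `G`/`P` group
  suffixes. Unofficial "little-g" groups are rejected by default.
  `read_allele_catalog()` / `validate_against_catalog()` resolve names to
  IPD-IMGT/HLA accession IDs by exact canonical lookup, with a distinct
  `unknown_at_resolution` state. `version_to_branch()` maps a release
  version to its repository branch (3.57.0 ↔ `3570`) and back.
* **GL Strings** — `parse_glstring()` / `serialize_glstring()` implement the
  five-delimiter ambiguity grammar, loosest to tightest binding:
  `^` locus blocks, `|` genotype alternatives, `+` haplotypes, `~` in-phase
  alleles, `/` allele ambiguity. `enumerate_genotypes()` performs Cartesian
  expansion of one locus with unordered-genotype deduplication and a hard
  cap; `parse_glcode()` handles the `namespace#version#glstring` reference
  context.
* **MAC** — `expand_mac()` rewrites a Multiple Allele Code in final-field
  position into its explicit `/`-joined allele list against a pluggable code
  table; `contains_mac()` flags MAC-bearing payloads.
* **GRID** — `validate_grid()` / `compute_checksum()` / `generate_grid()`
  implement the 4+14+1-character donor identifier. The default check
  character is the ISO 7064 MOD 37-2 pure system: the check value c
  satisfies `sum(a_i * 2^(n-i)) + c ≡ 1 (mod 37)` over the 18 payload
  characters, which detects 100% of single substitutions; truncation is
  caught by the exact-length rule. A numeric MOD 11-2 variant ships too.
* **Minimal HML** — `read_hml_xml()` / `write_hml_xml()` /
  `hml_to_json()` / `hml_from_json()` read and write a stripped-down HML
  profile (header, samples with `lab-ref`/`tc-ref`/`patient-ref`
  properties, allele assignments with database version, date and GL String,
  optional typing method and consensus sequence) losslessly between XML and
  JSON, preserving unknown elements verbatim.
* **Compliance** — `run_compliance()` evaluates ten rules (M1-M5, G1-G3,
  O1-O2) from a YAML rule catalog and returns a tibble report with
  per-tier verdicts; `report_to_json()` emits the audit record;
  `tidy()`/`glance()` summarise it broom-style.
* **Fixtures** — `gen_glstring()` / `gen_hml()` are seeded generators with
  single-defect injection for negative testing; `golden_figure3()` is the
  bundled reference message.
* **CLI** — `hla_dispatch()` plus the launcher
  `system.file("cli", "hlatool", package = "hlakit")` expose everything to
  shell scripts (`grid check`, `hml convert`, `validate`, ...), with stable
  exit codes 0/1/2.

## Worked example

Validate the bundled reference message (cell line IHW9224, typed by center
NUTTT for transplant center NLUT1 against IPD-IMGT/HLA 3.57.0) at the
General tier:

```r
library(hlakit)
msg <- read_hml_xml(system.file("extdata", "figure3_minimal.hml.xml",
                                package = "hlakit"))
run_compliance(msg, tier = "General", catalog = read_allele_catalog())
#> <hla_compliance_report> message MSG-IHW9224-0001, tier General
#>   verdicts: Minimal=pass, General=fail
#> # A tibble: 8 × 7
#>   rule_id tier    severity outcome evidence        description
#> 1 M1      Minimal error    pass    ""              Every samp…
#> ...
#> 6 G1      General error    fail    "sample[1 'IHW… Each typin…
```

All five Minimal rules pass — identifiers, center references, database
version, a parseable GL String, official nomenclature. The General verdict
fails on G1 because the reference typing was taken from the database and
carries no typing-method block; the report's `corrective_action` column
says what a submitting laboratory would have to add.

Expanding the classic exon-2-identical ambiguity, and the other converters:

```r
enumerate_genotypes("HLA-DRB1*14:01/HLA-DRB1*14:54+HLA-DRB1*01:01:01")
#> [1] "HLA-DRB1*01:01:01+HLA-DRB1*14:01" "HLA-DRB1*01:01:01+HLA-DRB1*14:54"

version_to_branch(release_version("3.57.0"))
#> [1] "3570"

g <- generate_grid("9990", seed = 1)
canonical_text(g)
#> [1] "9990836016120449593"
validate_grid(substr(canonical_text(g), 1, 18))   # truncation is caught
#> [1] "wrong_length"
```

The two DRB1 genotypes are exactly the clinical ambiguity: the alleles are
identical across the antigen recognition domain, so only the reported list
distinguishes them.

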