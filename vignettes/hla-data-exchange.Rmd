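---
title: "Standards-conformant exchange of HLA genotyping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standards-conformant exchange of HLA genotyping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlakit)
```

## The problem

Molecular HLA typing results move between analysers, laboratory information
systems, transplant centers and donor registries, and every hop is an
opportunity for loss of meaning: a truncated donor identifier, an allele
name valid only under an unstated database release, an ambiguity silently
collapsed to a single allele, a PDF that has to be re-keyed by hand.
`hlakit` treats the exchange artefacts themselves — allele names, GL
Strings, HML messages, MAC codes, GRID identifiers — as parseable, checkable
objects, and provides a tiered rule engine that turns "is this message fit
for exchange?" into an auditable computation.

This vignette explains the models and conventions behind each module, the
parameters that matter, what the synthetic generators do and do not emulate,
and the design decisions taken where the standards leave room.

## Allele names and reference releases

A WHO nomenclature allele name is `HLA-<locus>*f1:f2[:f3[:f4]]` plus an
optional suffix. The parser keeps the colon-separated fields as *strings*:
`"01"` and `"1"` are different labels, comparison is on the canonical
serialisation, and field count is the typing resolution (`resolution_of()`).
Names lacking the `HLA-` prefix occur in the wild and are accepted with a
warning, then normalised, because the canonical form must be single.
Unofficial "little-g" group names are rejected by default: they are
interpretations, not reportings, and only official WHO nomenclature should
cross laboratory boundaries. They can be parsed with `allow_g = TRUE` — the
leaf is flagged `official = FALSE` — precisely so the compliance engine can
*report* them rather than crash on them.

Allele names only mean something relative to an IPD-IMGT/HLA release.
Releases are mirrored by repository branches named by concatenating the
version digits (3.57.0 ↔ `3570`). The branch form has no separators, so
`branch_to_version()` needs a width convention; we use: last digit = patch,
preceding up to two digits = minor, remainder = major. That matches current
release numbering (single-digit major, minor below 100, patch below 10) and
makes the conversion an identity round trip on that whole range, which the
suite verifies by brute-force sweep. Degenerate long branches are parsed
under the same rule (`"35700"` → 35.70.0) rather than rejected; the result
still round-trips, and the convention is documented rather than guessed at
per-input.

Catalog lookup is deliberately exact — no fuzzy matching, no cross-release
translation. Translation is refused rather than attempted because a GL
String's accuracy is tied to the release it was called under. A query that
is a field-prefix of a catalog entry (or vice versa) returns
`unknown_at_resolution` instead of `not_found`, distinguishing "wrong name"
from "known allele, different resolution". The bundled catalog is a ~20
entry toy subset for release 3.57.0: one real worked pair
(`HLA-A*01:01:01:01` / `HLA00001`), synthetic `HLA9xxxx` accessions for the
rest, and the DRB1\*14:01 / 14:54 pair cross-annotated as ARD-identical
(identical exon 2 sequence, hence unresolvable by ARD-only typing).

## The GL String grammar

Nomenclature encodes resolution but not ambiguity between calls. The GL
String grammar does, with five delimiters (loosest to tightest binding):

| delimiter | joins | level |
|---|---|---|
| `^` | locus blocks | multilocus genotype |
| `\|` | genotype alternatives | one locus |
| `+` | haplotypes (gene copies) | genotype |
| `~` | allele lists in phase | haplotype |
| `/` | ambiguous alleles | allele list |

The standards name the concepts; the characters follow the published GL
String grammar. The parser is recursive descent over that hierarchy and the
suite separately checks it against a plain split-in-delimiter-order oracle,
so the precedence claim is tested, not assumed. Serialisation preserves
author ordering at every level; nothing is sorted on the wire.

`enumerate_genotypes()` expands one locus block to unambiguous genotypes.
Genotypes are unordered multisets of haplotypes, so expansions are
deduplicated after sorting haplotypes lexicographically — `a/b + a/b` gives
3 genotypes, not 4 — but that sort exists only inside
enumeration/comparison. The raw expansion count (sum over alternatives of
the product of allele-list sizes) is computed *before* expanding and
compared against a cap (default 10,000): exceeding it is an explicit
overflow error, never silent truncation, because a truncated ambiguity list
reads as a confident result.

Two permissive choices are intentional. Mixed resolutions within one allele
list are allowed by the parser (the standards do not forbid them) and left
to the compliance layer to flag if a deployment cares. And whitespace is
illegal in strict mode with a warn-and-strip lenient mode, since copy-pasted
clinical strings often grow spaces.

GL String Codes bind the reference context to the payload as
`namespace#version#glstring` (`#` per the GLSC syntax); parsing validates
all three parts and round-trips.

## Multiple Allele Codes

MACs are a registry-era shorthand: an uppercase letter code in final-field
position standing for a set of alternatives. The field is split on their
standing — tolerated in registry ambiguity reporting, discouraged for
interoperable exchange — so this toolkit takes no side in code: expansion
(`expand_mac()`) and detection (`contains_mac()`) are provided, the
compliance rule (O2) defaults to severity *warning*, and the severity is a
YAML edit away for deployments that want it to be an error.

Generic codes substitute the final field; allele-specific codes replace the
last *two* fields (the documented NMDP convention). When an allele-specific
expansion disagrees with the typed first field the expansion wins but a
warning is raised — silent acceptance is how transcription errors persist.
Expanded output is guaranteed MAC-free and re-parseable; both properties
are tested. Catalog validation applies only to fully expanded names: a
MAC-bearing name is not a WHO name and is never looked up directly.

## GRID identifiers

The donor-identifier module enforces the two structural guarantees that
give GRID its value: exactly 19 characters (4 issuer + 14 registrant + 1
check; widths are scheme constants), so any deletion is detectable by
length alone, and a check character over the first 18. The standard fixes
length and the existence of a checksum but not the algorithm, so the
algorithm is a pluggable strategy. The default is the ISO 7064 MOD 37-2
pure system over `0-9A-Z` (check alphabet `0-9A-Z*`), following the WMDA
GRID specification lineage; a pure-numeric MOD 11-2 variant is included.
For a pure system over prime modulus M with radix 2, a substitution at
position k changes the weighted sum by `(a-b)·2^k mod M ≠ 0`, so *every*
single-character substitution is detected — the suite confirms 100%
detection by exhaustive sweep rather than trusting the algebra. Whether
registrant bodies are numeric or alphanumeric varies by issuer practice and
is not fixed by the standard; both validate under the default scheme and
`generate_grid()` emits numeric bodies. Validation returns result kinds
(`wrong_length`, `illegal_character`, `checksum_mismatch`), never throws:
its callers are validators.

## The minimal HML profile

Full HML is large; the profile here is the minimal clinically sufficient
core: header (message id, creation timestamp, reporting center), samples
with registry properties (`lab-ref`, `tc-ref`, `patient-ref`), and per
typing an allele assignment (database, release version, date, GL String),
optional machine-readable method and optional consensus sequence. Everything
outside that profile is preserved verbatim in `extras` bags and re-emitted,
so read → write is lossless even for messages richer than the profile.

Serialisation choices, all in the service of diff-ability and audit:
deterministic element order (header, samples in input order, properties
sorted by key), two-space indentation, byte-stable output; JSON with
canonically sorted keys mirroring the XML model one-to-one, so XML → JSON →
XML is the identity (the JSON layout is published as a schema file under
`inst/extdata/`). Documents are accepted with or without an XML namespace
and emitted without one. Typographic hyphens and quotes are normalised to
ASCII on read — they are typesetting artifacts, not data. Dates are
timezone-free ISO-8601 calendar dates. Consensus sequences are carried as
opaque strings (sequence validation is out of scope) with a FASTA export
(`export_consensus_fasta()`) as the interoperability escape hatch.

## The compliance engine

The rule catalog is data (`compliance_rules.yaml`): id, tier, severity,
description, corrective action. Predicates live in code keyed by id. Tiers
nest — General expands on Minimal, Optional on General — and the verdict for
tier T considers every severity-`error` rule at tier ≤ T. Monotonicity
(pass(Optional) ⇒ pass(General) ⇒ pass(Minimal)) therefore holds by
construction and is additionally verified over a 1,000-message generated
corpus.

Three evaluation conventions matter:

* **No fail-fast.** Every rule is evaluated and every failure reported with
  an evidence string naming the offending element; audit reports that stop
  at the first error are useless for correction.
* **`not_evaluated` is not a pass.** The catalog-membership rule without a
  catalog (or with a catalog for a different release), and the
  nomenclature-inspection rules when no GL String parses, report
  `not_evaluated` explicitly. They do not fail the verdict — the defect that
  *caused* the missing input is already some other rule's finding — but
  they are visible in the report.
* **One defect, one rule.** An unparseable GL String fails the grammar rule
  (M4) only; the official-nomenclature rule (M5) inspects only payloads
  that parse, and treats MAC leaves as out of scope (the MAC rule owns
  them). Without this discipline a single injected defect flips several
  rules and mutation testing cannot localise anything.

Whether a method-less message can satisfy the General tier is a catalog
question, not a code constant: the bundled catalog says no (G1 is a
General-tier error), and the reference message — database-derived, hence
method-less — duly passes Minimal and fails General. Range/consistency
checking is realised as the bounded checks above; statistical outlier
detection on typing distributions is deliberately out of scope.

Reports record toolkit version, rule-catalog version, declared reference
release and timestamp, so a verdict can be reproduced from its recorded
inputs; two runs on the same input differ only in the timestamp. The
retention-profile table ships the HIPAA floor (6 years for
compliance documentation); `miring_capable()` encodes the fact that HML
versions ≥ 1.0 are structured implementations of the MIRING guideline.

## What the generators emulate — and what they do not

`gen_glstring()` and `gen_hml()` exist so every pipeline stage is testable
with no registry download. They emulate *structure*: ambiguity shapes
within configured bounds (allele-list size ≤ 3, ≤ 2 genotype alternatives,
phase depth ≤ 2 by default — the scale of routine clinical ambiguity
reporting, not worst-case registry payloads), leaves drawn from the toy
catalog so catalog membership passes by construction, messages that pass
the full default catalog unless a defect is requested, and exactly one
targeted mutation per requested rule id. Seeds fix outputs byte-for-byte,
are recorded in the generated message id and a `generator-seed` property
for provenance, and the generators restore the session RNG state.

They do **not** emulate population allele frequencies, realistic linkage
between loci, read-level sequencing artefacts, or the long-tail structural
variety of production HML (projects, QC blocks, multi-sample batches).
Passing the suite therefore demonstrates contract correctness — grammar,
losslessness, checksum algebra, rule logic — not robustness to every
malformed message a production gateway will see.

Phased same-locus allele lists (`a~b` within one block) are grammatically
valid and generated, though real phase reporting usually spans loci; the
profile here keeps blocks single-locus (the locus-consistency rule enforces
it) and represents phase within that constraint.

## Numerical and testing choices

Problem sizes in the shipped suite: 1,000-identifier GRID sweeps with
exhaustive single-deletion and single-substitution mutation (~700k
validations, vectorised); a 5,000-version brute-force round-trip sweep of
the branch mapping; 1,000 seeded GL Strings checked for round-trip identity
and expansion-count agreement against an independent `expand.grid` oracle;
a 1,000-message compliance corpus cycling through all eleven
defect-or-clean configurations. Smaller per-module tests re-check the same
properties at readable scale. All randomness flows through seeded local
RNGs that save and restore the caller's state.

## Known limitations

* G/P group names are parsed and carried but not expanded to member
  alleles: group-definition files are a registry artefact outside this
  package's inputs.
* Catalog and MAC tables are toy-scale bundled fixtures; production use
  plugs in real exports via the `path` arguments (the dialects are
  two-column TSV precisely so those exports are trivial to produce).
* The JSON schema files document the serialisations; runtime validation is
  structural (required paths) rather than a full JSON-Schema evaluation.
* No serologic antigen interpretation, no HL7/FHIR resource mapping, no
  sequence alignment, and no enforcement of organisational controls
  (access, encryption, backup) — those are process controls, not message
  computations.
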