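---
title: "Auditing COI reference databases with coiaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing COI reference databases with coiaudit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiaudit)
```

## The audit model

COI metabarcoding assigns anonymous amplicons to taxa by comparison with
reference sequences, so the usability of a reference database is a
function of a few auditable record properties. `coiaudit` models one
reference record by the fields that drive those properties: accession,
deposit year, organism name, lineage, keyword set (notably the INSDC
`BARCODE` flag), gene labels, sequence length, and the raw `country` and
`lat_lon` source qualifiers. The audit then answers four questions per
record partition: what fraction of names is usable at species rank, and —
among those — what fractions have good length, a country, and
coordinates.

### The name grammar

A name is **fully identified** when no whitespace-delimited token run
matches a disqualifier token (case-insensitively; multi-word tokens such
as `sp. nov.` match as contiguous runs) and the name starts with a
capitalized alphabetic genus followed by a lowercase alphabetic epithet
(internal hyphens allowed). Everything else is **insufficiently
identified**. Two disqualifier presets ship: `genbank` (`sp.`, `nr.`,
`aff.`, `cf.`) for screening NCBI names, and `iucn` (`affinis`, `sp.`,
`sp. nov.`) for screening Red-List species exports; the two screens come
from different curation traditions and are deliberately not unified.
Three choices here were genuinely open and are fixed as follows:

* Token comparison requires the trailing period where the preset prints
  one, so `sp.` never rejects `spectabilis` by substring accident.
* Trinomials and longer names with a valid leading binomial and no
  disqualifier are fully identified, with the epithet taken from token
  two; species rank is what the audit cares about.
* Hybrid markers (`x`, `×`) are not disqualifiers by default; a custom
  `disqualifier_set()` can add them.

The implementation is checked against a brute-force oracle that
enumerates every contiguous token run of a name.

### Percentages and growth

Every printed percentage goes through one rule,
`percent(n, d) = floor(100 n / d + 0.5)` (round half-up, 0 when `d = 0`).
Growth is the geometric average of year-over-year ratios, which
telescopes to `(n_last/n_first)^(1/k) − 1` over `k` intervals. Two
conventions needed fixing:

* **Denominators.** Completeness panels (length ≥ 500 bp, country,
  lat_lon) are computed among fully identified records; the audit report
  also carries the of-total percents because summary abstracts are often
  ambiguous about the denominator.
* **Growth basis.** Headline database growth is quoted on the
  *cumulative* basis by default (`geometric_growth(s, "cumulative")`),
  with the per-year *deposited* basis behind a flag; published headline
  rates for reference databases reproduce from cumulative endpoints.
  Zero counts make a geometric mean undefined: the package raises an
  error naming the offending year rather than silently skipping it,
  since silent skipping makes rates irreproducible.

### Partitions

Four partitions mirror common audit practice: all COI records
(`filter_coi`, matching gene labels CO1/COI/COX1/COXI
case-insensitively), `BARCODE`-flagged records (`filter_keyword`,
exact uppercase match — the INSDC keyword is standardized), high-level
freshwater biomonitoring target taxa (`filter_taxa` with the bundled
group list: Clitellata, Polychaeta, Coleoptera, Diptera, Ephemeroptera,
Megaloptera, Odonata, Plecoptera, Trichoptera, Amphipoda, Isopoda,
Bivalvia, Gastropoda, Turbellaria), and a species checklist partition
(`match_checklist`, with synonym resolution). Lineage matching is by
exact taxon-name string in the record lineage, not by rank: flatfiles do
not carry taxon ids, and the lineage string is the closest
flatfile-resident equivalent. A record matching several groups counts
once in the union and once per group in the attribution table; both
numbers are reported because the union/attribution distinction is
exactly where double-counting errors hide. Checklist partitions are
audited with `species_list_mode = TRUE`: records were *found by
searching for specific species names*, so the fully-identified panel is
100% by construction.

## File formats and their gaps

**GenBank flatfiles** are parsed for the audited slice only (LOCUS,
ACCESSION, KEYWORDS, SOURCE/ORGANISM, source and gene features, ORIGIN).
Flatfiles do not carry the Entrez deposition date (`PDAT`), so the
LOCUS-line date supplies the deposit year; the synthetic generator
writes the intended year into that date, which keeps every year-based
test exact while staying offline. Only the first source feature is
consulted for geo qualifiers (multi-source records are rare; a warning
is logged). Keywords are split on semicolons/whitespace and the
flatfile's trailing period stripped (`BARCODE.` → `BARCODE`).
`write_genbank()` exists so the generator can serialize fixtures; the
write-then-read round trip is the identity on all record fields and is
property-tested.

**BOLD dumps** are read either as TSV (header required; common BOLD
column spellings accepted) or FASTA with pipe-delimited headers in the
fixed order `id|taxon|marker|accession` (the common export layout;
the dialect argument keeps this explicit). Empty or placeholder
accession fields map to absent.

**Checklists** are two-column TSV: name, plus the canonical name when
the row is a synonym. Matching is case-insensitive and
whitespace-normalized; no fuzzy matching and no validation against a
taxonomy authority (out of scope by design).

## The BOLD/GenBank crossref

`crossref()` partitions BOLD records three ways: accession in the
BARCODE-flagged set; accession present but not BARCODE-flagged;
no accession (unique to BOLD). Accessions are uppercased and version
suffixes stripped on both sides — BOLD stores versionless accessions
inconsistently, and this is the conservative join. Records linked to an
accession absent from a supplied all-accession index (suppressed
GenBank records) are reported as a sub-count only; they stay in the
accession-linked category, because suppression status is usually
unknowable from a dump alone.

## Geography

`parse_lat_lon()` implements the INSDC `"DD.DD N DD.DD W"` dialect with
S/W as negative signs and range validation. In `summarize_geo()`
malformed coordinate strings demote the record to "no lat_lon" with a
logged count rather than aborting — real GenBank data contains dialect
violations. Country names take the substring before the first colon
(the `"Country: region"` convention) and then pass through a
user-extensible alias table (e.g. `USA` → `United States`) defaulting to
identity; no geocoding and no historical border reconciliation. The
top/bottom country split takes the top `ceiling(0.05 K)` of `K`
distinct countries by count, ties broken by descending count then
lexicographic name — the 5% cut is not operationally defined in common
usage, so this deterministic rule is fixed here. Tallies are computed
over fully identified records only, matching how such maps are
conventionally drawn.

## The synthetic generator: what a green test establishes

`generate_synthetic()` emulates the statistical structure the audit
assumes, with complete ground truth. Defaults state the emulated world:
deposition 2003–2017 growing geometrically at 51% per year
(`round_half_up(base · 1.51^(y−2003))` records per year); 55% of names
fully identified (the rest get a random disqualifier decoration); 28%
BARCODE-flagged, and BARCODE records always carry both geo qualifiers
(BARCODE-standard records are near-universally geotagged); 74% / 51%
of other records with country / lat_lon; sequence lengths uniform on
450–1000 bp (≈ 91% ≥ 500 bp); a Zipf-skewed country distribution over a
bundled 30-country list (exercising the top-5% split the way a
Canada-heavy record base does); a BOLD dump with category mix 15/48/37;
and a checklist half of whose names can match, plus synonyms that are
planted onto real records so synonym tallying has known truth.
`base_deposits` defaults to 10 first-year records (~9,500 records over
the window) — desk scale, not database scale. Species names are
synthesized from syllable templates; sequences are random nucleotides.

What a green test does establish: parsing, classification, filtering,
counting, growth, crossref and geo logic are exact on data whose truth
is known, at realistic proportions. What it does not establish: realism
of sequence composition, real-world name-spelling noise, taxonomy-id
resolution, or the behavior of live Entrez/BOLD retrieval (query strings
are built but never executed, by design).

Generator parameters, once stated, are never tuned toward test
outcomes; sampled proportions are asserted within three binomial
standard deviations, deterministic quantities exactly. The
parameter-recovery check runs with `p_barcode = 0` because the
BARCODE-forces-geotag rule otherwise shifts the marginal geo fractions
away from the configured values — that is a property of the emulated
world, not a test artifact.

## Numerical and interface choices

* Rounding is half-up everywhere a percent is printed; growth rates are
  kept at full precision internally and displayed at one decimal, with
  half-up integer rounding for headline figures.
* Degenerate inputs: an empty partition yields an all-zero report with
  a `degenerate` flag; an empty record set is valid everywhere.
* Configs are JSON (synthetic overrides) and TSV (taxon groups,
  checklists, aliases); all outputs are plain UTF-8 TSV/CSV/JSON.
* `run_cli()` returns an exit status instead of calling `quit()`, so
  the CLI is testable in-process; the `inst/cli/coiaudit.R` wrapper
  supplies the executable entry point. Every run writes a
  `manifest.json` (subcommand, inputs, seed, counts, version), and
  identical inputs plus seed reproduce byte-identical outputs.
* One published figure is deliberately not reproduced: a 27%/yr growth
  rate for endangered-species records whose printed endpoints (15 to
  3,217 over 14 intervals) yield ~47% under any basis — the endpoints
  are suspect (3,217 duplicates another partition's first-year count),
  so the package documents the discrepancy instead of guessing.
  Similarly, the published BOLD API row total disagrees with the sum of
  its three category counts by ~13k; `crossref_partition()` keeps the
  partition invariant (total = sum) and the published percents
  reproduce under either denominator.

## Known limitations

Only the audited slice of the flatfile grammar is modeled (no EMBL/DDBJ
dialects, no full feature-table semantics). Name classification is
grammatical, not nomenclatural. Country standardization is only as good
as the alias table. Cross-set record de-duplication is the caller's
responsibility beyond per-set accession uniqueness. Sequence quality
(ambiguity codes, stop codons) is out of scope: this is a metadata
audit.
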