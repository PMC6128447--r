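# coiaudit

Tools for auditing COI DNA-barcode reference databases in R.

## The problem

Cytochrome c oxidase subunit 1 (COI) is the standard animal DNA barcode,
and COI metabarcoding — identifying bulk or environmental amplicons
against a reference database — is only as reliable as the reference
records behind it. Practitioners therefore need to ask, of the millions
of COI records in the NCBI nucleotide database and the Barcode of Life
Data System (BOLD):

* How many records carry a usable species-rank name (a complete Latin
  binomial, with no `sp.` / `nr.` / `aff.` / `cf.` hedge)?
* How complete is the MIMARKS-relevant metadata — sequence length,
  `country`, `lat_lon`?
* How fast is the database growing, and how many distinct species do new
  records add per year?
* How much of BOLD is cross-referenced into GenBank (via accessions and
  the INSDC `BARCODE` keyword), and how much is unique to BOLD?
* Which countries dominate the geographic record?

`coiaudit` implements this audit as a reusable, fully offline pipeline:
GenBank flatfile and BOLD dump parsing, an organism-name grammar,
partition filters, completeness reports, growth statistics, a three-way
BOLD/GenBank reconciliation, geographic summaries, and builders for the
Entrez/BOLD query strings needed to reproduce a retrieval (the package
never touches the network). A synthetic record generator with complete
ground truth makes every stage testable without a download.

## The statistics at the core

All printed percentages use one rule, round-half-up:

    percent(n, d) = floor(100 * n / d + 0.5)

Database growth is the geometric average of year-over-year ratios of
counts n_y, which telescopes to the endpoint form

    rate = (n_last / n_first)^(1/k) - 1,   k = number of year intervals.

Completeness percentages (length ≥ 500 bp, country, lat_lon) are
computed among *fully identified* records — names that pass the
binomial grammar with no disqualifier token.

## Worked example

```r
library(coiaudit)

# a synthetic record universe: 2003-2017, 51%/yr deposition growth,
# 55% fully identified, 28% BARCODE, skewed country distribution
dat <- generate_synthetic(synthetic_config(seed = 7))
dat$records
#> <record_set> 9467 record(s) [synthetic(seed=7)]

audit(dat$records, label = "All")
#> <audit_report> All: n=9467
#>   fully identified: 5202 (55%)
#>   of fully identified: length >= 500 bp 91%, country 81%, lat_lon 65%

s <- build_series(dat$records, year_range = 2003:2017)
geometric_growth(s, basis = "deposited")
#> <growth_summary> 51.0% per year (deposited basis, 14 intervals; ~51%)

barcode_accs <- dat$records$records$accession[dat$truth$per_record$barcode]
crossref(dat$bold, barcode_accs, source_label = "synthetic BOLD")
#> <crossref_partition> synthetic BOLD n=1000
#>   barcode_linked   130 (13%)
#>   accession_linked 504 (50%)
#>   bold_only        366 (37%)
```

The audit line reads: of 9,467 records, 5,202 (55%) carry a full
binomial; among those, 91% are at least 500 bp and 81%/65% carry
country/lat_lon qualifiers (the marginal country rate exceeds the
configured 74% because BARCODE records are always geotagged). The
growth summary recovers the configured 51%/yr deposition growth; the
crossref partition recovers the generator's category mix.

The same operations run on real data: `read_genbank("file.gb")`,
`read_bold_dump("dump.tsv", "tsv")`, `read_checklist("iucn.tsv")`.

## Command line

```sh
Rscript inst/cli/coiaudit.R simulate --seed 7 --out sim
Rscript inst/cli/coiaudit.R audit --genbank sim/records.gb --checklist sim/checklist.tsv --out audit_out
Rscript inst/cli/coiaudit.R growth --genbank sim/records.gb --years 2003:2017 --basis deposited --out growth_out
Rscript inst/cli/coiaudit.R crossref --bold sim/bold.tsv --barcode-accessions accs.txt --out crossref_out
Rscript inst/cli/coiaudit.R geo --genbank sim/records.gb --out geo_out
Rscript inst/cli/coiaudit.R queries --year 2016 --keyword BARCODE
```

Every run writes a `manifest.json` beside its outputs; identical inputs
and seed reproduce identical files.

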