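Package: coiaudit
Title: Auditing COI DNA-Barcode Reference Database Records
Version: 0.1.0
Authors@R: person("coiaudit", "maintainers", email = "coiaudit@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing cytochrome c oxidase subunit 1 (COI)
    DNA-barcode reference records of the kind held in the NCBI nucleotide
    database and the Barcode of Life Data System (BOLD). Parses GenBank
    flatfiles and BOLD-style dumps, classifies organism names as fully or
    insufficiently identified, audits metadata completeness (sequence
    length, country, latitude-longitude), computes yearly deposition series
    and geometric-average growth rates, reconciles BOLD records against
    GenBank accession and BARCODE-keyword sets, summarizes geographic
    coverage, and builds (but never executes) the Entrez and BOLD query
    strings needed to reproduce a retrieval. A synthetic record generator
    with full ground truth makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
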