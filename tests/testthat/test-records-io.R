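test_that("read_genbank parses an empty stream to an empty record set", {
  expect_equal(n_records(read_genbank("")), 0)
  tf <- withr::local_tempfile(lines = character(0))
  expect_equal(n_records(read_genbank(tf)), 0)
})

test_that("read_genbank parses a single entry with all audited fields", {
  rs <- make_records("AB000001", deposit_year = 2016L,
                     organism_name = "Gammarus fossarum",
                     lineage = list(c("Eukaryota", "Metazoa", "Arthropoda",
                                      "Malacostraca", "Amphipoda")),
                     keywords = list("BARCODE"), gene_labels = list("COI"),
                     sequence_length = 658L,
                     country_raw = "Canada: Ontario",
                     lat_lon_raw = "45.50 N 73.57 W")
  tf <- withr::local_tempfile()
  write_genbank(rs, tf)
  got <- read_genbank(tf)
  expect_equal(n_records(got), 1)
  r <- got$records
  expect_equal(r$accession, "AB000001")
  expect_equal(r$deposit_year, 2016L)
  expect_equal(r$organism_name, "Gammarus fossarum")
  expect_equal(r$sequence_length, 658L)
  expect_true("BARCODE" %in% r$keywords[[1]])
  expect_true("COI" %in% r$gene_labels[[1]])
  expect_equal(r$country_raw, "Canada: Ontario")
  expect_equal(r$lat_lon_raw, "45.50 N 73.57 W")
  expect_equal(r$lineage[[1]][3], "Arthropoda")
})

test_that("geo-qualifier absence is preserved through the flatfile", {
  rs <- make_records("NOGEO1")
  lines <- write_genbank(rs)
  expect_false(any(grepl("/country", lines)))
  expect_false(any(grepl("/lat_lon", lines)))
  got <- read_genbank(paste(lines, collapse = "\n"))
  expect_true(is.na(got$records$country_raw))
  expect_true(is.na(got$records$lat_lon_raw))
})

test_that("write_genbank of an empty set emits no entries", {
  expect_length(write_genbank(record_set()), 0)
})

test_that("write_genbank rejects records missing mandatory fields", {
  rs <- make_records("OK1")
  rs$records$accession <- ""
  expect_error(write_genbank(rs), "missing accession")
})

test_that("GenBank round trip is the identity on a 100-record synthetic set", {
  dat <- generate_synthetic(synthetic_config(
    seed = 11, year_range = 2003:2007, base_deposits = 12, annual_growth = 0.5,
    n_bold = 0, n_species_pool = 60, bold_mix = c(bold_only = 1)))
  expect_gte(n_records(dat$records), 100)
  tf <- withr::local_tempfile()
  write_genbank(dat$records, tf)
  got <- read_genbank(tf, source_label = dat$records$source_label)
  expect_equal(got$records, dat$records$records)
})

test_that("parsing is count-preserving: one record per // terminator", {
  dat <- generate_synthetic(tiny_config())
  lines <- write_genbank(dat$records)
  expect_equal(sum(grepl("^//\\s*$", lines)), n_records(dat$records))
  expect_equal(n_records(read_genbank(paste(lines, collapse = "\n"))),
               n_records(dat$records))
})

test_that("malformed flatfiles raise parse errors naming the offset", {
  rs <- make_records("TRUNC1")
  lines <- write_genbank(rs)
  no_term <- lines[lines != "//"]
  expect_error(read_genbank(paste(no_term, collapse = "\n")),
               "byte offset.*TRUNC1")
  expect_error(read_genbank("this is not a flatfile\n"), "byte offset")
})

test_that("duplicate accessions are rejected", {
  lines <- write_genbank(make_records("DUP1"))
  two <- paste(c(lines, lines), collapse = "\n")
  expect_error(read_genbank(two), "duplicate record.*DUP1")
})

test_that("only the first source feature is consulted, with a warning", {
  lines <- write_genbank(make_records("MULTI1", country_raw = "Canada"))
  i <- grep("^     source", lines)
  extra <- c("     source          1..658",
             "                     /country=\"France\"")
  lines <- append(lines, extra, after = grep("^ORIGIN", lines) - 1)
  expect_warning(rs <- read_genbank(paste(lines, collapse = "\n")),
                 "source features")
  expect_equal(rs$records$country_raw, "Canada")
})

test_that("BOLD TSV and FASTA dialects parse to identical records", {
  dat <- generate_synthetic(tiny_config())
  tsv <- withr::local_tempfile()
  fa <- withr::local_tempfile()
  write_bold_dump(dat$bold, tsv, "tsv")
  write_bold_dump(dat$bold, fa, "fasta")
  a <- read_bold_dump(tsv, "tsv")
  b <- read_bold_dump(fa, "fasta")
  expect_equal(a, b)
  expect_equal(nrow(a), nrow(dat$bold))
  expect_equal(a$record_id, dat$bold$record_id)
  expect_equal(is.na(a$genbank_accession), is.na(dat$bold$genbank_accession))
})

test_that("BOLD parsing handles placeholder accessions and empty dumps", {
  tsv <- withr::local_tempfile(lines = c(
    "record_id\ttaxon_name\tmarker\tgenbank_accession",
    "BOLD001\tGammarus fossarum\tCOI-5P\tMG000001"))
  got <- read_bold_dump(tsv, "tsv")
  expect_equal(got$genbank_accession, "MG000001")

  fa <- withr::local_tempfile(lines = c(">BOLD002|Homo sapiens|COI-5P|", "ACGT"))
  got <- read_bold_dump(fa, "fasta")
  expect_true(is.na(got$genbank_accession))
  expect_equal(got$taxon_name, "Homo sapiens")

  empty <- withr::local_tempfile(lines = "record_id\ttaxon_name\tmarker\tgenbank_accession")
  expect_equal(nrow(read_bold_dump(empty, "tsv")), 0)
})

test_that("BOLD TSV errors name the missing column and reject duplicates", {
  bad <- withr::local_tempfile(lines = c("record_id\ttaxon_name\tmarker",
                                         "BOLD001\tX y\tCOI-5P"))
  expect_error(read_bold_dump(bad, "tsv"), "genbank_accession")
  dup <- withr::local_tempfile(lines = c(
    "record_id\ttaxon_name\tmarker\tgenbank_accession",
    "BOLD001\tX y\tCOI-5P\t", "BOLD001\tX z\tCOI-5P\t"))
  expect_error(read_bold_dump(dup, "tsv"), "duplicate record")
})
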