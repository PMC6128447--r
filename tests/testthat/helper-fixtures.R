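# shared fixtures and independent oracles

# build a record_set from per-record arguments with convenient defaults
make_records <- function(accession,
                         deposit_year = 2010L,
                         organism_name = "Homo sapiens",
                         lineage = list(c("Eukaryota", "Metazoa")),
                         keywords = list(character(0)),
                         gene_labels = list("COI"),
                         sequence_length = 658L,
                         country_raw = NA_character_,
                         lat_lon_raw = NA_character_,
                         sequence = NA_character_,
                         source_label = "fixture") {
  n <- length(accession)
  rep_list <- function(x) {
    if (!is.list(x)) x <- list(x)
    rep_len(x, n)
  }
  record_set(data.frame(
    accession = accession,
    deposit_year = rep_len(as.integer(deposit_year), n),
    organism_name = rep_len(organism_name, n),
    lineage = I(rep_list(lineage)),
    keywords = I(rep_list(keywords)),
    gene_labels = I(rep_list(gene_labels)),
    sequence_length = rep_len(as.integer(sequence_length), n),
    country_raw = rep_len(country_raw, n),
    lat_lon_raw = rep_len(lat_lon_raw, n),
    sequence = rep_len(sequence, n),
    stringsAsFactors = FALSE
  ), source_label)
}

# brute-force name-classification oracle, independent of classify_names():
# enumerate every contiguous token run of the name and compare (lowercase)
# against the disqualifier tokens; then check the binomial shape.
oracle_classify <- function(name, disq_tokens) {
  toks <- strsplit(gsub("\\s+", " ", trimws(name)), " ")[[1]]
  low <- tolower(toks)
  dlow <- tolower(disq_tokens)
  runs <- character(0)
  for (i in seq_along(low)) {
    for (j in i:length(low)) {
      runs <- c(runs, paste(low[i:j], collapse = " "))
    }
  }
  if (any(runs %in% dlow)) return("insufficiently_identified")
  ok <- length(toks) >= 2 &&
    grepl("^[A-Z][a-z]+$", toks[1]) &&
    grepl("^[a-z]+(-[a-z]+)*$", toks[2])
  if (ok) "fully_identified" else "insufficiently_identified"
}

# random organism names exercising every branch of the grammar
random_names <- function(n) {
  genus <- c("Gammarus", "Daphnia", "Homo", "Bison", "xanthus", "Canis2",
             "Panthera")
  epithet <- c("pulex", "sapiens", "lupus-familiaris", "Pulex", "sp.", "nr.",
               "aff.", "cf.", "nov.", "affinis", "spectabilis", "cf")
  extra <- c("", "sp.", "nov.", "subsp", "alpina", "x")
  vapply(seq_len(n), function(i) {
    parts <- c(sample(genus, 1),
               sample(epithet, sample(1:2, 1)),
               sample(extra, sample(0:2, 1), replace = TRUE))
    paste(parts[nzchar(parts)], collapse = " ")
  }, character(1))
}

# small deterministic synthetic config for fast tests
tiny_config <- function(seed = 42L, ...) {
  synthetic_config(seed = seed, year_range = 2003:2007, base_deposits = 20,
                   annual_growth = 0.5, n_bold = 200, n_species_pool = 100,
                   n_checklist = 20, n_synonyms = 4, ...)
}
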