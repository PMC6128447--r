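# BOLD-style dump I/O: TSV with a header, or FASTA with pipe-delimited
# headers (id|taxon|marker|accession).  Field names in the TSV follow
# common BOLD export spellings; a few aliases are accepted.

bold_aliases <- list(
  record_id = c("record_id", "processid", "process_id", "sequenceid", "recordid"),
  taxon_name = c("taxon_name", "taxon", "species_name", "identification"),
  marker = c("marker", "markercode", "marker_code"),
  genbank_accession = c("genbank_accession", "accession", "genbank_acc", "genbank")
)

accession_placeholders <- c("", "NA", "N/A", "-", "NONE", "NULL")

#' Read a BOLD-style dump
#'
#' @param path path to the dump file.
#' @param dialect `"tsv"` (header naming at least record id, taxon, marker
#'   and genbank accession columns) or `"fasta"` (pipe-delimited headers
#'   `id|taxon|marker|accession`; the accession field may be absent or
#'   empty).
#' @return a data.frame with columns `record_id`, `taxon_name`, `marker`,
#'   `genbank_accession` (`NA` when no accession); one row per record.
#' @export
read_bold_dump <- function(path, dialect = c("tsv", "fasta")) {
  dialect <- match.arg(dialect)
  out <- if (dialect == "tsv") read_bold_tsv(path) else read_bold_fasta(path)
  if (nrow(out) > 0) {
    if (any(is.na(out$record_id) | !nzchar(out$record_id))) {
      stop("read_bold_dump(): empty record id")
    }
    dup <- out$record_id[duplicated(out$record_id)]
    if (length(dup) > 0) {
      stop("duplicate record: BOLD record id ", dup[[1]], " appears more than once")
    }
    if (any(is.na(out$marker) | !nzchar(out$marker))) {
      stop("read_bold_dump(): empty marker field")
    }
  }
  rownames(out) <- NULL
  out
}

read_bold_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  pick <- function(field) {
    hit <- intersect(bold_aliases[[field]], tolower(names(df)))
    if (length(hit) == 0) {
      stop("read_bold_dump(): missing mandatory column for ", field,
           " (accepted names: ", paste(bold_aliases[[field]], collapse = ", "), ")")
    }
    df[[which(tolower(names(df)) == hit[1])[1]]]
  }
  out <- data.frame(
    record_id = pick("record_id"), taxon_name = pick("taxon_name"),
    marker = pick("marker"), genbank_accession = pick("genbank_accession"),
    stringsAsFactors = FALSE
  )
  out$genbank_accession[trimws(toupper(out$genbank_accession)) %in%
                          accession_placeholders] <- NA_character_
  out
}

read_bold_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  fields <- strsplit(headers, "|", fixed = TRUE)
  get <- function(f, i) if (length(f) >= i) trimws(f[[i]]) else ""
  out <- data.frame(
    record_id = vapply(fields, get, character(1), 1L),
    taxon_name = vapply(fields, get, character(1), 2L),
    marker = vapply(fields, get, character(1), 3L),
    genbank_accession = vapply(fields, get, character(1), 4L),
    stringsAsFactors = FALSE
  )
  out$genbank_accession[toupper(out$genbank_accession) %in%
                          accession_placeholders] <- NA_character_
  out
}

#' Write a BOLD-style dump
#'
#' Serializes BOLD records as either a TSV with header or a FASTA with
#' pipe-delimited headers.  The two serializations of the same records
#' read back identically via [read_bold_dump()].
#'
#' @param bold data.frame with columns `record_id`, `taxon_name`,
#'   `marker`, `genbank_accession`; an optional `sequence` column supplies
#'   FASTA sequence text (a short placeholder is used otherwise).
#' @param path output file path.
#' @param dialect `"tsv"` or `"fasta"`.
#' @return invisibly, `path`.
#' @export
write_bold_dump <- function(bold, path, dialect = c("tsv", "fasta")) {
  dialect <- match.arg(dialect)
  acc <- ifelse(is.na(bold$genbank_accession), "", bold$genbank_accession)
  if (dialect == "tsv") {
    df <- data.frame(record_id = bold$record_id, taxon_name = bold$taxon_name,
                     marker = bold$marker, genbank_accession = acc,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    seqs <- if ("sequence" %in% names(bold)) bold$sequence else
      rep("ACGTACGTACGT", nrow(bold))
    headers <- sprintf(">%s|%s|%s|%s", bold$record_id, bold$taxon_name,
                       bold$marker, acc)
    writeLines(as.vector(rbind(headers, seqs)), path)
  }
  invisible(path)
}
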