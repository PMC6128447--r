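# record_set: the in-memory container for parsed sequence records.
# One row per record; lineage/keywords/gene_labels are list-columns.

record_columns <- c(
  "accession", "deposit_year", "organism_name", "lineage", "keywords",
  "gene_labels", "sequence_length", "country_raw", "lat_lon_raw", "sequence"
)

#' Construct a record set
#'
#' A `record_set` holds one row per sequence record with the fields the
#' audit consumes: accession (primary key), deposit year, organism name,
#' lineage (most- to least-inclusive taxon names), keywords (e.g.
#' `"BARCODE"`), gene labels from gene-feature qualifiers, sequence length,
#' and the raw country / lat_lon source qualifiers (`NA` when absent).
#'
#' @param records a data.frame with columns `accession` (character),
#'   `deposit_year` (integer), `organism_name` (character), `lineage`,
#'   `keywords`, `gene_labels` (list-columns of character vectors),
#'   `sequence_length` (integer), `country_raw`, `lat_lon_raw`, `sequence`
#'   (character, `NA` allowed).
#' @param source_label free-text label for the provenance of the set.
#' @return an object of class `record_set`.
#' @export
record_set <- function(records = empty_records(), source_label = "") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("record_set(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[record_columns]
  rownames(records) <- NULL
  validate_records(records)
  structure(list(records = records, source_label = as.character(source_label)),
            class = "record_set")
}

empty_records <- function() {
  data.frame(
    accession = character(0), deposit_year = integer(0),
    organism_name = character(0),
    lineage = I(list()), keywords = I(list()), gene_labels = I(list()),
    sequence_length = integer(0), country_raw = character(0),
    lat_lon_raw = character(0), sequence = character(0),
    stringsAsFactors = FALSE
  )
}

validate_records <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$accession) | !nzchar(df$accession))) {
    stop("record_set(): empty accession")
  }
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup) > 0) {
    stop("duplicate record: accession ", dup[[1]], " appears more than once")
  }
  yr <- df$deposit_year
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  if (any(is.na(yr) | yr < 1982L | yr > this_year)) {
    stop("record_set(): deposit_year outside [1982, ", this_year, "]")
  }
  if (any(is.na(df$sequence_length) | df$sequence_length < 0)) {
    stop("record_set(): sequence_length must be >= 0")
  }
  has_seq <- !is.na(df$sequence)
  if (any(has_seq & nchar(df$sequence) != df$sequence_length)) {
    stop("record_set(): sequence_length disagrees with sequence text")
  }
  invisible(df)
}

#' Number of records in a record set
#' @param rs a `record_set`.
#' @return integer count.
#' @export
n_records <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  nrow(rs$records)
}

# subset a record_set by logical/integer index, keeping the class
rs_subset <- function(rs, idx, source_label = rs$source_label) {
  stopifnot(inherits(rs, "record_set"))
  out <- rs$records[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(records = out, source_label = source_label),
            class = "record_set")
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set> %d record(s)", nrow(x$records)))
  if (nzchar(x$source_label)) cat(sprintf(" [%s]", x$source_label))
  cat("\n")
  if (nrow(x$records) > 0) {
    show <- utils::head(x$records[c("accession", "deposit_year",
                                    "organism_name", "sequence_length")], 5)
    print(show)
    if (nrow(x$records) > 5) cat(sprintf("... and %d more\n", nrow(x$records) - 5))
  }
  invisible(x)
}
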