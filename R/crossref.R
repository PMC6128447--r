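# BOLD/GenBank reconciliation: the three-way partition of BOLD records
# into BARCODE-linked, accession-linked (non-BARCODE), and BOLD-only.

#' Construct a three-way crossref partition from counts
#'
#' Percents use the shared [percent()] rule; the three counts are
#' exhaustive and exclusive by construction.
#'
#' @param n_barcode_linked records whose GenBank accession is in the
#'   BARCODE-flagged accession set.
#' @param n_accession_linked records with a GenBank accession not in the
#'   BARCODE set (including accessions absent from any supplied GenBank
#'   index, e.g. suppressed records).
#' @param n_bold_only records with no GenBank accession.
#' @param source_label label for the partition row.
#' @return an object of class `crossref_partition` with the three counts,
#'   `n_total`, and `pct_barcode_linked` / `pct_accession_linked` /
#'   `pct_bold_only`.
#' @export
crossref_partition <- function(n_barcode_linked, n_accession_linked,
                               n_bold_only, source_label = "") {
  counts <- c(n_barcode_linked, n_accession_linked, n_bold_only)
  if (any(is.na(counts) | counts < 0)) {
    stop("crossref_partition(): counts must be non-negative")
  }
  n_total <- sum(counts)
  structure(list(
    source_label = source_label,
    n_barcode_linked = n_barcode_linked,
    n_accession_linked = n_accession_linked,
    n_bold_only = n_bold_only,
    n_total = n_total,
    pct_barcode_linked = percent(n_barcode_linked, n_total),
    pct_accession_linked = percent(n_accession_linked, n_total),
    pct_bold_only = percent(n_bold_only, n_total)
  ), class = "crossref_partition")
}

#' Cross-reference BOLD records against GenBank accession sets
#'
#' Assigns every BOLD record to exactly one category: `barcode_linked`
#' when its accession is in the BARCODE-flagged set; otherwise
#' `accession_linked` when any accession is present; otherwise
#' `bold_only`.  Accessions are uppercased and version suffixes (".1")
#' stripped on both sides before comparison.  When an `all_accessions`
#' index is supplied, accession-linked records whose accession is absent
#' from it are additionally reported as `n_suppressed` (a sub-count; it
#' does not change the category).
#'
#' @param bold data.frame of BOLD records as from [read_bold_dump()].
#' @param barcode_accessions character vector: accessions of
#'   BARCODE-flagged GenBank records.
#' @param all_accessions optional character vector: all known GenBank
#'   accessions, used only for the suppressed sub-count.
#' @param source_label label for the partition row.
#' @return a `crossref_partition` with an additional `assignments`
#'   character vector (one category per input record, in input order) and
#'   `n_suppressed` (`NA` when no index was supplied).
#' @export
crossref <- function(bold, barcode_accessions, all_accessions = NULL,
                     source_label = "") {
  stopifnot(is.data.frame(bold))
  dup <- bold$record_id[duplicated(bold$record_id)]
  if (length(dup) > 0) {
    stop("duplicate record: BOLD record id ", dup[[1]], " appears more than once")
  }
  barcode_set <- strip_accession_version(barcode_accessions)
  acc <- bold$genbank_accession
  has_acc <- !is.na(acc) & nzchar(trimws(acc))
  acc_norm <- rep(NA_character_, length(acc))
  acc_norm[has_acc] <- strip_accession_version(acc[has_acc])
  in_barcode <- has_acc & acc_norm %in% barcode_set
  category <- ifelse(in_barcode, "barcode_linked",
                     ifelse(has_acc, "accession_linked", "bold_only"))
  n_suppressed <- NA_integer_
  if (!is.null(all_accessions)) {
    all_set <- strip_accession_version(all_accessions)
    n_suppressed <- sum(category == "accession_linked" & !(acc_norm %in% all_set))
  }
  out <- crossref_partition(sum(category == "barcode_linked"),
                            sum(category == "accession_linked"),
                            sum(category == "bold_only"),
                            source_label)
  out$assignments <- category
  out$n_suppressed <- n_suppressed
  out
}

#' Tabulate crossref partitions in Table-1 shape
#'
#' One row per partition: source label, `count (pct%)` for each of the
#' three categories, and the total.
#'
#' @param partitions a `crossref_partition` or list of them.
#' @return a data.frame.
#' @export
crossref_table <- function(partitions) {
  if (inherits(partitions, "crossref_partition")) partitions <- list(partitions)
  fmt <- function(n, p) sprintf("%s (%d%%)", format(n, big.mark = ",", trim = TRUE), p)
  rows <- lapply(partitions, function(x) {
    data.frame(
      source = x$source_label,
      barcode_linked = fmt(x$n_barcode_linked, x$pct_barcode_linked),
      accession_linked = fmt(x$n_accession_linked, x$pct_accession_linked),
      bold_only = fmt(x$n_bold_only, x$pct_bold_only),
      total = format(x$n_total, big.mark = ",", trim = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.crossref_partition <- function(x, ...) {
  cat(sprintf("<crossref_partition> %s n=%d\n", x$source_label, x$n_total))
  cat(sprintf("  barcode_linked   %d (%d%%)\n", x$n_barcode_linked, x$pct_barcode_linked))
  cat(sprintf("  accession_linked %d (%d%%)\n", x$n_accession_linked, x$pct_accession_linked))
  cat(sprintf("  bold_only        %d (%d%%)\n", x$n_bold_only, x$pct_bold_only))
  if (!is.null(x$n_suppressed) && !is.na(x$n_suppressed)) {
    cat(sprintf("  (suppressed sub-count: %d)\n", x$n_suppressed))
  }
  invisible(x)
}
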