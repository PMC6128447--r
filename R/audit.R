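# Annotation-completeness audit: for one record partition, the proportion
# fully identified, and among fully identified records the proportions
# with good sequence length (>= 500 bp by default), a country qualifier,
# and a lat_lon qualifier.

#' Audit annotation completeness of a record partition
#'
#' Counts fully identified records (via [classify_names()]) and, among
#' those, records with sequence length at or above the threshold, a
#' country qualifier, and a lat_lon qualifier.  Percentages use the shared
#' half-up [percent()] rule.  Completeness denominators are the fully
#' identified records (both of-total percents are also reported for
#' transparency).  With `species_list_mode = TRUE` (checklist partitions
#' assembled by searching for specific species names) every record counts
#' as fully identified, so that proportion is 100% by construction.
#'
#' @param records a [record_set()] partition.
#' @param disq a [disqualifier_set()].
#' @param label partition label for the report row.
#' @param species_list_mode logical; see above.
#' @param length_threshold minimum "good" sequence length in bp
#'   (inclusive), default 500.
#' @return an object of class `audit_report`: counts `n_total`,
#'   `n_fully_identified`, `n_len_ge_500`, `n_country`, `n_latlon`;
#'   integer percents `pct_fully_identified`, `pct_len_ge_500`,
#'   `pct_country`, `pct_latlon` (fully-identified denominator);
#'   `pct_len_ge_500_of_total`, `pct_country_of_total`,
#'   `pct_latlon_of_total`; and `degenerate` (TRUE when `n_total` = 0,
#'   in which case every percent is 0).
#' @export
audit <- function(records, disq = disqualifier_preset("genbank"),
                  label = records$source_label, species_list_mode = FALSE,
                  length_threshold = 500) {
  stopifnot(inherits(records, "record_set"))
  df <- records$records
  n_total <- nrow(df)
  full <- if (species_list_mode) rep(TRUE, n_total) else
    fully_identified_mask(records, disq)
  n_full <- sum(full)
  good_len <- full & !is.na(df$sequence_length) &
    df$sequence_length >= length_threshold
  has_country <- full & !is.na(df$country_raw)
  has_latlon <- full & !is.na(df$lat_lon_raw)
  structure(list(
    partition_label = label,
    n_total = n_total,
    n_fully_identified = n_full,
    n_len_ge_500 = sum(good_len),
    n_country = sum(has_country),
    n_latlon = sum(has_latlon),
    pct_fully_identified = percent(n_full, n_total),
    pct_len_ge_500 = percent(sum(good_len), n_full),
    pct_country = percent(sum(has_country), n_full),
    pct_latlon = percent(sum(has_latlon), n_full),
    pct_len_ge_500_of_total = percent(sum(good_len), n_total),
    pct_country_of_total = percent(sum(has_country), n_total),
    pct_latlon_of_total = percent(sum(has_latlon), n_total),
    length_threshold = length_threshold,
    degenerate = n_total == 0
  ), class = "audit_report")
}

audit_report_fields <- c(
  "partition_label", "n_total", "n_fully_identified", "n_len_ge_500",
  "n_country", "n_latlon", "pct_fully_identified", "pct_len_ge_500",
  "pct_country", "pct_latlon", "pct_len_ge_500_of_total",
  "pct_country_of_total", "pct_latlon_of_total"
)

#' Tabulate audit reports
#'
#' @param reports a list of `audit_report` objects (or a single one).
#' @return a data.frame with one row per partition.
#' @export
audit_table <- function(reports) {
  if (inherits(reports, "audit_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    as.data.frame(r[audit_report_fields], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write audit reports as TSV and JSON
#'
#' @param reports list of `audit_report` objects.
#' @param tsv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the report table.
#' @export
write_audit_reports <- function(reports, tsv_path = NULL, json_path = NULL) {
  tab <- audit_table(reports)
  if (!is.null(tsv_path)) {
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(tab, json_path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(tab)
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %s: n=%d\n", x$partition_label, x$n_total))
  if (x$degenerate) {
    cat("  (degenerate: empty partition)\n")
    return(invisible(x))
  }
  cat(sprintf("  fully identified: %d (%d%%)\n",
              x$n_fully_identified, x$pct_fully_identified))
  cat(sprintf("  of fully identified: length >= %d bp %d%%, country %d%%, lat_lon %d%%\n",
              x$length_threshold, x$pct_len_ge_500, x$pct_country, x$pct_latlon))
  invisible(x)
}
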