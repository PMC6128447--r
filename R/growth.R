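# Yearly deposition series and geometric-average annual growth.

#' Build a yearly deposition series
#'
#' Tallies records deposited per year over an inclusive year range,
#' counts distinct fully identified species names per year, and
#' accumulates the running total.  Records outside the range are dropped
#' (their count is reported via a message and the `n_dropped` attribute).
#'
#' @param records a [record_set()].
#' @param disq a [disqualifier_set()] used to decide which organism names
#'   count toward unique species.
#' @param year_range integer vector; its range is used (e.g.
#'   `2003:2017` or `c(2003, 2017)`).
#' @return a data.frame of class `yearly_series` with columns `year`,
#'   `deposited`, `unique_species`, `cumulative` (contiguous years).
#' @export
build_series <- function(records, disq = disqualifier_preset("genbank"),
                         year_range = 2003:2017) {
  stopifnot(inherits(records, "record_set"), length(year_range) >= 1)
  years <- seq(min(year_range), max(year_range))
  df <- records$records
  in_range <- df$deposit_year >= min(years) & df$deposit_year <= max(years)
  n_dropped <- sum(!in_range)
  if (n_dropped > 0) {
    message(sprintf("build_series(): dropped %d record(s) outside %d-%d",
                    n_dropped, min(years), max(years)))
  }
  df <- df[in_range, , drop = FALSE]
  deposited <- vapply(years, function(y) sum(df$deposit_year == y), integer(1))
  full <- if (nrow(df) > 0) {
    classify_names(df$organism_name, disq)$verdict == "fully_identified"
  } else logical(0)
  unique_species <- vapply(years, function(y) {
    sel <- df$deposit_year == y & full
    length(unique(name_key(df$organism_name[sel])))
  }, integer(1))
  out <- data.frame(year = years, deposited = deposited,
                    unique_species = unique_species,
                    cumulative = cumsum(deposited))
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("yearly_series", "data.frame")
  out
}

#' Geometric-average annual growth of a yearly series
#'
#' The growth rate is the geometric mean of consecutive year-over-year
#' ratios minus one: `(prod(n_y / n_(y-1)))^(1/k) - 1` over the `k`
#' intervals, which telescopes to `(n_last / n_first)^(1/k) - 1`.
#' Database growth is conventionally quoted on the cumulative basis (the
#' default); the per-year deposited basis is available by flag.  Any zero
#' count makes the geometric mean undefined and is an error naming the
#' offending year — years are never silently skipped.
#'
#' @param series a `yearly_series` from [build_series()].
#' @param basis `"cumulative"` (default) or `"deposited"`.
#' @return a list of class `growth_summary` with `rate_percent` (real
#'   percent), `n_intervals`, `basis`.
#' @export
geometric_growth <- function(series, basis = c("cumulative", "deposited")) {
  basis <- match.arg(basis)
  stopifnot(inherits(series, "data.frame"), nrow(series) >= 2)
  counts <- series[[basis]]
  bad <- which(counts <= 0)
  if (length(bad) > 0) {
    stop(sprintf("geometric_growth(): undefined growth, %s count is %d in year %d",
                 basis, counts[bad[1]], series$year[bad[1]]))
  }
  rate <- exp(mean(diff(log(counts)))) - 1
  structure(list(rate_percent = 100 * rate,
                 n_intervals = length(counts) - 1L,
                 basis = basis),
            class = "growth_summary")
}

#' Geometric-average growth from endpoint counts
#'
#' Closed form of [geometric_growth()]: with positive first and last
#' counts and `n_intervals` year-to-year steps, the geometric-average
#' annual growth is `(last/first)^(1/n_intervals) - 1`, in percent.
#'
#' @param first,last positive endpoint counts.
#' @param n_intervals number of year-to-year intervals (>= 1).
#' @return real percent.
#' @examples
#' growth_from_endpoints(8137, 2530418, 14)  # ~ 50.7 (i.e. "51% per year")
#' @export
growth_from_endpoints <- function(first, last, n_intervals) {
  if (first <= 0 || last <= 0) {
    stop("growth_from_endpoints(): endpoint counts must be positive")
  }
  stopifnot(n_intervals >= 1)
  100 * ((last / first)^(1 / n_intervals) - 1)
}

#' Write a yearly series with its growth summary
#'
#' TSV with columns year, deposited, unique_species, cumulative; the
#' growth summary is appended as commented footer lines.
#'
#' @param series a `yearly_series`.
#' @param path output path.
#' @param summary optional `growth_summary` for the footer.
#' @return invisibly, `path`.
#' @export
write_series <- function(series, path, summary = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(series), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary)) {
    writeLines(sprintf("# geometric_growth basis=%s rate_percent=%.1f n_intervals=%d",
                       summary$basis, summary$rate_percent, summary$n_intervals),
               con)
  }
  invisible(path)
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf("<growth_summary> %.1f%% per year (%s basis, %d intervals; ~%d%%)\n",
              x$rate_percent, x$basis, x$n_intervals,
              as.integer(round_half_up(x$rate_percent))))
  invisible(x)
}
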