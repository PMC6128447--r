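# shared helpers: rounding, percent rule, string normalization

#' Round half-up to the nearest integer
#'
#' Unlike [base::round()] (banker's rounding), ties go away from zero for
#' positive input: 0.5 -> 1, 1.5 -> 2.  This is the rounding rule used for
#' every printed percentage in the audit reports.
#'
#' @param x numeric vector, assumed non-negative.
#' @return numeric vector of integers.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Integer percentage with the shared half-up rounding rule
#'
#' `percent(n, d)` is round-half-up(100 * n / d), defined as 0 when the
#' denominator is 0.  All completeness and partition percentages in the
#' package go through this one rule.
#'
#' @param numerator,denominator non-negative counts; vectors are recycled.
#' @return integer vector of percents in \[0, 100\].
#' @examples
#' percent(1383206, 2530418)  # 55
#' percent(718814, 2530418)   # 28
#' @export
percent <- function(numerator, denominator) {
  if (any(is.na(numerator)) || any(is.na(denominator))) {
    stop("percent(): NA counts are not allowed")
  }
  if (any(numerator < 0) || any(denominator < 0)) {
    stop("percent(): counts must be non-negative")
  }
  if (any(numerator > denominator)) {
    stop("percent(): numerator exceeds denominator")
  }
  out <- ifelse(denominator == 0, 0, round_half_up(100 * numerator / denominator))
  as.integer(out)
}

# collapse runs of whitespace and trim
normalize_ws <- function(x) gsub("\\s+", " ", trimws(x))

# case/whitespace-insensitive key used for name comparison
name_key <- function(x) tolower(normalize_ws(x))

# uppercase and drop a trailing ".<digits>" version suffix
strip_accession_version <- function(x) {
  toupper(sub("\\.[0-9]+$", "", trimws(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
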