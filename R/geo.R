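# Geographic summaries: INSDC lat_lon parsing, country-name extraction,
# per-country tallies and the top-5%/bottom-95% country split.

#' Parse INSDC lat_lon strings
#'
#' The INSDC dialect is `"<number> <N|S> <number> <E|W>"`; S and W map to
#' negative signs.  Latitudes must lie in \[-90, 90\] and longitudes in
#' \[-180, 180\].
#'
#' @param raw character vector of lat_lon strings.
#' @param strict when TRUE (default) a malformed or out-of-range value is
#'   an error carrying the raw string; when FALSE such values yield `NA`
#'   rows and a warning with the demotion count.
#' @return a data.frame with numeric columns `latitude`, `longitude`.
#' @examples
#' parse_lat_lon("45.50 N 73.57 W")  # 45.5, -73.57
#' @export
parse_lat_lon <- function(raw, strict = TRUE) {
  pat <- "^\\s*([0-9]+(?:\\.[0-9]+)?) ([NS]) ([0-9]+(?:\\.[0-9]+)?) ([EW])\\s*$"
  m <- regmatches(raw, regexec(pat, as.character(raw)))
  lat <- rep(NA_real_, length(raw))
  lon <- rep(NA_real_, length(raw))
  bad <- character(0)
  for (i in seq_along(raw)) {
    g <- m[[i]]
    if (length(g) == 5) {
      la <- as.numeric(g[2]) * if (g[3] == "S") -1 else 1
      lo <- as.numeric(g[4]) * if (g[5] == "W") -1 else 1
      if (abs(la) <= 90 && abs(lo) <= 180) {
        lat[i] <- la
        lon[i] <- lo
        next
      }
    }
    bad <- c(bad, as.character(raw[i]))
  }
  if (length(bad) > 0) {
    if (strict) {
      stop(sprintf("parse_lat_lon(): malformed lat_lon string '%s'", bad[1]))
    }
    warning(sprintf("parse_lat_lon(): %d malformed lat_lon value(s) demoted to NA (first: '%s')",
                    length(bad), bad[1]))
  }
  data.frame(latitude = lat, longitude = lon)
}

#' Format coordinates as an INSDC lat_lon string
#'
#' Inverse of [parse_lat_lon()]: `parse_lat_lon(format_lat_lon(lat, lon))`
#' returns the input exactly.
#'
#' @param latitude,longitude numeric degrees.
#' @return character vector of lat_lon strings.
#' @export
format_lat_lon <- function(latitude, longitude) {
  stopifnot(all(abs(latitude) <= 90), all(abs(longitude) <= 180))
  sprintf("%s %s %s %s",
          sprintf("%.17g", abs(latitude)), ifelse(latitude < 0, "S", "N"),
          sprintf("%.17g", abs(longitude)), ifelse(longitude < 0, "W", "E"))
}

#' Extract a country name from an INSDC country qualifier
#'
#' Takes the substring before the first colon (the INSDC
#' `"Country: region"` convention), trims whitespace, then applies a
#' user-extensible alias table (defaulting to identity) to absorb
#' spelling variants such as `"USA"` vs `"United States"`.
#'
#' @param raw character vector of non-empty country qualifier strings.
#' @param aliases optional named character vector mapping variant ->
#'   canonical country name.
#' @return character vector of country names.
#' @examples
#' parse_country("Canada: Ontario, Guelph")  # "Canada"
#' @export
parse_country <- function(raw, aliases = NULL) {
  raw <- as.character(raw)
  if (any(is.na(raw) | !nzchar(trimws(raw)))) {
    stop("parse_country(): empty country string")
  }
  out <- trimws(sub(":.*$", "", raw))
  if (!is.null(aliases) && length(aliases) > 0) {
    hit <- match(out, names(aliases))
    out[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  out
}

#' Geographic summary of a record set
#'
#' Computed over fully identified records only.  Produces per-country
#' tallies (country names via [parse_country()]), the count of records
#' with no country qualifier, a table of valid coordinate points
#' (malformed lat_lon values demote the record to "no lat_lon" with a
#' warning rather than aborting), and the top-5%/bottom-95% country
#' split: the top `ceiling(0.05 * K)` of the `K` distinct countries by
#' record count, ties broken by descending count then lexicographic name.
#'
#' @param records a [record_set()].
#' @param disq a [disqualifier_set()].
#' @param aliases optional alias table passed to [parse_country()].
#' @param top_fraction fraction of countries in the "top" split (0.05).
#' @return an object of class `geo_summary` with `country_counts` (named
#'   integer vector, sorted by the tie-break rule), `n_no_country`,
#'   `points` (data.frame accession/latitude/longitude), `n_bad_latlon`,
#'   `top_countries`, `bottom_countries`, `n_records_used`.
#' @export
summarize_geo <- function(records, disq = disqualifier_preset("genbank"),
                          aliases = NULL, top_fraction = 0.05) {
  stopifnot(inherits(records, "record_set"))
  full <- fully_identified_mask(records, disq)
  df <- records$records[full, , drop = FALSE]

  has_country <- !is.na(df$country_raw)
  countries <- if (any(has_country)) {
    parse_country(df$country_raw[has_country], aliases)
  } else character(0)
  tab <- table(countries)
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (length(counts) > 0) {
    counts <- counts[order(-counts, names(counts))]
  }

  has_ll <- !is.na(df$lat_lon_raw)
  pts <- parse_lat_lon(df$lat_lon_raw[has_ll], strict = FALSE)
  ok <- !is.na(pts$latitude)
  points <- data.frame(accession = df$accession[has_ll][ok],
                       latitude = pts$latitude[ok],
                       longitude = pts$longitude[ok],
                       stringsAsFactors = FALSE)

  k <- length(counts)
  n_top <- if (k > 0) as.integer(ceiling(top_fraction * k)) else 0L
  structure(list(
    country_counts = counts,
    n_no_country = sum(!has_country),
    points = points,
    n_bad_latlon = sum(has_ll) - sum(ok),
    top_countries = names(counts)[seq_len(n_top)],
    bottom_countries = if (k > n_top) names(counts)[(n_top + 1):k] else character(0),
    n_records_used = nrow(df)
  ), class = "geo_summary")
}

#' Write geo summary tables
#'
#' @param geo a `geo_summary`.
#' @param dir output directory; writes `country_counts.tsv` (country,
#'   count), `points.csv` (accession, latitude, longitude), and
#'   `country_split.tsv` (country, count, split).
#' @return invisibly, `dir`.
#' @export
write_geo_summary <- function(geo, dir) {
  stopifnot(inherits(geo, "geo_summary"))
  cc <- data.frame(country = names(geo$country_counts),
                   count = unname(geo$country_counts), stringsAsFactors = FALSE)
  utils::write.table(cc, file.path(dir, "country_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(geo$points, file.path(dir, "points.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  split <- rbind(
    data.frame(country = geo$top_countries, split = "top", stringsAsFactors = FALSE),
    data.frame(country = geo$bottom_countries, split = "bottom", stringsAsFactors = FALSE)
  )
  split$count <- unname(geo$country_counts[split$country])
  utils::write.table(split[c("country", "count", "split")],
                     file.path(dir, "country_split.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.geo_summary <- function(x, ...) {
  cat(sprintf("<geo_summary> %d fully identified record(s); %d countries, %d with no country\n",
              x$n_records_used, length(x$country_counts), x$n_no_country))
  cat(sprintf("  %d point(s); top split: %s\n", nrow(x$points),
              paste(x$top_countries, collapse = ", ")))
  invisible(x)
}
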