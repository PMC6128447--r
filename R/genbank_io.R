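# GenBank flatfile reader/writer.
#
# Only the slice of the flatfile grammar the audit consumes is modeled:
# LOCUS (length + date), ACCESSION, KEYWORDS, SOURCE/ORGANISM + lineage,
# FEATURES (source with /organism /country /lat_lon; gene with /gene),
# ORIGIN, and the // terminator.  The LOCUS-line date supplies the deposit
# year (flatfiles do not carry the Entrez PDAT field).

#' Read a GenBank flatfile into a record set
#'
#' Parses zero or more flatfile entries (`LOCUS` ... `//`).  The deposit
#' year is taken from the LOCUS-line date; keywords are split on
#' semicolons/whitespace with the trailing period stripped (`"BARCODE."`
#' becomes `"BARCODE"`); gene labels are collected from every gene-feature
#' `/gene` qualifier; country and lat_lon come from the first source
#' feature (additional source features are ignored with a warning).
#'
#' @param path path to a flatfile, or a character vector of lines (any
#'   element containing a newline is split).
#' @param source_label label stored on the returned set; defaults to the
#'   path when one was given.
#' @return a [record_set()].
#' @export
read_genbank <- function(path, source_label = NULL) {
  if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    source_label <- source_label %||% path
  } else {
    lines <- unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
    source_label <- source_label %||% ""
  }
  # byte offset of the start of each line, for parse errors
  offsets <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))

  locus_idx <- grep("^LOCUS\\b", lines)
  term_idx <- grep("^//\\s*$", lines)
  if (length(term_idx) < length(locus_idx)) {
    i <- locus_idx[length(term_idx) + 1L]
    partial <- normalize_ws(sub("^LOCUS", "", lines[i]))
    partial <- strsplit(partial, " ")[[1]][1]
    stop(sprintf(
      "malformed flatfile entry at byte offset %d (partial accession '%s'): no terminating //",
      offsets[i], partial %||% "?"))
  }
  # any non-blank content must sit between a LOCUS and its terminator
  if (length(locus_idx) == 0) {
    if (any(nzchar(trimws(lines)))) {
      i <- which(nzchar(trimws(lines)))[1]
      stop(sprintf("malformed flatfile entry at byte offset %d: content with no LOCUS line",
                   offsets[i]))
    }
    return(record_set(empty_records(), source_label))
  }
  starts <- locus_idx
  ends <- vapply(starts, function(s) term_idx[term_idx > s][1], integer(1))
  covered <- logical(length(lines))
  for (k in seq_along(starts)) covered[starts[k]:ends[k]] <- TRUE
  stray <- which(!covered & nzchar(trimws(lines)))
  if (length(stray) > 0) {
    stop(sprintf("malformed flatfile entry at byte offset %d: content outside LOCUS..// block",
                 offsets[stray[1]]))
  }

  entries <- lapply(seq_along(starts), function(k) {
    parse_genbank_entry(lines[starts[k]:ends[k]], offsets[starts[k]])
  })
  df <- do.call(rbind, c(list(empty_records()), entries))
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup) > 0) {
    stop("duplicate record: accession ", dup[[1]], " appears more than once")
  }
  record_set(df, source_label)
}

parse_genbank_entry <- function(lines, offset) {
  locus_tok <- strsplit(normalize_ws(lines[1]), " ")[[1]]
  locus_name <- locus_tok[2] %||% NA_character_
  bp_pos <- which(locus_tok == "bp")
  seq_len <- if (length(bp_pos) == 1 && bp_pos > 1) {
    suppressWarnings(as.integer(locus_tok[bp_pos - 1]))
  } else NA_integer_
  date_tok <- grep("^[0-9]{2}-[A-Z]{3}-[0-9]{4}$", locus_tok, value = TRUE)
  year <- if (length(date_tok) >= 1) as.integer(substr(date_tok[1], 8, 11)) else NA_integer_
  if (is.na(year)) {
    stop(sprintf("malformed flatfile entry at byte offset %d (partial accession '%s'): no LOCUS date",
                 offset, locus_name))
  }

  top_idx <- grep("^[A-Z]+", lines)
  top_name <- sub("^([A-Z]+).*", "\\1", lines[top_idx])
  section <- function(name) {
    k <- which(top_name == name)[1]
    if (is.na(k)) return(character(0))
    end <- if (k < length(top_idx)) top_idx[k + 1] - 1L else length(lines)
    lines[top_idx[k]:end]
  }

  acc_lines <- section("ACCESSION")
  accession <- if (length(acc_lines) > 0) {
    strsplit(normalize_ws(sub("^ACCESSION", "", acc_lines[1])), " ")[[1]][1]
  } else locus_name

  kw_lines <- section("KEYWORDS")
  keywords <- character(0)
  if (length(kw_lines) > 0) {
    kw_text <- paste(c(sub("^KEYWORDS", "", kw_lines[1]), kw_lines[-1]), collapse = " ")
    toks <- strsplit(normalize_ws(kw_text), "[;[:space:]]+")[[1]]
    toks <- sub("\\.$", "", toks)
    keywords <- unique(toks[nzchar(toks)])
  }

  src_lines <- section("SOURCE")
  organism <- NA_character_
  lineage <- character(0)
  org_at <- grep("^ {2}ORGANISM\\b", src_lines)
  if (length(org_at) > 0) {
    organism <- normalize_ws(sub("^ {2}ORGANISM", "", src_lines[org_at[1]]))
    lin_lines <- src_lines[-seq_len(org_at[1])]
    if (length(lin_lines) > 0) {
      lin_text <- normalize_ws(paste(lin_lines, collapse = " "))
      lin_text <- sub("\\.$", "", lin_text)
      lineage <- trimws(strsplit(lin_text, ";")[[1]])
      lineage <- lineage[nzchar(lineage)]
    }
  }

  feats <- parse_feature_table(section("FEATURES"))
  src_feats <- feats[vapply(feats, function(f) f$key == "source", logical(1))]
  if (length(src_feats) > 1) {
    warning(sprintf("record %s: %d source features; using the first",
                    accession, length(src_feats)))
  }
  country <- NA_character_
  lat_lon <- NA_character_
  if (length(src_feats) >= 1) {
    q <- src_feats[[1]]$qualifiers
    country <- q[["country"]] %||% NA_character_
    lat_lon <- q[["lat_lon"]] %||% NA_character_
    if (!is.null(q[["organism"]])) organism <- q[["organism"]]
  }
  genes <- unlist(lapply(feats, function(f) {
    if (f$key == "gene") f$qualifiers[["gene"]] else NULL
  }), use.names = FALSE)

  origin_lines <- section("ORIGIN")
  seq_text <- NA_character_
  if (length(origin_lines) > 1) {
    seq_text <- gsub("[^A-Za-z]", "", paste(origin_lines[-1], collapse = ""))
    if (!nzchar(seq_text)) seq_text <- NA_character_
  }
  if (is.na(seq_len) && !is.na(seq_text)) seq_len <- nchar(seq_text)

  data.frame(
    accession = accession, deposit_year = year,
    organism_name = organism,
    lineage = I(list(lineage)), keywords = I(list(keywords)),
    gene_labels = I(list(unique(genes %||% character(0)))),
    sequence_length = seq_len, country_raw = country, lat_lon_raw = lat_lon,
    sequence = seq_text, stringsAsFactors = FALSE
  )
}

# FEATURES block -> list of list(key, qualifiers = named character list)
parse_feature_table <- function(lines) {
  if (length(lines) <= 1) return(list())
  lines <- lines[-1]  # drop the "FEATURES  Location/Qualifiers" header
  feats <- list()
  cur <- NULL
  cur_qual <- NULL
  flush_qual <- function() {
    if (!is.null(cur_qual) && !is.null(cur)) {
      val <- cur_qual$value
      val <- sub('^"', "", sub('"$', "", val))
      cur$qualifiers[[cur_qual$name]] <<- val
    }
    cur_qual <<- NULL
  }
  for (ln in lines) {
    if (grepl("^ {5}\\S", ln) && !grepl("^ {6}", ln)) {      # new feature
      flush_qual()
      if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
      key <- strsplit(normalize_ws(ln), " ")[[1]][1]
      cur <- list(key = key, qualifiers = list())
    } else if (grepl("^\\s+/", ln)) {                        # new qualifier
      flush_qual()
      body <- sub("^\\s+/", "", ln)
      eq <- regexpr("=", body, fixed = TRUE)
      if (eq > 0) {
        cur_qual <- list(name = substr(body, 1, eq - 1),
                         value = substr(body, eq + 1, nchar(body)))
      } else {
        cur_qual <- list(name = body, value = "")
      }
    } else if (!is.null(cur_qual)) {                         # continuation
      cur_qual$value <- paste0(cur_qual$value, " ", trimws(ln))
    }
  }
  flush_qual()
  if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
  feats
}

#' Write a record set as a GenBank flatfile
#'
#' Emits one flatfile entry per record, readable back by [read_genbank()]
#' with all `record_set` fields preserved.  The deposit year is written
#' into the LOCUS-line date (as 01-JAN-year).  Records lacking a sequence
#' get an `n`-run of the declared length so the entry stays well formed.
#'
#' @param rs a [record_set()].
#' @param path output file path, or `NULL` to return the lines invisibly.
#' @return invisibly, the character vector of flatfile lines.
#' @export
write_genbank <- function(rs, path = NULL) {
  stopifnot(inherits(rs, "record_set"))
  df <- rs$records
  if (nrow(df) > 0) {
    bad <- is.na(df$accession) | !nzchar(df$accession) | is.na(df$deposit_year)
    if (any(bad)) {
      stop("write_genbank(): record ", which(bad)[1],
           " is missing accession or deposit year")
    }
  }
  out <- unlist(lapply(seq_len(nrow(df)), function(i) {
    format_genbank_entry(df[i, , drop = FALSE])
  }), use.names = FALSE)
  if (is.null(out)) out <- character(0)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

format_genbank_entry <- function(r) {
  seq_text <- r$sequence
  if (is.na(seq_text)) {
    seq_text <- paste(rep("n", r$sequence_length), collapse = "")
  }
  lines <- c(
    sprintf("LOCUS       %-17s %9d bp    DNA     linear   INV %s",
            r$accession, r$sequence_length,
            sprintf("01-JAN-%04d", r$deposit_year)),
    sprintf("DEFINITION  %s cytochrome c oxidase subunit 1 (COI) gene, partial cds.",
            r$organism_name),
    sprintf("ACCESSION   %s", r$accession)
  )
  kw <- r$keywords[[1]]
  lines <- c(lines, sprintf("KEYWORDS    %s",
                            if (length(kw) > 0) paste0(paste(kw, collapse = "; "), ".") else "."))
  lines <- c(lines,
             sprintf("SOURCE      %s", r$organism_name),
             sprintf("  ORGANISM  %s", r$organism_name))
  lin <- r$lineage[[1]]
  if (length(lin) > 0) {
    wrapped <- strwrap(paste0(paste(lin, collapse = "; "), "."), width = 67)
    lines <- c(lines, paste0("            ", wrapped))
  }
  span <- sprintf("1..%d", r$sequence_length)
  lines <- c(lines,
             "FEATURES             Location/Qualifiers",
             sprintf("     source          %s", span),
             sprintf("                     /organism=\"%s\"", r$organism_name))
  if (!is.na(r$country_raw)) {
    lines <- c(lines, sprintf("                     /country=\"%s\"", r$country_raw))
  }
  if (!is.na(r$lat_lon_raw)) {
    lines <- c(lines, sprintf("                     /lat_lon=\"%s\"", r$lat_lon_raw))
  }
  for (g in r$gene_labels[[1]]) {
    lines <- c(lines,
               sprintf("     gene            %s", span),
               sprintf("                     /gene=\"%s\"", g))
  }
  lines <- c(lines, "ORIGIN")
  n <- nchar(seq_text)
  if (n > 0) {
    starts <- seq(1, n, by = 60)
    seq_lines <- vapply(starts, function(s) {
      chunk <- substr(seq_text, s, min(s + 59, n))
      groups <- substring(chunk, seq(1, nchar(chunk), by = 10),
                          pmin(seq(10, nchar(chunk) + 9, by = 10), nchar(chunk)))
      sprintf("%9d %s", s, paste(groups, collapse = " "))
    }, character(1))
    lines <- c(lines, seq_lines)
  }
  c(lines, "//")
}
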