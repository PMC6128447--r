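# Query-string builders.  These construct — but never execute — the
# Entrez nucleotide/taxonomy queries and BOLD API terms needed to
# reproduce a retrieval out-of-band.  All builders are pure and emit
# balanced parentheses and quotes.

#' Build an Entrez nucleotide query
#'
#' The gene disjunction ANDed with an organism-scope clause, optionally a
#' deposition-year `[PDAT]` clause, a keyword `[KYWD]` clause, and a raw
#' species clause (parenthesized as given).
#'
#' @param gene_synonyms ordered character vector of gene labels.
#' @param organism_scope organism-scope term, default `"Eukaryota"`.
#' @param year optional integer deposition year.
#' @param keyword optional keyword, e.g. `"BARCODE"`.
#' @param species_clause optional raw species clause string (the builder
#'   does not guess how species lists are encoded).
#' @return the query string.
#' @examples
#' build_nucleotide_query(year = 2016)
#' @export
build_nucleotide_query <- function(gene_synonyms = c("CO1", "COI", "COX1", "COXI"),
                                   organism_scope = "Eukaryota",
                                   year = NULL, keyword = NULL,
                                   species_clause = NULL) {
  if (length(gene_synonyms) == 0) {
    stop("build_nucleotide_query(): gene_synonyms must be non-empty")
  }
  if (!nzchar(organism_scope)) {
    stop("build_nucleotide_query(): organism_scope must be non-empty")
  }
  gene <- paste(sprintf("\"%s\"[GENE]", gene_synonyms), collapse = " OR ")
  q <- sprintf("(%s) AND \"%s\"[ORGN]", gene, organism_scope)
  if (!is.null(year)) q <- sprintf("%s AND %d[PDAT]", q, as.integer(year))
  if (!is.null(keyword)) q <- sprintf("%s AND \"%s\"[KYWD]", q, keyword)
  if (!is.null(species_clause) && nzchar(species_clause)) {
    q <- sprintf("%s AND (%s)", q, species_clause)
  }
  q
}

#' Build an Entrez taxonomy query
#'
#' The `+`-joined taxonomy form, e.g.
#' `"Eukaryota[ORGN]+AND+species[RANK]"`.
#'
#' @param scope non-empty organism scope.
#' @param rank non-empty rank name.
#' @return the query string.
#' @export
build_taxonomy_query <- function(scope = "Eukaryota", rank = "species") {
  if (!nzchar(scope) || !nzchar(rank)) {
    stop("build_taxonomy_query(): scope and rank must be non-empty")
  }
  sprintf("%s[ORGN]+AND+%s[RANK]", scope, rank)
}

#' Build a BOLD API query term
#'
#' `marker=<m1>|<m2>&taxon=<taxon>` with markers pipe-joined.
#'
#' @param taxon non-empty taxon name.
#' @param markers non-empty character vector of marker codes.
#' @return the query string.
#' @examples
#' build_bold_query("Chordata")  # "marker=COI-3P|COI-5P&taxon=Chordata"
#' @export
build_bold_query <- function(taxon, markers = c("COI-3P", "COI-5P")) {
  if (length(taxon) != 1 || !nzchar(taxon)) {
    stop("build_bold_query(): taxon must be non-empty")
  }
  if (length(markers) == 0 || any(!nzchar(markers))) {
    stop("build_bold_query(): markers must be non-empty")
  }
  sprintf("marker=%s&taxon=%s", paste(markers, collapse = "|"), taxon)
}

#' Chunk species terms into bounded OR-clauses
#'
#' Long species lists must be batched: terms are quoted, OR-joined, and
#' split into clauses no longer than `max_chars` (a clause always holds at
#' least one term).
#'
#' @param terms character vector of species terms.
#' @param max_chars maximum clause length in characters.
#' @return character vector of clause strings, usable as
#'   `species_clause` in [build_nucleotide_query()].
#' @export
chunk_species_terms <- function(terms, max_chars = 2000) {
  stopifnot(length(terms) > 0, max_chars > 0)
  quoted <- sprintf("\"%s\"", terms)
  clauses <- character(0)
  cur <- character(0)
  cur_len <- 0L
  for (t in quoted) {
    add <- nchar(t) + if (length(cur) > 0) 4L else 0L  # " OR "
    if (length(cur) > 0 && cur_len + add > max_chars) {
      clauses <- c(clauses, paste(cur, collapse = " OR "))
      cur <- character(0)
      cur_len <- 0L
      add <- nchar(t)
    }
    cur <- c(cur, t)
    cur_len <- cur_len + add
  }
  c(clauses, paste(cur, collapse = " OR "))
}
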