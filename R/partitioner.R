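# Partition builders: COI gene filter, BARCODE keyword filter, and
# lineage-based taxon-group filter (e.g. the freshwater biomonitoring
# target groups).

#' Taxon group specifications
#'
#' A taxon group is a name plus a non-empty set of lineage tokens; a
#' record belongs to the group when any token appears (exact string match)
#' in its lineage.
#'
#' @param groups named list mapping group name -> character vector of
#'   lineage tokens.
#' @return an object of class `taxon_groups`.
#' @export
taxon_groups <- function(groups) {
  if (length(groups) == 0 || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("taxon_groups(): need a non-empty named list")
  }
  groups <- lapply(groups, as.character)
  if (any(lengths(groups) == 0)) {
    stop("taxon_groups(): every group needs at least one lineage token")
  }
  structure(groups, class = "taxon_groups")
}

#' Read taxon groups from a TSV config
#'
#' Two tab-separated columns, no header: group name, lineage token.
#' Repeated group names accumulate tokens.
#'
#' @param path path to the TSV file.
#' @return a [taxon_groups()] object.
#' @export
read_taxon_groups <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character",
                          col.names = c("group_name", "token"))
  taxon_groups(split(trimws(df$token), df$group_name))
}

#' The freshwater biomonitoring target groups
#'
#' The bundled high-level freshwater target taxa: Annelida classes
#' Clitellata and Polychaeta; Insecta orders Coleoptera, Diptera,
#' Ephemeroptera, Megaloptera, Odonata, Plecoptera, and Trichoptera;
#' Malacostraca orders Amphipoda and Isopoda; Mollusca classes Bivalvia
#' and Gastropoda; and Platyhelminthes class Turbellaria.  Each group is
#' keyed by its own taxon name.
#'
#' @return a [taxon_groups()] object.
#' @export
freshwater_groups <- function() {
  path <- system.file("extdata", "freshwater_groups.tsv", package = "coiaudit",
                      mustWork = TRUE)
  read_taxon_groups(path)
}

#' Filter records by COI gene label
#'
#' Retains records whose gene labels intersect the COI synonym set under
#' case-insensitive comparison.
#'
#' @param records a [record_set()].
#' @param gene_synonyms character vector of accepted gene labels;
#'   defaults to CO1/COI/COX1/COXI.
#' @return the retained [record_set()].
#' @export
filter_coi <- function(records, gene_synonyms = c("CO1", "COI", "COX1", "COXI")) {
  stopifnot(inherits(records, "record_set"), length(gene_synonyms) > 0)
  syn <- tolower(gene_synonyms)
  keep <- vapply(records$records$gene_labels, function(g) {
    any(tolower(g) %in% syn)
  }, logical(1))
  if (n_records(records) == 0) keep <- logical(0)
  rs_subset(records, keep)
}

#' Filter records by keyword
#'
#' Retains records carrying the keyword (exact, case-sensitive comparison
#' on the normalized keyword set; the INSDC `BARCODE` flag is uppercase by
#' standard).
#'
#' @param records a [record_set()].
#' @param keyword non-empty keyword, default `"BARCODE"`.
#' @return the retained [record_set()].
#' @export
filter_keyword <- function(records, keyword = "BARCODE") {
  stopifnot(inherits(records, "record_set"))
  if (length(keyword) != 1 || !nzchar(keyword)) {
    stop("filter_keyword(): keyword must be a non-empty string")
  }
  keep <- vapply(records$records$keywords, function(k) keyword %in% k, logical(1))
  if (n_records(records) == 0) keep <- logical(0)
  rs_subset(records, keep)
}

#' Filter records by taxon group membership
#'
#' Retains records whose lineage contains any group's lineage token (exact
#' string match on lineage entries) and reports per-group attribution: a
#' record matching two groups counts once in the union but once per group
#' in the attribution table.
#'
#' @param records a [record_set()].
#' @param groups a [taxon_groups()] object, e.g. [freshwater_groups()].
#' @return a list of class `taxa_partition` with elements `records` (the
#'   filtered union [record_set()]) and `group_counts` (named integer
#'   vector, one entry per group).
#' @export
filter_taxa <- function(records, groups) {
  stopifnot(inherits(records, "record_set"))
  if (!inherits(groups, "taxon_groups")) groups <- taxon_groups(groups)
  lineages <- records$records$lineage
  membership <- vapply(groups, function(tokens) {
    vapply(lineages, function(lin) any(tokens %in% lin), logical(1))
  }, logical(length(lineages)))
  if (n_records(records) == 0) {
    membership <- matrix(FALSE, nrow = 0, ncol = length(groups),
                         dimnames = list(NULL, names(groups)))
  }
  membership <- matrix(membership, ncol = length(groups),
                       dimnames = list(NULL, names(groups)))
  keep <- rowSums(membership) > 0
  structure(list(records = rs_subset(records, keep),
                 group_counts = colSums(membership)),
            class = "taxa_partition")
}

#' @export
print.taxa_partition <- function(x, ...) {
  cat(sprintf("<taxa_partition> %d record(s) in union\n", n_records(x$records)))
  print(x$group_counts)
  invisible(x)
}
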