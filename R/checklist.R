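# Species checklists with synonyms: e.g. an IUCN Red-List export of
# endangered species names plus their junior synonyms.

#' Construct a species checklist
#'
#' @param canonical_names character vector of accepted species names.
#' @param synonyms named character vector mapping synonym -> canonical
#'   name; every value must appear in `canonical_names`.
#' @return an object of class `species_checklist`.
#' @export
species_checklist <- function(canonical_names, synonyms = character(0)) {
  canonical_names <- unique(normalize_ws(as.character(canonical_names)))
  if (length(canonical_names) == 0) {
    stop("species_checklist(): no canonical names")
  }
  synonyms <- vapply(synonyms, normalize_ws, character(1))
  if (length(synonyms) > 0) {
    if (is.null(names(synonyms)) || any(!nzchar(names(synonyms)))) {
      stop("species_checklist(): synonyms must be a named vector")
    }
    missing <- setdiff(synonyms, canonical_names)
    if (length(missing) > 0) {
      stop("species_checklist(): synonym target(s) not in canonical names: ",
           paste(utils::head(missing, 3), collapse = ", "))
    }
  }
  structure(list(canonical_names = canonical_names, synonyms = synonyms),
            class = "species_checklist")
}

#' Read a species checklist from a two-column TSV
#'
#' Column 1 is a name; column 2, when non-blank, is the canonical name the
#' row's name is a synonym of (blank second column means the row is itself
#' canonical).  No header.
#'
#' @param path path to the TSV file.
#' @return a [species_checklist()].
#' @export
read_checklist <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("name", "canonical"), fill = TRUE)
  df$canonical[is.na(df$canonical)] <- ""
  is_syn <- nzchar(trimws(df$canonical))
  syn <- trimws(df$canonical[is_syn])
  names(syn) <- trimws(df$name[is_syn])
  species_checklist(trimws(df$name[!is_syn]), syn)
}

# resolve names to canonical checklist names (NA when unmatched);
# comparison is case-insensitive and whitespace-normalized
resolve_checklist <- function(names, checklist) {
  stopifnot(inherits(checklist, "species_checklist"))
  keys <- name_key(names)
  canon_map <- stats::setNames(checklist$canonical_names,
                               name_key(checklist$canonical_names))
  syn_map <- stats::setNames(unname(checklist$synonyms),
                             name_key(names(checklist$synonyms)))
  out <- unname(canon_map[keys])
  miss <- is.na(out)
  out[miss] <- unname(syn_map[keys[miss]])
  out
}

#' Filter a record set against a species checklist
#'
#' Retains records whose organism name equals a canonical checklist name
#' or a synonym (case-insensitive, whitespace-normalized).  Synonym hits
#' are tallied under their canonical name: the returned set carries a
#' `matched_canonical` attribute aligned with its rows.
#'
#' @param records a [record_set()].
#' @param checklist a [species_checklist()].
#' @return the retained [record_set()] with attribute `matched_canonical`.
#' @export
match_checklist <- function(records, checklist) {
  stopifnot(inherits(records, "record_set"))
  canon <- resolve_checklist(records$records$organism_name, checklist)
  keep <- !is.na(canon)
  out <- rs_subset(records, keep)
  attr(out, "matched_canonical") <- canon[keep]
  out
}

#' Checklist coverage of a record set
#'
#' How many canonical checklist species are represented by at least one
#' record (synonym matches count toward their canonical name).
#'
#' @inheritParams match_checklist
#' @return a list with `n_matched`, `n_checklist`, and `pct` (integer
#'   percent via the shared [percent()] rule).
#' @export
species_coverage <- function(records, checklist) {
  stopifnot(inherits(records, "record_set"))
  canon <- resolve_checklist(records$records$organism_name, checklist)
  n_matched <- length(unique(canon[!is.na(canon)]))
  n_checklist <- length(checklist$canonical_names)
  list(n_matched = n_matched, n_checklist = n_checklist,
       pct = percent(n_matched, n_checklist))
}
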