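# Organism-name grammar: "fully identified" means a complete Latin
# binomial at species rank with no disqualifying abbreviation; everything
# else is "insufficiently identified".

#' Disqualifier token sets
#'
#' A disqualifier set holds the tokens whose presence in an organism name
#' marks it as insufficiently identified.  Two presets are built in:
#' `"genbank"` = \{sp., nr., aff., cf.\} (the screen applied to NCBI
#' species names) and `"iucn"` = \{affinis, sp., sp. nov.\} (the screen
#' applied to Red-List species lists).  Multi-word tokens are matched as
#' contiguous token runs.
#'
#' @param tokens non-empty character vector of tokens.
#' @param label free-text label.
#' @return an object of class `disqualifier_set`.
#' @export
disqualifier_set <- function(tokens, label = "custom") {
  tokens <- unique(as.character(tokens))
  if (length(tokens) == 0 || any(!nzchar(tokens))) {
    stop("disqualifier_set(): tokens must be non-empty")
  }
  structure(list(tokens = tokens, label = label), class = "disqualifier_set")
}

#' @rdname disqualifier_set
#' @param preset `"genbank"` or `"iucn"`.
#' @export
disqualifier_preset <- function(preset = c("genbank", "iucn")) {
  preset <- match.arg(preset)
  switch(preset,
    genbank = disqualifier_set(c("sp.", "nr.", "aff.", "cf."), "genbank"),
    iucn = disqualifier_set(c("affinis", "sp.", "sp. nov."), "iucn")
  )
}

#' Classify an organism name
#'
#' A name is fully identified iff (a) no whitespace-delimited token run,
#' compared case-insensitively, equals a disqualifier token, and (b) it has
#' at least two tokens with token 1 a capitalized alphabetic genus and
#' token 2 a lowercase alphabetic epithet (internal hyphens allowed).
#' Trinomials (subspecies) with no disqualifier are fully identified with
#' the epithet taken from token 2.  Token comparison keeps trailing
#' periods, so `"sp."` does not reject `"Gammarus spectabilis"`.
#'
#' @param name organism name (non-empty after whitespace normalization).
#' @param disq a [disqualifier_set()]; defaults to the `"genbank"` preset.
#' @return a list of class `name_classification` with fields `verdict`
#'   (`"fully_identified"` or `"insufficiently_identified"`),
#'   `matched_disqualifier` (`NA` unless a disqualifier fired), `genus`,
#'   `epithet` (`NA` unless fully identified).
#' @examples
#' classify_name("Homo sapiens")$verdict          # fully_identified
#' classify_name("Gammarus sp.")$matched_disqualifier  # "sp."
#' @export
classify_name <- function(name, disq = disqualifier_preset("genbank")) {
  stopifnot(length(name) == 1)
  as_classification(classify_names(name, disq), 1L)
}

as_classification <- function(df, i) {
  structure(list(verdict = df$verdict[i],
                 matched_disqualifier = df$matched_disqualifier[i],
                 genus = df$genus[i], epithet = df$epithet[i]),
            class = "name_classification")
}

#' Classify a vector of organism names
#'
#' Vectorized form of [classify_name()].
#'
#' @param names character vector of organism names.
#' @inheritParams classify_name
#' @return a data.frame with one row per name and columns `name`,
#'   `verdict`, `matched_disqualifier`, `genus`, `epithet`.
#' @export
classify_names <- function(names, disq = disqualifier_preset("genbank")) {
  stopifnot(inherits(disq, "disqualifier_set"))
  names <- as.character(names)
  norm <- normalize_ws(names)
  if (any(is.na(norm) | !nzchar(norm))) {
    stop("classify_names(): empty name at position ",
         which(is.na(norm) | !nzchar(norm))[1])
  }
  # disqualifiers as lowercase token runs, longest first for determinism
  dtoks <- strsplit(tolower(disq$tokens), " ", fixed = TRUE)
  ord <- order(-lengths(dtoks), tolower(disq$tokens))
  dtoks <- dtoks[ord]
  dlabel <- disq$tokens[ord]

  tok_list <- strsplit(norm, " ", fixed = TRUE)
  n <- length(norm)
  verdict <- character(n)
  matched <- rep(NA_character_, n)
  genus <- rep(NA_character_, n)
  epithet <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    toks <- tok_list[[i]]
    low <- tolower(toks)
    hit <- NA_character_
    for (pos in seq_along(low)) {
      for (d in seq_along(dtoks)) {
        dl <- length(dtoks[[d]])
        if (pos + dl - 1L <= length(low) &&
            identical(low[pos:(pos + dl - 1L)], dtoks[[d]])) {
          hit <- dlabel[d]
          break
        }
      }
      if (!is.na(hit)) break
    }
    if (!is.na(hit)) {
      verdict[i] <- "insufficiently_identified"
      matched[i] <- hit
    } else if (length(toks) >= 2 &&
               grepl("^[A-Z][a-z]+$", toks[1]) &&
               grepl("^[a-z]+(-[a-z]+)*$", toks[2])) {
      verdict[i] <- "fully_identified"
      genus[i] <- toks[1]
      epithet[i] <- toks[2]
    } else {
      verdict[i] <- "insufficiently_identified"
    }
  }
  data.frame(name = names, verdict = verdict, matched_disqualifier = matched,
             genus = genus, epithet = epithet, stringsAsFactors = FALSE)
}

# logical mask of fully identified organism names for a record_set
fully_identified_mask <- function(rs, disq) {
  if (n_records(rs) == 0) return(logical(0))
  classify_names(rs$records$organism_name, disq)$verdict == "fully_identified"
}

#' @export
print.name_classification <- function(x, ...) {
  cat(sprintf("<name_classification> %s", x$verdict))
  if (!is.na(x$matched_disqualifier)) {
    cat(sprintf(" (disqualifier '%s')", x$matched_disqualifier))
  }
  if (!is.na(x$genus)) cat(sprintf(" [%s %s]", x$genus, x$epithet))
  cat("\n")
  invisible(x)
}
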