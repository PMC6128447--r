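# Synthetic record generator.  Emulates the statistical structure the
# audit assumes — yearly deposition counts following a fixed geometric
# growth rate, configurable fractions of fully identified names, BARCODE
# keywords and geo qualifiers, a skewed country distribution, a BOLD dump
# with known crossref categories, and a species checklist with synonyms —
# with complete per-record ground truth.  Sequences are random
# nucleotides; no attempt is made to imitate real COI composition.

synthetic_countries <- c(
  "Canada", "United States", "Costa Rica", "Australia", "China", "Germany",
  "Brazil", "Mexico", "India", "South Africa", "France", "Japan", "Norway",
  "Argentina", "Kenya", "Indonesia", "Peru", "Spain", "Sweden", "Italy",
  "Russia", "New Zealand", "Chile", "Finland", "Vietnam", "Panama",
  "Madagascar", "Ecuador", "Portugal", "Thailand"
)

# lineages for the bundled freshwater target groups; keys match
# freshwater_groups() group names
freshwater_lineages <- list(
  Clitellata = c("Annelida", "Clitellata"),
  Polychaeta = c("Annelida", "Polychaeta"),
  Coleoptera = c("Arthropoda", "Insecta", "Coleoptera"),
  Diptera = c("Arthropoda", "Insecta", "Diptera"),
  Ephemeroptera = c("Arthropoda", "Insecta", "Ephemeroptera"),
  Megaloptera = c("Arthropoda", "Insecta", "Megaloptera"),
  Odonata = c("Arthropoda", "Insecta", "Odonata"),
  Plecoptera = c("Arthropoda", "Insecta", "Plecoptera"),
  Trichoptera = c("Arthropoda", "Insecta", "Trichoptera"),
  Amphipoda = c("Arthropoda", "Malacostraca", "Amphipoda"),
  Isopoda = c("Arthropoda", "Malacostraca", "Isopoda"),
  Bivalvia = c("Mollusca", "Bivalvia"),
  Gastropoda = c("Mollusca", "Gastropoda"),
  Turbellaria = c("Platyhelminthes", "Turbellaria")
)

#' Synthetic data configuration
#'
#' Defaults state the world the audit emulates: deposition 2003-2017 with
#' a 51% geometric annual growth rate; 55% of records fully identified;
#' 28% BARCODE-flagged; 74% with country and 51% with lat_lon qualifiers
#' (BARCODE records always carry both, mirroring the near-complete
#' geotagging of BARCODE-standard records); sequence lengths uniform on
#' 450-1000 bp; BOLD crossref mix 15/48/37.  `base_deposits` sets desk
#' scale (10 first-year records, ~9,500 records over the window), not
#' database scale.
#'
#' @param seed integer seed driving all randomness.
#' @param year_range integer vector; its range is the deposition window.
#' @param base_deposits records deposited in the first year.
#' @param annual_growth geometric annual growth rate of yearly deposits
#'   (> -1); yearly counts are `round_half_up(base * (1+g)^(y-y0))`.
#' @param p_full fraction of records with a valid binomial name.
#' @param p_barcode fraction flagged BARCODE.
#' @param p_country,p_latlon fractions of non-BARCODE records with
#'   country / lat_lon qualifiers.
#' @param length_distribution `list(kind = "fixed", bp =)` or
#'   `list(kind = "uniform", min =, max =)`.
#' @param n_species_pool size of the synthetic binomial name pool.
#' @param group_mix named fractions over [freshwater_groups()] names
#'   (rest of the records get a non-target lineage); sums to <= 1.
#' @param bold_mix fractions for the three crossref categories
#'   (barcode_linked, accession_linked, bold_only); sums to <= 1,
#'   remainder is bold_only; must be named with those categories.
#' @param n_bold number of BOLD records.
#' @param n_checklist checklist size; half of the names come from the
#'   species pool (and can be matched), the rest are novel.
#' @param n_synonyms number of synonym rows added to the checklist.
#' @param country_skew Zipf exponent of the country distribution (higher
#'   = more skewed toward the first countries in the bundled list).
#' @param n_countries number of distinct countries drawn from.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             year_range = 2003:2017,
                             base_deposits = 10,
                             annual_growth = 0.51,
                             p_full = 0.55,
                             p_barcode = 0.28,
                             p_country = 0.74,
                             p_latlon = 0.51,
                             length_distribution = list(kind = "uniform",
                                                        min = 450, max = 1000),
                             n_species_pool = 500,
                             group_mix = c(Diptera = 0.25, Coleoptera = 0.08,
                                           Gastropoda = 0.05, Trichoptera = 0.05),
                             bold_mix = c(barcode_linked = 0.15,
                                          accession_linked = 0.48,
                                          bold_only = 0.37),
                             n_bold = 1000,
                             n_checklist = 50,
                             n_synonyms = 10,
                             country_skew = 1.5,
                             n_countries = 30) {
  cfg <- list(seed = as.integer(seed), year_range = range(year_range),
              base_deposits = base_deposits, annual_growth = annual_growth,
              p_full = p_full, p_barcode = p_barcode, p_country = p_country,
              p_latlon = p_latlon, length_distribution = length_distribution,
              n_species_pool = n_species_pool, group_mix = group_mix,
              bold_mix = bold_mix, n_bold = n_bold, n_checklist = n_checklist,
              n_synonyms = n_synonyms, country_skew = country_skew,
              n_countries = n_countries)
  fr <- c(cfg$p_full, cfg$p_barcode, cfg$p_country, cfg$p_latlon,
          cfg$group_mix, cfg$bold_mix)
  if (any(fr < 0 | fr > 1)) {
    stop("synthetic_config(): fractions must lie in [0, 1]")
  }
  if (sum(cfg$group_mix) > 1 + 1e-9) {
    stop("synthetic_config(): group_mix fractions sum to more than 1")
  }
  if (sum(cfg$bold_mix) > 1 + 1e-9) {
    stop("synthetic_config(): bold_mix fractions sum to more than 1")
  }
  bold_cats <- c("barcode_linked", "accession_linked", "bold_only")
  if (is.null(names(cfg$bold_mix)) ||
      !all(names(cfg$bold_mix) %in% bold_cats)) {
    stop("synthetic_config(): bold_mix must be named with ",
         paste(bold_cats, collapse = "/"))
  }
  if (cfg$annual_growth <= -1) {
    stop("synthetic_config(): annual_growth must be > -1")
  }
  if (cfg$base_deposits < 0 || cfg$n_species_pool < 1) {
    stop("synthetic_config(): invalid sizes")
  }
  bad_groups <- setdiff(names(cfg$group_mix), names(freshwater_lineages))
  if (length(bad_groups) > 0) {
    stop("synthetic_config(): unknown group(s) in group_mix: ",
         paste(bad_groups, collapse = ", "))
  }
  structure(cfg, class = "synthetic_config")
}

# pronounceable binomials from syllable templates; deterministic under the
# caller's RNG state
synth_species_pool <- function(n) {
  syl <- c("ba", "ce", "di", "fo", "ga", "hu", "le", "mi", "no", "pa",
           "ru", "sa", "ti", "vo", "xe", "zu", "dra", "cor", "lin", "mus")
  make <- function(k, n_syl) {
    vapply(seq_len(k), function(i) {
      paste(sample(syl, n_syl, replace = TRUE), collapse = "")
    }, character(1))
  }
  out <- character(0)
  while (length(out) < n) {
    genus <- make(2 * n, 3)
    genus <- paste0(toupper(substr(genus, 1, 1)), substr(genus, 2, nchar(genus)))
    epithet <- make(2 * n, 3)
    out <- unique(c(out, paste(genus, epithet)))
  }
  out[seq_len(n)]
}

# lowercase letter suffixes: a, b, ..., z, aa, ab, ...
letter_suffix <- function(i) {
  vapply(i, function(k) {
    out <- ""
    k <- k - 1L
    repeat {
      out <- paste0(letters[k %% 26L + 1L], out)
      k <- k %/% 26L - 1L
      if (k < 0) break
    }
    out
  }, character(1))
}

random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic record universe with ground truth
#'
#' Builds a GenBank-style [record_set()], a BOLD dump (data.frame), a
#' species checklist, and a `truth` list holding every label the
#' generator randomized: per-record flags, exact per-year counts,
#' per-group and per-country compositions, BOLD category assignments, and
#' checklist match counts.  All randomness is driven by `config$seed`;
#' the same seed yields identical output.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_data` with elements `records`,
#'   `bold`, `checklist`, `truth`, `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  years <- seq(config$year_range[1], config$year_range[2])
  deposited <- as.integer(round_half_up(
    config$base_deposits * (1 + config$annual_growth)^(seq_along(years) - 1)))
  n <- sum(deposited)

  pool <- synth_species_pool(config$n_species_pool)
  year <- rep(years, deposited)
  accession <- sprintf("SYN%07d", seq_len(n))
  full <- runif(n) < config$p_full
  species <- sample(pool, n, replace = TRUE)
  organism <- species
  if (any(!full)) {
    genus <- vapply(strsplit(species[!full], " "), `[[`, character(1), 1)
    disq <- sample(c("sp.", "nr.", "aff.", "cf."), sum(!full), replace = TRUE)
    tail_epithet <- ifelse(disq == "sp.", "",
                           paste0(" ", vapply(strsplit(sample(pool, sum(!full),
                                                              replace = TRUE), " "),
                                              `[[`, character(1), 2)))
    organism[!full] <- paste0(genus, " ", disq, tail_epithet)
  }
  barcode <- runif(n) < config$p_barcode
  has_country <- barcode | runif(n) < config$p_country
  has_latlon <- barcode | runif(n) < config$p_latlon

  ld <- config$length_distribution
  seq_len_bp <- switch(ld$kind,
    fixed = rep(as.integer(ld$bp), n),
    uniform = sample(seq(ld$min, ld$max), n, replace = TRUE),
    stop("generate_synthetic(): unknown length_distribution kind '", ld$kind, "'")
  )

  group_names <- c(names(config$group_mix), "other")
  group_probs <- c(config$group_mix, other = 1 - sum(config$group_mix))
  group <- sample(group_names, n, replace = TRUE, prob = group_probs)
  lineage <- lapply(group, function(g) {
    if (g == "other") c("Eukaryota", "Metazoa", "Chordata", "Mammalia")
    else c("Eukaryota", "Metazoa", freshwater_lineages[[g]])
  })

  countries <- synthetic_countries[seq_len(min(config$n_countries,
                                               length(synthetic_countries)))]
  cprob <- seq_along(countries)^(-config$country_skew)
  country_base <- sample(countries, n, replace = TRUE, prob = cprob)
  with_region <- runif(n) < 0.3
  country_raw <- ifelse(with_region,
                        paste0(country_base, ": Region ",
                               sample(LETTERS, n, replace = TRUE)),
                        country_base)
  country_raw[!has_country] <- NA_character_
  country_base[!has_country] <- NA_character_

  lat <- round(runif(n, -60, 70), 2)
  lon <- round(runif(n, -180, 180), 2)
  lat_lon_raw <- sprintf("%.2f %s %.2f %s", abs(lat),
                         ifelse(lat < 0, "S", "N"), abs(lon),
                         ifelse(lon < 0, "W", "E"))
  lat_lon_raw[!has_latlon] <- NA_character_

  gene_label <- sample(c("COI", "CO1", "COX1", "cox1"), n, replace = TRUE)

  # checklist: part matchable pool names, part novel, plus synonyms
  n_in_pool <- min(round_half_up(config$n_checklist / 2), config$n_species_pool)
  canon_in <- sample(pool, n_in_pool)
  n_novel <- config$n_checklist - n_in_pool
  canon_novel <- if (n_novel > 0) {
    paste("Novus", paste0("listedspecies", letter_suffix(seq_len(n_novel))))
  } else character(0)
  canonical <- c(canon_in, canon_novel)
  syn_targets <- sample(canonical, min(config$n_synonyms, length(canonical)))
  # synonym names stay valid binomials so rewritten records remain
  # classifier-fully-identified
  synonyms <- stats::setNames(
    syn_targets,
    paste0("Vetus", letter_suffix(seq_along(syn_targets)), " synonymum"))
  # rewrite one matching record per synonym to use the synonym name, so
  # synonym resolution is exercised with known truth
  for (s in names(synonyms)) {
    cand <- which(full & organism == synonyms[[s]])
    if (length(cand) > 0) organism[cand[1]] <- s
  }

  records <- record_set(data.frame(
    accession = accession, deposit_year = year, organism_name = organism,
    lineage = I(lineage), keywords = I(lapply(barcode, function(b) {
      if (b) "BARCODE" else character(0)
    })),
    gene_labels = I(as.list(gene_label)),
    sequence_length = seq_len_bp, country_raw = country_raw,
    lat_lon_raw = lat_lon_raw, sequence = random_dna(seq_len_bp),
    stringsAsFactors = FALSE
  ), source_label = sprintf("synthetic(seed=%d)", config$seed))

  bold <- generate_bold(config, accession, barcode, pool)

  canon_resolved <- resolve_checklist(organism, species_checklist(canonical, synonyms))
  truth <- list(
    n_records = n,
    yearly = data.frame(
      year = years, deposited = deposited,
      unique_species = vapply(years, function(y) {
        length(unique(organism[year == y & full]))
      }, integer(1)),
      cumulative = cumsum(deposited)
    ),
    per_record = data.frame(
      accession = accession, year = year, full = full, barcode = barcode,
      has_country = has_country, has_latlon = has_latlon,
      sequence_length = seq_len_bp, group = group, country = country_base,
      organism = organism, stringsAsFactors = FALSE
    ),
    n_full = sum(full), n_barcode = sum(barcode),
    n_country = sum(has_country), n_latlon = sum(has_latlon),
    n_full_country = sum(full & has_country),
    n_full_latlon = sum(full & has_latlon),
    n_full_len_ge_500 = sum(full & seq_len_bp >= 500),
    group_counts = table(factor(group, levels = group_names)),
    country_counts = sort(table(country_base[full & has_country]),
                          decreasing = TRUE),
    bold_category_counts = table(factor(bold$category,
                                        levels = c("barcode_linked",
                                                   "accession_linked",
                                                   "bold_only"))),
    checklist = list(
      canonical = canonical, synonyms = synonyms,
      n_matched_species = length(unique(canon_resolved[!is.na(canon_resolved)])),
      n_matched_records = sum(!is.na(canon_resolved))
    )
  )
  structure(list(records = records,
                 bold = bold[c("record_id", "taxon_name", "marker",
                               "genbank_accession", "sequence", "category")],
                 checklist = species_checklist(canonical, synonyms),
                 truth = truth, config = config),
            class = "synthetic_data")
}

generate_bold <- function(config, accession, barcode, pool) {
  n_bold <- config$n_bold
  if (n_bold == 0) {
    return(data.frame(record_id = character(0), taxon_name = character(0),
                      marker = character(0), genbank_accession = character(0),
                      sequence = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  mix <- config$bold_mix
  category <- sample(c(names(mix), "bold_only"), n_bold, replace = TRUE,
                     prob = c(mix, 1 - sum(mix)))
  acc <- rep(NA_character_, n_bold)
  is_bc <- category == "barcode_linked"
  if (any(is_bc)) {
    bc_pool <- accession[barcode]
    if (length(bc_pool) == 0) {
      stop("generate_synthetic(): bold_mix wants barcode-linked records but no GenBank record is BARCODE-flagged")
    }
    acc[is_bc] <- sample(bc_pool, sum(is_bc), replace = TRUE)
  }
  is_al <- category == "accession_linked"
  if (any(is_al)) {
    nb_pool <- accession[!barcode]
    suppressed <- runif(sum(is_al)) < 0.5  # half point at suppressed records
    acc_al <- character(sum(is_al))
    acc_al[suppressed] <- sprintf("SUP%07d", seq_len(sum(suppressed)))
    if (any(!suppressed)) {
      if (length(nb_pool) == 0) nb_pool <- sprintf("SUP9%06d", seq_len(10))
      acc_al[!suppressed] <- sample(nb_pool, sum(!suppressed), replace = TRUE)
    }
    acc[is_al] <- acc_al
  }
  data.frame(
    record_id = sprintf("SYNBOLD%05d", seq_len(n_bold)),
    taxon_name = sample(pool, n_bold, replace = TRUE),
    marker = sample(c("COI-5P", "COI-3P"), n_bold, replace = TRUE, prob = c(0.8, 0.2)),
    genbank_accession = acc,
    sequence = random_dna(rep(60L, n_bold)),
    category = category,
    stringsAsFactors = FALSE
  )
}

#' Serialize a checklist as a two-column TSV
#'
#' @param checklist a [species_checklist()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_checklist <- function(checklist, path) {
  stopifnot(inherits(checklist, "species_checklist"))
  lines <- c(paste0(checklist$canonical_names, "\t"),
             if (length(checklist$synonyms) > 0) {
               paste0(names(checklist$synonyms), "\t", checklist$synonyms)
             })
  writeLines(lines, path)
  invisible(path)
}

#' Write synthetic data to a directory
#'
#' Serializes a [generate_synthetic()] result: `records.gb` (GenBank
#' flatfile), `bold.tsv` and `bold.fasta` (the same BOLD dump in both
#' dialects), `checklist.tsv`, and `truth.json`.
#'
#' @param x a `synthetic_data` object, or a [synthetic_config()] (which
#'   is generated first).
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of file paths.
#' @export
write_synthetic <- function(x, dir) {
  if (inherits(x, "synthetic_config")) x <- generate_synthetic(x)
  stopifnot(inherits(x, "synthetic_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genbank = file.path(dir, "records.gb"),
    bold_tsv = file.path(dir, "bold.tsv"),
    bold_fasta = file.path(dir, "bold.fasta"),
    checklist = file.path(dir, "checklist.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_genbank(x$records, paths$genbank)
  write_bold_dump(x$bold, paths$bold_tsv, "tsv")
  write_bold_dump(x$bold, paths$bold_fasta, "fasta")
  write_checklist(x$checklist, paths$checklist)
  truth <- x$truth
  truth$group_counts <- as.list(truth$group_counts)
  truth$country_counts <- as.list(truth$country_counts)
  truth$bold_category_counts <- as.list(truth$bold_category_counts)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
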