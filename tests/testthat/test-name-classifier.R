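test_that("classify_name handles the canonical grammar cases", {
  gb <- disqualifier_preset("genbank")

  full <- classify_name("Homo sapiens", gb)
  expect_equal(full$verdict, "fully_identified")
  expect_equal(full$genus, "Homo")
  expect_equal(full$epithet, "sapiens")
  expect_true(is.na(full$matched_disqualifier))

  sp <- classify_name("Gammarus sp.", gb)
  expect_equal(sp$verdict, "insufficiently_identified")
  expect_equal(sp$matched_disqualifier, "sp.")

  cf <- classify_name("Daphnia cf. pulex", gb)
  expect_equal(cf$verdict, "insufficiently_identified")
  expect_equal(cf$matched_disqualifier, "cf.")

  expect_equal(classify_name("Bison", gb)$verdict, "insufficiently_identified")

  # trinomials with no disqualifier are fully identified, epithet = token 2
  tri <- classify_name("Canis lupus familiaris", gb)
  expect_equal(tri$verdict, "fully_identified")
  expect_equal(tri$epithet, "lupus")

  # trailing period required: "sp." must not reject "spectabilis"
  expect_equal(classify_name("Gammarus spectabilis", gb)$verdict,
               "fully_identified")
  # comparison is case-insensitive
  expect_equal(classify_name("Gammarus SP.", gb)$verdict,
               "insufficiently_identified")
})

test_that("multi-word disqualifiers match as contiguous token runs", {
  iucn <- disqualifier_preset("iucn")
  hit <- classify_name("Panthera sp. nov.", iucn)
  expect_equal(hit$verdict, "insufficiently_identified")
  expect_equal(hit$matched_disqualifier, "sp. nov.")
  expect_equal(classify_name("Gammarus affinis", iucn)$verdict,
               "insufficiently_identified")
  # "affinis" is only an IUCN-side disqualifier
  expect_equal(classify_name("Gammarus affinis",
                             disqualifier_preset("genbank"))$verdict,
               "fully_identified")
})

test_that("empty names are rejected", {
  expect_error(classify_name("  "), "empty name")
  expect_error(disqualifier_set(character(0)), "non-empty")
})

test_that("classify_names agrees with the brute-force token-run oracle", {
  gb <- disqualifier_preset("genbank")
  iucn <- disqualifier_preset("iucn")
  set.seed(101)
  names <- random_names(2000)
  got_gb <- classify_names(names, gb)$verdict
  got_iucn <- classify_names(names, iucn)$verdict
  exp_gb <- vapply(names, oracle_classify, character(1), gb$tokens)
  exp_iucn <- vapply(names, oracle_classify, character(1), iucn$tokens)
  expect_equal(unname(got_gb), unname(exp_gb))
  expect_equal(unname(got_iucn), unname(exp_iucn))
})

test_that("adding a disqualifier token never rescues a rejected name", {
  set.seed(102)
  names <- random_names(400)
  base <- disqualifier_set(c("sp.", "nr."))
  wider <- disqualifier_set(c("sp.", "nr.", "aff.", "cf.", "nov."))
  v1 <- classify_names(names, base)$verdict
  v2 <- classify_names(names, wider)$verdict
  expect_false(any(v1 == "insufficiently_identified" & v2 == "fully_identified"))
})

test_that("match_checklist retains matches and resolves synonyms", {
  cl <- species_checklist("Panthera uncia",
                          c("Uncia uncia" = "Panthera uncia"))
  rs <- make_records(c("A1", "A2", "A3"),
                     organism_name = c("Panthera uncia", "Uncia uncia",
                                       "Homo sapiens"))
  got <- match_checklist(rs, cl)
  expect_equal(got$records$accession, c("A1", "A2"))
  expect_equal(attr(got, "matched_canonical"),
               c("Panthera uncia", "Panthera uncia"))

  # disjoint checklist -> empty result; subset + idempotence properties
  none <- match_checklist(rs, species_checklist("Nulla species"))
  expect_equal(n_records(none), 0)
  again <- match_checklist(got, cl)
  expect_equal(again$records, got$records)
})

test_that("species_coverage counts canonical species via the percent rule", {
  cl <- species_checklist(sprintf("Genus species%02d", 1:50))
  empty_cov <- species_coverage(record_set(), cl)
  expect_equal(empty_cov$n_matched, 0)
  expect_equal(empty_cov$pct, 0L)

  rs <- make_records(sprintf("R%02d", 1:20),
                     organism_name = rep(sprintf("Genus species%02d", 1:10), 2))
  cov <- species_coverage(rs, cl)
  expect_equal(cov$n_matched, 10)  # duplicates collapse to distinct species
  expect_equal(cov$n_checklist, 50)
  expect_equal(cov$pct, 20L)
})

test_that("checklist round-trips through its TSV serialization", {
  cl <- species_checklist(c("Panthera uncia", "Ailurus fulgens"),
                          c("Uncia uncia" = "Panthera uncia"))
  tf <- withr::local_tempfile()
  write_checklist(cl, tf)
  got <- read_checklist(tf)
  expect_setequal(got$canonical_names, cl$canonical_names)
  expect_equal(got$synonyms[["Uncia uncia"]], "Panthera uncia")
  expect_error(species_checklist("A b", c("X y" = "Missing target")),
               "not in canonical")
})
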