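test_that("percent follows the shared half-up rule", {
  expect_identical(percent(1383206, 2530418), 55L)
  expect_identical(percent(718814, 2530418), 28L)
  expect_identical(percent(0, 100), 0L)
  expect_identical(percent(0, 0), 0L)
  expect_identical(percent(1, 200), 1L)     # 0.5 rounds up
  expect_identical(percent(1, 8), 13L)      # 12.5 rounds up
  expect_error(percent(3, 2), "exceeds")
  expect_error(percent(-1, 2), "non-negative")
})

test_that("audit of an empty partition is degenerate with all-zero percents", {
  rep <- audit(record_set(), label = "empty")
  expect_true(rep$degenerate)
  expect_equal(rep$n_total, 0)
  expect_equal(rep$pct_fully_identified, 0L)
  expect_equal(rep$pct_country, 0L)
})

test_that("audit counts completeness among fully identified records only", {
  rs <- make_records(
    c("A1", "A2", "A3", "A4"),
    organism_name = c("Homo sapiens", "Gammarus sp.", "Daphnia pulex", "Bison"),
    sequence_length = c(658L, 658L, 120L, 658L),
    country_raw = c("Canada", "Canada", NA, "Canada"),
    lat_lon_raw = c("1.00 N 2.00 E", NA, NA, NA))
  rep <- audit(rs, label = "mix")
  expect_equal(rep$n_total, 4)
  expect_equal(rep$n_fully_identified, 2)
  expect_equal(rep$pct_fully_identified, 50L)
  # among the two fully identified: one good length, one country, one latlon
  expect_equal(rep$n_len_ge_500, 1)
  expect_equal(rep$n_country, 1)
  expect_equal(rep$n_latlon, 1)
  expect_equal(rep$pct_len_ge_500, 50L)
  # the insufficiently identified A2's country does not count
  expect_equal(rep$pct_country, 50L)
})

test_that("species_list_mode forces 100% fully identified", {
  rs <- make_records(c("A1", "A2"),
                     organism_name = c("Panthera uncia", "Panthera uncia"))
  rep <- audit(rs, label = "checklist", species_list_mode = TRUE)
  expect_equal(rep$pct_fully_identified, 100L)
  expect_equal(rep$n_fully_identified, 2)
})

test_that("the length threshold is inclusive and configurable", {
  rs <- make_records(c("A1", "A2"), sequence_length = c(500L, 499L))
  rep <- audit(rs, label = "thr")
  expect_equal(rep$n_len_ge_500, 1)
  rep2 <- audit(rs, label = "thr", length_threshold = 499)
  expect_equal(rep2$n_len_ge_500, 2)
})

test_that("audit counts are additive over disjoint partitions", {
  dat <- generate_synthetic(tiny_config(seed = 21))
  rs <- dat$records
  half <- n_records(rs) %/% 2
  a <- audit(rs_a <- coiaudit:::rs_subset(rs, seq_len(half)), label = "a")
  b <- audit(coiaudit:::rs_subset(rs, (half + 1):n_records(rs)), label = "b")
  whole <- audit(rs, label = "whole")
  for (f in c("n_total", "n_fully_identified", "n_len_ge_500", "n_country",
              "n_latlon")) {
    expect_equal(a[[f]] + b[[f]], whole[[f]], info = f)
  }
})

test_that("audit recovers configured proportions on synthetic data", {
  n <- 20000
  cfg <- synthetic_config(seed = 31, year_range = 2015, base_deposits = n,
                          p_full = 0.5, p_barcode = 0, p_country = 0.74,
                          p_latlon = 0.51, n_bold = 0,
                          bold_mix = c(bold_only = 1))
  dat <- generate_synthetic(cfg)
  rep <- audit(dat$records, label = "recovery")
  # exact agreement with the generator's own bookkeeping
  expect_equal(rep$n_fully_identified, dat$truth$n_full)
  expect_equal(rep$n_country, dat$truth$n_full_country)
  expect_equal(rep$n_latlon, dat$truth$n_full_latlon)
  expect_equal(rep$n_len_ge_500, dat$truth$n_full_len_ge_500)
  # configured proportions recovered within 3 binomial SD
  sd_pct <- function(p, m) 100 * sqrt(p * (1 - p) / m)
  expect_lt(abs(rep$pct_fully_identified - 50), 3 * sd_pct(0.5, n))
  expect_lt(abs(rep$pct_country - 74), 3 * sd_pct(0.74, rep$n_fully_identified))
  expect_lt(abs(rep$pct_latlon - 51), 3 * sd_pct(0.51, rep$n_fully_identified))
})

test_that("percents are scale-invariant", {
  expect_equal(percent(7, 13), percent(7 * 1000, 13 * 1000))
  expect_equal(percent(28, 100), percent(2800, 10000))
})

test_that("audit reports serialize to TSV and JSON", {
  dat <- generate_synthetic(tiny_config(seed = 23))
  reports <- list(audit(dat$records, label = "All"),
                  audit(filter_keyword(dat$records), label = "BARCODE"))
  tsv <- withr::local_tempfile()
  js <- withr::local_tempfile()
  tab <- write_audit_reports(reports, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 2)
  expect_equal(back$n_total, tab$n_total)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$partition_label, c("All", "BARCODE"))
})
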