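test_that("parse_lat_lon follows the INSDC sign convention", {
  expect_equal(parse_lat_lon("0 N 0 E"),
               data.frame(latitude = 0, longitude = 0))
  expect_equal(parse_lat_lon("45.50 N 73.57 W"),
               data.frame(latitude = 45.5, longitude = -73.57))
  expect_equal(parse_lat_lon("12.10 S 96.90 E"),
               data.frame(latitude = -12.1, longitude = 96.9))
})

test_that("malformed or out-of-range lat_lon errors carry the raw string", {
  expect_error(parse_lat_lon("45.5, -73.57"), "45.5, -73.57")
  expect_error(parse_lat_lon("95.00 N 10.00 E"), "95.00 N 10.00 E")
  expect_error(parse_lat_lon("10.00 N 190.00 E"), "malformed")
  got <- suppressWarnings(parse_lat_lon(c("1.00 N 2.00 E", "junk"),
                                        strict = FALSE))
  expect_equal(got$latitude, c(1, NA))
  expect_warning(parse_lat_lon("junk", strict = FALSE), "demoted")
})

test_that("format_lat_lon round-trips through parse_lat_lon", {
  set.seed(61)
  lat <- round(runif(200, -90, 90), 4)
  lon <- round(runif(200, -180, 180), 4)
  back <- parse_lat_lon(format_lat_lon(lat, lon))
  expect_equal(back$latitude, lat)
  expect_equal(back$longitude, lon)
})

test_that("parse_country applies the first-colon rule, trimming, aliases", {
  expect_equal(parse_country("Canada: Ontario, Guelph"), "Canada")
  expect_equal(parse_country("   France "), "France")
  expect_equal(parse_country("USA", aliases = c(USA = "United States")),
               "United States")
  expect_equal(parse_country("USA: Alaska", aliases = c(USA = "United States")),
               "United States")
  expect_error(parse_country(""), "empty")
})

test_that("summarize_geo tallies fully identified records only", {
  rs <- make_records(
    c("A1", "A2", "A3", "A4"),
    organism_name = c("Homo sapiens", "Homo sapiens", "Gammarus sp.",
                      "Daphnia pulex"),
    country_raw = c("Canada: Ontario", "Canada", "Canada", NA),
    lat_lon_raw = c("1.00 N 2.00 E", NA, NA, "bad string"))
  geo <- suppressWarnings(summarize_geo(rs))
  expect_equal(unname(geo$country_counts["Canada"]), 2L)  # A3 excluded
  expect_equal(geo$n_no_country, 1)                        # A4
  expect_equal(nrow(geo$points), 1)
  expect_equal(geo$n_bad_latlon, 1)                        # A4 demoted
  # conservation: countries + no-country = fully identified records
  expect_equal(sum(geo$country_counts) + geo$n_no_country, geo$n_records_used)
})

test_that("empty input yields an empty summary", {
  geo <- summarize_geo(record_set())
  expect_equal(length(geo$country_counts), 0)
  expect_equal(geo$n_no_country, 0)
  expect_equal(nrow(geo$points), 0)
  expect_equal(length(geo$top_countries), 0)
})

test_that("the top-5% split takes ceil(0.05 K) countries, deterministically", {
  rs <- make_records(sprintf("R%02d", 1:21),
                     organism_name = "Homo sapiens",
                     country_raw = c(rep("Canada", 2), sprintf("Land%02d", 1:19)))
  geo <- summarize_geo(rs)
  expect_equal(length(geo$country_counts), 20)
  expect_equal(geo$top_countries, "Canada")  # ceil(0.05 * 20) = 1, top count
  expect_equal(length(geo$bottom_countries), 19)
  # ties broken by descending count then lexicographic name
  expect_equal(geo$bottom_countries, sort(sprintf("Land%02d", 1:19)))
  # split is a partition of the distinct countries
  expect_setequal(c(geo$top_countries, geo$bottom_countries),
                  names(geo$country_counts))
})

test_that("geo tallies recover the generator's country distribution", {
  dat <- generate_synthetic(tiny_config(seed = 63))
  geo <- summarize_geo(dat$records)
  truth <- dat$truth$country_counts
  expect_equal(sum(geo$country_counts), sum(truth))
  for (cn in names(truth)) {
    expect_equal(unname(geo$country_counts[cn]), unname(truth[[cn]]), info = cn)
  }
  expect_equal(sum(geo$country_counts) + geo$n_no_country, geo$n_records_used)
})

test_that("geo summary tables are written as plain text", {
  dat <- generate_synthetic(tiny_config(seed = 65))
  dir <- withr::local_tempdir()
  write_geo_summary(summarize_geo(dat$records), dir)
  cc <- utils::read.delim(file.path(dir, "country_counts.tsv"))
  expect_true(all(c("country", "count") %in% names(cc)))
  split <- utils::read.delim(file.path(dir, "country_split.tsv"))
  expect_setequal(unique(split$split), c("top", "bottom"))
})
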