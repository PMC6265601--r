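# File dialect round-trips and parse-error surfacing.

users_header <- "user_id|gender|age|conditions|condition_categories|medications"
records_header <- paste("user_id|timestamp|severity|locations|symptoms",
                        "characteristics|environments|aggravating_factors",
                        "alleviating_factors|ineffective_factors",
                        "medications_used|pain_type|pain_duration", sep = "|")

write_users_file <- function(rows) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(c("#painvol users v1 delim=| inner=;", users_header, rows), path)
  path
}

write_records_file <- function(rows) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(c("#painvol records v1 delim=| inner=;", records_header, rows), path)
  path
}

test_that("write/read round-trip is the identity on synthetic users and records", {
  coh <- generate_cohort(generator_config(50, seed = 3))
  up <- withr::local_tempfile(fileext = ".txt")
  rp <- withr::local_tempfile(fileext = ".txt")
  write_users(coh$users, up)
  write_records(coh$records, rp)
  expect_equal(read_users(up), coh$users)
  # records are returned sorted; the generator output is already sorted, so
  # multiset equality collapses to identity
  expect_equal(read_records(rp), coh$records, ignore_attr = "row.names")
})

test_that("reader output ordering is deterministic regardless of input row order", {
  coh <- generate_cohort(generator_config(10, seed = 5))
  shuffled <- coh$records[withr::with_seed(1, sample(nrow(coh$records))), ]
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_records(coh$records, p1)
  write_records(shuffled, p2)
  expect_equal(read_records(p1), read_records(p2), ignore_attr = "row.names")
})

test_that("missing gender and age map to explicit unknown states", {
  path <- write_users_file(c("u1||abc|||", "u2|female|44|migraine||gabapentin:anticonvulsants"))
  users <- read_users(path)
  expect_equal(users$gender, c("unknown", "female"))
  expect_equal(users$age, c(NA_integer_, 44L))
  expect_equal(users$conditions[[2]], "migraine")
  expect_equal(users$medications[[2]], c(gabapentin = "anticonvulsants"))
})

test_that("header-only files give empty results; malformed input errors name the line", {
  expect_equal(nrow(read_users(write_users_file(character(0)))), 0)
  expect_equal(nrow(read_records(write_records_file(character(0)))), 0)
  expect_error(read_users(write_users_file("u1|female")), "line 3")
  expect_error(read_users(write_users_file(c("u1|||||", "u1|||||"))),
               "duplicate user_id")
})

test_that("records reader validates severity range and vocabulary membership", {
  good <- "u1|2020-01-01T00:00:00|7|head;neck|||||||||"
  recs <- read_records(write_records_file(good))
  expect_equal(recs$severity, 7L)
  expect_length(recs$locations[[1]], 2)
  bad_sev <- paste0("u1|2020-01-01T00:00:00|11", strrep("|", 10))
  expect_error(read_records(write_records_file(bad_sev)), "\\[0,10\\]")
  bad_tok <- "u1|2020-01-01T00:00:00|3|kneecap|||||||||"
  expect_error(read_records(write_records_file(bad_tok)), "kneecap")
  no_header <- withr::local_tempfile()
  writeLines(c(records_header, good), no_header)
  expect_error(read_records(no_header), "dialect header")
})

test_that("feature matrix CSV round-trips at full precision", {
  feats <- demo_features()[1:5, ]
  labels <- c("low", "high", "low", "low", "high")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(feats, labels, path)
  back <- read_feature_matrix(path)
  expect_identical(back$labels, labels)
  expect_equal(back$features, feats, ignore_attr = "row.names")
  # full-precision check on the continuous block
  expect_identical(back$features$predictor_volatility, feats$predictor_volatility)
  expect_identical(back$features$trend_change, feats$trend_change)
  # header row: user_id + 130 features + label
  expect_length(strsplit(readLines(path, n = 1), ",")[[1]], 132)
})

test_that("feature matrix writer rejects schema mismatches", {
  feats <- demo_features()[1:3, ]
  expect_error(write_feature_matrix(feats[, -5], c("low", "low", "high"), tempfile()),
               "schema")
  expect_error(write_feature_matrix(feats, c("low", "low"), tempfile()), "labels")
  # empty input still writes a header-only file
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(feats[0, ], character(0), path)
  expect_length(readLines(path), 1)
})
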