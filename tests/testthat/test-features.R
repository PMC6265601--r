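# The canonical 130-feature schema and its extraction rules.

test_that("the schema has 130 uniquely named features in the documented blocks", {
  schema <- feature_schema()
  expect_equal(nrow(schema), 130)
  expect_false(anyDuplicated(schema$name) > 0)
  expect_equal(sum(schema$block == "descriptors"), 64)
  expect_equal(sum(schema$block == "factors"), 43)
  expect_equal(sum(schema$block == "medications"), 5)
  expect_equal(sum(schema$type == "categorical"), 4)
})

test_that("extraction is a pure function yielding the canonical columns", {
  coh <- demo_cohort()
  pl <- demo_pipeline()
  fm <- demo_features()
  expect_equal(names(fm), c("user_id", feature_schema()$name))
  expect_equal(nrow(fm), length(pl$eligible))
  # purity: re-extracting one user reproduces their row exactly
  uid <- fm$user_id[7]
  wrow <- pl$windows[pl$windows$user_id == uid & pl$windows$role == "predictor", ]
  again <- extract_features(coh$users[coh$users$user_id == uid, ],
                            wrow$records[[1]], pl$cls$threshold)
  expect_identical(again, fm[7, ])
  # bounds
  expect_true(all(fm$severity_mean >= 0 & fm$severity_mean <= 10))
  expect_true(all(fm$n_active_days <= fm$n_records))
  expect_true(all(fm$n_active_days <= 30))
})

test_that("an all-missing profile maps to unknown categories and zero flags", {
  profile <- make_profile("u9", gender = "unknown", age = NA)
  recs <- make_records("u9", 0:4, c(3, 4, 4, 3, 5))
  fv <- extract_features(profile, recs, threshold = 1.6)
  expect_equal(as.character(fv$gender), "unknown")
  expect_equal(as.character(fv$age_cat), "unknown")
  expect_equal(as.character(fv$n_conditions_cat), "unknown")
  schema <- feature_schema()
  flag_cols <- schema$name[schema$block %in%
                             c("conditions", "descriptors", "factors", "medications") &
                             schema$type == "binary"]
  expect_length(flag_cols, 117)
  expect_true(all(as.numeric(fv[, flag_cols]) == 0))
  expect_equal(fv$neuropathic_flag, 0L)
  expect_equal(fv$mental_health_flag, 0L)
  # severities (3,4,4,3,5): mean 3.8 -> mild
  expect_equal(fv$severity_mean, 3.8)
  expect_equal(as.character(fv$severity_group), "mild")
})

test_that("age bins follow the (>a and <=b) pattern with unknown and >70", {
  expect_equal(as.character(categorize_age(20L)), "(0,20]")
  expect_equal(as.character(categorize_age(21L)), "(20,30]")
  expect_equal(as.character(categorize_age(70L)), "(60,70]")
  expect_equal(as.character(categorize_age(71L)), ">70")
  expect_equal(as.character(categorize_age(NA_integer_)), "unknown")
  expect_error(categorize_age(0L), "positive")
})

test_that("severity grouping boundaries are exact", {
  expect_equal(as.character(categorize_severity(c(3.99, 4, 7, 7.01))),
               c("mild", "moderate", "moderate", "severe"))
})

test_that("trend change equals the closed-form OLS oracle", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  # perfect line 0 -> 10 over the window
  ts <- t0 + seq(0, 29, length.out = 11) * 86400
  expect_equal(compute_trend_change(ts, seq(0, 10, length.out = 11)), 10)
  expect_equal(compute_trend_change(ts, rep(4, 11)), 0)
  # all records at the same instant: defined as 0
  expect_equal(compute_trend_change(rep(t0, 3), c(1, 5, 9)), 0)
  # random points vs normal equations
  withr::with_seed(31, {
    x_days <- sort(runif(12, 0, 30))
    y <- runif(12, 0, 10)
  })
  ts <- t0 + x_days * 86400
  X <- cbind(1, x_days)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(compute_trend_change(ts, y), beta[2] * (max(x_days) - min(x_days)))
})

test_that("neuropathic flag needs two qualifying items in a single record", {
  one <- make_record("u1", 0, 5, characteristics = c("burning", "numbness"))
  expect_equal(flag_neuropathic(one), 1L)
  split2 <- dplyr::bind_rows(
    make_record("u1", 0, 5, characteristics = "burning"),
    make_record("u1", 1, 5, characteristics = "numbness"))
  expect_equal(flag_neuropathic(split2), 0L)
  mixed <- make_record("u1", 0, 5, characteristics = "burning",
                       aggravating = "light touch or clothing")
  expect_equal(flag_neuropathic(mixed), 1L)
  # non-qualifying characteristics never trigger it
  other <- make_record("u1", 0, 5, characteristics = c("aching", "dull", "sharp"))
  expect_equal(flag_neuropathic(other), 0L)
})

test_that("mental-health flag fires on any single qualifying item", {
  expect_equal(flag_mental_health(make_record("u1", 0, 5, symptoms = "anxiety")), 1L)
  expect_equal(flag_mental_health(make_record("u1", 0, 5, aggravating = "stress")), 1L)
  expect_equal(flag_mental_health(make_record("u1", 0, 5, symptoms = "fever")), 0L)
})

test_that("count_flags marks presence over the whole window in vocabulary order", {
  vocab <- load_vocabularies()
  recs <- dplyr::bind_rows(
    make_record("u1", 0, 5, locations = "head"),
    make_record("u1", 1, 5, locations = c("back", "knee")))
  flags <- count_flags(recs, vocab$locations, "locations")
  expect_length(flags, 24)
  expect_equal(sum(flags), 3)
  expect_equal(flags[match(c("head", "back", "knee"), vocab$locations)], c(1L, 1L, 1L))
  empty <- count_flags(recs[0, ], vocab$aggravating, "aggravating_factors")
  expect_equal(empty, rep(0L, 15))
})

test_that("medication flags are record-attached, not merely profile-listed", {
  profile <- make_profile("u1", medications = c(gabapentin = "anticonvulsants",
                                                oxycodone = "opioids"))
  no_use <- make_records("u1", 0:4, rep(5, 5))
  fv <- extract_features(profile, no_use, threshold = 1.6)
  expect_equal(fv$med_anticonvulsants + fv$med_opioids, 0L)
  used <- dplyr::bind_rows(
    make_records("u1", 0:3, rep(5, 4)),
    make_record("u1", 4, 5, medications_used = c(gabapentin = "effective")))
  fv2 <- extract_features(profile, used, threshold = 1.6)
  expect_equal(fv2$med_anticonvulsants, 1L)
  expect_equal(fv2$med_opioids, 0L)
})

test_that("an empty predictor window is an upstream eligibility violation", {
  profile <- make_profile("u1")
  expect_error(extract_features(profile, make_records("u1", 0, 5)[0, ], 1.6),
               "eligibility")
})
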