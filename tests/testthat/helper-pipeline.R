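# Shared fixtures, built in code. Cohorts are memoised per test run so the
# heavier end-to-end checks can share one generation pass.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- fn()
  .test_cache[[key]]
}

demo_cohort <- function() {
  cached("demo", function() generate_cohort(generator_config(200, seed = 11)))
}

big_cohort <- function() {
  cached("big", function() generate_cohort(generator_config(2000, seed = 13)))
}

# predictor/outcome volatility scores, threshold and labels for a cohort
pipeline_from_cohort <- function(coh, seed = 1L, min_records = 5L) {
  windows <- build_windows(coh$records)
  eligible <- filter_eligible(coh$users, windows, min_records)
  wv <- window_volatility(windows)
  wv <- wv[wv$user_id %in% eligible, ]
  predictor_scores <- stats::setNames(
    wv$volatility[wv$role == "predictor"], wv$user_id[wv$role == "predictor"])
  outcome_scores <- stats::setNames(
    wv$volatility[wv$role == "outcome"], wv$user_id[wv$role == "outcome"])
  cls <- derive_threshold(predictor_scores, outcome_scores, seed = seed)
  list(windows = windows, eligible = eligible, scores = wv,
       predictor_scores = predictor_scores, outcome_scores = outcome_scores,
       cls = cls)
}

demo_pipeline <- function() {
  cached("demo_pipeline", function() pipeline_from_cohort(demo_cohort()))
}

demo_features <- function() {
  cached("demo_features", function() {
    coh <- demo_cohort()
    pl <- demo_pipeline()
    extract_feature_matrix(coh$users, pl$windows, pl$cls$threshold,
                           eligible = pl$eligible)
  })
}

# minimal hand-built record rows for boundary tests
make_record <- function(user_id, day, severity, t0 = as.POSIXct("2020-01-01", tz = "UTC"),
                        locations = character(0), symptoms = character(0),
                        characteristics = character(0), environments = character(0),
                        aggravating = character(0), alleviating = character(0),
                        ineffective = character(0),
                        medications_used = stats::setNames(character(0), character(0))) {
  tibble::tibble(
    user_id = user_id, timestamp = t0 + day * 86400, severity = as.integer(severity),
    locations = list(locations), symptoms = list(symptoms),
    characteristics = list(characteristics), environments = list(environments),
    aggravating_factors = list(aggravating), alleviating_factors = list(alleviating),
    ineffective_factors = list(ineffective), medications_used = list(medications_used),
    pain_type = NA_character_, pain_duration = NA_character_
  )
}

make_records <- function(user_id, days, severities, ...) {
  dplyr::bind_rows(Map(function(d, s) make_record(user_id, d, s, ...),
                       days, severities))
}

make_profile <- function(user_id, gender = "female", age = 40L,
                         conditions = character(0),
                         condition_categories = character(0),
                         medications = stats::setNames(character(0), character(0))) {
  tibble::tibble(user_id = user_id, gender = gender, age = as.integer(age),
                 conditions = list(conditions),
                 condition_categories = list(condition_categories),
                 medications = list(medications))
}

# exhaustive sorted-split optimum for 1-D 2-means (independent oracle)
best_split_sse <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- Inf
  for (cut in 1:(n - 1)) {
    lo <- v[1:cut]; hi <- v[(cut + 1):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best) best <- sse
  }
  best
}
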