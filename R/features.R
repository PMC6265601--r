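# The canonical 130-feature predictor vector, extracted per eligible user
# from the profile plus the predictor-window records. The count decomposes as
# gender 1 + age 1 + number-of-conditions 1 + condition-category flags 5 +
# record counts 2 + severity statistics 3 + trend 1 + volatility 2 +
# descriptor flags 64 + factor flags 43 + medication-category flags 5 +
# neuropathic 1 + mental health 1 = 130. Categorical fields count as one
# feature each in the canonical schema; one-hot expansion happens at model
# fit time.

AGE_LEVELS <- c("unknown", "(0,20]", "(20,30]", "(30,40]", "(40,50]",
                "(50,60]", "(60,70]", ">70")
NCOND_LEVELS <- c("unknown", "1", "2", "3", ">3")
SEVERITY_LEVELS <- c("mild", "moderate", "severe")
GENDER_LEVELS <- c("male", "female", "other", "unknown")

#' The canonical feature schema
#'
#' @param vocab Vocabularies from [load_vocabularies()]; token order fixes
#'   the flag-column order.
#' @return Tibble with `name`, `block`, `type` (`categorical`, `binary`,
#'   `integer`, `numeric`) and `levels` (list-column; `NULL` for
#'   non-categorical features). Always 130 rows.
#' @export
feature_schema <- function(vocab = load_vocabularies()) {
  prefix <- c(locations = "loc", symptoms = "sym", characteristics = "chr",
              environments = "env", aggravating = "agg", alleviating = "alv",
              ineffective = "ine")
  flag_block <- function(v, block) {
    tibble::tibble(name = paste0(prefix[[v]], "_", sanitize_token(vocab[[v]])),
                   block = block, type = "binary", levels = list(NULL))
  }
  cat_row <- function(name, block, levels) {
    tibble::tibble(name = name, block = block, type = "categorical",
                   levels = list(levels))
  }
  num_row <- function(name, block, type = "numeric") {
    tibble::tibble(name = name, block = block, type = type, levels = list(NULL))
  }
  schema <- dplyr::bind_rows(
    cat_row("gender", "demographics", GENDER_LEVELS),
    cat_row("age_cat", "demographics", AGE_LEVELS),
    cat_row("n_conditions_cat", "conditions", NCOND_LEVELS),
    tibble::tibble(name = paste0("cond_", sanitize_token(CONDITION_CATEGORIES)),
                   block = "conditions", type = "binary", levels = list(NULL)),
    num_row("n_records", "usage", "integer"),
    num_row("n_active_days", "usage", "integer"),
    num_row("severity_mean", "severity"),
    num_row("severity_sd", "severity"),
    cat_row("severity_group", "severity", SEVERITY_LEVELS),
    num_row("trend_change", "trend"),
    num_row("predictor_volatility", "volatility"),
    num_row("predictor_volatility_level", "volatility", "binary"),
    dplyr::bind_rows(lapply(DESCRIPTOR_VOCABS, flag_block, block = "descriptors")),
    dplyr::bind_rows(lapply(FACTOR_VOCABS, flag_block, block = "factors")),
    tibble::tibble(name = paste0("med_", MEDICATION_CATEGORIES),
                   block = "medications", type = "binary", levels = list(NULL)),
    num_row("neuropathic_flag", "clinical", "binary"),
    num_row("mental_health_flag", "clinical", "binary")
  )
  stopifnot(nrow(schema) == 130L, !anyDuplicated(schema$name))
  schema
}

#' Bin an age into the 8 canonical categories
#'
#' Bins follow the lower-exclusive/upper-inclusive pattern (>a and <=b), with
#' `unknown` (NA) as its own category and >70 as the open top bin.
#'
#' @param age Integer years, or NA for unknown. Vectorized.
#' @return Factor with the 8 age levels.
#' @export
categorize_age <- function(age) {
  if (any(!is.na(age) & age <= 0)) stop("known age must be positive")
  cut_bin <- cut(age, breaks = c(0, 20, 30, 40, 50, 60, 70, Inf),
                 labels = AGE_LEVELS[-1], right = TRUE)
  out <- as.character(cut_bin)
  out[is.na(age)] <- "unknown"
  factor(out, levels = AGE_LEVELS)
}

#' Group a mean severity rating into mild/moderate/severe
#'
#' mild: mean < 4; moderate: 4 <= mean <= 7; severe: mean > 7.
#'
#' @param mean_rating Mean pain rating(s) in \[0, 10\]. Vectorized.
#' @return Factor with levels mild/moderate/severe.
#' @export
categorize_severity <- function(mean_rating) {
  stopifnot(all(mean_rating >= 0 & mean_rating <= 10))
  factor(ifelse(mean_rating < 4, "mild",
                ifelse(mean_rating <= 7, "moderate", "severe")),
         levels = SEVERITY_LEVELS)
}

#' Change in the fitted pain trend over a window
#'
#' Fits an ordinary least squares line of severity on elapsed days since the
#' first window record and returns the difference between the fitted values
#' at the last and first record times (slope times elapsed span). Elapsed
#' time, not record index, is the regressor, so irregular sampling does not
#' distort the slope. Returns 0 when all timestamps coincide.
#'
#' @param timestamps POSIXct vector (ascending).
#' @param severities Numeric vector, same length.
#' @return Scalar trend change in rating units.
#' @export
compute_trend_change <- function(timestamps, severities) {
  stopifnot(length(timestamps) == length(severities), length(severities) >= 2)
  x <- as.numeric(difftime(timestamps, timestamps[1], units = "days"))
  if (stats::var(x) == 0) return(0)
  slope <- stats::cov(x, severities) / stats::var(x)
  slope * (max(x) - min(x))
}

#' Presence flags for a token vocabulary over a window
#'
#' @param window_records Records tibble restricted to one window.
#' @param tokens Character vector of vocabulary tokens (canonical order).
#' @param field Name of the set-valued record column to scan.
#' @return Integer 0/1 vector, one per token: 1 iff the token appears in any
#'   record of the window.
#' @export
count_flags <- function(window_records, tokens, field) {
  seen <- unique(unlist(window_records[[field]], use.names = FALSE))
  as.integer(tokens %in% seen)
}

#' Neuropathic pain indicator
#'
#' 1 iff at least one single record carries two or more of the five
#' qualifying items: the characteristics "pins and needles or tingling",
#' "burning", "numbness", "electric shocks", and the aggravating factor
#' "light touch or clothing". Items are counted within one record, never
#' pooled across records.
#'
#' @param window_records Records tibble restricted to one window.
#' @return Integer 0/1.
#' @export
flag_neuropathic <- function(window_records) {
  if (nrow(window_records) == 0) return(0L)
  counts <- vapply(seq_len(nrow(window_records)), function(i) {
    sum(NEUROPATHIC_CHARACTERISTICS %in% window_records$characteristics[[i]]) +
      as.integer(NEUROPATHIC_AGGRAVATING %in% window_records$aggravating_factors[[i]])
  }, integer(1))
  as.integer(any(counts >= 2L))
}

#' Mental-health issue indicator
#'
#' 1 iff any record in the window reports the associated symptom "anxiety" or
#' "depression", or the aggravating factor "negative mood" or "stress".
#'
#' @param window_records Records tibble restricted to one window.
#' @return Integer 0/1.
#' @export
flag_mental_health <- function(window_records) {
  if (nrow(window_records) == 0) return(0L)
  hit <- vapply(seq_len(nrow(window_records)), function(i) {
    any(MENTAL_HEALTH_SYMPTOMS %in% window_records$symptoms[[i]]) ||
      any(MENTAL_HEALTH_AGGRAVATING %in% window_records$aggravating_factors[[i]])
  }, logical(1))
  as.integer(any(hit))
}

#' Extract the 130-feature vector for one user
#'
#' A pure function of the user profile, the predictor-window records and the
#' global volatility threshold. Missing profile information maps to its
#' explicit unknown category (never an error); an empty window is an error
#' because eligibility should have been enforced upstream.
#'
#' @param profile One-row users tibble for the user.
#' @param window_records Records tibble for the user's predictor window,
#'   sorted by timestamp.
#' @param threshold Global volatility threshold from [derive_threshold()].
#' @param vocab Vocabularies from [load_vocabularies()].
#' @param schema Optional precomputed [feature_schema()] (for batch callers).
#' @return One-row tibble: `user_id` plus the 130 canonical features.
#' @export
extract_features <- function(profile, window_records, threshold,
                             vocab = load_vocabularies(),
                             schema = feature_schema(vocab)) {
  if (nrow(window_records) == 0) {
    stop("empty predictor window for user ", profile$user_id,
         " (eligibility violated upstream)")
  }
  sev <- window_records$severity
  n_cond <- length(profile$conditions[[1]])
  cond_cats <- profile$condition_categories[[1]]
  vol <- compute_volatility(sev)

  # medication-category flags: a category fires when a medication of that
  # category appears attached to any record in the window
  med_tags <- profile$medications[[1]]
  used <- unique(unlist(lapply(window_records$medications_used, names),
                        use.names = FALSE))
  used_cats <- unlist(strsplit(med_tags[names(med_tags) %in% used], ",",
                               fixed = TRUE), use.names = FALSE)

  set_fields <- record_set_fields()
  flags <- unlist(lapply(c(DESCRIPTOR_VOCABS, FACTOR_VOCABS), function(v) {
    count_flags(window_records, vocab[[v]], set_fields[[v]])
  }), use.names = FALSE)

  out <- c(
    list(
      user_id = profile$user_id,
      gender = factor(profile$gender, levels = GENDER_LEVELS),
      age_cat = categorize_age(profile$age),
      n_conditions_cat = factor(
        if (n_cond == 0) "unknown" else if (n_cond > 3) ">3" else as.character(n_cond),
        levels = NCOND_LEVELS),
      cond_fibromyalgia = as.integer("fibromyalgia" %in% cond_cats),
      cond_headaches = as.integer("headaches" %in% cond_cats),
      cond_back_pain = as.integer("back pain" %in% cond_cats),
      cond_arthritis = as.integer("arthritis" %in% cond_cats),
      cond_depression_anxiety = as.integer("depression-anxiety" %in% cond_cats),
      n_records = nrow(window_records),
      n_active_days = length(unique(as.Date(window_records$timestamp, tz = "UTC"))),
      severity_mean = mean(sev),
      severity_sd = stats::sd(sev),
      severity_group = categorize_severity(mean(sev)),
      trend_change = compute_trend_change(window_records$timestamp, sev),
      predictor_volatility = vol,
      predictor_volatility_level = as.integer(vol > threshold)
    ),
    stats::setNames(as.list(flags),
                    schema$name[schema$block %in% c("descriptors", "factors")]),
    stats::setNames(as.list(as.integer(MEDICATION_CATEGORIES %in% used_cats)),
                    paste0("med_", MEDICATION_CATEGORIES)),
    list(
      neuropathic_flag = flag_neuropathic(window_records),
      mental_health_flag = flag_mental_health(window_records)
    )
  )
  tibble::as_tibble(out)[, c("user_id", schema$name)]
}

#' Extract the feature matrix for a set of eligible users
#'
#' @param users Users tibble.
#' @param windows Window tibble from [build_windows()].
#' @param threshold Global volatility threshold.
#' @param eligible Character vector of user ids to extract (default: all
#'   users with a non-empty predictor window).
#' @param vocab Vocabularies.
#' @return Tibble: `user_id` plus 130 features, one row per user, sorted by
#'   user id.
#' @export
extract_feature_matrix <- function(users, windows, threshold, eligible = NULL,
                                   vocab = load_vocabularies()) {
  schema <- feature_schema(vocab)
  pred <- windows[windows$role == "predictor", , drop = FALSE]
  if (is.null(eligible)) eligible <- pred$user_id[pred$n_records > 0]
  eligible <- sort(eligible)
  rows <- lapply(eligible, function(uid) {
    extract_features(users[users$user_id == uid, , drop = FALSE],
                     pred$records[[match(uid, pred$user_id)]],
                     threshold, vocab, schema)
  })
  dplyr::bind_rows(rows)
}
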