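# Synthetic pain-app cohorts with a known latent volatility structure.
#
# Each user carries a latent volatility regime (low/high) in month 1 and in
# month 6; month 6 equals month 1 with probability `regime_persistence`.
# Severity paths are discretized mean-reverting AR(1) walks whose innovation
# scale is calibrated per regime so the realized mean absolute successive
# difference concentrates near the configured target (0.8 low / 3.0 high by
# default). A plantable signal links five designated descriptor tokens in
# month 1 to the month-6 regime. Missingness rates (gender, age, descriptor
# and factor reporting) default to the rates observed in the app population
# the generator emulates.

.painvol_cache <- new.env(parent = emptyenv())

#' Generator configuration
#'
#' @param n_users Number of users (>= 1).
#' @param seed Integer seed; identical (config, seed) gives identical output.
#' @param p_high_outcome Probability a user's month-6 latent regime is high.
#'   Default 171/782, the high-volatility prevalence the generator emulates.
#' @param regime_persistence Probability the month-6 regime equals the
#'   month-1 regime. Month-1 volatility is itself a predictor feature, so
#'   this is the dominant channel of predictability; the default 0.75 yields
#'   roughly the ~70 percent balanced predictability seen in comparable app
#'   cohorts.
#' @param low_state_mean_abs_step,high_state_mean_abs_step Target mean
#'   absolute successive rating change per regime (rating units).
#' @param records_per_month List with `mean` (Poisson mean records per
#'   user-month), `min` and `enforce_min` (floor the counts at `min`).
#' @param p_gender_unknown,p_age_unknown Probability gender/age is missing
#'   (defaults 0.25 / 0.31).
#' @param p_gender_other Probability of gender `other` (default 0; set
#'   positive to exercise the eligibility exclusion).
#' @param p_no_descriptors Probability a user reports no descriptors at all
#'   (default 0.02).
#' @param p_no_factors Probability a user reports no pain factors (default
#'   0.08).
#' @param signal_strength Difference in month-1 presence probability of each
#'   of the five designated descriptor tokens between month-6-high and
#'   month-6-low users (0 = no planted descriptor signal).
#' @param ar_phi AR(1) coefficient of the latent severity walk.
#' @param start_date First possible calendar date of a user's first record.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_users,
                             seed = 1L,
                             p_high_outcome = 171 / 782,
                             regime_persistence = 0.75,
                             low_state_mean_abs_step = 0.8,
                             high_state_mean_abs_step = 3.0,
                             records_per_month = list(mean = 12, min = 5,
                                                      enforce_min = TRUE),
                             p_gender_unknown = 0.25,
                             p_age_unknown = 0.31,
                             p_gender_other = 0,
                             p_no_descriptors = 0.02,
                             p_no_factors = 0.08,
                             signal_strength = 0.25,
                             ar_phi = 0.3,
                             start_date = "2016-01-01") {
  if (n_users < 1) stop("n_users must be at least 1")
  probs <- c(p_high_outcome, regime_persistence, p_gender_unknown,
             p_age_unknown, p_gender_other, p_no_descriptors, p_no_factors,
             signal_strength)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (low_state_mean_abs_step >= high_state_mean_abs_step) {
    stop("low_state_mean_abs_step must be below high_state_mean_abs_step")
  }
  structure(list(
    n_users = as.integer(n_users), seed = as.integer(seed),
    p_high_outcome = p_high_outcome, regime_persistence = regime_persistence,
    low_state_mean_abs_step = low_state_mean_abs_step,
    high_state_mean_abs_step = high_state_mean_abs_step,
    records_per_month = records_per_month,
    p_gender_unknown = p_gender_unknown, p_age_unknown = p_age_unknown,
    p_gender_other = p_gender_other, p_no_descriptors = p_no_descriptors,
    p_no_factors = p_no_factors, signal_strength = signal_strength,
    ar_phi = ar_phi, start_date = start_date
  ), class = "generator_config")
}

#' Calibrate the innovation scale for a target mean absolute step
#'
#' Finds the AR(1) innovation scale such that an integer-clipped path on the
#' 0-10 scale realizes a mean absolute successive difference near `target`.
#' The mapping is evaluated on a fixed 1e5-step simulated path (common random
#' numbers, so the calibration is deterministic and monotone in the scale)
#' and inverted by root finding. `target = 0` returns scale 0 (constant
#' path); `target = 10` returns `Inf`, which the path generator interprets
#' as the only attainable pattern, alternation between the scale extremes.
#'
#' @param target Target mean absolute successive difference, in \[0, 10\].
#' @param phi AR(1) coefficient (default 0.3; higher persistence lowers the
#'   attainable ceiling).
#' @param mu Latent mean severity used for calibration (default 5, scale
#'   midpoint).
#' @param n_steps Simulation length for the calibration path.
#' @return Innovation scale (standard deviation of the AR(1) innovations).
#' @export
calibrate_step_scale <- function(target, phi = 0.3, mu = 5, n_steps = 1e5) {
  if (target < 0) stop("target must be non-negative")
  if (target > 10) stop("targets above 10 are unattainable on a 0-10 scale")
  if (target == 0) return(0)
  if (target == 10) return(Inf)
  key <- sprintf("%.12g|%.12g|%.12g|%d", target, phi, mu, as.integer(n_steps))
  cached <- .painvol_cache[[key]]
  if (!is.null(cached)) return(cached)
  eps <- withr::with_seed(104729L, stats::rnorm(n_steps))
  w <- as.numeric(stats::filter(eps, phi, method = "recursive"))
  realized <- function(scale) {
    r <- pmin(10, pmax(0, round(mu + scale * w)))
    mean(abs(diff(r)))
  }
  upper <- 1
  while (realized(upper) < target && upper < 1e4) upper <- upper * 2
  if (realized(upper) < target) {
    stop("target mean absolute step is unattainable under the AR(1) severity model")
  }
  scale <- stats::uniroot(function(s) realized(s) - target,
                          lower = 1e-8, upper = upper, tol = 1e-4)$root
  .painvol_cache[[key]] <- scale
  scale
}

# One user-month severity path: stationary-start AR(1) around mu, clipped and
# rounded; Inf scale = alternating extremes.
simulate_month_severity <- function(n, mu, phi, scale) {
  if (!is.finite(scale)) {
    start <- stats::rbinom(1, 1, 0.5)
    return(as.integer(rep_len(c(0L, 10L), n + start)[(1 + start):(n + start)]))
  }
  if (scale == 0) return(rep(as.integer(pmin(10, pmax(0, round(mu)))), n))
  dev <- numeric(n)
  dev[1] <- stats::rnorm(1, sd = scale / sqrt(1 - phi^2))
  if (n > 1) {
    eps <- stats::rnorm(n - 1, sd = scale)
    for (t in 2:n) dev[t] <- phi * dev[t - 1] + eps[t - 1]
  }
  as.integer(pmin(10, pmax(0, round(mu + dev))))
}

# token lists from a logical presence matrix (rows = records, cols = vocab
# order); canonical order falls out of the column ordering
presence_to_sets <- function(mat, tokens) {
  out <- rep(list(character(0)), nrow(mat))
  hits <- which(mat, arr.ind = TRUE)
  if (nrow(hits) > 0) {
    ord <- order(hits[, 1], hits[, 2])
    sp <- split(tokens[hits[ord, 2]], hits[ord, 1])
    out[as.integer(names(sp))] <- sp
  }
  out
}

#' Generate a synthetic cohort
#'
#' Produces user profiles, a six-month record stream per user, and the true
#' latent regimes for months 1 and 6. Records span months 1 through 6
#' (30-day blocks anchored at the user's first record, which is placed at
#' the exact window origin).
#'
#' @param config A [generator_config()].
#' @param vocab Vocabularies from [load_vocabularies()].
#' @return List with `users`, `records`, `truth` (tibble: user_id,
#'   month1_state, month6_state as `"low"`/`"high"`) and `config`.
#' @export
generate_cohort <- function(config, vocab = load_vocabularies()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config, vocab))
}

generate_cohort_impl <- function(config, vocab) {
  n <- config$n_users
  user_id <- sprintf("u%05d", seq_len(n))
  scales <- c(low = calibrate_step_scale(config$low_state_mean_abs_step,
                                         phi = config$ar_phi),
              high = calibrate_step_scale(config$high_state_mean_abs_step,
                                          phi = config$ar_phi))

  ## latent regimes
  month6 <- stats::rbinom(n, 1, config$p_high_outcome)
  persist <- stats::rbinom(n, 1, config$regime_persistence)
  month1 <- ifelse(persist == 1, month6, 1 - month6)
  switch_month <- sample(2:6, n, replace = TRUE)  # used only when regimes differ
  month_state <- sapply(1:6, function(m) {
    ifelse(month1 == month6, month1, ifelse(m < switch_month, month1, month6))
  })  # n x 6, 0 = low, 1 = high

  ## profiles
  g <- stats::runif(n)
  gender <- ifelse(g < config$p_gender_other, "other",
                   ifelse(g < config$p_gender_other + config$p_gender_unknown,
                          "unknown", ifelse(stats::runif(n) < 0.5, "male", "female")))
  age <- ifelse(stats::runif(n) < config$p_age_unknown, NA_integer_,
                sample(18:80, n, replace = TRUE))
  cond_map <- utils::read.csv(system.file("extdata", "conditions_synthetic.csv",
                                          package = "painvol"),
                              stringsAsFactors = FALSE)
  med_map <- utils::read.csv(system.file("extdata", "medications_synthetic.csv",
                                         package = "painvol"),
                             stringsAsFactors = FALSE)
  n_cond <- sample(0:4, n, replace = TRUE, prob = c(.25, .30, .25, .12, .08))
  conditions <- lapply(n_cond, function(k) {
    if (k == 0) character(0) else sort(sample(cond_map$condition, k))
  })
  condition_categories <- lapply(conditions, function(cs) {
    cats <- cond_map$category[match(cs, cond_map$condition)]
    sort(unique(cats[nzchar(cats)]))
  })
  n_med <- sample(0:3, n, replace = TRUE, prob = c(.35, .30, .20, .15))
  medications <- lapply(n_med, function(k) {
    if (k == 0) return(stats::setNames(character(0), character(0)))
    rows <- sample(nrow(med_map), k)
    stats::setNames(med_map$category[rows], med_map$medication[rows])
  })
  users <- tibble::tibble(user_id = user_id, gender = gender, age = age,
                          conditions = conditions,
                          condition_categories = condition_categories,
                          medications = medications)

  ## record skeleton: counts, times, severities
  rpm <- config$records_per_month
  counts <- matrix(stats::rpois(n * 6, rpm$mean), nrow = n)
  if (isTRUE(rpm$enforce_min)) counts <- pmax(counts, rpm$min)
  counts <- pmax(counts, 2L)  # a month needs >= 2 ratings for V(R) to exist
  t0 <- as.POSIXct(config$start_date, tz = "UTC") +
    sample(0:364, n, replace = TRUE) * DAY_SECONDS
  n_rec <- sum(counts)
  rec_user <- integer(n_rec); rec_time <- numeric(n_rec)
  rec_sev <- integer(n_rec); rec_month <- integer(n_rec)
  pos <- 0L
  for (u in seq_len(n)) {
    mu_u <- stats::runif(1, 3, 7)
    for (m in 1:6) {
      k <- counts[u, m]
      offs <- sort(stats::runif(k, (m - 1) * 30, m * 30))
      if (m == 1) offs[1] <- 0
      sev <- simulate_month_severity(
        k, mu_u, config$ar_phi,
        scales[[if (month_state[u, m] == 1) "high" else "low"]])
      idx <- pos + seq_len(k)
      rec_user[idx] <- u
      rec_time[idx] <- as.numeric(t0[u]) + offs * DAY_SECONDS
      rec_sev[idx] <- sev
      rec_month[idx] <- m
      pos <- pos + k
    }
  }

  ## descriptor and factor sets
  expected_tokens <- c(locations = 1.5, symptoms = 1.0, characteristics = 1.2,
                       environments = 0.8, aggravating = 0.9, alleviating = 0.9,
                       ineffective = 0.7)
  no_desc <- stats::runif(n) < config$p_no_descriptors
  no_fact <- stats::runif(n) < config$p_no_factors
  pres <- lapply(names(VOCAB_SIZES), function(v) {
    size <- VOCAB_SIZES[[v]]
    m <- matrix(stats::runif(n_rec * size) < expected_tokens[[v]] / size,
                nrow = n_rec)
    suppressed <- if (v %in% DESCRIPTOR_VOCABS) no_desc else no_fact
    m[suppressed[rec_user], ] <- FALSE
    m
  })
  names(pres) <- names(VOCAB_SIZES)

  ## planted month-1 signal: five designated tokens, window-level presence
  ## probability 0.5 +/- signal_strength/2 by month-6 regime
  designated <- c("locations", "symptoms", "characteristics", "environments",
                  "aggravating")
  s <- config$signal_strength
  month1_idx <- split(which(rec_month == 1L),
                      rec_user[rec_month == 1L])
  for (v in designated) {
    suppressed <- if (v %in% DESCRIPTOR_VOCABS) no_desc else no_fact
    p_present <- 0.5 + ifelse(month6 == 1, s / 2, -s / 2)
    present <- stats::runif(n) < p_present
    for (u in which(!suppressed)) {
      m1 <- month1_idx[[as.character(u)]]
      if (present[u]) {
        if (!any(pres[[v]][m1, 1])) {
          pres[[v]][m1[sample.int(length(m1), 1)], 1] <- TRUE
        }
      } else {
        pres[[v]][m1, 1] <- FALSE
      }
    }
  }
  sets <- lapply(names(VOCAB_SIZES), function(v) {
    presence_to_sets(pres[[v]], vocab[[v]])
  })
  names(sets) <- names(VOCAB_SIZES)

  ## record-attached medications
  meds_used <- rep(list(stats::setNames(character(0), character(0))), n_rec)
  has_med <- n_med[rec_user] > 0
  attach <- which(has_med & stats::runif(n_rec) < 0.3)
  for (i in attach) {
    m <- medications[[rec_user[i]]]
    pick <- sample.int(length(m), 1)
    meds_used[[i]] <- stats::setNames(
      sample(MEDICATION_ROLES, 1, prob = c(.15, .60, .25)), names(m)[pick])
  }

  pain_type <- sample(c(NA, "chronic", "acute", "intermittent"), n_rec,
                      replace = TRUE, prob = c(.30, .40, .15, .15))
  pain_duration <- sample(c(NA, "<1 hour", "1-12 hours", ">1 day"), n_rec,
                          replace = TRUE, prob = c(.35, .25, .25, .15))

  records <- tibble::tibble(
    user_id = user_id[rec_user],
    timestamp = as.POSIXct(rec_time, origin = "1970-01-01", tz = "UTC"),
    severity = rec_sev,
    locations = sets$locations, symptoms = sets$symptoms,
    characteristics = sets$characteristics, environments = sets$environments,
    aggravating_factors = sets$aggravating,
    alleviating_factors = sets$alleviating,
    ineffective_factors = sets$ineffective,
    medications_used = meds_used,
    pain_type = pain_type, pain_duration = pain_duration
  )
  records <- sort_records(records)

  truth <- tibble::tibble(
    user_id = user_id,
    month1_state = ifelse(month1 == 1, "high", "low"),
    month6_state = ifelse(month6 == 1, "high", "low")
  )
  list(users = users, records = records, truth = truth, config = config)
}
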