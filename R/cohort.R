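# Observation windows and eligibility. Months are 30-day blocks anchored at
# each user's first record: predictor = [t0, t0+30d), outcome =
# [t0+150d, t0+180d), both half-open so a boundary record is never counted
# twice (a record at exactly day 30 falls in neither window).

DAY_SECONDS <- 86400

#' Build predictor and outcome observation windows per user
#'
#' Anchors a user's timeline at their first record timestamp t0 and assigns
#' records to the predictor window \[t0, t0+30d) or the outcome window
#' \[t0+150d, t0+180d). Records outside both windows are dropped from the
#' windows but counted in the `dropped` attribute for provenance.
#'
#' @param records A records tibble (any row order; sorted internally).
#' @return Tibble with one row per (user, role): `user_id`, `role`
#'   (`"predictor"`/`"outcome"`), `start`, `end`, `n_records`, and `records`
#'   (list-column of record tibbles sorted by timestamp). Attribute `dropped`
#'   is a named integer vector of out-of-window record counts per user.
#' @export
build_windows <- function(records) {
  if (nrow(records) == 0) stop("no records supplied")
  records <- sort_records(records)
  by_user <- split(seq_len(nrow(records)), records$user_id)
  user_ids <- names(by_user)
  n_users <- length(user_ids)
  rows <- vector("list", 2 * n_users)
  dropped <- stats::setNames(integer(n_users), user_ids)
  for (i in seq_len(n_users)) {
    idx <- by_user[[i]]
    recs <- records[idx, , drop = FALSE]
    t0 <- recs$timestamp[1]
    bounds <- list(
      predictor = c(t0, t0 + 30 * DAY_SECONDS),
      outcome = c(t0 + 150 * DAY_SECONDS, t0 + 180 * DAY_SECONDS)
    )
    in_any <- rep(FALSE, nrow(recs))
    for (j in 1:2) {
      role <- names(bounds)[j]
      b <- bounds[[j]]
      inside <- recs$timestamp >= b[1] & recs$timestamp < b[2]
      in_any <- in_any | inside
      rows[[2 * (i - 1) + j]] <- tibble::tibble(
        user_id = user_ids[i], role = role, start = b[1], end = b[2],
        n_records = sum(inside), records = list(recs[inside, , drop = FALSE])
      )
    }
    dropped[i] <- sum(!in_any)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped") <- dropped
  out
}

#' Apply the eligibility filters
#'
#' A user is eligible when they have at least `min_records` records in both
#' the predictor and the outcome window and their reported gender is not
#' `other` (excluded downstream for small sample size). Two records is the
#' mathematical minimum for a volatility score; the five-record default is
#' the reliability cut. Record counts, not distinct days, are compared
#' against the cut.
#'
#' @param users A users tibble.
#' @param windows Window tibble from [build_windows()].
#' @param min_records Minimum records per window (default 5).
#' @return Character vector of eligible user ids, sorted.
#' @export
filter_eligible <- function(users, windows, min_records = 5L) {
  counts <- dplyr::summarise(
    dplyr::group_by(windows, .data$user_id),
    ok = sum(.data$role == "predictor" & .data$n_records >= min_records) > 0 &&
      sum(.data$role == "outcome" & .data$n_records >= min_records) > 0,
    .groups = "drop"
  )
  enough <- counts$user_id[counts$ok]
  not_other <- users$user_id[users$gender != "other"]
  sort(intersect(enough, not_other))
}

#' Per-user window summary
#'
#' @inheritParams filter_eligible
#' @return Tibble with user_id, n_predictor_records, n_outcome_records and an
#'   `eligible` flag, one row per user appearing in `windows`.
#' @export
cohort_summary <- function(users, windows, min_records = 5L) {
  wide <- tibble::tibble(
    user_id = windows$user_id[windows$role == "predictor"],
    n_predictor_records = windows$n_records[windows$role == "predictor"],
    n_outcome_records = windows$n_records[windows$role == "outcome"]
  )
  eligible <- filter_eligible(users, windows, min_records)
  wide$eligible <- wide$user_id %in% eligible
  dplyr::arrange(wide, .data$user_id)
}
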