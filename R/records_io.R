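# Readers and writers for the two delimited exports (user profiles and pain
# records) and for the feature-matrix CSV.
#
# Dialect: fields separated by "|", multi-valued fields by ";", and structured
# entries (medications) by "name:tag,tag". The first line of each file is a
# dialect declaration, e.g. "#painvol users v1 delim=| inner=;". Dates are
# timezone-naive ISO-8601 date-times, stored as UTC POSIXct in memory.
#
# In-memory representation:
#  * users: tibble with user_id, gender ("male"/"female"/"other"/"unknown"),
#    age (integer years, NA = unknown), conditions (list of character),
#    condition_categories (list of character), medications (list of named
#    character vectors: medication name -> comma-joined category tags).
#  * records: tibble with user_id, timestamp (POSIXct), severity (integer
#    0-10), seven set-valued list-columns in canonical vocabulary order,
#    medications_used (list of named character: name -> role), pain_type and
#    pain_duration (character, NA when absent). Severity is the only
#    mandatory item; every set may be empty.

USERS_HEADER <- c("user_id", "gender", "age", "conditions",
                  "condition_categories", "medications")
RECORDS_HEADER <- c("user_id", "timestamp", "severity", "locations",
                    "symptoms", "characteristics", "environments",
                    "aggravating_factors", "alleviating_factors",
                    "ineffective_factors", "medications_used",
                    "pain_type", "pain_duration")
MEDICATION_ROLES <- c("aggravating", "effective", "ineffective")

dialect_line <- function(kind) sprintf("#painvol %s v1 delim=| inner=;", kind)

# strsplit drops trailing empty fields; pad to the delimiter count.
split_fields <- function(line) {
  parts <- strsplit(line, "|", fixed = TRUE)[[1]]
  m <- gregexpr("|", line, fixed = TRUE)[[1]]
  n <- if (length(m) == 1 && m[1] == -1L) 1L else length(m) + 1L
  c(parts, rep("", n - length(parts)))
}

split_inner <- function(x) {
  if (!nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

check_dialect <- function(lines, kind, path) {
  if (length(lines) < 2 || !startsWith(lines[1], sprintf("#painvol %s v1", kind))) {
    stop(sprintf("'%s' does not start with a '#painvol %s v1' dialect header", path, kind))
  }
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_timestamp <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

assert_no_delims <- function(x, what) {
  bad <- grepl("[|;:\n]", x)
  if (any(bad)) {
    stop(sprintf("%s value contains a reserved delimiter: '%s'", what, x[bad][1]))
  }
}

## ---- users ----------------------------------------------------------------

parse_medications <- function(field, line_no) {
  entries <- split_inner(field)
  if (length(entries) == 0) return(stats::setNames(character(0), character(0)))
  name <- sub(":.*$", "", entries)
  tags <- ifelse(grepl(":", entries, fixed = TRUE), sub("^[^:]*:", "", entries), "")
  if (any(!nzchar(name))) {
    stop(sprintf("line %d: medication entry with empty name", line_no))
  }
  stats::setNames(tags, name)
}

#' Read a user-profile file
#'
#' Parses the pipe-delimited user export. Empty or unparseable gender and age
#' fields map to their explicit unknown states (`"unknown"` and `NA`), never
#' to an error; structurally malformed rows and duplicated user ids are
#' errors. Row order is preserved.
#'
#' @param path Path to a users file written by [write_users()] (or any file
#'   in the same dialect).
#' @return A users tibble (see package docs for the column contract).
#' @export
read_users <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  check_dialect(lines, "users", path)
  if (!identical(split_fields(lines[2]), USERS_HEADER)) {
    stop(sprintf("'%s': unexpected users header row", path))
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    line_no <- i + 2L
    f <- split_fields(body[i])
    if (length(f) != length(USERS_HEADER)) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   line_no, length(USERS_HEADER), length(f)))
    }
    if (!nzchar(f[1])) stop(sprintf("line %d: empty user_id", line_no))
    gender <- if (f[2] %in% c("male", "female", "other")) f[2] else "unknown"
    age <- if (grepl("^[0-9]+$", f[3])) as.integer(f[3]) else NA_integer_
    rows[[i]] <- list(
      user_id = f[1], gender = gender, age = age,
      conditions = split_inner(f[4]),
      condition_categories = split_inner(f[5]),
      medications = parse_medications(f[6], line_no)
    )
  }
  ids <- vapply(rows, `[[`, character(1), "user_id")
  if (anyDuplicated(ids)) {
    stop("duplicate user_id: ", ids[duplicated(ids)][1])
  }
  tibble::tibble(
    user_id = ids,
    gender = vapply(rows, `[[`, character(1), "gender"),
    age = vapply(rows, `[[`, integer(1), "age"),
    conditions = lapply(rows, `[[`, "conditions"),
    condition_categories = lapply(rows, `[[`, "condition_categories"),
    medications = lapply(rows, `[[`, "medications")
  )
}

#' Write a user-profile file
#'
#' @param users A users tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_users <- function(users, path) {
  meds_txt <- vapply(users$medications, function(m) {
    if (length(m) == 0) return("")
    assert_no_delims(names(m), "medication name")
    paste0(names(m), ":", unname(m), collapse = ";")
  }, character(1))
  conds <- vapply(users$conditions, function(x) {
    assert_no_delims(x, "condition")
    paste(x, collapse = ";")
  }, character(1))
  cats <- vapply(users$condition_categories, paste, character(1), collapse = ";")
  age <- ifelse(is.na(users$age), "", as.character(users$age))
  rows <- paste(users$user_id, users$gender, age, conds, cats, meds_txt, sep = "|")
  writeLines(c(dialect_line("users"), paste(USERS_HEADER, collapse = "|"), rows),
             path, useBytes = FALSE)
  invisible(path)
}

## ---- records --------------------------------------------------------------

validate_tokens <- function(tokens, vocab_tokens, vocab_name, line_no) {
  bad <- setdiff(tokens, vocab_tokens)
  if (length(bad) > 0) {
    stop(sprintf("line %d: token '%s' is not in the %s vocabulary",
                 line_no, bad[1], vocab_name))
  }
  # canonical order: vocabulary order, duplicates collapsed
  vocab_tokens[vocab_tokens %in% tokens]
}

#' Read a pain-record file
#'
#' Parses the pipe-delimited record export, validating severities against the
#' 0-10 scale and every descriptor/factor token against its vocabulary.
#' Set-valued fields are normalized to canonical vocabulary order. Records
#' are returned sorted by (user_id, timestamp); records with equal timestamps
#' keep their file order (the export does not define a finer ordering, so
#' ties are resolved by position).
#'
#' @param path Path to a records file.
#' @param vocab Vocabularies from [load_vocabularies()].
#' @return A records tibble.
#' @export
read_records <- function(path, vocab = load_vocabularies()) {
  lines <- readLines(path, encoding = "UTF-8")
  check_dialect(lines, "records", path)
  if (!identical(split_fields(lines[2]), RECORDS_HEADER)) {
    stop(sprintf("'%s': unexpected records header row", path))
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  n <- length(body)
  set_fields <- record_set_fields()
  sets <- lapply(set_fields, function(f) vector("list", n))
  user_id <- character(n); ts <- character(n); severity <- integer(n)
  meds <- vector("list", n)
  pain_type <- character(n); pain_duration <- character(n)
  for (i in seq_len(n)) {
    line_no <- i + 2L
    f <- split_fields(body[i])
    if (length(f) != length(RECORDS_HEADER)) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   line_no, length(RECORDS_HEADER), length(f)))
    }
    user_id[i] <- f[1]
    ts[i] <- f[2]
    sev <- suppressWarnings(as.integer(f[3]))
    if (is.na(sev) || f[3] != as.character(sev) || sev < 0 || sev > 10) {
      stop(sprintf("line %d: severity '%s' is not an integer in [0,10]", line_no, f[3]))
    }
    severity[i] <- sev
    for (v in names(set_fields)) {
      col <- which(RECORDS_HEADER == set_fields[[v]])
      sets[[v]][[i]] <- validate_tokens(split_inner(f[col]), vocab[[v]], v, line_no)
    }
    mu <- split_inner(f[11])
    if (length(mu) > 0) {
      nm <- sub(":.*$", "", mu)
      role <- sub("^[^:]*:", "", mu)
      if (any(!role %in% MEDICATION_ROLES)) {
        stop(sprintf("line %d: medication role '%s' is not one of %s", line_no,
                     setdiff(role, MEDICATION_ROLES)[1],
                     paste(MEDICATION_ROLES, collapse = "/")))
      }
      meds[[i]] <- stats::setNames(role, nm)
    } else {
      meds[[i]] <- stats::setNames(character(0), character(0))
    }
    pain_type[i] <- if (nzchar(f[12])) f[12] else NA_character_
    pain_duration[i] <- if (nzchar(f[13])) f[13] else NA_character_
  }
  timestamp <- parse_timestamp(ts)
  if (anyNA(timestamp) && n > 0) {
    stop(sprintf("line %d: unparseable timestamp '%s'",
                 which(is.na(timestamp))[1] + 2L, ts[which(is.na(timestamp))[1]]))
  }
  out <- tibble::tibble(
    user_id = user_id, timestamp = timestamp, severity = severity,
    locations = sets$locations, symptoms = sets$symptoms,
    characteristics = sets$characteristics, environments = sets$environments,
    aggravating_factors = sets$aggravating, alleviating_factors = sets$alleviating,
    ineffective_factors = sets$ineffective, medications_used = meds,
    pain_type = pain_type, pain_duration = pain_duration
  )
  sort_records(out)
}

#' @keywords internal
sort_records <- function(records) {
  ord <- order(records$user_id, records$timestamp, seq_len(nrow(records)),
               method = "radix")
  records[ord, , drop = FALSE]
}

#' Write a pain-record file
#'
#' @param records A records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  join <- function(col) vapply(col, paste, character(1), collapse = ";")
  meds_txt <- vapply(records$medications_used, function(m) {
    if (length(m) == 0) return("")
    paste0(names(m), ":", unname(m), collapse = ";")
  }, character(1))
  na_blank <- function(x) ifelse(is.na(x), "", x)
  rows <- paste(records$user_id, format_timestamp(records$timestamp),
                records$severity,
                join(records$locations), join(records$symptoms),
                join(records$characteristics), join(records$environments),
                join(records$aggravating_factors), join(records$alleviating_factors),
                join(records$ineffective_factors), meds_txt,
                na_blank(records$pain_type), na_blank(records$pain_duration),
                sep = "|")
  writeLines(c(dialect_line("records"), paste(RECORDS_HEADER, collapse = "|"), rows),
             path, useBytes = FALSE)
  invisible(path)
}

## ---- feature matrix -------------------------------------------------------

#' Write a feature matrix with class labels to CSV
#'
#' One row per user: `user_id`, the 130 canonical features, and a `label`
#' column. Numeric values are written with round-trippable precision.
#'
#' @param features Feature tibble from [extract_feature_matrix()].
#' @param labels Character/factor vector of class labels, aligned with
#'   `features` rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, labels, path) {
  schema <- feature_schema()
  expected <- c("user_id", schema$name)
  if (!identical(names(features), expected)) {
    stop("feature matrix does not match the canonical 130-column schema")
  }
  if (nrow(features) != length(labels)) {
    stop("labels length does not match the number of feature rows")
  }
  out <- features
  out$label <- as.character(labels)
  for (col in schema$name[schema$type == "categorical"]) {
    out[[col]] <- as.character(out[[col]])
  }
  for (col in schema$name[schema$type == "numeric"]) {
    # 17 significant digits: doubles survive the text round-trip bit-exactly
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Path to the CSV.
#' @return List with `features` (canonical tibble, categorical columns
#'   restored as factors) and `labels` (character vector).
#' @export
read_feature_matrix <- function(path) {
  schema <- feature_schema()
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           colClasses = "character",
                                           check.names = FALSE))
  expected <- c("user_id", schema$name, "label")
  if (!identical(names(raw), expected)) {
    stop("file does not match the canonical feature-matrix schema")
  }
  feats <- raw[, c("user_id", schema$name)]
  for (i in which(schema$type == "categorical")) {
    col <- schema$name[i]
    feats[[col]] <- factor(as.character(feats[[col]]), levels = schema$levels[[i]])
  }
  for (i in which(schema$type %in% c("integer", "binary"))) {
    feats[[schema$name[i]]] <- as.integer(feats[[schema$name[i]]])
  }
  for (i in which(schema$type == "numeric")) {
    feats[[schema$name[i]]] <- as.numeric(feats[[schema$name[i]]])
  }
  list(features = feats, labels = raw$label)
}
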