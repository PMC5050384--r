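#' Canonical screener-entry schema
#'
#' One row per respondent to the online eligibility screener. The fixed
#' column set is: `entry_id`, `couple_id` (optional referral token such as
#' `"2452EW"`), `submitted_at` (ISO-8601), `completion_minutes` (optional),
#' `ip`, `self_name`, `self_sex`, `self_age`, `self_birth_month`,
#' `self_email`, `self_phone`, `partner_name`, `partner_age`,
#' `partner_birth_month`, `partner_email`, `partner_phone`,
#' `rel_length_months`, `hiv_status`, `cas_with_partner`, `ipv_year`,
#' `sexual_agreement`, `mobile_plus_internet` and the 17 screener item
#' responses `q01`..`q17`.
#'
#' @return Character vector of canonical column names.
#' @export
screener_columns <- function() {
  c("entry_id", "couple_id", "submitted_at", "completion_minutes", "ip",
    "self_name", "self_sex", "self_age", "self_birth_month", "self_email",
    "self_phone", "partner_name", "partner_age", "partner_birth_month",
    "partner_email", "partner_phone", "rel_length_months", "hiv_status",
    "cas_with_partner", "ipv_year", "sexual_agreement",
    "mobile_plus_internet", item_columns())
}

item_columns <- function() sprintf("q%02d", 1:17)

# zero-row tibble with the canonical columns and types
empty_entries_df <- function() {
  chr0 <- character(); int0 <- integer(); lgl0 <- logical()
  base <- tibble::tibble(
    entry_id = chr0, couple_id = chr0,
    submitted_at = as.POSIXct(chr0, tz = "UTC"),
    completion_minutes = numeric(), ip = chr0, self_name = chr0,
    self_sex = chr0, self_age = int0, self_birth_month = int0,
    self_email = chr0, self_phone = chr0, partner_name = chr0,
    partner_age = int0, partner_birth_month = int0, partner_email = chr0,
    partner_phone = chr0, rel_length_months = int0, hiv_status = chr0,
    cas_with_partner = lgl0, ipv_year = lgl0, sexual_agreement = lgl0,
    mobile_plus_internet = lgl0)
  for (q in item_columns()) base[[q]] <- chr0
  base
}

# columns that may be absent from a CSV without a schema error
optional_columns <- function() "completion_minutes"

#' Read screener entries from CSV
#'
#' Loads a CSV export of eligibility-screener entries in the canonical
#' schema, coercing types and checking row-level invariants. Rows violating
#' an invariant (out-of-range birth month, unparseable timestamp, negative
#' ages or lengths, unknown category) are returned in a `rejects` tibble with
#' a reason, never silently dropped. A missing required column or a
#' duplicated `entry_id` is a load error.
#'
#' @param path Path to a CSV file with a header row.
#' @param tz Timezone the source system recorded naive timestamps in;
#'   timestamps are stored as UTC instants. Default `"UTC"`.
#' @return A list with `entries` (tibble of class `screener_entries`) and
#'   `rejects` (tibble with `row`, `entry_id`, `reason`).
#' @export
read_entries <- function(path, tz = "UTC") {
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_entries(raw, tz = tz)
}

#' Validate and coerce a raw entries data frame
#'
#' The workhorse behind [read_entries()]; usable directly on in-memory data.
#'
#' @param df Data frame with character (or already typed) columns in the
#'   canonical schema.
#' @inheritParams read_entries
#' @return As [read_entries()].
#' @export
validate_entries <- function(df, tz = "UTC") {
  required <- setdiff(screener_columns(), optional_columns())
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"completion_minutes" %in% names(df)) df$completion_minutes <- NA_character_
  df <- df[screener_columns()]
  n <- nrow(df)
  chr <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & trimws(x) == ""] <- NA_character_
    trimws(x)
  }
  ids <- chr(df$entry_id)

  dup <- ids[!is.na(ids)][duplicated(ids[!is.na(ids)])]
  if (length(dup)) {
    rows <- which(ids %in% dup)
    stop("load error: duplicated entry_id (",
         paste(unique(dup), collapse = ", "), ") at rows ",
         paste(rows, collapse = ", "), call. = FALSE)
  }

  reasons <- vector("list", n)
  add_reason <- function(bad, msg) {
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], msg)
  }

  add_reason(is.na(ids), "entry_id missing")

  if (inherits(df$submitted_at, "POSIXct")) {
    ts <- as.POSIXct(trunc(as.numeric(df$submitted_at)),
                     origin = "1970-01-01", tz = "UTC")
    add_reason(is.na(ts), "submitted_at missing")
  } else {
    ts <- suppressWarnings(
      readr::parse_datetime(chr(df$submitted_at),
                            locale = readr::locale(tz = tz))
    )
    attr(ts, "problems") <- NULL
    add_reason(is.na(ts) & !is.na(chr(df$submitted_at)),
               "submitted_at unparseable")
    add_reason(is.na(chr(df$submitted_at)), "submitted_at missing")
  }

  int_col <- function(x, name, lo = -Inf, hi = Inf) {
    x <- chr(x)
    v <- suppressWarnings(as.numeric(x))
    bad_type <- !is.na(x) & (is.na(v) | v != floor(v))
    add_reason(bad_type, paste(name, "not an integer"))
    v[bad_type] <- NA
    bad_range <- !is.na(v) & (v < lo | v > hi)
    add_reason(bad_range, paste(name, "out of range"))
    v[bad_range] <- NA
    as.integer(v)
  }

  num_col <- function(x, name, lo = -Inf) {
    x <- chr(x)
    v <- suppressWarnings(as.numeric(x))
    add_reason(!is.na(x) & is.na(v), paste(name, "not numeric"))
    bad <- !is.na(v) & v < lo
    add_reason(bad, paste(name, "out of range"))
    v[bad] <- NA
    v
  }

  cat_col <- function(x, name, levels) {
    x <- tolower(chr(x))
    bad <- !is.na(x) & !x %in% levels
    add_reason(bad, paste0(name, " not one of {", paste(levels, collapse = ", "), "}"))
    x[bad] <- NA
    x
  }

  lgl_col <- function(x, name) {
    x <- tolower(chr(x))
    v <- rep(NA, length(x))
    v[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
    v[x %in% c("false", "f", "no", "n", "0")] <- FALSE
    add_reason(!is.na(x) & is.na(v), paste(name, "not interpretable as logical"))
    v
  }

  out <- tibble::tibble(
    entry_id = ids,
    couple_id = chr(df$couple_id),
    submitted_at = ts,
    completion_minutes = num_col(df$completion_minutes, "completion_minutes", lo = 0),
    ip = chr(df$ip),
    self_name = chr(df$self_name),
    self_sex = cat_col(df$self_sex, "self_sex", c("male", "female", "other")),
    self_age = int_col(df$self_age, "self_age", lo = 0, hi = 130),
    self_birth_month = int_col(df$self_birth_month, "self_birth_month", 1, 12),
    self_email = chr(df$self_email),
    self_phone = chr(df$self_phone),
    partner_name = chr(df$partner_name),
    partner_age = int_col(df$partner_age, "partner_age", lo = 0, hi = 130),
    partner_birth_month = int_col(df$partner_birth_month, "partner_birth_month", 1, 12),
    partner_email = chr(df$partner_email),
    partner_phone = chr(df$partner_phone),
    rel_length_months = int_col(df$rel_length_months, "rel_length_months", lo = 0),
    hiv_status = cat_col(df$hiv_status, "hiv_status",
                         c("negative", "positive", "unknown")),
    cas_with_partner = lgl_col(df$cas_with_partner, "cas_with_partner"),
    ipv_year = lgl_col(df$ipv_year, "ipv_year"),
    sexual_agreement = lgl_col(df$sexual_agreement, "sexual_agreement"),
    mobile_plus_internet = lgl_col(df$mobile_plus_internet, "mobile_plus_internet")
  )
  for (q in item_columns()) out[[q]] <- chr(df[[q]])

  bad_rows <- which(vapply(reasons, length, 1L) > 0)
  rejects <- tibble::tibble(
    row = bad_rows,
    entry_id = ids[bad_rows],
    reason = vapply(reasons[bad_rows], paste, "", collapse = "; ")
  )
  entries <- out[setdiff(seq_len(n), bad_rows), ]
  class(entries) <- c("screener_entries", class(entries))
  list(entries = entries, rejects = rejects)
}

#' Coerce a data frame to validated screener entries
#'
#' Like [validate_entries()] but errors if any row is rejected; convenient
#' for programmatically built cohorts that must be fully valid.
#'
#' @inheritParams validate_entries
#' @return A `screener_entries` tibble.
#' @export
as_screener_entries <- function(df, tz = "UTC") {
  res <- validate_entries(df, tz = tz)
  if (nrow(res$rejects)) {
    stop("invalid entries: ",
         paste(sprintf("row %d (%s)", res$rejects$row, res$rejects$reason),
               collapse = "; "), call. = FALSE)
  }
  res$entries
}

#' Write screener entries to CSV in the canonical schema
#'
#' Timestamps are written as ISO-8601 UTC so that a written file re-reads to
#' identical entries.
#'
#' @param entries A `screener_entries` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entries <- function(entries, path) {
  out <- as.data.frame(entries)
  out$submitted_at <- format(entries$submitted_at, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.screener_entries <- function(x, ...) {
  cat("<screener_entries> ", nrow(x), " entries, ",
      dplyr::n_distinct(x$couple_id[!is.na(x$couple_id)]),
      " referral tokens\n", sep = "")
  NextMethod()
}
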