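#' Specify a synthetic screener cohort
#'
#' Describes the composition of a labeled synthetic cohort: honest couples
#' with optional reporting noise, plus the fraud archetypes seen in online
#' couple recruitment — self-pairs (one actor fabricating both partners, with
#' a shared IP, stem-sequential emails, back-to-back submissions and
#' near-identical responses), eligibility fishers (repeat attempts from one
#' IP with an eligibility answer drifting toward passing) and duplicate
#' couples (one email pair enrolled under two referral tokens).
#'
#' @param n_true_couples Number of honest couples (two entries each).
#' @param p_report_noise Probability that an honest partner misreports one
#'   verification field (relationship length, partner age or partner
#'   birth month) beyond its tolerance.
#' @param n_self_pairs Number of fabricated self-pair couples.
#' @param n_fishers Number of eligibility fishers.
#' @param attempts_per_fisher Screener attempts per fisher (at least 2).
#' @param n_duplicate_couples Number of duplicate enrollments (each adds two
#'   couples, four entries, sharing one email pair).
#' @param n_female_names Number of honest entries given a female-typical name
#'   to exercise the name/sex mismatch flag.
#' @param seed Integer seed; identical spec and seed give byte-identical
#'   output.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_true_couples = 50L, p_report_noise = 0,
                        n_self_pairs = 0L, n_fishers = 0L,
                        attempts_per_fisher = 2L, n_duplicate_couples = 0L,
                        n_female_names = 0L, seed = 1L) {
  spec <- structure(
    list(n_true_couples = as.integer(n_true_couples),
         p_report_noise = as.numeric(p_report_noise),
         n_self_pairs = as.integer(n_self_pairs),
         n_fishers = as.integer(n_fishers),
         attempts_per_fisher = as.integer(attempts_per_fisher),
         n_duplicate_couples = as.integer(n_duplicate_couples),
         n_female_names = as.integer(n_female_names),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  counts <- unlist(spec[c("n_true_couples", "n_self_pairs", "n_fishers",
                          "n_duplicate_couples", "n_female_names")])
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("spec error: counts must be nonnegative", call. = FALSE)
  }
  if (spec$p_report_noise < 0 || spec$p_report_noise > 1) {
    stop("spec error: p_report_noise must be in [0, 1]", call. = FALSE)
  }
  if (spec$n_fishers > 0 && spec$attempts_per_fisher < 2) {
    stop("spec error: attempts_per_fisher must be >= 2 when n_fishers > 0",
         call. = FALSE)
  }
  if (spec$n_female_names > 2 * spec$n_true_couples) {
    stop("spec error: n_female_names exceeds the number of honest entries",
         call. = FALSE)
  }
  spec
}

default_male_names <- function() {
  path <- system.file("extdata", "male_names.txt", package = "dyadscreen")
  readLines(path, warn = FALSE)
}

#' Generate a labeled synthetic screener cohort
#'
#' Draws a cohort per the [cohort_spec()] and returns both the entries and
#' the ground truth the pipeline is expected to recover. Honest-couple
#' attributes use desk-scale distributions (ages uniform on 18–70,
#' relationship length log-uniform on 6–240 months); with
#' `p_report_noise = 0` every honest couple satisfies all four verification
#' rules by construction. All randomness derives from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `entries` (a `screener_entries` tibble, rows shuffled)
#'   and `truth`, itself a list of `entry_labels` (tibble: `entry_id`,
#'   `label`), `couple_truth` (tibble: `couple_key`, `couple_id`,
#'   `archetype`, `expected_classification`, `expected_disposition`,
#'   `expected_flags` list column) and `entry_expectations` (tibble:
#'   `entry_id`, `expected_flags` list column, for unpaired fraud entries).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)

  names_pool <- default_male_names()
  female_pool <- default_female_names()
  domains <- c("example.com", "mailbox.org", "inbox.net", "webmail.co")
  base_time <- as.POSIXct("2016-01-15 08:00:00", tz = "UTC")

  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("E%05d", counter)
  }
  ip_counter <- 0L
  next_ip <- function() {
    ip_counter <<- ip_counter + 1L
    sprintf("10.%d.%d.%d", ip_counter %/% 65536L,
            (ip_counter %/% 256L) %% 256L, ip_counter %% 256L)
  }
  token_counter <- 0L
  next_token <- function() {
    token_counter <<- token_counter + 1L
    paste0(sprintf("%04d", 2000L + token_counter),
           paste(sample(LETTERS, 2, replace = TRUE), collapse = ""))
  }
  phone_counter <- 0L
  next_phone <- function() {
    phone_counter <<- phone_counter + 1L
    sprintf("305555%04d", phone_counter)
  }
  mk_email <- function(name, domain, suffix = NULL) {
    sprintf("%s%s@%s", name, suffix %||% sprintf("%02d", counter), domain)
  }
  rand_items <- function() sample(c("a", "b", "c", "d"), 17, replace = TRUE)

  blank_entry <- function() {
    e <- list(entry_id = next_id(), couple_id = NA_character_,
              submitted_at = base_time, completion_minutes = round(stats::runif(1, 20, 30), 1),
              ip = next_ip(), self_name = NA_character_, self_sex = "male",
              self_age = NA_integer_, self_birth_month = NA_integer_,
              self_email = NA_character_, self_phone = NA_character_,
              partner_name = NA_character_, partner_age = NA_integer_,
              partner_birth_month = NA_integer_, partner_email = NA_character_,
              partner_phone = NA_character_, rel_length_months = NA_integer_,
              hiv_status = "negative", cas_with_partner = TRUE,
              ipv_year = FALSE, sexual_agreement = FALSE,
              mobile_plus_internet = TRUE)
    items <- as.list(rand_items())
    names(items) <- item_columns()
    c(e, items)
  }

  # a pair of internally concordant entries for two identities
  concordant_pair <- function(token, t0, gap_min, same_ip = FALSE,
                              emails = NULL, share_items = FALSE) {
    nm <- sample(names_pool, 2)
    age <- sample(18:70, 2, replace = TRUE)
    bm <- sample(1:12, 2, replace = TRUE)
    rel <- as.integer(round(exp(stats::runif(1, log(6), log(240)))))
    a <- blank_entry(); b <- blank_entry()
    if (same_ip) b$ip <- a$ip
    dom <- sample(domains, 2, replace = FALSE)
    a$self_name <- nm[1]; b$self_name <- nm[2]
    a$self_age <- age[1]; b$self_age <- age[2]
    a$self_birth_month <- bm[1]; b$self_birth_month <- bm[2]
    a$self_email <- emails[1] %||% mk_email(nm[1], dom[1])
    b$self_email <- emails[2] %||% mk_email(nm[2], dom[2])
    a$self_phone <- next_phone(); b$self_phone <- next_phone()
    a$rel_length_months <- rel; b$rel_length_months <- rel
    a$partner_name <- nm[2]; b$partner_name <- nm[1]
    a$partner_age <- age[2]; b$partner_age <- age[1]
    a$partner_birth_month <- bm[2]; b$partner_birth_month <- bm[1]
    a$partner_email <- b$self_email; b$partner_email <- a$self_email
    a$partner_phone <- b$self_phone; b$partner_phone <- a$self_phone
    a$couple_id <- token; b$couple_id <- token
    a$submitted_at <- t0
    b$submitted_at <- t0 + round(gap_min * 60)
    if (share_items) for (q in item_columns()) b[[q]] <- a[[q]]
    list(a = a, b = b)
  }

  entries <- list()
  labels <- list()
  couple_truth <- list()
  entry_expect <- list()
  add_couple_truth <- function(a, b, token, archetype, classification,
                               disposition, flags) {
    couple_truth[[length(couple_truth) + 1L]] <<- tibble::tibble(
      couple_key = couple_key_of(a$entry_id, b$entry_id),
      couple_id = token, archetype = archetype,
      expected_classification = classification,
      expected_disposition = disposition,
      expected_flags = list(sort(flags)))
  }

  # ---- honest couples -------------------------------------------------
  female_left <- spec$n_female_names
  for (i in seq_len(spec$n_true_couples)) {
    token <- next_token()
    t0 <- base_time + i * 6 * 3600
    pair <- concordant_pair(token, t0, gap_min = stats::runif(1, 60, 2880))
    broken <- character()
    flags <- character()
    for (side in c("a", "b")) {
      if (spec$p_report_noise > 0 && stats::runif(1) < spec$p_report_noise) {
        field <- sample(c("rel", "age", "month"), 1)
        e <- pair[[side]]
        if (field == "rel") {
          e$rel_length_months <- e$rel_length_months + 2L + sample(1:3, 1)
          broken <- union(broken, "R1")
        } else if (field == "age") {
          e$partner_age <- e$partner_age + 2L + sample(1:3, 1)
          broken <- union(broken, "R3")
        } else {
          e$partner_birth_month <- (e$partner_birth_month %% 12L) + 1L
          broken <- union(broken, "R2")
        }
        pair[[side]] <- e
      }
    }
    for (side in c("a", "b")) {
      if (female_left > 0L) {
        nm <- sample(female_pool, 1)
        other <- if (side == "a") "b" else "a"
        pair[[side]]$self_name <- nm
        pair[[other]]$partner_name <- nm
        female_left <- female_left - 1L
        flags <- union(flags, "NAME_SEX_MISMATCH")
      }
    }
    n_conc <- 4L - length(broken)
    classification <- classify_verification(n_conc, rule_config())
    disposition <- if (classification != "verified") {
      NA_character_
    } else if (length(flags)) "suspicious" else "valid"
    entries <- c(entries, list(pair$a, pair$b))
    labels[[length(labels) + 1L]] <- tibble::tibble(
      entry_id = c(pair$a$entry_id, pair$b$entry_id), label = "honest")
    add_couple_truth(pair$a, pair$b, token, "honest", classification,
                     disposition, flags)
  }

  # ---- self-pairs: one actor fabricating both partners ----------------
  for (i in seq_len(spec$n_self_pairs)) {
    token <- next_token()
    t0 <- base_time + (1000 + i) * 7 * 3600
    actor <- sample(names_pool, 1)
    stem <- paste0(actor, "mc", sprintf("%02d", i))
    pair <- concordant_pair(
      token, t0, gap_min = stats::runif(1, 20, 30), same_ip = TRUE,
      emails = c(paste0(stem, "1@gmail.com"), paste0(stem, "2@gmail.com")),
      share_items = TRUE)
    entries <- c(entries, list(pair$a, pair$b))
    labels[[length(labels) + 1L]] <- tibble::tibble(
      entry_id = c(pair$a$entry_id, pair$b$entry_id), label = "fabricated")
    add_couple_truth(pair$a, pair$b, token, "self_pair", "verified", "invalid",
                     c("SAME_IP_MULTI_ENTRY", "SEQUENTIAL_EMAIL", "BACK_TO_BACK"))
  }

  # ---- eligibility fishers --------------------------------------------
  for (i in seq_len(spec$n_fishers)) {
    k <- spec$attempts_per_fisher
    nm <- sample(names_pool, 1)
    partner_nm <- sample(names_pool, 1)
    ip <- next_ip()
    email <- mk_email(nm, sample(domains, 1), suffix = sprintf("f%02d", i))
    phone <- next_phone()
    items <- rand_items()
    rel_seq <- c(seq(5 - (k - 2), 5, by = 1), 7L)
    t0 <- base_time + (2000 + i) * 5 * 3600
    ids <- character(k)
    for (j in seq_len(k)) {
      e <- blank_entry()
      e$ip <- ip
      e$self_name <- nm
      e$self_age <- 30L
      e$self_birth_month <- 6L
      e$self_email <- email
      e$self_phone <- phone
      e$partner_name <- partner_nm
      e$partner_age <- 31L
      e$partner_birth_month <- 7L
      e$partner_email <- sprintf("nonexistent.partner%02d@nowhere.example", i)
      e$partner_phone <- ""
      e$rel_length_months <- as.integer(rel_seq[j])
      e$submitted_at <- t0 + round((j - 1) * stats::runif(1, 40, 120) * 60)
      for (q in item_columns()) e[[q]] <- items[match(q, item_columns())]
      ids[j] <- e$entry_id
      entries <- c(entries, list(e))
    }
    labels[[length(labels) + 1L]] <- tibble::tibble(entry_id = ids,
                                                    label = "fisher")
    entry_expect[[length(entry_expect) + 1L]] <- tibble::tibble(
      entry_id = ids,
      expected_flags = rep(list(sort(c("SAME_IP_MULTI_ENTRY",
                                       "ELIGIBILITY_FISHING"))), k))
  }

  # ---- duplicate couples: one email pair, two referral tokens ---------
  for (i in seq_len(spec$n_duplicate_couples)) {
    nm <- sample(names_pool, 2)
    dom <- sample(domains, 2, replace = FALSE)
    emails <- c(mk_email(nm[1], dom[1], suffix = sprintf("d%02da", i)),
                mk_email(nm[2], dom[2], suffix = sprintf("d%02db", i)))
    tokens <- c(next_token(), next_token())
    pairs <- list()
    for (rep_i in 1:2) {
      t0 <- base_time + (3000 + 2 * i + rep_i) * 9 * 3600
      pair <- concordant_pair(tokens[rep_i], t0,
                              gap_min = stats::runif(1, 90, 1440),
                              emails = emails)
      # same two identities re-enrolling: overwrite the sampled names
      pair$a$self_name <- nm[1]; pair$b$self_name <- nm[2]
      pair$a$partner_name <- nm[2]; pair$b$partner_name <- nm[1]
      entries <- c(entries, list(pair$a, pair$b))
      labels[[length(labels) + 1L]] <- tibble::tibble(
        entry_id = c(pair$a$entry_id, pair$b$entry_id), label = "duplicate")
      add_couple_truth(pair$a, pair$b, tokens[rep_i], "duplicate", "verified",
                       "suspicious", "DUPLICATE_COUPLE")
      pairs[[rep_i]] <- pair
    }
  }

  df <- if (length(entries)) {
    dplyr::bind_rows(lapply(entries, tibble::as_tibble))
  } else {
    empty_entries_df()
  }
  if (nrow(df)) df <- df[sample.int(nrow(df)), ]
  truth <- list(
    entry_labels = dplyr::bind_rows(c(labels, list(
      tibble::tibble(entry_id = character(), label = character())))),
    couple_truth = dplyr::bind_rows(c(couple_truth, list(
      tibble::tibble(couple_key = character(), couple_id = character(),
                     archetype = character(),
                     expected_classification = character(),
                     expected_disposition = character(),
                     expected_flags = list())))),
    entry_expectations = dplyr::bind_rows(c(entry_expect, list(
      tibble::tibble(entry_id = character(), expected_flags = list())))),
    spec = unclass(spec)
  )
  list(entries = as_screener_entries(df), truth = truth)
}

#' Write a synthetic cohort to disk as a test fixture
#'
#' Writes the entries as a canonical-schema CSV and the ground truth as JSON.
#' The CSV round-trips through [read_entries()] to identical entries, and
#' regenerating with the recorded spec reproduces the files byte for byte.
#'
#' @param entries A `screener_entries` tibble.
#' @param truth The truth list from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_fixture <- function(entries, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries_path <- file.path(dir, "entries.csv")
  truth_path <- file.path(dir, "truth.json")
  write_entries(entries, entries_path)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(c(entries = entries_path, truth = truth_path))
}
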