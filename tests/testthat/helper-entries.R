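# construct typed screener entries in code; no fixture files needed

entry_defaults <- function() {
  list(
    entry_id = "A", couple_id = NA_character_,
    submitted_at = as.POSIXct("2016-01-01 10:00:00", tz = "UTC"),
    completion_minutes = 25, ip = "10.0.0.1",
    self_name = "alan", self_sex = "male", self_age = 29L,
    self_birth_month = 3L, self_email = "alan@example.com",
    self_phone = "3055550001",
    partner_name = "brian", partner_age = 31L, partner_birth_month = 11L,
    partner_email = "brian@sample.org", partner_phone = "3055550002",
    rel_length_months = 18L, hiv_status = "negative",
    cas_with_partner = TRUE, ipv_year = FALSE, sexual_agreement = FALSE,
    mobile_plus_internet = TRUE
  )
}

make_entry <- function(...) {
  e <- entry_defaults()
  items <- stats::setNames(as.list(rep("a", 17)), sprintf("q%02d", 1:17))
  e <- c(e, items)
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(e)))
  e[names(dots)] <- dots
  tibble::as_tibble(e[dyadscreen::screener_columns()])
}

# a fully cross-consistent couple; overrides apply per member via lists
make_couple <- function(id_a = "A", id_b = "B", couple_id = "1000AA",
                        gap_min = 120, a = list(), b = list()) {
  base <- as.POSIXct("2016-01-01 10:00:00", tz = "UTC")
  ea <- do.call(make_entry, c(list(
    entry_id = id_a, couple_id = couple_id, submitted_at = base,
    ip = paste0("10.1.0.", sum(utf8ToInt(id_a)) %% 256),
    self_name = "alan", self_age = 29L, self_birth_month = 3L,
    self_email = paste0("alan.", tolower(id_a), "@example.com"),
    self_phone = "3055550001",
    partner_name = "brian", partner_age = 31L, partner_birth_month = 11L,
    partner_email = paste0("brian.", tolower(id_b), "@sample.org"),
    partner_phone = "3055550002"), a))
  eb <- do.call(make_entry, c(list(
    entry_id = id_b, couple_id = couple_id,
    submitted_at = base + gap_min * 60,
    ip = paste0("10.2.0.", sum(utf8ToInt(id_b)) %% 256),
    self_name = "brian", self_age = 31L, self_birth_month = 11L,
    self_email = paste0("brian.", tolower(id_b), "@sample.org"),
    self_phone = "3055550002",
    partner_name = "alan", partner_age = 29L, partner_birth_month = 3L,
    partner_email = paste0("alan.", tolower(id_a), "@example.com"),
    partner_phone = "3055550001",
    q01 = "b", q02 = "c", q03 = "d"), b))
  dplyr::bind_rows(ea, eb)
}

# ---- independent brute-force oracle for contact linkage ------------------
# Exhaustive pair enumeration with its own minimal normalization; a pair is
# accepted iff the claims are reciprocal and neither member is involved in
# any claim with a third entry.
bf_email <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", x)))
  x
}
bf_phone <- function(x) {
  d <- gsub("[^0-9]", "", ifelse(is.na(x), "", x))
  d <- ifelse(nchar(d) == 11 & substr(d, 1, 1) == "1", substring(d, 2), d)
  ifelse(nchar(d) >= 7, d, "")
}
brute_force_contact_pairs <- function(entries) {
  n <- nrow(entries)
  if (n < 2) return(character())
  se <- bf_email(entries$self_email); pe <- bf_email(entries$partner_email)
  sp <- bf_phone(entries$self_phone); pp <- bf_phone(entries$partner_phone)
  claim <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    claim[i, j] <- (nzchar(pe[i]) && pe[i] == se[j]) ||
      (nzchar(pp[i]) && pp[i] == sp[j])
  }
  involved <- function(i) which(claim[i, ] | claim[, i])
  keys <- character()
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    if (claim[i, j] && claim[j, i] &&
        identical(involved(i), j) && identical(involved(j), i)) {
      ids <- sort(c(entries$entry_id[i], entries$entry_id[j]))
      keys <- c(keys, paste(ids, collapse = "|"))
    }
  }
  sort(keys)
}

# random tokenless batch with planted reciprocal, one-way and conflicting
# contact claims, for matching equivalence checks
random_contact_batch <- function(n, seed) {
  withr::local_seed(seed)
  ids <- sprintf("R%03d", seq_len(n))
  entries <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_entry(entry_id = ids[i], couple_id = NA_character_,
               self_email = sprintf("user%03d@example.com", i),
               self_phone = sprintf("30555%05d", i),
               partner_email = NA_character_, partner_phone = NA_character_,
               ip = sprintf("10.9.%d.%d", i %/% 256, i %% 256))
  }))
  point_at <- function(i, j, via = c("email", "phone")) {
    via <- match.arg(via)
    if (via == "email") {
      entries$partner_email[i] <<- entries$self_email[j]
    } else {
      entries$partner_phone[i] <<- entries$self_phone[j]
    }
  }
  free <- sample(seq_len(n))
  while (length(free) >= 2) {
    kind <- sample(c("mutual", "oneway", "conflict", "none"), 1,
                   prob = c(0.45, 0.2, 0.2, 0.15))
    if (kind == "mutual" || length(free) < 3) {
      i <- free[1]; j <- free[2]; free <- free[-(1:2)]
      point_at(i, j, sample(c("email", "phone"), 1))
      point_at(j, i, sample(c("email", "phone"), 1))
    } else if (kind == "oneway") {
      i <- free[1]; j <- free[2]; free <- free[-(1:2)]
      point_at(i, j)
    } else if (kind == "conflict") {
      i <- free[1]; j <- free[2]; k <- free[3]; free <- free[-(1:3)]
      point_at(i, j); point_at(j, i); point_at(k, i)
    } else {
      free <- free[-1]
    }
  }
  entries
}

# handcrafted batch encoding the characteristic fraud patterns: sequential
# gmail stems, a female-typical name, the Heath/heather near-miss, and one
# email pair enrolled under two couple IDs
fraud_pattern_batch <- function() {
  dplyr::bind_rows(
    make_couple("K1", "K2", couple_id = "1001KC", gap_min = 300,
                a = list(self_email = "kylemcap1@gmail.com",
                         partner_email = "kylemcap2@gmail.com"),
                b = list(self_email = "kylemcap2@gmail.com",
                         partner_email = "kylemcap1@gmail.com")),
    make_couple("M1", "M2", couple_id = "1002MW", gap_min = 400,
                a = list(self_name = "Melissa Wise",
                         self_email = "mwise@example.com",
                         partner_email = "jordan.m2@sample.org"),
                b = list(partner_name = "Melissa Wise",
                         self_email = "jordan.m2@sample.org",
                         partner_email = "mwise@example.com")),
    make_couple("H1", "H2", couple_id = "1003HB", gap_min = 500,
                a = list(self_name = "Heath Brown",
                         self_email = "heather1@gmail.com",
                         partner_email = "marcus.h2@sample.org"),
                b = list(partner_name = "Heath Brown",
                         self_email = "marcus.h2@sample.org",
                         partner_email = "heather1@gmail.com")),
    make_couple("D1", "D2", couple_id = "2452EW", gap_min = 600,
                a = list(self_email = "dupa@example.com",
                         partner_email = "dupb@sample.org"),
                b = list(self_email = "dupb@sample.org",
                         partner_email = "dupa@example.com")),
    make_couple("D3", "D4", couple_id = "2864OD", gap_min = 700,
                a = list(self_email = "dupa@example.com",
                         partner_email = "dupb@sample.org"),
                b = list(self_email = "dupb@sample.org",
                         partner_email = "dupa@example.com"))
  )
}
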