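#' Normalize email addresses for matching
#'
#' Canonicalizes raw email strings for exact matching and derives the "stem"
#' used by fraud heuristics: the local part with the maximal trailing run of
#' digits removed (so `kylemcap1@gmail.com` and `kylemcap2@gmail.com` share
#' the stem `kylemcap`). Total function: malformed input is returned in
#' canonical form with `conformant = FALSE`, never an error.
#'
#' @param raw Character vector of raw email strings (may be `NA`, empty or
#'   malformed).
#' @return A tibble with one row per input and columns `raw`, `canonical`
#'   (lowercased, trimmed), `local`, `domain`, `stem` and `conformant`.
#' @export
#' @examples
#' normalize_email("KyleMcap1@Gmail.com")
normalize_email <- function(raw) {
  raw <- as.character(raw)
  canonical <- tolower(trimws(raw))
  canonical[is.na(canonical)] <- ""
  conformant <- grepl("^[^@[:space:]]+@[^@[:space:]]+\\.[^@[:space:]]+$", canonical)
  local <- ifelse(conformant, sub("@.*$", "", canonical), "")
  domain <- ifelse(conformant, sub("^.*@", "", canonical), "")
  stem <- sub("[0-9]+$", "", local)
  tibble::tibble(
    raw = ifelse(is.na(raw), "", raw),
    canonical = canonical,
    local = local,
    domain = domain,
    stem = stem,
    conformant = conformant
  )
}

#' Normalize phone numbers for matching
#'
#' Strips everything but digits; an 11-digit number with a leading national
#' prefix `1` is reduced to its trailing 10 digits. Numbers with fewer than 7
#' digits are treated as absent for matching (`usable = FALSE`).
#'
#' @param raw Character vector of raw phone strings.
#' @return A tibble with columns `raw`, `digits` (empty when unusable) and
#'   `usable`.
#' @export
#' @examples
#' normalize_phone("(305) 555-0100")
normalize_phone <- function(raw) {
  raw <- as.character(raw)
  digits <- gsub("[^0-9]", "", ifelse(is.na(raw), "", raw))
  eleven <- nchar(digits) == 11L & startsWith(digits, "1")
  digits[eleven] <- substring(digits[eleven], 2L)
  usable <- nchar(digits) >= 7L
  digits[!usable] <- ""
  tibble::tibble(raw = ifelse(is.na(raw), "", raw), digits = digits,
                 usable = usable)
}

# Collapse provider aliasing (dots and plus-tags in the local part) for the
# configured domains. Used only inside fraud heuristics, never for the
# verification contact rule, which is an exact-match contract.
collapse_email_alias <- function(canonical, alias_domains) {
  norm <- normalize_email(canonical)
  local <- norm$local
  idx <- norm$domain %in% alias_domains
  local[idx] <- gsub("\\.", "", sub("\\+.*$", "", local[idx]))
  out <- norm$canonical
  out[norm$conformant] <- paste0(local[norm$conformant], "@",
                                 norm$domain[norm$conformant])
  out
}
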