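#' Individual eligibility criteria
#'
#' Applies the eight individual-level inclusion criteria to each screener
#' entry:
#'
#' * `E1` self-reports as male
#' * `E2` at least 18 years of age
#' * `E3` in the relationship for at least 6 months
#' * `E4` self-reports HIV-negative
#' * `E5` practices condomless anal sex with the main partner
#' * `E6` no intimate partner violence or coercion in the past year
#' * `E7` no established sexual agreement in the relationship
#' * `E8` owns a mobile phone and has an alternate way to access the internet
#'
#' Every failed criterion is returned, not just the first. A missing field
#' fails its criterion conservatively and is additionally recorded in
#' `missing_criteria` so reviewers can distinguish "said no" from "said
#' nothing". Which criteria are applied is taken from
#' `cfg$eligibility_criteria`.
#'
#' @param entries A `screener_entries` tibble.
#' @param cfg A [rule_config()].
#' @return A tibble with `entry_id`, `eligible`, `failed_criteria` (list
#'   column of codes) and `missing_criteria` (list column, subset of
#'   `failed_criteria`).
#' @export
assess_individual <- function(entries, cfg = rule_config()) {
  checks <- list(
    E1 = entries$self_sex == "male",
    E2 = entries$self_age >= 18L,
    E3 = entries$rel_length_months >= 6L,
    E4 = entries$hiv_status == "negative",
    E5 = entries$cas_with_partner,
    E6 = !entries$ipv_year,
    E7 = !entries$sexual_agreement,
    E8 = entries$mobile_plus_internet
  )
  checks <- checks[cfg$eligibility_criteria]
  pass <- vapply(checks, function(x) !is.na(x) & x, logical(nrow(entries)))
  missing <- vapply(checks, is.na, logical(nrow(entries)))
  if (nrow(entries) == 1L) {
    pass <- matrix(pass, nrow = 1, dimnames = list(NULL, names(checks)))
    missing <- matrix(missing, nrow = 1, dimnames = list(NULL, names(checks)))
  }
  codes <- names(checks)
  tibble::tibble(
    entry_id = entries$entry_id,
    eligible = rowSums(!pass) == 0L,
    failed_criteria = lapply(seq_len(nrow(entries)), function(i) codes[!pass[i, ]]),
    missing_criteria = lapply(seq_len(nrow(entries)), function(i) codes[missing[i, ]])
  )
}

#' Couple-level eligibility
#'
#' A couple is eligible only when both members individually meet all
#' criteria. Symmetric in its arguments.
#'
#' @param a,b Single rows of the tibble returned by [assess_individual()]
#'   (or logical scalars giving each member's eligibility).
#' @return `TRUE` iff both individuals are eligible.
#' @export
assess_couple <- function(a, b) {
  ea <- if (is.logical(a)) a else a$eligible
  eb <- if (is.logical(b)) b else b$eligible
  isTRUE(ea) && isTRUE(eb)
}
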