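#' Relationship-verification concordance rules
#'
#' Four predetermined decision rules establish, from independently reported
#' facts, that two screener entries describe a real relationship:
#'
#' * `R1_rel_length` — reported relationship lengths agree within a margin
#'   (`cfg$rel_length_tolerance_months`, default 1 month).
#' * `R2_birth_month` — each partner's self-reported birthday month exactly
#'   equals the month the other partner reports for him, in both directions.
#' * `R3_age` — each self-reported age is within
#'   `cfg$age_tolerance_years` (default 1 year) of the age the other partner
#'   reports, in both directions.
#' * `R4_contact` — at least `cfg$contact_match_min` (default 1) of the four
#'   directed contact correspondences (partner-reported vs self-reported
#'   email and phone) match exactly after normalization.
#'
#' Each rule returns `"concordant"`, `"discordant"` or `"missing"`. A missing
#' value counts as not-concordant toward classification but is reported
#' distinctly so reviewers can tell disagreement from silence.
#'
#' @param a,b Single-row `screener_entries` (one per partner).
#' @param cfg A [rule_config()].
#' @return A string: `"concordant"`, `"discordant"` or `"missing"`.
#' @name verification_rules
NULL

outcome <- function(x) {
  if (is.na(x)) "missing" else if (x) "concordant" else "discordant"
}

#' @rdname verification_rules
#' @export
rule_rel_length <- function(a, b, cfg = rule_config()) {
  la <- a$rel_length_months; lb <- b$rel_length_months
  if (is.na(la) || is.na(lb)) return("missing")
  outcome(abs(la - lb) <= cfg$rel_length_tolerance_months)
}

#' @rdname verification_rules
#' @export
rule_birth_month <- function(a, b) {
  vals <- c(a$self_birth_month, b$partner_birth_month,
            b$self_birth_month, a$partner_birth_month)
  if (anyNA(vals)) return("missing")
  outcome(vals[1] == vals[2] && vals[3] == vals[4])
}

#' @rdname verification_rules
#' @export
rule_age <- function(a, b, cfg = rule_config()) {
  vals <- c(a$self_age, b$partner_age, b$self_age, a$partner_age)
  if (anyNA(vals)) return("missing")
  outcome(abs(vals[1] - vals[2]) <= cfg$age_tolerance_years &&
            abs(vals[3] - vals[4]) <= cfg$age_tolerance_years)
}

#' @rdname verification_rules
#' @export
rule_contact <- function(a, b, cfg = rule_config()) {
  cf <- contact_fields(dplyr::bind_rows(a, b))
  m <- directed_contact_matches(cf, 1L, 2L)
  if (all(is.na(m))) return("missing")
  outcome(sum(m, na.rm = TRUE) >= cfg$contact_match_min)
}

#' Classify a vector of rule outcomes
#'
#' The concordant-rule count maps to the three groups used for couples:
#' at least `cfg$verified_min_rules` (default all 4) concordant rules is
#' `verified`; a count inside `cfg$partial_rules_range` (default 2–3) is
#' `partially_verified` and queues a second assessment; anything lower is
#' `unverified`. Missing outcomes never count as concordant.
#'
#' @param outcomes Character vector of rule outcomes (values in
#'   `concordant`, `discordant`, `missing`), or an integer count of
#'   concordant rules.
#' @param cfg A [rule_config()].
#' @return `"verified"`, `"partially_verified"` or `"unverified"`.
#' @export
classify_verification <- function(outcomes, cfg = rule_config()) {
  n <- if (is.numeric(outcomes)) outcomes else sum(outcomes == "concordant")
  if (n >= cfg$verified_min_rules) {
    "verified"
  } else if (n >= cfg$partial_rules_range[1] && n <= cfg$partial_rules_range[2]) {
    "partially_verified"
  } else {
    "unverified"
  }
}

#' Verify one couple against the four concordance rules
#'
#' @param a,b Single-row `screener_entries`, one per partner. Symmetric:
#'   swapping `a` and `b` gives identical outcomes and classification.
#' @param cfg A [rule_config()].
#' @return A one-row tibble: `couple_key`, outcome columns `R1_rel_length`,
#'   `R2_birth_month`, `R3_age`, `R4_contact`, `n_concordant` and
#'   `classification`.
#' @export
verify_couple <- function(a, b, cfg = rule_config()) {
  out <- c(
    R1_rel_length = rule_rel_length(a, b, cfg),
    R2_birth_month = rule_birth_month(a, b),
    R3_age = rule_age(a, b, cfg),
    R4_contact = rule_contact(a, b, cfg)
  )
  n <- sum(out == "concordant")
  tibble::tibble(
    couple_key = couple_key_of(a$entry_id, b$entry_id),
    R1_rel_length = out[["R1_rel_length"]],
    R2_birth_month = out[["R2_birth_month"]],
    R3_age = out[["R3_age"]],
    R4_contact = out[["R4_contact"]],
    n_concordant = n,
    classification = classify_verification(n, cfg)
  )
}

#' Verify a set of linked couples
#'
#' @param couples Couples tibble from [link_couples()].
#' @param entries The `screener_entries` batch.
#' @param cfg A [rule_config()].
#' @return One row per couple, as [verify_couple()], in `couple_key` order.
#' @export
verify_couples <- function(couples, entries, cfg = rule_config()) {
  if (nrow(couples) == 0L) {
    return(tibble::tibble(couple_key = character(),
                          R1_rel_length = character(),
                          R2_birth_month = character(),
                          R3_age = character(), R4_contact = character(),
                          n_concordant = integer(),
                          classification = character()))
  }
  rows <- lapply(seq_len(nrow(couples)), function(k) {
    a <- entries[entries$entry_id == couples$id_a[k], ]
    b <- entries[entries$entry_id == couples$id_b[k], ]
    verify_couple(a, b, cfg)
  })
  dplyr::bind_rows(rows)
}
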