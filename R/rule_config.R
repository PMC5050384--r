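#' Rule configuration for screening, verification and validation
#'
#' Collects every tolerance, threshold, window and word-list the pipeline
#' uses, so that both a manual-review era scheme and a fully automated scheme
#' can be expressed from one object. All values are serializable to JSON and
#' round-trip unchanged through [write_rule_config()] / [read_rule_config()].
#'
#' @param rel_length_tolerance_months Maximum absolute difference, in whole
#'   months, between the two partners' reported relationship lengths that
#'   still counts as concordant. Default 1.
#' @param age_tolerance_years Maximum absolute difference, in years, between a
#'   partner's self-reported age and the age the other partner reports for
#'   him. Default 1.
#' @param verified_min_rules Minimum number of concordant verification rules
#'   (out of 4) for a couple to be classified `verified`. Default 4.
#' @param partial_rules_range Length-2 integer vector: the inclusive range of
#'   concordant-rule counts classified `partially_verified`. Default `c(2, 3)`.
#' @param contact_match_min Minimum number of directed contact
#'   correspondences (partner-reported vs self-reported email/phone, four in
#'   total) required for the contact rule to be concordant. Default 1.
#' @param back_to_back_window_minutes Length-2 numeric vector: inclusive
#'   window, in minutes, of submission-time gaps considered suspicious for
#'   back-to-back completion. Default `c(0, 30)`.
#' @param response_similarity_threshold Fraction of identical aligned screener
#'   items at or above which two entries' responses are considered
#'   near-identical. Default 0.9.
#' @param email_stem_min_length Minimum length of a shared email stem (local
#'   part with the trailing digit run stripped) for the sequential-email flag
#'   to fire on the stem route. Default 4.
#' @param invalidate_min_flag_categories Number of distinct normal-severity
#'   flag categories required before a couple's disposition is `invalid`
#'   rather than `suspicious`. Default 2: no single criterion condemns.
#' @param female_name_list Character vector of female-typical given names used
#'   by the name/sex mismatch flag in a male-only study. Defaults to the list
#'   packaged in `extdata/female_names.txt`; matching is exact-token and
#'   case-insensitive so that e.g. "Heath" never matches "Heather".
#' @param alias_domains Email domains for which provider aliasing (dots in
#'   the local part, plus-tags) is collapsed inside fraud heuristics only.
#' @param eligibility_criteria Character vector of criterion codes (subset of
#'   `E1`..`E8`) actually applied; lets either study phase be expressed.
#'
#' @return An object of class `rule_config` (a named list).
#' @export
#' @examples
#' cfg <- rule_config()
#' cfg$rel_length_tolerance_months
rule_config <- function(rel_length_tolerance_months = 1L,
                        age_tolerance_years = 1L,
                        verified_min_rules = 4L,
                        partial_rules_range = c(2L, 3L),
                        contact_match_min = 1L,
                        back_to_back_window_minutes = c(0, 30),
                        response_similarity_threshold = 0.9,
                        email_stem_min_length = 4L,
                        invalidate_min_flag_categories = 2L,
                        female_name_list = NULL,
                        alias_domains = c("gmail.com", "googlemail.com"),
                        eligibility_criteria = paste0("E", 1:8)) {
  if (is.null(female_name_list)) {
    female_name_list <- default_female_names()
  }
  cfg <- structure(
    list(
      rel_length_tolerance_months = as.integer(rel_length_tolerance_months),
      age_tolerance_years = as.integer(age_tolerance_years),
      n_verification_rules = 4L,
      verified_min_rules = as.integer(verified_min_rules),
      partial_rules_range = as.integer(partial_rules_range),
      contact_match_min = as.integer(contact_match_min),
      back_to_back_window_minutes = as.numeric(back_to_back_window_minutes),
      response_similarity_threshold = as.numeric(response_similarity_threshold),
      email_stem_min_length = as.integer(email_stem_min_length),
      invalidate_min_flag_categories = as.integer(invalidate_min_flag_categories),
      female_name_list = tolower(as.character(female_name_list)),
      alias_domains = tolower(as.character(alias_domains)),
      eligibility_criteria = as.character(eligibility_criteria)
    ),
    class = "rule_config"
  )
  validate_rule_config(cfg)
}

validate_rule_config <- function(cfg) {
  stopifnot(inherits(cfg, "rule_config"))
  if (cfg$verified_min_rules > cfg$n_verification_rules) {
    stop("verified_min_rules must not exceed the number of verification rules",
         call. = FALSE)
  }
  if (length(cfg$partial_rules_range) != 2L ||
      cfg$partial_rules_range[1] > cfg$partial_rules_range[2]) {
    stop("partial_rules_range must be an ordered length-2 interval", call. = FALSE)
  }
  if (cfg$partial_rules_range[2] >= cfg$verified_min_rules) {
    stop("partial_rules_range must lie strictly below verified_min_rules",
         call. = FALSE)
  }
  if (length(cfg$back_to_back_window_minutes) != 2L ||
      cfg$back_to_back_window_minutes[1] > cfg$back_to_back_window_minutes[2]) {
    stop("back_to_back_window_minutes must be an ordered length-2 interval",
         call. = FALSE)
  }
  if (cfg$response_similarity_threshold < 0 || cfg$response_similarity_threshold > 1) {
    stop("response_similarity_threshold must be in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(cfg$eligibility_criteria, paste0("E", 1:8))
  if (length(bad)) {
    stop("unknown eligibility criteria: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

default_female_names <- function() {
  path <- system.file("extdata", "female_names.txt", package = "dyadscreen")
  if (!nzchar(path)) stop("packaged female name list not found", call. = FALSE)
  readLines(path, warn = FALSE)
}

#' Read and write rule configurations as JSON
#'
#' @param path Path to a JSON file.
#' @return `read_rule_config()` returns a [rule_config()] object;
#'   `write_rule_config()` returns `path` invisibly.
#' @export
read_rule_config <- function(path) {
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("config error: cannot parse JSON config: ",
                             conditionMessage(e), call. = FALSE)
  )
  known <- names(formals(rule_config))
  unknown <- setdiff(names(raw), c(known, "n_verification_rules"))
  if (length(unknown)) {
    stop("config error: unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  raw$n_verification_rules <- NULL
  tryCatch(
    do.call(rule_config, raw),
    error = function(e) stop("config error: ", conditionMessage(e), call. = FALSE)
  )
}

#' @rdname read_rule_config
#' @param cfg A [rule_config()] object.
#' @export
write_rule_config <- function(cfg, path) {
  validate_rule_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.rule_config <- function(x, ...) {
  cat("<rule_config>\n")
  cat("  verification: ", x$verified_min_rules, "/", x$n_verification_rules,
      " rules to verify; partial at ",
      x$partial_rules_range[1], "-", x$partial_rules_range[2], "\n", sep = "")
  cat("  tolerances: rel length ±", x$rel_length_tolerance_months,
      " mo, age ±", x$age_tolerance_years, " yr, contact ≥",
      x$contact_match_min, "\n", sep = "")
  cat("  validation: back-to-back window [",
      x$back_to_back_window_minutes[1], ",", x$back_to_back_window_minutes[2],
      "] min, similarity ≥ ", x$response_similarity_threshold,
      ", invalid at ≥ ", x$invalidate_min_flag_categories,
      " flag categories\n", sep = "")
  cat("  eligibility criteria: ", paste(x$eligibility_criteria, collapse = " "),
      "\n", sep = "")
  invisible(x)
}
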