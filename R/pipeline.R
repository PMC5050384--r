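#' Run the full screening, verification and validation pipeline
#'
#' Executes the stages in order: load and validate entries, assess
#' individual eligibility, link entries into candidate couples, verify
#' relationships via the four concordance rules (couples with both members
#' individually eligible only), raise post hoc fraud flags, and compute
#' dispositions for verified couples. Deterministic given its inputs.
#'
#' @param entries A `screener_entries` tibble, or a path to a CSV in the
#'   canonical schema.
#' @param cfg A [rule_config()], or a path to a JSON rule configuration.
#' @param out_dir Optional directory; when given, the report JSON, per-couple
#'   CSVs and the manual-review queue (JSON lines) are written there.
#' @return A `pipeline_report`: a list with `counts`, `rejects`,
#'   `eligibility`, `couples`, `unpaired`, `verification`, `flags`,
#'   `dispositions`, `manual_review`, `config` and `metadata`.
#' @export
run_pipeline <- function(entries, cfg = rule_config(), out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_rule_config(cfg)
  validate_rule_config(cfg)
  if (is.character(entries)) {
    loaded <- read_entries(entries)
  } else {
    loaded <- list(entries = entries,
                   rejects = tibble::tibble(row = integer(),
                                            entry_id = character(),
                                            reason = character()))
  }
  e <- loaded$entries

  elig <- assess_individual(e, cfg)
  linked <- link_couples(e)
  couples <- linked$couples

  eligible_of <- stats::setNames(elig$eligible, elig$entry_id)
  couple_eligible <- vapply(seq_len(nrow(couples)), function(k) {
    assess_couple(eligible_of[[couples$id_a[k]]],
                  eligible_of[[couples$id_b[k]]])
  }, logical(1))
  eligible_couples <- couples[couple_eligible, ]
  ineligible_couples <- couples[!couple_eligible, ]

  routed <- route_partial_matches(eligible_couples, e)
  verification <- verify_couples(eligible_couples, e, cfg)
  cls <- stats::setNames(verification$classification, verification$couple_key)
  verified <- eligible_couples[cls[eligible_couples$couple_key] == "verified", ]
  partial_keys <- verification$couple_key[
    verification$classification == "partially_verified"]

  flags <- validate_couples(couples, e, cfg)
  disposed <- dispose(verified, flags, cfg)

  second_assessment <- tibble::tibble(
    couple_key = partial_keys,
    reason = "partially verified: second assessment required",
    fields = lapply(partial_keys, function(k) {
      row <- verification[verification$couple_key == k, ]
      nm <- c("R1_rel_length", "R2_birth_month", "R3_age", "R4_contact")
      nm[unlist(row[, nm]) != "concordant"]
    }),
    suggested_action = "call or email the potential participants to verify partner information"
  )
  manual_review <- dplyr::bind_rows(
    dplyr::mutate(routed$manual_review, stage = "matching"),
    dplyr::mutate(second_assessment, stage = "verification"),
    dplyr::mutate(disposed$manual_review, stage = "validation")
  )

  # per-entry conservation: every loaded entry lands in exactly one bucket
  bucket <- stats::setNames(rep(NA_character_, nrow(e)), e$entry_id)
  bucket[linked$unpaired$entry_id] <- "unpaired"
  for (k in seq_len(nrow(ineligible_couples))) {
    bucket[c(ineligible_couples$id_a[k], ineligible_couples$id_b[k])] <-
      "ineligible_couple"
  }
  for (k in seq_len(nrow(eligible_couples))) {
    bucket[c(eligible_couples$id_a[k], eligible_couples$id_b[k])] <-
      cls[[eligible_couples$couple_key[k]]]
  }
  if (anyNA(bucket)) {
    stop("internal error: entries not accounted for: ",
         paste(names(bucket)[is.na(bucket)], collapse = ", "), call. = FALSE)
  }

  counts <- list(
    loaded = nrow(e),
    rejected = nrow(loaded$rejects),
    eligible_individuals = sum(elig$eligible),
    unpaired = nrow(linked$unpaired),
    candidate_couples = nrow(couples),
    ineligible_couples = nrow(ineligible_couples),
    verified = sum(verification$classification == "verified"),
    partially_verified = sum(verification$classification == "partially_verified"),
    unverified = sum(verification$classification == "unverified"),
    valid = sum(disposed$dispositions$status == "valid"),
    suspicious = sum(disposed$dispositions$status == "suspicious"),
    invalid = sum(disposed$dispositions$status == "invalid")
  )

  report <- structure(list(
    counts = counts,
    rejects = loaded$rejects,
    eligibility = elig,
    couples = couples,
    unpaired = linked$unpaired,
    verification = verification,
    flags = flags,
    dispositions = disposed$dispositions,
    manual_review = manual_review,
    entry_buckets = tibble::tibble(entry_id = names(bucket),
                                   bucket = unname(bucket)),
    config = unclass(cfg),
    metadata = list(package_version = as.character(utils::packageVersion("dyadscreen")),
                    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC"))
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_report_files(report, out_dir)
  report
}

# plain-list (JSON-ready) representation; deterministic except metadata
report_to_list <- function(report, include_metadata = TRUE) {
  listify <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, ])
      lapply(row, function(v) if (is.list(v)) v[[1]] else v)
    })
  }
  out <- list(
    counts = report$counts,
    rejects = listify(report$rejects),
    couples = listify(report$couples),
    unpaired = listify(report$unpaired),
    verification = listify(report$verification),
    flags = listify(report$flags),
    dispositions = listify(report$dispositions),
    manual_review = listify(report$manual_review),
    config = report$config
  )
  if (include_metadata) out$metadata <- report$metadata
  out
}

#' Render a pipeline report
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param format `"json"` (lossless, machine-readable) or `"text"`
#'   (stage counts plus the manual-review queue with evidence).
#' @return A character scalar.
#' @export
render_report <- function(report, format = c("json", "text")) {
  if (!is.character(format) || !all(format %in% c("json", "text"))) {
    stop("usage error: format must be \"json\" or \"text\"", call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_to_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", na = "null",
                                         pretty = TRUE)))
  }
  lines <- c(
    "== pipeline report ==",
    sprintf("%-22s %d", names(report$counts), unlist(report$counts)),
    "",
    sprintf("manual review queue (%d items):", nrow(report$manual_review))
  )
  if (nrow(report$manual_review)) {
    items <- sprintf("  [%s] %s: %s (%s) -> %s",
                     report$manual_review$stage,
                     report$manual_review$couple_key,
                     report$manual_review$reason,
                     vapply(report$manual_review$fields, paste, "",
                            collapse = ", "),
                     report$manual_review$suggested_action)
    lines <- c(lines, items)
  }
  paste(lines, collapse = "\n")
}

write_report_files <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(render_report(report, "json"), file.path(out_dir, "report.json"))
  readr::write_csv(report$couples, file.path(out_dir, "couples.csv"),
                   progress = FALSE)
  readr::write_csv(report$verification, file.path(out_dir, "verification.csv"),
                   progress = FALSE)
  disp <- report$dispositions
  disp$triggering_flags <- vapply(disp$triggering_flags, paste, "",
                                  collapse = ";")
  readr::write_csv(disp, file.path(out_dir, "dispositions.csv"),
                   progress = FALSE)
  mr <- report$manual_review
  queue <- vapply(seq_len(nrow(mr)), function(i) {
    as.character(jsonlite::toJSON(
      list(couple_key = mr$couple_key[i], stage = mr$stage[i],
           reason = mr$reason[i], fields = mr$fields[[i]],
           suggested_action = mr$suggested_action[i]),
      auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(queue, file.path(out_dir, "manual_review.jsonl"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
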