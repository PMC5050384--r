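#' @keywords internal
empty_flags <- function() {
  tibble::tibble(scope = character(), key = character(), flag = character(),
                 severity = character(), raised = logical(),
                 evidence = character())
}

flag_row <- function(scope, key, flag, evidence, severity = "normal",
                     raised = TRUE) {
  tibble::tibble(scope = scope, key = key, flag = flag, severity = severity,
                 raised = raised, evidence = evidence)
}

# eligibility-relevant answers compared across repeat attempts from one IP
fishing_fields <- function() {
  c("self_sex", "self_age", "rel_length_months", "hiv_status",
    "cas_with_partner", "ipv_year", "sexual_agreement",
    "mobile_plus_internet")
}

#' Flag IP addresses appearing in multiple screener entries
#'
#' Raises `SAME_IP_MULTI_ENTRY` on every entry whose IP address occurs in
#' more than one entry. When an IP is shared only by the two members of one
#' linked couple the flag is raised at reduced severity — cohabiting partners
#' plausibly answer from the same computer — and reduced-severity flags never
#' count toward invalidation.
#'
#' @param entries A `screener_entries` tibble.
#' @param couples Optional couples tibble from [link_couples()]; used to
#'   recognize couple-internal IP sharing.
#' @return A flags tibble (`scope`, `key`, `flag`, `severity`, `raised`,
#'   `evidence`).
#' @export
flag_same_ip <- function(entries, couples = NULL) {
  ip <- entries$ip
  counts <- table(ip[!is.na(ip)])
  shared <- names(counts)[counts > 1]
  if (!length(shared)) return(empty_flags())
  couple_of <- character()
  if (!is.null(couples) && nrow(couples)) {
    couple_of <- stats::setNames(
      rep(couples$couple_key, 2), c(couples$id_a, couples$id_b))
  }
  out <- lapply(shared, function(addr) {
    ids <- entries$entry_id[!is.na(ip) & ip == addr]
    within_one_couple <- length(ids) == 2 &&
      all(ids %in% names(couple_of)) &&
      couple_of[[ids[1]]] == couple_of[[ids[2]]]
    if (within_one_couple) {
      flag_row("entry", ids, "SAME_IP_MULTI_ENTRY",
               sprintf("IP %s shared only by the two members of couple %s; possible cohabitation",
                       addr, couple_of[[ids[1]]]),
               severity = "reduced")
    } else {
      flag_row("entry", ids, "SAME_IP_MULTI_ENTRY",
               sprintf("IP %s seen in %d entries: %s", addr, length(ids),
                       paste(ids, collapse = ", ")))
    }
  })
  dplyr::bind_rows(out)
}

#' Flag eligibility fishing: repeat attempts with drifting answers
#'
#' Raises `ELIGIBILITY_FISHING` when one IP address carries two or more
#' entries whose eligibility-relevant answers differ across attempts —
#' the signature of someone re-taking the screener to discover the inclusion
#' criteria. Evidence lists the changed fields between consecutive attempts
#' in submission-time order. Two same-IP entries that form one linked couple
#' are exempt: two cohabiting partners are expected to differ.
#'
#' @param entries A `screener_entries` tibble.
#' @param couples Optional couples tibble, for the cohabitation exemption.
#' @return A flags tibble.
#' @export
flag_fishing <- function(entries, couples = NULL) {
  ip <- entries$ip
  counts <- table(ip[!is.na(ip)])
  shared <- names(counts)[counts > 1]
  if (!length(shared)) return(empty_flags())
  keys <- if (!is.null(couples)) couples$couple_key else character()
  out <- list()
  for (addr in shared) {
    idx <- which(!is.na(ip) & ip == addr)
    idx <- idx[order(entries$submitted_at[idx], entries$entry_id[idx])]
    ids <- entries$entry_id[idx]
    if (length(ids) == 2 && couple_key_of(ids[1], ids[2]) %in% keys) next
    drift <- character()
    for (k in seq_along(idx)[-1]) {
      prev <- entries[idx[k - 1], fishing_fields()]
      cur <- entries[idx[k], fishing_fields()]
      changed <- vapply(fishing_fields(), function(f) {
        !identical(prev[[f]], cur[[f]])
      }, logical(1))
      if (any(changed)) {
        drift <- c(drift, sprintf(
          "%s -> %s: %s", ids[k - 1], ids[k],
          paste(sprintf("%s %s->%s", fishing_fields()[changed],
                        format(unlist(prev[changed], use.names = FALSE)),
                        format(unlist(cur[changed], use.names = FALSE))),
                collapse = ", ")))
      }
    }
    if (length(drift)) {
      out[[addr]] <- flag_row("entry", ids, "ELIGIBILITY_FISHING",
                              sprintf("IP %s, %d attempts; %s", addr,
                                      length(ids),
                                      paste(drift, collapse = "; ")))
    }
  }
  dplyr::bind_rows(c(out, list(empty_flags())))
}

#' Flag sequential or near-identical email accounts within a couple
#'
#' Raises `SEQUENTIAL_EMAIL` on a couple when the two members' email stems
#' (local part with the trailing digit run stripped) are identical, at least
#' `cfg$email_stem_min_length` characters long, and the stripped digit runs
#' differ — the `kylemcap1`/`kylemcap2` pattern — or when the canonical local
#' parts are within edit distance 1 on the same domain after provider-alias
#' collapsing (dots and plus-tags on the configured alias domains).
#'
#' @param couples Couples tibble.
#' @param entries The `screener_entries` batch.
#' @param cfg A [rule_config()].
#' @return A flags tibble with `scope = "couple"`.
#' @export
flag_sequential_email <- function(couples, entries, cfg = rule_config()) {
  if (nrow(couples) == 0L) return(empty_flags())
  out <- list()
  for (k in seq_len(nrow(couples))) {
    ea <- normalize_email(entries$self_email[entries$entry_id == couples$id_a[k]])
    eb <- normalize_email(entries$self_email[entries$entry_id == couples$id_b[k]])
    if (!ea$conformant || !eb$conformant) next
    run_a <- substring(ea$local, nchar(ea$stem) + 1L)
    run_b <- substring(eb$local, nchar(eb$stem) + 1L)
    stem_route <- nzchar(ea$stem) && ea$stem == eb$stem &&
      nchar(ea$stem) >= cfg$email_stem_min_length && run_a != run_b
    la <- normalize_email(collapse_email_alias(ea$canonical, cfg$alias_domains))
    lb <- normalize_email(collapse_email_alias(eb$canonical, cfg$alias_domains))
    edit_route <- la$domain == lb$domain &&
      utils::adist(la$local, lb$local)[1, 1] <= 1
    if (stem_route || edit_route) {
      why <- if (stem_route) {
        sprintf("shared stem \"%s\" with differing digit runs (%s vs %s)",
                ea$stem, ifelse(nzchar(run_a), run_a, "<none>"),
                ifelse(nzchar(run_b), run_b, "<none>"))
      } else {
        sprintf("local parts \"%s\" and \"%s\" within edit distance 1 on %s",
                la$local, lb$local, la$domain)
      }
      out[[couples$couple_key[k]]] <- flag_row(
        "couple", couples$couple_key[k], "SEQUENTIAL_EMAIL",
        sprintf("%s vs %s: %s", ea$canonical, eb$canonical, why))
    }
  }
  dplyr::bind_rows(c(out, list(empty_flags())))
}

#' Flag female-typical given names in a male-only study
#'
#' Raises `NAME_SEX_MISMATCH` when an entry's given name (first name token)
#' exactly matches, case-insensitively, a name on the configured
#' female-typical list. The match is exact-token by construction: a listed
#' name that merely prefixes the given name never fires ("Heath" does not
#' match "Heather"), avoiding the known false positive. This flag is
#' advisory; it never invalidates a couple on its own.
#'
#' @param entries A `screener_entries` tibble.
#' @param cfg A [rule_config()].
#' @return A flags tibble with `scope = "entry"`.
#' @export
flag_name_sex <- function(entries, cfg = rule_config()) {
  if (nrow(entries) == 0L) return(empty_flags())
  nm <- entries$self_name
  given <- tolower(vapply(strsplit(ifelse(is.na(nm), "", nm), "[[:space:]-]+"),
                          function(x) if (length(x)) x[1] else "", character(1)))
  hit <- nzchar(given) & given %in% cfg$female_name_list
  if (!any(hit)) return(empty_flags())
  flag_row("entry", entries$entry_id[hit], "NAME_SEX_MISMATCH",
           sprintf("given name \"%s\" is on the female-typical name list",
                   given[hit]))
}

#' Proportion of identical aligned screener item responses
#'
#' Compares the 17 item responses of two entries position by position. Items
#' missing in either entry are excluded from both numerator and denominator;
#' with no comparable items the similarity is 0.
#'
#' @param a,b Single-row `screener_entries`.
#' @return A fraction in `[0, 1]`.
#' @export
response_similarity <- function(a, b) {
  ra <- unlist(a[, item_columns()], use.names = FALSE)
  rb <- unlist(b[, item_columns()], use.names = FALSE)
  ok <- !is.na(ra) & !is.na(rb)
  if (!any(ok)) return(0)
  mean(ra[ok] == rb[ok])
}

#' Flag back-to-back completions with near-identical responses
#'
#' Raises `BACK_TO_BACK` on a couple when the two submission instants differ
#' by an amount inside `cfg$back_to_back_window_minutes` (default 0–30
#' minutes, about one survey duration) *and* the response similarity is at
#' least `cfg$response_similarity_threshold`. A suspicious time gap alone
#' produces an evidence record with `raised = FALSE`, so reviewers still see
#' it, but it never enters the disposition.
#'
#' @param couples Couples tibble.
#' @param entries The `screener_entries` batch.
#' @param cfg A [rule_config()].
#' @return A flags tibble with `scope = "couple"`.
#' @export
flag_back_to_back <- function(couples, entries, cfg = rule_config()) {
  if (nrow(couples) == 0L) return(empty_flags())
  out <- list()
  for (k in seq_len(nrow(couples))) {
    a <- entries[entries$entry_id == couples$id_a[k], ]
    b <- entries[entries$entry_id == couples$id_b[k], ]
    if (is.na(a$submitted_at) || is.na(b$submitted_at)) next
    gap <- abs(as.numeric(difftime(a$submitted_at, b$submitted_at,
                                   units = "mins")))
    if (gap < cfg$back_to_back_window_minutes[1] ||
        gap > cfg$back_to_back_window_minutes[2]) next
    sim <- response_similarity(a, b)
    raised <- sim >= cfg$response_similarity_threshold
    out[[couples$couple_key[k]]] <- flag_row(
      "couple", couples$couple_key[k], "BACK_TO_BACK",
      sprintf("submissions %.1f min apart; response similarity %.2f%s",
              gap, sim,
              if (raised) "" else " (below threshold; time gap noted only)"),
      raised = raised)
  }
  dplyr::bind_rows(c(out, list(empty_flags())))
}

#' Flag duplicate couple enrollments
#'
#' Raises `DUPLICATE_COUPLE` on every couple whose unordered pair of
#' canonical self-reported email addresses recurs under a different referral
#' token (`couple_id`) — the same two emails enrolling as two different
#' couples. Evidence names all colliding couple IDs.
#'
#' @param couples Couples tibble.
#' @param entries The `screener_entries` batch.
#' @return A flags tibble with `scope = "couple"`.
#' @export
flag_duplicate_couple <- function(couples, entries) {
  if (nrow(couples) == 0L) return(empty_flags())
  canon <- stats::setNames(normalize_email(entries$self_email)$canonical,
                           entries$entry_id)
  pair <- vapply(seq_len(nrow(couples)), function(k) {
    e <- sort(c(canon[[couples$id_a[k]]], canon[[couples$id_b[k]]]))
    if (!all(nzchar(e))) return(NA_character_)
    paste(e, collapse = "|")
  }, character(1))
  tokens <- ifelse(is.na(couples$couple_id), couples$couple_key,
                   couples$couple_id)
  out <- list()
  for (p in unique(pair[!is.na(pair)])) {
    idx <- which(!is.na(pair) & pair == p)
    if (length(unique(tokens[idx])) < 2) next
    out[[p]] <- flag_row(
      "couple", couples$couple_key[idx], "DUPLICATE_COUPLE",
      sprintf("email pair %s enrolled under couple IDs: %s", p,
              paste(sort(unique(tokens[idx])), collapse = ", ")))
  }
  dplyr::bind_rows(c(out, list(empty_flags())))
}

#' Run all post hoc validation flags
#'
#' Applies every fraud heuristic — IP reuse, eligibility fishing, sequential
#' emails, name/sex mismatch, back-to-back completion and duplicate couples —
#' and returns one combined flags tibble.
#'
#' @param couples Couples tibble (typically the verified couples; entry-level
#'   heuristics always scan the whole batch).
#' @param entries The full `screener_entries` batch.
#' @param cfg A [rule_config()].
#' @return A flags tibble.
#' @export
validate_couples <- function(couples, entries, cfg = rule_config()) {
  dplyr::bind_rows(
    flag_same_ip(entries, couples),
    flag_fishing(entries, couples),
    flag_sequential_email(couples, entries, cfg),
    flag_name_sex(entries, cfg),
    flag_back_to_back(couples, entries, cfg),
    flag_duplicate_couple(couples, entries)
  )
}

# flags attributable to one couple: couple-scope rows keyed by couple_key
# plus entry-scope rows keyed by either member
couple_flags <- function(couple_key, id_a, id_b, flags) {
  flags[flags$raised &
          ((flags$scope == "couple" & flags$key == couple_key) |
             (flags$scope == "entry" & flags$key %in% c(id_a, id_b))), ]
}

#' Disposition of validated couples
#'
#' Converts each couple's raised flags into a disposition, never condemning
#' on a single criterion: no flags is `valid`; flags from at least
#' `cfg$invalidate_min_flag_categories` (default 2) distinct normal-severity
#' categories is `invalid`; anything else is `suspicious`. Multiple instances
#' of one flag count once, and reduced-severity flags (couple-internal IP
#' sharing) never count toward invalidation. Suspicious and invalid couples
#' receive a manual-review action item.
#'
#' @param couples Couples tibble.
#' @param flags Flags tibble from [validate_couples()].
#' @param cfg A [rule_config()].
#' @return A list with `dispositions` (tibble: `couple_key`, `status`,
#'   `n_flag_categories`, `triggering_flags` list column) and
#'   `manual_review` (tibble: `couple_key`, `reason`, `fields`,
#'   `suggested_action`).
#' @export
dispose <- function(couples, flags, cfg = rule_config()) {
  disp <- lapply(seq_len(nrow(couples)), function(k) {
    fl <- couple_flags(couples$couple_key[k], couples$id_a[k],
                       couples$id_b[k], flags)
    cats <- sort(unique(fl$flag))
    hard <- sort(unique(fl$flag[fl$severity == "normal"]))
    status <- if (!length(cats)) {
      "valid"
    } else if (length(hard) >= cfg$invalidate_min_flag_categories) {
      "invalid"
    } else {
      "suspicious"
    }
    tibble::tibble(couple_key = couples$couple_key[k], status = status,
                   n_flag_categories = length(cats),
                   triggering_flags = list(cats))
  })
  dispositions <- dplyr::bind_rows(c(disp, list(
    tibble::tibble(couple_key = character(), status = character(),
                   n_flag_categories = integer(), triggering_flags = list())
  )))
  needs_review <- dispositions[dispositions$status != "valid", ]
  manual_review <- tibble::tibble(
    couple_key = needs_review$couple_key,
    reason = sprintf("disposition %s (%d flag categories)",
                     needs_review$status, needs_review$n_flag_categories),
    fields = needs_review$triggering_flags,
    suggested_action = "call both individuals and verify specific screener answers by phone"
  )
  list(dispositions = dispositions, manual_review = manual_review)
}
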