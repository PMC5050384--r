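# Normalized contact fields for a batch of entries; "" means absent.
contact_fields <- function(entries) {
  tibble::tibble(
    entry_id = entries$entry_id,
    self_email = normalize_email(entries$self_email)$canonical,
    partner_email = normalize_email(entries$partner_email)$canonical,
    self_phone = normalize_phone(entries$self_phone)$digits,
    partner_phone = normalize_phone(entries$partner_phone)$digits
  )
}

# The four directed contact correspondences between entry rows i and j of a
# contact_fields() table: i's partner-reported contact vs j's self-reported
# contact and vice versa. Returns a named logical vector; NA when either side
# of a comparison is absent.
directed_contact_matches <- function(cf, i, j) {
  cmp <- function(x, y) {
    if (!nzchar(x) || !nzchar(y)) return(NA)
    x == y
  }
  c(
    a_partner_email_vs_b_self_email = cmp(cf$partner_email[i], cf$self_email[j]),
    b_partner_email_vs_a_self_email = cmp(cf$partner_email[j], cf$self_email[i]),
    a_partner_phone_vs_b_self_phone = cmp(cf$partner_phone[i], cf$self_phone[j]),
    b_partner_phone_vs_a_self_phone = cmp(cf$partner_phone[j], cf$self_phone[i])
  )
}

couple_key_of <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "|")
}

empty_couples <- function() {
  tibble::tibble(couple_key = character(), id_a = character(),
                 id_b = character(), couple_id = character(),
                 link_method = character(), contact_consistent = logical())
}

empty_unpaired <- function() {
  tibble::tibble(entry_id = character(), reason = character())
}

make_couples <- function(entries, ia, ib, couple_id, link_method) {
  if (!length(ia)) return(empty_couples())
  cf <- contact_fields(entries)
  id_a <- pmin(entries$entry_id[ia], entries$entry_id[ib])
  id_b <- pmax(entries$entry_id[ia], entries$entry_id[ib])
  consistent <- vapply(seq_along(ia), function(k) {
    m <- directed_contact_matches(cf, ia[k], ib[k])
    isTRUE(any(m, na.rm = TRUE))
  }, logical(1))
  out <- tibble::tibble(
    couple_key = couple_key_of(id_a, id_b),
    id_a = id_a, id_b = id_b,
    couple_id = couple_id,
    link_method = link_method,
    contact_consistent = consistent
  )
  out[order(out$id_a, out$id_b), ]
}

#' Link entries into candidate couples via the partner-referral token
#'
#' Entries sharing a `couple_id` referral token are paired. A token carried
#' by more or fewer than two entries is degenerate: all of its entries are
#' returned unpaired with the token multiplicity as the reason. Entries with
#' no token are returned unpaired so that [link_by_contact()] can try the
#' contact cross-reference fallback.
#'
#' @param entries A `screener_entries` tibble.
#' @return A list with `couples` (tibble: `couple_key`, `id_a`, `id_b`,
#'   `couple_id`, `link_method`, `contact_consistent`) and `unpaired`
#'   (tibble: `entry_id`, `reason`). `contact_consistent` is `TRUE` iff at
#'   least one partner-reported contact equals the other entry's
#'   self-reported contact after normalization.
#' @export
link_by_referral <- function(entries) {
  if (nrow(entries) == 0L) {
    return(list(couples = empty_couples(), unpaired = empty_unpaired()))
  }
  has_token <- !is.na(entries$couple_id)
  unpaired <- tibble::tibble(
    entry_id = entries$entry_id[!has_token],
    reason = rep("no referral token", sum(!has_token))
  )
  tok <- entries$couple_id[has_token]
  idx <- which(has_token)
  ia <- integer(); ib <- integer(); tok_ok <- character()
  for (t in sort(unique(tok))) {
    members <- idx[tok == t]
    if (length(members) == 2L) {
      ia <- c(ia, members[1]); ib <- c(ib, members[2]); tok_ok <- c(tok_ok, t)
    } else {
      unpaired <- dplyr::bind_rows(unpaired, tibble::tibble(
        entry_id = entries$entry_id[members],
        reason = sprintf("token multiplicity %d", length(members))
      ))
    }
  }
  couples <- make_couples(entries, ia, ib, tok_ok, "referral_token")
  unpaired <- unpaired[order(unpaired$entry_id), ]
  list(couples = couples, unpaired = unpaired)
}

#' Link unpaired entries by reciprocal contact cross-reference
#'
#' Entry A "claims" entry B when A's partner-reported email or phone equals
#' B's self-reported email or phone after normalization. A and B are paired
#' when they claim each other and neither is involved in any claim with a
#' third entry; any multi-way conflict leaves all involved entries unpaired
#' with reason `"ambiguous"` — ambiguity is never auto-resolved, mirroring
#' the manual phone-call fallback.
#'
#' @param entries A `screener_entries` tibble (typically the referral-token
#'   leftovers).
#' @return As [link_by_referral()]; `link_method` is `"contact_xref"` and
#'   `couple_id` is `NA`.
#' @export
link_by_contact <- function(entries) {
  n <- nrow(entries)
  if (n == 0L) {
    return(list(couples = empty_couples(), unpaired = empty_unpaired()))
  }
  cf <- contact_fields(entries)
  by_email <- lapply(cf$partner_email, function(k) {
    if (nzchar(k)) which(cf$self_email == k & nzchar(cf$self_email)) else integer()
  })
  by_phone <- lapply(cf$partner_phone, function(k) {
    if (nzchar(k)) which(cf$self_phone == k & nzchar(cf$self_phone)) else integer()
  })
  claims <- lapply(seq_len(n), function(i) {
    setdiff(sort(unique(c(by_email[[i]], by_phone[[i]]))), i)
  })
  neighbors <- lapply(seq_len(n), function(i) {
    inbound <- which(vapply(claims, function(cl) i %in% cl, logical(1)))
    sort(unique(c(claims[[i]], inbound)))
  })
  ia <- integer(); ib <- integer()
  for (i in seq_len(n)) {
    for (j in claims[[i]]) {
      if (j > i && i %in% claims[[j]] &&
          identical(neighbors[[i]], j) && identical(neighbors[[j]], i)) {
        ia <- c(ia, i); ib <- c(ib, j)
      }
    }
  }
  paired <- c(ia, ib)
  leftover <- setdiff(which(lengths(neighbors) > 0), paired)
  no_contact <- setdiff(seq_len(n), c(paired, leftover))
  reason <- vapply(leftover, function(i) {
    conflicted <- length(neighbors[[i]]) > 1 ||
      any(lengths(neighbors[neighbors[[i]]]) > 1)
    if (conflicted) "ambiguous" else "no reciprocal contact link"
  }, character(1))
  unpaired <- dplyr::bind_rows(
    tibble::tibble(entry_id = entries$entry_id[leftover], reason = reason),
    tibble::tibble(entry_id = entries$entry_id[no_contact],
                   reason = rep("no contact cross-reference", length(no_contact)))
  )
  couples <- make_couples(entries, ia, ib, NA_character_, "contact_xref")
  unpaired <- unpaired[order(unpaired$entry_id), ]
  list(couples = couples, unpaired = unpaired)
}

#' Link a batch of entries into candidate couples
#'
#' Referral-token linkage first (the token encodes the study's own referral
#' flow), then reciprocal contact cross-reference on the entries that carried
#' no token. Entries under a degenerate token stay unpaired for manual
#' review.
#'
#' @inheritParams link_by_referral
#' @return As [link_by_referral()].
#' @export
link_couples <- function(entries) {
  ref <- link_by_referral(entries)
  retry_ids <- ref$unpaired$entry_id[ref$unpaired$reason == "no referral token"]
  rest <- ref$unpaired[ref$unpaired$reason != "no referral token", ]
  con <- link_by_contact(entries[entries$entry_id %in% retry_ids, ])
  couples <- dplyr::bind_rows(ref$couples, con$couples)
  couples <- couples[order(couples$id_a, couples$id_b), ]
  unpaired <- dplyr::bind_rows(rest, con$unpaired)
  unpaired <- unpaired[order(unpaired$entry_id), ]
  list(couples = couples, unpaired = unpaired)
}

#' Route couples with mismatched contact information to manual review
#'
#' A couple whose two entries disagree on the partner-reported contact
#' details is only "partially matched": it requires manual verification by
#' contacting the potential participants. The action item names the
#' mismatched correspondences.
#'
#' @param couples Couples tibble from [link_couples()].
#' @param entries The `screener_entries` the couples were linked from.
#' @return A list with `auto` (couples proceeding automatically) and
#'   `manual_review` (tibble: `couple_key`, `reason`, `fields`,
#'   `suggested_action`).
#' @export
route_partial_matches <- function(couples, entries) {
  manual_idx <- which(!couples$contact_consistent)
  if (!length(manual_idx)) {
    return(list(auto = couples,
                manual_review = tibble::tibble(couple_key = character(),
                                               reason = character(),
                                               fields = list(),
                                               suggested_action = character())))
  }
  cf <- contact_fields(entries)
  pos <- match(c(couples$id_a, couples$id_b), cf$entry_id)
  pa <- pos[seq_len(nrow(couples))]
  pb <- pos[nrow(couples) + seq_len(nrow(couples))]
  fields <- lapply(manual_idx, function(k) {
    m <- directed_contact_matches(cf, pa[k], pb[k])
    names(m)[is.na(m) | !m]
  })
  manual <- tibble::tibble(
    couple_key = couples$couple_key[manual_idx],
    reason = "contact information mismatch (partially matched)",
    fields = fields,
    suggested_action = "contact both potential participants to verify partner details"
  )
  list(auto = couples[-manual_idx, ], manual_review = manual)
}
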