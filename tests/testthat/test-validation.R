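test_that("an IP recurring across unrelated entries flags every entry, with the count", {
  entries <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_entry(entry_id = paste0("E", i), ip = "198.51.100.7",
               self_email = sprintf("u%d@x.org", i))
  }))
  flags <- flag_same_ip(entries)
  expect_equal(nrow(flags), 5)
  expect_true(all(flags$flag == "SAME_IP_MULTI_ENTRY"))
  expect_true(all(flags$severity == "normal"))
  expect_match(flags$evidence[1], "5 entries")
})

test_that("an IP shared only within one linked couple is reduced severity", {
  entries <- make_couple("A", "B", couple_id = "5000AA")
  entries$ip <- "203.0.113.9"
  couples <- link_couples(entries)$couples
  flags <- flag_same_ip(entries, couples)
  expect_equal(nrow(flags), 2)
  expect_true(all(flags$severity == "reduced"))
  expect_match(flags$evidence[1], "cohabitation")

  distinct <- make_couple("C", "D", couple_id = "5001BB")
  expect_equal(nrow(flag_same_ip(distinct)), 0)
})

test_that("eligibility fishing requires answer drift, not mere IP reuse", {
  drift <- dplyr::bind_rows(
    make_entry(entry_id = "F1", ip = "10.7.0.1", rel_length_months = 5L,
               submitted_at = as.POSIXct("2016-01-01 10:00:00", tz = "UTC")),
    make_entry(entry_id = "F2", ip = "10.7.0.1", rel_length_months = 7L,
               submitted_at = as.POSIXct("2016-01-01 11:00:00", tz = "UTC"))
  )
  flags <- flag_fishing(drift)
  expect_equal(sort(unique(flags$flag)), "ELIGIBILITY_FISHING")
  expect_match(flags$evidence[1], "rel_length_months 5->7")

  same <- drift
  same$rel_length_months <- 7L
  expect_equal(nrow(flag_fishing(same)), 0)
  all_ip_flags <- flag_same_ip(same)
  expect_equal(sort(unique(all_ip_flags$flag)), "SAME_IP_MULTI_ENTRY")

  singles <- make_entry(entry_id = "S1", ip = "10.8.0.1")
  expect_equal(nrow(flag_fishing(singles)), 0)
})

test_that("sequential email stems flag a couple; unrelated or short stems do not", {
  cfg <- rule_config()
  seqc <- make_couple("K1", "K2",
                      a = list(self_email = "kylemcap1@gmail.com",
                               partner_email = "kylemcap2@gmail.com"),
                      b = list(self_email = "kylemcap2@gmail.com",
                               partner_email = "kylemcap1@gmail.com"))
  couples <- link_couples(seqc)$couples
  flags <- flag_sequential_email(couples, seqc, cfg)
  expect_equal(flags$flag, "SEQUENTIAL_EMAIL")
  expect_match(flags$evidence, "kylemcap")

  unrelated <- make_couple("J1", "J2",
                           a = list(self_email = "jsmith@x.org",
                                    partner_email = "asmith@y.org"),
                           b = list(self_email = "asmith@y.org",
                                    partner_email = "jsmith@x.org"))
  expect_equal(nrow(flag_sequential_email(link_couples(unrelated)$couples,
                                          unrelated, cfg)), 0)

  short_stem <- make_couple("T1", "T2",
                            a = list(self_email = "abc12@x.org",
                                     partner_email = "abc34@x.org"),
                            b = list(self_email = "abc34@x.org",
                                     partner_email = "abc12@x.org"))
  expect_equal(nrow(flag_sequential_email(link_couples(short_stem)$couples,
                                          short_stem, cfg)), 0)
})

test_that("provider-alias collapsing catches dot and plus-tag evasion on alias domains", {
  cfg <- rule_config()
  aliased <- make_couple("G1", "G2",
                         a = list(self_email = "ky.lemcap@gmail.com",
                                  partner_email = "kylemcap+x@gmail.com"),
                         b = list(self_email = "kylemcap+x@gmail.com",
                                  partner_email = "ky.lemcap@gmail.com"))
  flags <- flag_sequential_email(link_couples(aliased)$couples, aliased, cfg)
  expect_equal(flags$flag, "SEQUENTIAL_EMAIL")
  # the same pattern on a non-alias domain keeps the dots and does not fire
  plain <- make_couple("P1", "P2",
                       a = list(self_email = "ky.lemcap@example.com",
                                partner_email = "kylemcap+x@example.com"),
                       b = list(self_email = "kylemcap+x@example.com",
                                partner_email = "ky.lemcap@example.com"))
  expect_equal(nrow(flag_sequential_email(link_couples(plain)$couples,
                                          plain, cfg)), 0)
})

test_that("female-typical names flag on exact token only; prefixes never fire", {
  cfg <- rule_config()
  entries <- dplyr::bind_rows(
    make_entry(entry_id = "N1", self_name = "Melissa Wise"),
    make_entry(entry_id = "N2", self_name = "Heath Brown"),
    make_entry(entry_id = "N3", self_name = ""),
    make_entry(entry_id = "N4", self_name = "heather green")
  )
  flags <- flag_name_sex(entries, cfg)
  expect_setequal(flags$key, c("N1", "N4"))
  expect_true(all(flags$flag == "NAME_SEX_MISMATCH"))
})

test_that("response similarity excludes missing items and handles no overlap", {
  a <- make_entry(entry_id = "A")
  b <- make_entry(entry_id = "B")
  expect_equal(response_similarity(a, b), 1.0)

  b2 <- b
  b2$q01 <- "b"; b2$q02 <- "c"
  expect_equal(response_similarity(a, b2), 15 / 17)

  a3 <- a; b3 <- b
  for (q in sprintf("q%02d", 1:8)) a3[[q]] <- NA_character_
  for (q in sprintf("q%02d", 9:17)) b3[[q]] <- NA_character_
  expect_equal(response_similarity(a3, b3), 0)

  a4 <- a
  a4$q01 <- NA_character_
  b4 <- b
  b4$q02 <- "z"
  expect_equal(response_similarity(a4, b4), 15 / 16)
})

test_that("back-to-back needs both the time window and elevated similarity", {
  cfg <- rule_config()
  base <- as.POSIXct("2016-01-01 10:00:00", tz = "UTC")
  twin <- make_couple("B1", "B2", gap_min = 25,
                      b = as.list(stats::setNames(rep("a", 17),
                                                  sprintf("q%02d", 1:17))))
  couples <- link_couples(twin)$couples
  flags <- flag_back_to_back(couples, twin, cfg)
  expect_true(flags$raised)
  expect_match(flags$evidence, "25.0 min")

  dissimilar <- make_couple("C1", "C2", gap_min = 25)
  for (q in sprintf("q%02d", 1:10)) dissimilar[[q]][2] <- "z"
  fl2 <- flag_back_to_back(link_couples(dissimilar)$couples, dissimilar, cfg)
  expect_equal(nrow(fl2), 1)
  expect_false(fl2$raised)
  expect_match(fl2$evidence, "below threshold")

  apart <- make_couple("D1", "D2", gap_min = 3 * 24 * 60,
                       b = as.list(stats::setNames(rep("a", 17),
                                                   sprintf("q%02d", 1:17))))
  expect_equal(nrow(flag_back_to_back(link_couples(apart)$couples, apart, cfg)), 0)
})

test_that("a recurring email pair under different couple IDs flags every enrollment", {
  batch <- dplyr::bind_rows(
    make_couple("D1", "D2", couple_id = "2452EW",
                a = list(self_email = "dupa@x.org", partner_email = "dupb@y.org"),
                b = list(self_email = "dupb@y.org", partner_email = "dupa@x.org")),
    make_couple("D3", "D4", couple_id = "2864OD",
                a = list(self_email = "dupa@x.org", partner_email = "dupb@y.org"),
                b = list(self_email = "dupb@y.org", partner_email = "dupa@x.org")),
    make_couple("E1", "E2", couple_id = "7777ZZ")
  )
  couples <- link_couples(batch)$couples
  flags <- flag_duplicate_couple(couples, batch)
  expect_setequal(flags$key, c("D1|D2", "D3|D4"))
  expect_true(all(grepl("2452EW", flags$evidence)))
  expect_true(all(grepl("2864OD", flags$evidence)))

  three <- dplyr::bind_rows(batch[1:8, ],
    make_couple("D5", "D6", couple_id = "9100QQ",
                a = list(self_email = "dupa@x.org", partner_email = "dupb@y.org"),
                b = list(self_email = "dupb@y.org", partner_email = "dupa@x.org")))
  fl3 <- flag_duplicate_couple(link_couples(three)$couples, three)
  expect_setequal(fl3$key, c("D1|D2", "D3|D4", "D5|D6"))
  expect_true(all(grepl("9100QQ", fl3$evidence)))
})

test_that("every raised flag carries non-empty evidence", {
  cohort <- generate_cohort(cohort_spec(n_true_couples = 5, n_self_pairs = 2,
                                        n_fishers = 2, n_duplicate_couples = 1,
                                        n_female_names = 1, seed = 21))
  linked <- link_couples(cohort$entries)
  flags <- validate_couples(linked$couples, cohort$entries)
  expect_gt(nrow(flags), 0)
  expect_true(all(nzchar(flags$evidence)))
})

test_that("disposition follows the category-count rule over all flag subsets", {
  cfg <- rule_config()
  all_flags <- c("SAME_IP_MULTI_ENTRY", "ELIGIBILITY_FISHING",
                 "SEQUENTIAL_EMAIL", "NAME_SEX_MISMATCH", "BACK_TO_BACK",
                 "RESPONSE_SIMILARITY", "DUPLICATE_COUPLE")
  couples <- tibble::tibble(couple_key = "A|B", id_a = "A", id_b = "B",
                            couple_id = "1000AA",
                            link_method = "referral_token",
                            contact_consistent = TRUE)
  for (mask in 0:(2^7 - 1)) {
    subset <- all_flags[bitwAnd(mask, 2^(0:6)) > 0]
    flags <- if (length(subset)) {
      dplyr::bind_rows(lapply(subset, function(f) {
        tibble::tibble(scope = "couple", key = "A|B", flag = f,
                       severity = "normal", raised = TRUE, evidence = f)
      }))
    } else {
      validate_couples(couples[0, ], make_couple("A", "B")[0, ], cfg)
    }
    status <- dispose(couples, flags, cfg)$dispositions$status
    oracle <- if (length(subset) == 0) "valid" else
      if (length(subset) >= cfg$invalidate_min_flag_categories) "invalid" else
        "suspicious"
    expect_equal(status, oracle, info = paste(subset, collapse = "+"))
  }
})

test_that("duplicate flag instances count once and reduced severity never invalidates", {
  cfg <- rule_config()
  couples <- tibble::tibble(couple_key = "A|B", id_a = "A", id_b = "B",
                            couple_id = "1000AA",
                            link_method = "referral_token",
                            contact_consistent = TRUE)
  doubled <- dplyr::bind_rows(
    tibble::tibble(scope = "entry", key = c("A", "B"),
                   flag = "SAME_IP_MULTI_ENTRY", severity = "normal",
                   raised = TRUE, evidence = "ip")
  )
  expect_equal(dispose(couples, doubled, cfg)$dispositions$status, "suspicious")

  reduced_plus_one <- dplyr::bind_rows(
    tibble::tibble(scope = "entry", key = c("A", "B"),
                   flag = "SAME_IP_MULTI_ENTRY", severity = "reduced",
                   raised = TRUE, evidence = "cohab ip"),
    tibble::tibble(scope = "couple", key = "A|B", flag = "SEQUENTIAL_EMAIL",
                   severity = "normal", raised = TRUE, evidence = "seq")
  )
  res <- dispose(couples, reduced_plus_one, cfg)
  expect_equal(res$dispositions$status, "suspicious")
  expect_match(res$manual_review$suggested_action, "phone")

  # identical flag sets always yield identical status
  expect_equal(dispose(couples, reduced_plus_one, cfg)$dispositions,
               res$dispositions)
})

test_that("adding entries to a batch never removes previously raised flags", {
  cohort <- generate_cohort(cohort_spec(n_true_couples = 4, n_self_pairs = 2,
                                        n_fishers = 1, seed = 31))
  entries <- cohort$entries
  linked <- link_couples(entries)
  before <- validate_couples(linked$couples, entries)
  more <- make_couple("Z8", "Z9", couple_id = "9999ZY")
  grown <- dplyr::bind_rows(entries, more)
  linked2 <- link_couples(grown)
  after <- validate_couples(linked2$couples, grown)
  key <- function(f) paste(f$scope, f$key, f$flag)
  expect_true(all(key(before[before$raised, ]) %in% key(after[after$raised, ])))
})
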