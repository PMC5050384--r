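couple_ab <- function(a = list(), b = list()) {
  entries <- make_couple("A", "B", a = a, b = b)
  list(a = entries[1, ], b = entries[2, ])
}

test_that("relationship-length concordance cuts exactly at the 1-month margin", {
  cfg <- rule_config()
  for (offset in 0:3) {
    p <- couple_ab(b = list(rel_length_months = 18L + offset))
    expected <- if (offset <= cfg$rel_length_tolerance_months)
      "concordant" else "discordant"
    expect_equal(rule_rel_length(p$a, p$b, cfg), expected,
                 info = paste("offset", offset))
  }
  p <- couple_ab(b = list(rel_length_months = NA_integer_))
  expect_equal(rule_rel_length(p$a, p$b, cfg), "missing")
})

test_that("birthday months must match exactly in both directions", {
  p <- couple_ab()
  expect_equal(rule_birth_month(p$a, p$b), "concordant")
  for (delta in 1:11) {
    shifted <- couple_ab(b = list(partner_birth_month = ((3L + delta - 1L) %% 12L) + 1L))
    expect_equal(rule_birth_month(shifted$a, shifted$b), "discordant",
                 info = paste("delta", delta))
  }
  missing <- couple_ab(b = list(partner_birth_month = NA_integer_))
  expect_equal(rule_birth_month(missing$a, missing$b), "missing")
})

test_that("age concordance cuts exactly at the 1-year margin, both directions", {
  cfg <- rule_config()
  for (offset in 0:3) {
    p <- couple_ab(b = list(partner_age = 29L + offset))
    expected <- if (offset <= cfg$age_tolerance_years) "concordant" else "discordant"
    expect_equal(rule_age(p$a, p$b, cfg), expected, info = paste("b->a", offset))
    q <- couple_ab(a = list(partner_age = 31L + offset))
    expect_equal(rule_age(q$a, q$b, cfg), expected, info = paste("a->b", offset))
  }
})

test_that("one matching contact in any direction suffices; case is folded", {
  cfg <- rule_config()
  # phone matches one direction, emails absent everywhere
  p <- couple_ab(
    a = list(self_email = NA_character_, partner_email = NA_character_),
    b = list(self_email = NA_character_, partner_email = NA_character_,
             partner_phone = NA_character_))
  expect_equal(rule_contact(p$a, p$b, cfg), "concordant")

  q <- couple_ab(a = list(partner_email = "KyleM@x.com",
                          partner_phone = NA_character_),
                 b = list(self_email = "kylem@x.com",
                          partner_email = "zz@zz.org",
                          partner_phone = NA_character_,
                          self_phone = NA_character_))
  expect_equal(rule_contact(q$a, q$b, cfg), "concordant")

  r <- couple_ab(a = list(partner_email = "w1@x.com", partner_phone = "3055551111"),
                 b = list(partner_email = "w2@x.com", partner_phone = "3055552222"))
  expect_equal(rule_contact(r$a, r$b, cfg), "discordant")

  s <- couple_ab(
    a = list(self_email = NA_character_, partner_email = NA_character_,
             self_phone = NA_character_, partner_phone = NA_character_),
    b = list(self_email = NA_character_, partner_email = NA_character_,
             self_phone = NA_character_, partner_phone = NA_character_))
  expect_equal(rule_contact(s$a, s$b, cfg), "missing")
})

test_that("classification follows the all-4 / 2-3 / otherwise thresholds over all 81 vectors", {
  cfg <- rule_config()
  grid <- expand.grid(R1 = c("concordant", "discordant", "missing"),
                      R2 = c("concordant", "discordant", "missing"),
                      R3 = c("concordant", "discordant", "missing"),
                      R4 = c("concordant", "discordant", "missing"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 81)
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, ])
    n <- sum(v == "concordant")
    oracle <- if (n == 4) "verified" else if (n %in% 2:3)
      "partially_verified" else "unverified"
    expect_equal(classify_verification(v, cfg), oracle,
                 info = paste(v, collapse = ","))
  }
})

test_that("verify_couple is symmetric and aggregates rule outcomes", {
  p <- couple_ab(b = list(rel_length_months = 25L,
                          partner_birth_month = 4L))
  ab <- verify_couple(p$a, p$b)
  ba <- verify_couple(p$b, p$a)
  expect_equal(ab, ba)
  expect_equal(ab$R1_rel_length, "discordant")
  expect_equal(ab$R2_birth_month, "discordant")
  expect_equal(ab$n_concordant, 2L)
  expect_equal(ab$classification, "partially_verified")

  all4 <- couple_ab()
  expect_equal(verify_couple(all4$a, all4$b)$classification, "verified")

  withr::local_seed(7)
  for (i in 1:20) {
    tweaks <- list(
      rel_length_months = sample(c(18L, 20L, NA), 1),
      partner_age = sample(c(29L, 33L), 1),
      partner_birth_month = sample(c(3L, 7L, NA), 1),
      partner_email = sample(c("alan.a@example.com", "x@y.org"), 1)
    )
    q <- couple_ab(b = tweaks)
    expect_equal(verify_couple(q$a, q$b), verify_couple(q$b, q$a))
  }
})

test_that("tightening a tolerance never converts discordant to concordant", {
  loose <- rule_config(rel_length_tolerance_months = 3, age_tolerance_years = 3)
  tight <- rule_config(rel_length_tolerance_months = 0, age_tolerance_years = 0)
  for (offset in 0:5) {
    p <- couple_ab(b = list(rel_length_months = 18L + offset,
                            partner_age = 29L + offset))
    for (rule in list(rule_rel_length, rule_age)) {
      if (rule(p$a, p$b, loose) == "discordant") {
        expect_equal(rule(p$a, p$b, tight), "discordant")
      }
    }
  }
})

test_that("missing counts as not-concordant toward classification", {
  p <- couple_ab(b = list(rel_length_months = NA_integer_))
  res <- verify_couple(p$a, p$b)
  expect_equal(res$R1_rel_length, "missing")
  expect_equal(res$n_concordant, 3L)
  expect_equal(res$classification, "partially_verified")
})
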