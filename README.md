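# dyadscreen

Data-quality tooling for couple-based studies that recruit online.

Studies that enroll **both members of a couple** through a web eligibility
screener face two data-integrity questions that individual-level studies do
not:

1. **Verification** — do these two screener entries really describe two
   people in a relationship with each other?
2. **Validation** — do the two entries come from two *unique individuals*,
   or did one person fill in the screener twice to pose as a couple?

`dyadscreen` implements a deterministic, rule-based pipeline for both
questions, aimed at study coordinators and data managers running dyadic
online recruitment (for example couple-based HIV-prevention trials
recruiting male couples through social-media advertising). It takes a CSV
export of screener entries and produces classifications, fraud flags,
dispositions and a manual-review queue.

## The rules at its core

**Eligibility.** Eight individual criteria (`E1`–`E8`) gate everything
else: male self-report, age ≥ 18, relationship ≥ 6 months, HIV-negative
self-report, condomless anal sex with the main partner, no intimate partner
violence in the past year, no established sexual agreement, and mobile
phone plus alternate internet access. A couple is eligible only if both
members are.

**Linkage.** Entries are paired by a partner-referral token (`couple_id`);
entries without a token are paired by reciprocal contact cross-reference
(A names B's email/phone and B names A's). Ambiguous multi-way claims are
never auto-resolved — they go to manual review.

**Verification.** Four concordance rules over independently reported facts:

| rule | concordant when |
|---|---|
| R1 relationship length | \|len_A − len_B\| ≤ 1 month |
| R2 birthday months | exact cross-match, both directions |
| R3 ages | \|self − partner-reported\| ≤ 1 year, both directions |
| R4 contact info | ≥ 1 of 4 partner↔self email/phone correspondences exact |

With *n* the number of concordant rules: *n* = 4 → **verified**,
*n* ∈ {2, 3} → **partially verified** (second assessment by phone/email),
otherwise **unverified**.

**Validation.** Post hoc fraud flags on verified couples:
`SAME_IP_MULTI_ENTRY`, `ELIGIBILITY_FISHING` (repeat same-IP attempts with
answers drifting toward passing), `SEQUENTIAL_EMAIL`
(`kylemcap1@…`/`kylemcap2@…` stems), `NAME_SEX_MISMATCH` (exact-token
female-typical name match, so "Heath" never trips on "Heather"),
`BACK_TO_BACK` (submissions ≤ 30 min apart **and** ≥ 90 % identical item
responses), `DUPLICATE_COUPLE` (one email pair under two couple IDs).
Dispositions never condemn on a single criterion: no flags → **valid**, one
flag category → **suspicious** (manual review), ≥ 2 categories →
**invalid**. An IP shared only within one couple is reduced severity —
cohabiting partners share computers.

## Worked example

```r
library(dyadscreen)

spec <- cohort_spec(n_true_couples = 6, n_self_pairs = 2, n_fishers = 1,
                    n_duplicate_couples = 1, seed = 42)
cohort <- generate_cohort(spec)     # labeled synthetic screener entries
report <- run_pipeline(cohort$entries)
print(report)
```

```
== pipeline report ==
loaded                 22
rejected               0
eligible_individuals   21
unpaired               2
candidate_couples      10
ineligible_couples     0
verified               10
partially_verified     0
unverified             0
valid                  6
suspicious             2
invalid                2

manual review queue (4 items):
  [validation] E00013|E00014: disposition invalid (3 flag categories) (BACK_TO_BACK, SAME_IP_MULTI_ENTRY, SEQUENTIAL_EMAIL) -> ...
  [validation] E00015|E00016: disposition invalid (3 flag categories) (BACK_TO_BACK, SAME_IP_MULTI_ENTRY, SEQUENTIAL_EMAIL) -> ...
  [validation] E00019|E00020: disposition suspicious (1 flag categories) (DUPLICATE_COUPLE) -> ...
  [validation] E00021|E00022: disposition suspicious (1 flag categories) (DUPLICATE_COUPLE) -> ...
```

Reading the numbers: 22 entries load (6 honest couples, 2 self-pairs, 1
fisher with 2 attempts, 1 duplicate enrollment = 2 couples). The fisher's
two attempts never pair (`unpaired 2`); all 10 linked couples satisfy the
four concordance rules (internally consistent fabrications *pass*
verification — that is exactly why post hoc validation exists). Validation
then separates them: the 6 honest couples are valid, both self-pairs are
invalid on three independent flag categories, and both halves of the
duplicate enrollment are suspicious on one category, queued for a phone
call rather than auto-rejected.

The same stages are exposed individually (`read_entries()`,
`assess_individual()`, `link_couples()`, `verify_couples()`,
`validate_couples()`, `dispose()`), and a thin CLI wraps them:

```sh
exec/dyadscreen simulate --spec cohort.json --out-dir sim/
exec/dyadscreen report --in sim/entries.csv --out-dir out/ --format text
```

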