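---
title: "Verifying and validating dyadic screener data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying and validating dyadic screener data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadscreen)
```

## The problem

Couple-based online studies collect one screener entry per partner and must
decide, before enrollment, (a) whether two entries describe a genuine
relationship and (b) whether they come from two unique people. Financial
incentives attract fabricated "couples": one actor answering the screener
twice with consistent invented details, re-taking it to learn the inclusion
criteria, or re-enrolling the same pair under a new referral ID. Because a
careful fabricator produces *internally concordant* answers, relationship
verification and uniqueness validation are different problems and are run
as separate stages here, validation deliberately after verification: only
couples worth enrolling are worth the per-couple fraud review.

## Pipeline model

Stages run strictly in order: load → individual eligibility → linkage →
verification → validation → disposition. Every stage is a pure function of
its inputs and the rule configuration, so identical inputs give identical
reports (timestamps live in an excluded metadata field), and each loaded
entry ends in exactly one terminal bucket — unpaired, member of an
ineligible couple, or member of a couple classified verified / partially
verified / unverified. That conservation property is asserted on every run.

### Eligibility

Eight boolean criteria (`E1`–`E8`), each fed by one field. All failures are
reported, not just the first, and a missing field fails its criterion
*conservatively* while being listed separately in `missing_criteria`:
reviewers can distinguish "said no" from "said nothing". IPV exposure is
one boolean by design; multi-item violence scales are out of scope. The
applied criterion set is configurable (`eligibility_criteria`) because
screening instruments evolve between study phases — a developmental phase
and a trial phase may use different subsets of the same screener.

### Linkage

The referral token is trusted over contact cross-reference because it is
generated by the study's own referral flow, while self-typed contact
details are noisy. Tokens with a multiplicity other than two are degenerate
and never guessed about. The contact fallback pairs A and B only when the
claims are *reciprocal* and *exclusive*: any third entry claiming either
member makes the whole conflict set "ambiguous" and routes it to manual
review. We never resolve ambiguity by a best-similarity heuristic — the
operational fallback is a phone call, so the software's job is to queue it,
not to gamble. Report ordering is made deterministic by sorting couples on
the lexicographically smaller entry ID.

### Verification rules

Relationship length concordance uses a ±1 month margin; ages ±1 year in
both reporting directions; birthday months must match exactly in both
directions; contact information requires at least one exact correspondence
among the four directed email/phone comparisons. Lengths are compared in
whole months (sub-month precision is truncated at load) since the margin
itself is stated in months. Email comparison for this rule is exact on the
canonical (lowercased, trimmed) form: verification is an exact-match
contract, so provider aliasing (gmail dots, plus-tags) is *not* collapsed
here. Missing values are scored not-concordant for classification but kept
as a distinct outcome in reports.

The classification thresholds (4 concordant → verified, 2–3 → partially
verified with a second assessment, otherwise unverified) are configuration,
not code, so a stricter or looser scheme remains expressible. The
disposition of "sexual agreement" is an eligibility criterion (`E7`), not a
fifth concordance rule; a custom concordance rule can be emulated by
tightening `verified_min_rules` against a config with modified tolerances.

### Validation flags and disposition

Seven named flags, each carrying human-readable evidence. Design points
that were genuinely open:

* **Back-to-back completions** require the *conjunction* of a suspicious
  submission gap (default window 0–30 minutes, about one survey duration)
  and elevated response similarity. A timing coincidence alone is recorded
  as evidence (`raised = FALSE`) but never disposes a couple. The
  similarity threshold (default 0.90 of aligned items identical, missing
  items excluded pairwise) is an operating point we chose, exposed in the
  configuration; the field reports the signal qualitatively and gives no
  number.
* **Sequential emails** fire on a shared local-part stem (trailing digit
  run stripped, stem at least 4 characters) with differing digit runs, or
  on same-domain local parts within edit distance 1 *after* provider-alias
  collapsing. Alias collapsing is used only inside this fraud heuristic —
  fraud detection hunts for evasion, verification does not.
* **Name/sex mismatch** is an exact, case-insensitive token match of the
  given name against a replaceable packaged list of female-typical names.
  Exact-token matching avoids by construction the known false positive of a
  prefix collision (a man named Heath flagged because Heather is listed).
  The flag is always advisory.
* **Eligibility fishing** compares eligibility-relevant answers across
  same-IP attempts in time order. Two same-IP entries that form one linked
  couple are exempt: two cohabiting partners legitimately differ, and their
  shared IP is instead flagged at reduced severity.
* **Disposition** implements "multiple criteria as a whole": valid with no
  flags, invalid only with at least two distinct normal-severity flag
  categories (multiple instances of one flag count once; reduced-severity
  flags never count toward invalidation), suspicious otherwise. Suspicious
  and invalid couples become manual-review action items — the pipeline
  emits the phone-call task, it never executes it.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the pipeline is designed
for: honest couples whose cross-reports are consistent by construction,
plus the three fraud archetypes with the signatures that define them
(self-pairs: shared IP, `stem1`/`stem2` gmail addresses, submissions 20–30
minutes apart, identical item responses; fishers: one IP, one identity,
relationship length drifting from below 6 months to 7 across attempts;
duplicates: one email pair under two referral tokens). Honest attribute
distributions are desk-scale choices — ages uniform 18–70, relationship
length log-uniform 6–240 months, item responses uniform over four
categories, partner submissions 1 hour to 2 days apart — documented here
and irrelevant to rule correctness. `p_report_noise` is the probability
that an honest partner misreports one verification field beyond its
tolerance, which is the only mechanism by which an honest couple can lose
verified status; fraud signatures are constructed directly and cannot
disappear under noise.

What the generator does *not* emulate: realistic demographic marginals,
correlated item responses, device fingerprints, geolocation, or base rates
of fraud (none are published; cohort mixes are user-chosen). Passing the
parameter-recovery tests therefore shows the rules fire exactly on their
defining signatures, not that real-world fraud prevalence or subtler
fabrication strategies would be caught.

## Numerical and procedural choices

* Timestamps are stored as UTC instants; the loader accepts a source
  timezone (default UTC) since screener platforms rarely document one.
* Phone normalization keeps digits only, reduces a leading `1` on 11-digit
  numbers to the trailing 10 (a North-American assumption, stated as such),
  and treats fewer than 7 digits as absent-for-matching.
* Degenerate inputs are total-function territory: malformed emails
  normalize to a non-conformant canonical form, empty batches flow through
  every stage, and row-level invariant violations become a rejects table
  with reasons, never silent drops.
* Test problem sizes: the matching oracle compares indexed linkage against
  exhaustive pair enumeration on 50 random batches of 20–200 entries;
  parameter recovery uses ten seeds of 142-entry cohorts (50 honest
  couples, 10 self-pairs, 5 two-attempt fishers, 3 duplicate enrollments).
  These sizes exercise every code path while keeping the default suite
  fast.

## Known limitations

The pipeline is deterministic and rule-based by design — no probabilistic
record-linkage scores — because its operational endpoint is a human
phone-call queue, not an automated rejection. IPs are compared as opaque
strings (no subnet or NAT reasoning). The female-typical name list ships as
a small replaceable text file and is inherently incomplete. Whether a
respondent could legitimately appear under two referral tokens
(re-screening) is not modeled beyond entry-ID uniqueness at load.
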