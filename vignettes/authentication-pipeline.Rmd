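---
title: "Authenticating web-enrolled participants: models, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating web-enrolled participants: models, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(authsieve)
```

## The problem and the model

A fully web-based trial never meets its participants. Between the
moment someone finishes the baseline questionnaire and the moment they
are randomized, the study team must decide whether this is a new,
eligible, honestly-responding human — using nothing but the data trail:
contact fields, screener answers, timestamps, IP addresses, response
patterns, and (when volunteered) social-media handles.

`authsieve` models this decision as a two-stage classifier.

The **automated stage** applies deterministic rules and assigns each
attempt exactly one status. The statuses are mutually exclusive, so a
precedence order is needed for attempts that violate several rules at
once; we order them eligibility → duplicate → foreign IP → completion
failure → address cluster → referred. The ordering follows the logic of
cost: eligibility is decided from the participant's own answers
(cheapest, least disputable), duplication is decided against the
registry, location and completion follow, and the cluster signature —
which only becomes meaningful once several attempts have accumulated —
is checked last among the exclusions. Every check still runs and is
written to the audit log regardless of which one determines the status,
so the evidence for a multi-problem record is never lost.

The **manual stage** is a checklist resolution process, not a free-form
review. Six items (time stamp, age comparison, duplicate check, pattern
check, social-media check, zip/location check) start as *pass*,
*pending* (when an automated flag maps to them) or *not applicable*
(social media without a handle). Staff findings are supplied as
structured evidence: a pending item is either confirmed as a failure or
resolved as explainable — the latter requiring a free-text note,
because "we contacted the participant and travel explains the IP
mismatch" is an audit artifact worth keeping. Any failed item fails the
checklist. An attempt with a clean checklist still only enrolls after
answering a verification email inside the 30-day window.

Two modelling choices deserve explicit statement:

* **Both prior attempts and enrolled participants block re-entry.** The
  registry holds canonical contact keys for everyone ever evaluated;
  each processed attempt joins it immediately, in submission order. A
  fraudster's second try therefore collides with their first even if
  the first was itself rejected.
* **IP-consistency findings are resolved on the zip/location checklist
  item.** The checklist is fixed to the six named categories; IP-state
  vs mailing-state and screening-vs-baseline IP mismatches are location
  evidence and are reviewed (and, often, resolved as travel) together
  with the address.

## Matching: canonicalization and the partial-match rules

Contact fields are canonicalized before comparison: emails lowercased,
trimmed, `+tag` stripped (configurable); phones reduced to 10 digits
with a leading US country code removed; names lowercased with
punctuation and whitespace collapsed; street suffixes normalized from a
fixed synonym table (st/street, rd/road, ave/avenue, blvd/boulevard,
ln/lane, dr/drive, ct/court). Canonicalization is idempotent, and every
comparison is symmetric.

Match rules per field family:

| family  | exact | partial |
|---------|-------|---------|
| email   | equal canonical address | local part within 1 edit, same domain |
| phone   | any shared 10-digit key (primary or alternate) | — |
| IP      | shared address | — |
| handle  | equal platform+handle | — |
| name    | equal name key | within 1 edit |
| address | all five components equal | same street/city/state/zip, different house number |

The edit-distance bound of 1 is a declared default, not a
reconstruction of any particular system: it catches the common
"jdoe1 → jdoe2" re-enrollment pattern while bounding false positives,
and it is configurable (`name_edit_max`, `email_edit_max`). Phones,
IPs and handles are exact-only because a one-digit phone edit is a
different number, not a variant spelling.

Partial matching at distance 1 is implemented with a deletion-variant
index (two strings are within one edit iff they are equal, one is a
single-deletion variant of the other, or they share a deletion variant
at the same position). This is exactly equivalent to pairwise edit
distance — the test suite checks equivalence against a quadratic
brute-force oracle — while keeping each lookup proportional to key
length, so an all-clean cohort of 10,000 records screens in about a
minute on one core. Above `blocking_threshold` (default 10,000 registry
records) wider-than-default edit limits restrict their fallback scan to
blocked candidates.

The address-cluster detector declares a cluster when at least
`cluster_min_size = 3` registry records share the attempt's
street/city/state/zip with different house numbers. Sequential registry
growth matters here: when a batch of attempts walks a street house by
house, the first two attempts refer to manual review (or match on other
fields), and every attempt from the third onward is excluded as a
cluster case. In the default synthetic cohort the registry starts with
two enrolled residents of the clustered street and the phone-reusing
index attempt precedes the cluster, so all 23 planted cluster attempts
cross the threshold.

## Thresholds, with units and rationale

| parameter | default | meaning |
|---|---|---|
| `min_age`, `max_age` | 13, 18 years | eligible age range, inclusive |
| `subset_fail_frac` | 0.60 of 27 items | hard gate: < `ceil(0.6·27)` = 17 answered fails |
| `outcome_fail_frac` | 0.70 of 62 items | hard gate: < 44 answered fails |
| `manual_flag_frac` | 0.80 | flag band: < 22/27 or < 50/62 answered refers to review |
| `min_minutes` | 20 min | speeder flag, strict `<`, for a ~30-minute instrument |
| `max_hours` | 72 h | unusually-long flag (flag, never auto-exclusion) |
| `email_window_days` | 30 d | verification window; expiry the day after |
| `reminder_period_days` | 7 d | reminders at days 7, 14, 21, 28 |
| `code_digits` | 3 | SMS verification code length |
| `cluster_min_size` | 3 records | street-cluster threshold |
| `straightline_threshold` | 0.95 | longest-run fraction of answered items |
| `zigzag_threshold` | 0.9 | alternation index (below) |
| `likert_min/max` | 1–5 | response scale; the scale is a configuration, not an assumption |

Completion gates are derived as `ceiling(frac × N)` answered items,
which reproduces all four printed operating points (17/27, 44/62,
22/27, 50/62) from the two stated fractions. Boundary semantics are
strict as stated: exactly 20 minutes passes, 19:59 flags; 17 answered
of 27 escapes the hard gate but sits in the flag band until 22.

**Pattern operators.** Straight-lining is the length of the longest
constant run among answered items divided by the number answered.
The "Christmas tree" zigzag is operationalized as an *alternation
index*: the fraction of adjacent difference pairs that reverse sign
with both magnitudes at least half the scale span. The name describes a
paper-era bubble-sheet geometry that the source material cites without
defining; the alternation index is our explicit stand-in, and both
thresholds are declared defaults. Conflict rules (`mutually_exclusive`,
`requires`, `max_abs_difference`) are supplied by the study in YAML;
none ship as defaults because incompatibility is instrument-specific.
Survey review runs for any record carrying a flag or sitting in the
completion flag band — patterns are only sought where something else
already looks off, mirroring how review effort is actually rationed.

## The synthetic cohort generator

`simulate_cohort()` emulates the enrollment funnel of a reference
web-based adolescent HIV-prevention trial: 1224 attempts that started
the baseline questionnaire, of which the automated battery excludes
492 (32 eligibility — 30 via the generic quota predicate, 2
HIV-positive — 177 duplicates, 8 foreign IPs, 252 completion failures,
23 street-cluster attempts) and refers 732; manual review then yields
600 enrollments, 123 checklist failures and 9 pre-checklist duplicates.
These composition counts *are* the study conditions; they are fixed in
`default_archetype_mix()` and are not tuning knobs.

Design points:

* **One planted anomaly per record** keeps the automated statuses
  exactly reproducible under the precedence rule. The exception is the
  manual-failure mix: the five failure-reason tallies (33 time-stamp,
  20 age, 28 duplicate, 33 pattern, 20 social) sum to 134 over 123
  failures, so eleven records carry two reasons each (5 speeder +
  straight-liner, 3 age + social, 3 partial-duplicate + zigzag).
* **The street cluster** plants two already-enrolled residents in the
  registry, one index attempt whose phone equals the first resident's
  secondary number (an exact cross-slot match, hence counted among the
  177 duplicates), and 23 further attempts with sequential house
  numbers and otherwise clean, unique contacts — classified as cluster
  cases.
* **The 9 late duplicates** are planted beyond the automated partial
  thresholds (names two edits away, emails on a different domain) and
  are confirmed by a pre-checklist staff finding in the generated
  evidence — the situation where a human recognizes a returnee the
  rules cannot.
* **Identity fields** come from deterministic word lists keyed by the
  seed, combined so that two distinct generated values are never within
  one edit of each other (numeric suffixes are encoded as doubled
  letters for this reason). No real personal data is generated.
  Changing the seed changes every name, address and timestamp but never
  which checks a record satisfies — a metamorphic property the tests
  assert.
* Clean records answer 24–27 subset and 56–62 outcome items in 25–55
  minutes; planted zigzag blocks are fully answered, because a skipped
  item splices two equal responses together and would dilute the
  alternation the archetype exists to exhibit.

**What the generator does not emulate** — and hence what passing tests
do and do not show. Real enrollment data has correlated anomalies
(fraudsters are often fast *and* careless *and* duplicated),
shared-household IPs and legitimate address overlaps in dense housing,
typo-laden honest contact data, and response distributions with real
psychometric structure. The generator produces none of that: its
specificity results (zero false positives on clean cohorts) certify the
rules' logic, not their false-positive rate on humans, and its perfect
recovery results certify that each rule fires where intended, not field
sensitivity. The discussion of selection-bias risk — similar addresses
in high-density housing being flagged disproportionately — applies to
the method itself and cannot be resolved by synthetic data.

## Numerical and formatting choices

Percentages are computed with exact integer arithmetic and an explicit
convention. Published enrollment tables mix conventions — 1224/1324 is
printed truncated (92.44; half-up rounding gives 92.45), while
252/1224 is printed rounded (20.59) and a 600/732 share appears as 81.9
(truncation at one decimal; rounding gives 82.0). `status_tables()`
therefore pins round-half-up at two decimals for the automated table,
truncation at one decimal for dispositions, and round-half-up at one
decimal for failure reasons, and `percent_format()` exposes both modes
rather than silently normalizing. The formatter agrees with a
long-division oracle across random numerator/denominator pairs in the
tests.

Other conventions: timestamps are stored and compared in UTC throughout
(outcomes are invariant to the host timezone, asserted in the tests);
age is civil age (calendar-year difference, decremented before the
birthday), with a DOB up to 31 days in the future annotated as an
explainable year-typo but still flagged; an unmapped IP flags as
unknown rather than failing, because only a *confirmed* non-US location
excludes; invalid input rows are quarantined with row-level diagnostics
instead of aborting a batch; and the email-verification window closes
strictly after day 30, with a day-30 response still verifying.

Degenerate inputs: an all-missing Likert block has no defined pattern
and returns false with fraction 0; blocks shorter than
`pattern_min_items` (10 answered) are not pattern-judged; an empty name
canonicalizes to an empty key that never matches; a blank street
participates only in zip/city comparisons.

## Open design points, resolved

* The disposition vocabulary has no value for "checklist clean but email
  expired"; such cases fail the checklist with an explanatory note,
  preserving the three-way partition. The default cohort contains none.
* Whether the 23 cluster attempts should also count as duplicates is
  resolved by the precedence rule: cluster cases are attempts with *no*
  exact contact match; the phone-reusing index attempt is a duplicate.
* Race/ethnicity enrollment quotas are modelled as a generic boolean
  quota predicate on the screening record (`quota_gating`), since quota
  logic is protocol-specific.
* Follow-up waves may report a DOB or an integer age; when both are
  present the DOB wins, being the higher-resolution datum.

## Problem sizes used in validation

The shipped test suite validates at the study's own scale: the full
1224-attempt default cohort end to end (exact status, disposition and
reason counts), matcher-vs-brute-force equivalence on 500-record random
cohorts, a 10,000-record all-clean specificity run, and
2,500-pair-per-mode percent-formatting checks. These sizes are the
package's validation design; the generator and pipeline accept
arbitrary mixes.

## Known limitations

Manual-stage "staff" behavior is supplied as structured evidence, so the
package validates the resolution *process*, not human judgment. Social
profiles are structured fact records, not live platform lookups. GeoIP
is an offline lookup table; proxy/VPN detection is out of scope. The
matcher is deterministic record-linkage, deliberately not probabilistic
(Fellegi–Sunter) linkage or phonetic encoding — partial-match
thresholds are declared operating points, and studies with noisier
contact data should widen them consciously rather than rely on the
defaults.
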