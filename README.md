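# authsieve

Two-stage participant authentication for fully web-based study
enrollment.

Web-recruited trials — especially those enrolling hard-to-reach
populations such as adolescent MSM through social-media ads — attract
duplicate, ineligible and outright fraudulent enrollment attempts:
people re-enrolling under variant contact details for incentives, bots
racing through questionnaires, respondents misreporting age or serostatus.
`authsieve` implements the defense a study team runs between "started the
baseline questionnaire" and "randomized": an automated battery that
excludes the clear-cut cases, followed by a checklist-driven manual
review of everything the battery flags.

## The pipeline

**Stage 1 — automated battery** (`run_auto_battery()`). Each enrollment
attempt (a *dossier*: joined contact + screening + baseline record) is
checked, audited, and given exactly one status by precedence:

1. `eligibility_fail` — age outside 13–18, not a same-sex-attracted
   cisgender male, HIV-positive at baseline, or an unmet enrollment
   quota;
2. `duplicate` — an exact contact match against the registry of enrolled
   participants and *all prior attempts*, across six field families
   (email, phone incl. cross-slot primary/alternate, IP, mailing
   address, social handle, preferred name);
3. `ip_foreign` — baseline IP geolocating outside the US (an offline
   `ip → country/state` lookup table stands in for a GeoIP service);
4. `completion_fail` — answered fewer than `ceil(0.60·27) = 17` of the
   random question subset or `ceil(0.70·62) = 44` of the primary-outcome
   items;
5. `cluster_case` — at least `cluster_min_size = 3` registry records on
   the same street with different house numbers (the coordinated
   "walking one street" fraud signature);
6. `referred_manual` — everything else, carrying its flags (partial
   contact matches at edit distance ≤ 1, IP-state vs mailing-state
   mismatches, screener-age vs DOB inconsistencies, completions under
   20 minutes or over 72 hours, completion counts in the 80 % flag
   band) into stage 2.

**Stage 2 — manual review** (`run_manual_stage()`). Each referred record
gets a six-item checklist (time stamp, age comparison, duplicate check,
pattern check, social media check, zip/location check). Flags
pre-populate items as pending; survey review runs straight-lining /
zigzag ("Christmas tree") / conflicting-answer detectors on any
triggered record; structured social-profile evidence corroborates or
contradicts the dossier; staff resolutions either confirm a failure or
resolve it as explainable (with a mandatory note). Enrollment finally
requires answering a verification email within 30 days (weekly
reminders at days 7/14/21/28). Dispositions: `enrolled`,
`failed_checklist`, `failed_duplicate_no_checklist`.

A seeded generator (`simulate_cohort()`) produces labelled synthetic
cohorts in which every planted anomaly archetype violates exactly its
intended check, so sensitivity and specificity of the whole pipeline are
testable record by record. Post-enrollment QA (follow-up age
verification, alternate-contact cross-matching, administrative
discontinuation) lives in `check_followup_age()`,
`cross_match_alternates()` and `discontinue()`.

## Worked example

```r
library(authsieve)

cohort    <- simulate_cohort(seed = 20210831)   # default 1224-attempt mix
decisions <- run_auto_battery(cohort)
cases     <- run_manual_stage(decisions, cohort)

glance(decisions)
#>       n eligibility_fail duplicate ip_foreign completion_fail cluster_case
#>    1224               32       177          8             252           23
#> # referred_manual 732, referred_with_flags 146

tabs <- status_tables(decisions, cases)
tabs$manual
#> Manual authentication status (N=732)
#>   failed_duplicate_no_checklist                   9 (1.2)
#>   failed_checklist                              123 (16.8)
#>   enrolled                                      600 (81.9)
tabs$reasons
#> Manual checklist failure reasons (non-exclusive) (N=123)
#>   time_stamp                                     33 (26.8)
#>   age_comparison                                 20 (16.3)
#>   duplicate_check                                28 (22.8)
#>   pattern_check                                  33 (26.8)
#>   social_media_check                             20 (16.3)

prevented_enrollments(decisions, cases)
#> $automated 492   $manual 132   $total 624   $automated_share_pct 79
```

Reading: of 1224 attempts that started the baseline questionnaire, the
battery excluded 492 (most for incomplete questionnaires) and referred
732; manual review removed another 132 (9 of them duplicates spotted
before the checklist was even completed), enrolling 600. In total 624
bad enrollments were prevented, 79 % of them by the automated stage —
the manual effort concentrates on the genuinely ambiguous fifth of the
intake. Failure reasons overlap (a speeder may also straight-line), so
the reasons table is not a partition.

`autoplot()` methods draw the status and funnel bar charts;
`tidy()`/`glance()` return plain tibbles for downstream analysis. A thin
command-line wrapper is installed at `inst/cli/authsieve.R`
(`synth`, `auto`, `manual`, `qa`, `report` subcommands over CSV/JSONL
files).

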