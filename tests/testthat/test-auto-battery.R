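test_that("SMS code verification passes, flags or fails on the entry log", {
  expect_equal(verify_sms_code("123", "123")$outcome, "pass")
  wrong_then_right <- verify_sms_code("123", c("321", "123"))
  expect_equal(wrong_then_right$outcome, "pass")
  expect_equal(wrong_then_right$evidence[[1]]$support_events, 1)
  expect_equal(verify_sms_code("123", "321")$outcome, "flag")
  expect_equal(verify_sms_code("123", character())$outcome, "fail")
  expect_error(verify_sms_code("12", "12"), class = "authsieve_config_error")
})

test_that("eligibility recheck fails on each stated criterion and flags incompleteness", {
  expect_equal(recheck_eligibility(make_dossier())$outcome, "pass")
  expect_equal(recheck_eligibility(make_dossier(reported_age_years = 19L))$outcome, "fail")
  expect_equal(recheck_eligibility(make_dossier(reported_age_years = 12L))$outcome, "fail")
  expect_equal(recheck_eligibility(make_dossier(hiv_status = "positive"))$outcome, "fail")
  expect_equal(recheck_eligibility(make_dossier(same_sex_attracted = FALSE))$outcome, "fail")
  expect_equal(recheck_eligibility(make_dossier(gender_identity = "woman"))$outcome, "fail")
  expect_equal(recheck_eligibility(make_dossier(meets_quota = FALSE))$outcome, "fail")
  no_gate <- auth_config(quota_gating = FALSE)
  expect_equal(recheck_eligibility(make_dossier(meets_quota = FALSE), no_gate)$outcome, "pass")
  incomplete <- recheck_eligibility(make_dossier(hiv_status = NA_character_))
  expect_equal(incomplete$outcome, "flag")
  expect_match(incomplete$reason, "incomplete")
})

test_that("age consistency compares whole-year age at completion, annotating future DOBs", {
  r <- check_age_consistency(16L, as.Date("2002-03-10"), as.Date("2018-06-01"))
  expect_equal(r$outcome, "pass")
  # birthday not yet reached
  r2 <- check_age_consistency(15L, as.Date("2002-08-10"), as.Date("2018-06-01"))
  expect_equal(r2$outcome, "pass")
  future <- check_age_consistency(17L, as.Date("2018-06-15"), as.Date("2018-06-01"))
  expect_equal(future$outcome, "flag")
  expect_match(future$reason, "explainable: future DOB")
  old <- check_age_consistency(15L, as.Date("1990-01-01"), as.Date("2018-06-01"))
  expect_equal(old$outcome, "flag")
  expect_equal(old$evidence[[1]]$computed_age, 28L)
  expect_error(check_age_consistency(15L, as.Date("1890-01-01"), as.Date("2018-06-01")),
               class = "authsieve_validation_error")
})

test_that("IP checks fail only on confirmed non-US, flag on mismatch or unknown", {
  geo <- list(geoip = tibble::tibble(
    ip = c("1.1.1.1", "2.2.2.2", "3.3.3.3"),
    country = c("CA", "US", "US"),
    state = c("ON", "GA", "NY")
  ))
  foreign <- check_ip_location("2.2.2.2", "1.1.1.1", "GA", geo)
  expect_equal(foreign$outcome[foreign$check_id == "ip_country"], "fail")

  ok <- check_ip_location("2.2.2.2", "2.2.2.2", "GA", geo)
  expect_true(all(ok$outcome == "pass"))

  moved <- check_ip_location("2.2.2.2", "3.3.3.3", "NY", geo)
  expect_equal(moved$outcome[moved$check_id == "ip_screen_vs_baseline"], "flag")
  expect_equal(moved$outcome[moved$check_id == "ip_state_vs_mailing"], "pass")

  unknown <- check_ip_location("2.2.2.2", "9.9.9.9", "GA", geo)
  expect_equal(unknown$outcome[unknown$check_id == "ip_country"], "flag")
  expect_match(unknown$reason[unknown$check_id == "ip_country"], "unknown")
})

test_that("completion-time gate is strict at 20 minutes and 72 hours", {
  t0 <- as.POSIXct("2018-06-01 10:00:00", tz = "UTC")
  expect_equal(check_completion_time(t0, t0 + 19 * 60 + 59)$outcome, "flag")
  expect_equal(check_completion_time(t0, t0 + 20 * 60)$outcome, "pass")
  slow <- check_completion_time(t0, t0 + 73 * 3600)
  expect_equal(slow$outcome, "flag")
  expect_equal(slow$reason, "unusually long")
  expect_equal(check_completion_time(t0, t0 + 72 * 3600)$outcome, "pass")
  expect_error(check_completion_time(t0, t0 - 1), class = "authsieve_validation_error")
})

test_that("completion-score gates sit exactly at 17/27, 44/62 and flag below 22/27, 50/62", {
  g <- completion_gates(auth_config())
  expect_equal(g$subset_fail, 17L)
  expect_equal(g$outcome_fail, 44L)
  expect_equal(g$subset_flag, 22L)
  expect_equal(g$outcome_flag, 50L)

  mk <- function(a, n) c(rep(1L, a), rep(NA_integer_, n - a))
  s <- function(a27, a62) score_completion(mk(a27, 27), mk(a62, 62))$result$outcome
  expect_equal(s(16, 62), "fail")
  expect_equal(s(17, 44), "flag")
  expect_equal(s(17, 62), "flag")
  expect_equal(s(22, 49), "flag")
  expect_equal(s(22, 50), "pass")
  expect_equal(s(27, 62), "pass")
  expect_equal(s(27, 43), "fail")
  expect_error(score_completion(mk(10, 26), mk(44, 62)),
               class = "authsieve_validation_error")
})

test_that("an exact duplicate that is also a speeder is classified duplicate by precedence", {
  cohort <- simulate_cohort(archetype_mix(clean = 2), seed = 3)
  reg <- cohort$registry
  fast_dup <- make_dossier(
    participant_id = "P99999",
    email = cohort$dossiers$email[1],             # exact duplicate of attempt 1
    baseline_started_at = max(cohort$dossiers$baseline_started_at) + 3600,
    baseline_ended_at = max(cohort$dossiers$baseline_started_at) + 3600 + 10 * 60
  )
  dossiers <- dplyr::bind_rows(cohort$dossiers, fast_dup)
  lookups <- generate_lookup_tables(dossiers)
  dec <- run_auto_battery(dossiers, registry = reg, lookups = lookups)
  expect_equal(dec$status[dec$participant_id == "P99999"], "duplicate")
  # the time flag was still computed and audited
  audit <- attr(dec, "audit")
  expect_equal(
    audit$outcome[audit$participant_id == "P99999" & audit$check_id == "completion_time"],
    "flag"
  )
})

test_that("clean records are referred with zero flags and statuses partition the cohort", {
  cohort <- simulate_cohort(archetype_mix(clean = 12), seed = 8)
  dec <- run_auto_battery(cohort)
  expect_true(all(dec$status == "referred_manual"))
  expect_true(all(dec$n_flags == 0))
  expect_equal(nrow(dec), sum(table(dec$status)))
})

test_that("the battery is deterministic and idempotent", {
  cohort <- simulate_cohort(archetype_mix(clean = 5, speeder = 2, exact_duplicate = 2),
                            seed = 44)
  d1 <- run_auto_battery(cohort)
  d2 <- run_auto_battery(cohort)
  expect_identical(tidy(d1), tidy(d2))
  expect_identical(attr(d1, "audit"), attr(d2, "audit"))
})

test_that("every processed attempt joins the registry and blocks later re-entry", {
  cohort <- simulate_cohort(archetype_mix(clean = 3), seed = 15)
  dec <- run_auto_battery(cohort)
  grown <- attr(dec, "registry")
  expect_equal(nrow(grown), nrow(cohort$registry) + 3)
  # resubmitting the same cohort against the grown registry: all duplicates
  dec2 <- run_auto_battery(cohort$dossiers, registry = grown, lookups = cohort$lookups)
  expect_true(all(dec2$status == "duplicate"))
})
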