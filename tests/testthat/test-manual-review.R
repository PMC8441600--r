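mk_decision <- function(flags = character(), status = "referred_manual",
                        pid = "P00001") {
  tibble::tibble(participant_id = pid, status = status, flags = list(flags),
                 n_flags = length(flags), answered_subset = 27L,
                 answered_outcome = 62L)
}

test_that("checklists pre-populate pending items from carried flags", {
  d <- make_dossier()
  case <- build_checklist(mk_decision("completion_time"), d)
  oc <- setNames(case$items$outcome, case$items$item)
  expect_equal(unname(oc["time_stamp"]), "pending")
  expect_equal(unname(oc["age_comparison"]), "pass")
  expect_equal(unname(oc["social_media_check"]), "not_applicable") # no handle

  fast_path <- build_checklist(mk_decision(), d)
  expect_true(all(fast_path$items$outcome %in% c("pass", "not_applicable")))

  two <- build_checklist(mk_decision(c("age_consistency", "completion_score")), d)
  oc2 <- setNames(two$items$outcome, two$items$item)
  expect_equal(unname(oc2["age_comparison"]), "pending")
  expect_equal(unname(oc2["pattern_check"]), "pending")

  with_handle <- build_checklist(mk_decision(),
                                 make_dossier(social_handles = "instagram:someone"))
  oc3 <- setNames(with_handle$items$outcome, with_handle$items$item)
  expect_equal(unname(oc3["social_media_check"]), "pass")

  expect_error(build_checklist(mk_decision(status = "duplicate"), d),
               class = "authsieve_contract_error")
})

test_that("zip verification flags gazetteer mismatches and triggers similar-address review", {
  d <- make_dossier()
  lookups <- list(gazetteer = tibble::tibble(
    street = "Maple Grove St", city = "Springfield", state = "GA", zip = "30305"
  ))
  reg <- canonicalize_contacts(make_dossier(
    participant_id = "R1", house_number = "14",
    email = "other.person@x.org", phone_primary = "4045559999",
    preferred_name = "Other Person"
  ))
  r <- verify_zip(d, lookups, registry = reg)
  expect_equal(r$outcome, "flag")
  expect_equal(r$evidence[[1]]$indexed, "30305")
  expect_equal(r$evidence[[1]]$similar_addresses, "R1")

  lookups$gazetteer$zip <- "30301"
  expect_equal(verify_zip(d, lookups)$outcome, "pass")

  unknown <- verify_zip(make_dossier(street = "Unknown Way"), lookups)
  expect_equal(unknown$outcome, "flag")
  expect_match(unknown$reason, "unknown")
})

test_that("social evidence passes on corroboration, fails on contradiction, else stays pending", {
  d <- make_dossier(social_handles = "instagram:someone")
  case <- build_checklist(mk_decision(), d)

  ok <- apply_social_evidence(case, tibble::tibble(
    profile_age = 16L, profile_gender = "man", profile_state = "GA"
  ), d)
  expect_equal(ok$items$outcome[ok$items$item == "social_media_check"], "pass")

  bad_age <- apply_social_evidence(case, tibble::tibble(profile_age = 25L), d)
  expect_equal(bad_age$items$outcome[bad_age$items$item == "social_media_check"], "fail")

  nothing <- apply_social_evidence(case, NULL, d)
  expect_equal(nothing$items$outcome[nothing$items$item == "social_media_check"], "pending")

  no_handle <- build_checklist(mk_decision(), make_dossier())
  same <- apply_social_evidence(no_handle, tibble::tibble(profile_age = 25L), make_dossier())
  expect_equal(same$items$outcome[same$items$item == "social_media_check"],
               "not_applicable")
})

test_that("the email window closes after day 30 with reminders at 7/14/21/28", {
  issued <- as.Date("2018-06-01")
  st <- list(issued_on = issued)

  on_deadline <- email_verification_step(st, now = issued + 30, response = issued + 30)
  expect_equal(on_deadline$status, "verified")

  expired <- email_verification_step(st, now = issued + 31)
  expect_equal(expired$status, "expired")
  expect_equal(expired$reminders_sent, issued + c(7, 14, 21, 28))

  quick <- email_verification_step(st, now = issued + 2, response = issued + 1)
  expect_equal(quick$status, "verified")
  expect_equal(length(quick$reminders_sent), 0)

  waiting <- email_verification_step(st, now = issued + 10)
  expect_equal(waiting$status, "pending")
  expect_equal(waiting$reminders_sent, issued + 7)

  expect_error(email_verification_step(st, now = issued, response = issued - 1),
               class = "authsieve_validation_error")
})

test_that("case resolution maps item outcomes to the three dispositions", {
  d <- make_dossier()
  verified <- list(issued_on = as.Date("2018-06-02"), status = "verified")

  case <- build_checklist(mk_decision("completion_time"), d)
  case$email_state <- verified
  resolved <- resolve_case(case, tibble::tibble(
    item = "time_stamp", outcome = "resolved_explainable",
    note = "travel; confirmed by contact"
  ))
  expect_equal(resolved$disposition, "enrolled")

  case2 <- build_checklist(mk_decision(), d)
  case2$email_state <- verified
  case2$items$outcome[case2$items$item == "pattern_check"] <- "fail"
  expect_equal(resolve_case(case2)$disposition, "failed_checklist")

  case3 <- build_checklist(mk_decision(), d)
  dup <- resolve_case(case3, duplicate_confirmed = TRUE)
  expect_equal(dup$disposition, "failed_duplicate_no_checklist")

  pending <- build_checklist(mk_decision("completion_time"), d)
  expect_error(resolve_case(pending), "unresolved pending",
               class = "authsieve_contract_error")
  expect_error(
    resolve_case(pending, tibble::tibble(item = "time_stamp",
                                         outcome = "resolved_explainable", note = "")),
    "non-empty note", class = "authsieve_contract_error"
  )
})

test_that("no case enrolls without a verified email, over random resolution sequences", {
  set.seed(31)
  d <- make_dossier()
  for (i in 1:20) {
    case <- build_checklist(mk_decision(), d)
    case$email_state <- list(
      issued_on = as.Date("2018-06-02"),
      status = sample(c("pending", "expired", "verified"), 1)
    )
    out <- resolve_case(case)
    if (out$disposition == "enrolled") {
      expect_equal(case$email_state$status, "verified")
    } else {
      expect_false(identical(case$email_state$status, "verified"))
    }
  }
  no_state <- build_checklist(mk_decision(), d)
  expect_equal(resolve_case(no_state)$disposition, "failed_checklist")
})

test_that("the manual stage recovers planted dispositions on a mixed cohort", {
  cohort <- simulate_cohort(
    archetype_mix(clean = 6, speeder = 2, slow_outlier = 2, state_mismatch_ip = 2,
                  social_contradicted = 2, age_inconsistent = 1, straightliner = 2,
                  late_duplicate = 2, email_nonresponder = 1),
    seed = 77
  )
  dec <- run_auto_battery(cohort)
  expect_true(all(dec$status == "referred_manual"))
  cases <- run_manual_stage(dec, cohort)
  m <- dplyr::left_join(tidy(cases), cohort$truth, by = "participant_id")
  expect_equal(m$disposition, m$expected_disposition)
  # dispositions partition the referred cohort
  expect_equal(sum(table(cases$disposition)), nrow(cases))
  # the email non-responder failed for exactly that reason
  nr <- m[m$archetype == "email_nonresponder", ]
  expect_equal(nr$email_status, "expired")
  expect_match(nr$note, "email verification")
  # resolved-explainable items carry their notes
  slow <- tidy(cases)[m$archetype == "slow_outlier", ]
  expect_true(all(slow$time_stamp == "resolved_explainable"))
})

test_that("reason multiplicity: summed reason counts are at least the failure count", {
  cohort <- simulate_cohort(
    archetype_mix(clean = 3, speeder = 2, speeder_straightliner = 2,
                  social_contradicted = 1),
    seed = 41
  )
  dec <- run_auto_battery(cohort)
  cases <- run_manual_stage(dec, cohort)
  failed <- cases[cases$disposition == "failed_checklist", ]
  reason_sum <- sum(
    failed$time_stamp == "fail", failed$age_comparison == "fail",
    failed$duplicate_check == "fail", failed$pattern_check == "fail",
    failed$social_media_check == "fail"
  )
  expect_gte(reason_sum, nrow(failed))
})
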