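test_that("record counts equal the archetype mix exactly", {
  mix <- archetype_mix(clean = 7, speeder = 3, foreign_ip = 2, exact_duplicate = 4)
  cohort <- simulate_cohort(mix, seed = 1)
  expect_equal(nrow(cohort$dossiers), sum(mix$count))
  expect_equal(as.integer(table(cohort$truth$archetype)[mix$archetype]), mix$count)
  expect_equal(nrow(default_archetype_mix()), 21)
  expect_equal(sum(default_archetype_mix()$count), 1224)
})

test_that("generation is byte-identical for a fixed seed and differs across seeds", {
  mix <- archetype_mix(clean = 5, speeder = 2, exact_duplicate = 2)
  a <- simulate_cohort(mix, seed = 123)
  b <- simulate_cohort(mix, seed = 123)
  expect_identical(a$dossiers, b$dossiers)
  expect_identical(a$registry, b$registry)
  expect_identical(a$manual_evidence, b$manual_evidence)

  c2 <- simulate_cohort(mix, seed = 124)
  expect_false(identical(a$dossiers$subset_responses, c2$dossiers$subset_responses))
})

test_that("changing the seed never changes which checks an archetype satisfies", {
  mix <- archetype_mix(clean = 4, speeder = 2, low_completion_subset = 2,
                       foreign_ip = 1, exact_duplicate = 2, age_inconsistent = 1)
  for (seed in c(2, 1234, 99991)) {
    cohort <- simulate_cohort(mix, seed = seed)
    dec <- run_auto_battery(cohort)
    expect_equal(dec$status, cohort$truth$expected_status, info = paste("seed", seed))
  }
})

test_that("clean archetypes are fully specific: referred with zero flags", {
  cohort <- simulate_cohort(archetype_mix(clean = 10), seed = 31)
  dec <- run_auto_battery(cohort)
  expect_true(all(dec$status == "referred_manual"))
  expect_true(all(dec$n_flags == 0))
  cases <- run_manual_stage(dec, cohort)
  expect_true(all(cases$disposition == "enrolled"))
})

test_that("each exclusion archetype earns its intended automated status", {
  per_type <- list(
    underage = "eligibility_fail", overage = "eligibility_fail",
    not_same_sex_attracted = "eligibility_fail", hiv_positive = "eligibility_fail",
    quota_fail = "eligibility_fail", exact_duplicate = "duplicate",
    foreign_ip = "ip_foreign", low_completion_subset = "completion_fail",
    low_completion_outcome = "completion_fail"
  )
  for (ty in names(per_type)) {
    args <- list(clean = 2)
    args[[ty]] <- 2
    cohort <- simulate_cohort(do.call(archetype_mix, args), seed = 55)
    dec <- run_auto_battery(cohort)
    got <- dec$status[cohort$truth$archetype == ty]
    expect_equal(got, rep(per_type[[ty]], 2), info = ty)
    expect_equal(dec$status[cohort$truth$archetype == "clean"],
                 rep("referred_manual", 2), info = ty)
  }
})

test_that("the street cluster plants 23 cluster attempts plus one phone-matched index attempt", {
  cohort <- simulate_cohort(archetype_mix(clean = 2, wisteria_index = 1,
                                          wisteria_cluster = 23), seed = 66)
  dec <- run_auto_battery(cohort)
  tr <- cohort$truth
  expect_equal(dec$status[tr$archetype == "wisteria_index"], "duplicate")
  expect_equal(dec$status[tr$archetype == "wisteria_cluster"], rep("cluster_case", 23))
  # the index attempt's phone is an enrolled participant's secondary number
  idx_row <- cohort$dossiers[tr$archetype == "wisteria_index", ]
  m <- find_duplicates(idx_row, cohort$registry)
  expect_true(any(m$field == "phone" & m$kind == "exact"))
})

test_that("generated lookup tables cover every IP and street with archetype-consistent entries", {
  cohort <- simulate_cohort(archetype_mix(clean = 3, foreign_ip = 2,
                                          state_mismatch_ip = 2), seed = 13)
  d <- cohort$dossiers
  geo <- cohort$lookups$geoip
  expect_true(all(d$baseline_ip %in% geo$ip))
  tr <- cohort$truth
  for (i in which(tr$archetype == "foreign_ip")) {
    expect_false(geo$country[geo$ip == d$baseline_ip[i]] == "US")
  }
  for (i in which(tr$archetype == "state_mismatch_ip")) {
    expect_true(geo$country[geo$ip == d$baseline_ip[i]] == "US")
    expect_false(geo$state[geo$ip == d$baseline_ip[i]] == d$state[i])
  }
  for (i in which(tr$archetype == "clean")) {
    expect_equal(geo$state[geo$ip == d$baseline_ip[i]], d$state[i])
    gz <- cohort$lookups$gazetteer
    hit <- gz$zip[gz$street == d$street[i] & gz$city == d$city[i]]
    expect_equal(hit, d$mailing_zip[i])
  }
})

test_that("impossible mixes error out", {
  expect_error(archetype_mix(clean = 2, nonsense = 1), class = "authsieve_config_error")
  expect_error(simulate_cohort(archetype_mix(underage = 1), seed = 1,
                               config = auth_config(min_age = 0)),
               class = "authsieve_config_error")
})

test_that("a conflicted record fails pattern review when conflict rules are supplied", {
  cohort <- simulate_cohort(archetype_mix(clean = 2, conflicted = 1), seed = 21)
  dec <- run_auto_battery(cohort)
  rules <- tibble::tibble(item_a = "subset_01", item_b = "subset_02",
                          predicate = "mutually_exclusive", param = NA_real_)
  cases <- run_manual_stage(dec, cohort, rules = rules)
  got <- tidy(cases)
  tr <- cohort$truth
  expect_equal(got$pattern_check[match(tr$participant_id[tr$archetype == "conflicted"],
                                       got$participant_id)], "fail")
  expect_equal(got$disposition[match(tr$participant_id[tr$archetype == "clean"],
                                     got$participant_id)], rep("enrolled", 2))
})
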