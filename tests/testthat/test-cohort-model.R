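test_that("a well-formed cohort reads into one dossier per baseline row", {
  cohort <- simulate_cohort(archetype_mix(clean = 3, speeder = 1), seed = 11)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(list(
    contacts = file.path(dir, "contacts.csv"),
    screening = file.path(dir, "screening.csv"),
    baseline = file.path(dir, "baseline.csv"),
    geoip = file.path(dir, "geoip.csv"),
    gazetteer = file.path(dir, "gazetteer.csv")
  ))
  expect_equal(nrow(back$dossiers), 4)
  expect_equal(nrow(back$rejects), 0)
})

test_that("write/read round-trip is lossless for every dossier field", {
  cohort <- simulate_cohort(
    archetype_mix(clean = 8, speeder = 2, foreign_ip = 2, low_completion_subset = 2,
                  age_inconsistent = 2, straightliner = 2),
    seed = 23
  )
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(list(
    contacts = file.path(dir, "contacts.csv"),
    screening = file.path(dir, "screening.csv"),
    baseline = file.path(dir, "baseline.csv"),
    geoip = file.path(dir, "geoip.csv"),
    gazetteer = file.path(dir, "gazetteer.csv")
  ))
  orig <- cohort$dossiers[order(cohort$dossiers$participant_id), ]
  got <- back$dossiers[order(back$dossiers$participant_id), ]
  for (col in names(orig)) {
    expect_equal(got[[col]], orig[[col]], info = col, ignore_attr = TRUE)
  }
  # a second round trip is a fixed point
  dir2 <- withr::local_tempdir()
  write_cohort(back, dir2)
  expect_identical(readLines(file.path(dir, "baseline.csv")),
                   readLines(file.path(dir2, "baseline.csv")))
})

test_that("rows violating invariants are quarantined with diagnostics, not dropped silently", {
  cohort <- simulate_cohort(archetype_mix(clean = 3), seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  bl <- readr::read_csv(file.path(dir, "baseline.csv"), show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  # drop one subset slot on the first record: 26 slots instead of 27
  bl$random_subset_responses[1] <-
    sub("^[^|]*\\|", "", bl$random_subset_responses[1])
  readr::write_csv(bl, file.path(dir, "baseline.csv"), na = "")
  back <- read_cohort(list(
    contacts = file.path(dir, "contacts.csv"),
    screening = file.path(dir, "screening.csv"),
    baseline = file.path(dir, "baseline.csv")
  ))
  expect_equal(nrow(back$dossiers), 2)
  expect_true(any(grepl("subset length", back$rejects$reason)))
  expect_equal(back$rejects$id[grepl("subset length", back$rejects$reason)],
               bl$participant_id[1])
})

test_that("schema and orphan violations are hard errors naming the offender", {
  cohort <- simulate_cohort(archetype_mix(clean = 2), seed = 6)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  ct <- readr::read_csv(file.path(dir, "contacts.csv"), show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  readr::write_csv(ct[, setdiff(names(ct), "email")], file.path(dir, "contacts.csv"), na = "")
  paths <- list(contacts = file.path(dir, "contacts.csv"),
                screening = file.path(dir, "screening.csv"),
                baseline = file.path(dir, "baseline.csv"))
  expect_error(read_cohort(paths), "email", class = "authsieve_schema_error")

  # restore contacts but drop one contact row entirely -> orphan baseline row
  readr::write_csv(ct[-1, ], file.path(dir, "contacts.csv"), na = "")
  expect_error(read_cohort(paths), ct$participant_id[1],
               class = "authsieve_orphan_error")
})

test_that("decisions files have one ordered row per attempt and round-trip their enums", {
  decisions <- tibble::tibble(
    participant_id = c("P2", "P1", "P6", "P3", "P4", "P5"),
    status = c("eligibility_fail", "duplicate", "ip_foreign", "completion_fail",
               "cluster_case", "referred_manual"),
    flags = list(character(), character(), character(), character(),
                 character(), c("completion_time"))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_decisions(decisions, path)
  back <- read_decisions(path)
  expect_equal(nrow(back), 6)
  expect_equal(back$participant_id, sort(decisions$participant_id))
  expect_setequal(back$status, decisions$status)
  expect_equal(back$flags[back$participant_id == "P5"][[1]], "completion_time")

  dup <- decisions[c(1, 1), ]
  expect_error(write_decisions(dup, path), "duplicate decision",
               class = "authsieve_decision_error")
  bad <- decisions
  bad$status[1] <- "unheard_of"
  expect_error(write_decisions(bad, path), "unknown status",
               class = "authsieve_decision_error")
})

test_that("the audit log is append-only JSON lines whose replay reconstructs outcomes", {
  res <- tibble::tibble(
    participant_id = sprintf("P%d", 1:5),
    check_id = c("eligibility", "duplicate", "completion_time", "completion_score", "pattern"),
    outcome = c("pass", "fail", "flag", "pass", "fail"),
    reason = c("", "exact match", "too fast", "", "straightline")
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_audit(res, path, run_id = "run-A")
  expect_equal(length(readLines(path)), 5)
  write_audit(res, path, run_id = "run-B")
  back <- read_audit(path)
  expect_equal(nrow(back), 10)
  expect_setequal(unique(back$run_id), c("run-A", "run-B"))
  a <- back[back$run_id == "run-A", c("participant_id", "check_id", "outcome", "reason")]
  b <- back[back$run_id == "run-B", c("participant_id", "check_id", "outcome", "reason")]
  expect_equal(a, b, ignore_attr = TRUE)

  empty <- res[0, ]
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_audit(empty, p2)
  expect_true(!file.exists(p2) || file.size(p2) == 0)
})

test_that("check results with flag or fail outcomes must carry a reason", {
  expect_error(authsieve:::check_result("eligibility", "fail", ""),
               class = "authsieve_contract_error")
  expect_silent(authsieve:::check_result("eligibility", "pass"))
})

test_that("pipeline outcomes are invariant to the host timezone", {
  cohort <- simulate_cohort(archetype_mix(clean = 4, speeder = 2), seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  paths <- list(contacts = file.path(dir, "contacts.csv"),
                screening = file.path(dir, "screening.csv"),
                baseline = file.path(dir, "baseline.csv"),
                geoip = file.path(dir, "geoip.csv"),
                gazetteer = file.path(dir, "gazetteer.csv"))
  run_in_tz <- function(tz) {
    withr::with_timezone(tz, {
      back <- read_cohort(paths)
      dec <- run_auto_battery(back, registry = cohort$registry)
      tidy(dec)
    })
  }
  expect_equal(run_in_tz("UTC"), run_in_tz("Pacific/Kiritimati"))
  expect_equal(run_in_tz("UTC"), run_in_tz("America/New_York"))
})
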