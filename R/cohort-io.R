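# Record schemas and delimited-text I/O for the enrollment pipeline.
# All tables are UTF-8 CSV with a header row; MISSING is an empty field.
# Dates are ISO-8601 (YYYY-MM-DD); timestamps ISO-8601 UTC with Z suffix.
# Multi-valued fields are packed into one column: lists joined with ";",
# ordered Likert response slots joined with "|" (empty slot = skipped item),
# social handles as "platform:handle" pairs joined with ";".

US_STATES <- c(
  "AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "FL", "GA", "HI", "ID",
  "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD", "MA", "MI", "MN", "MS",
  "MO", "MT", "NE", "NV", "NH", "NJ", "NM", "NY", "NC", "ND", "OH", "OK",
  "OR", "PA", "RI", "SC", "SD", "TN", "TX", "UT", "VT", "VA", "WA", "WV",
  "WI", "WY", "DC"
)

AUTO_STATUSES <- c(
  "eligibility_fail", "duplicate", "ip_foreign", "completion_fail",
  "cluster_case", "referred_manual"
)

DISPOSITIONS <- c("enrolled", "failed_checklist", "failed_duplicate_no_checklist")

CHECK_IDS <- c(
  "sms_code", "eligibility", "duplicate", "ip_country", "ip_state_vs_mailing",
  "ip_screen_vs_baseline", "age_consistency", "completion_time",
  "completion_score", "pattern", "zip_mismatch", "social_media",
  "email_verification", "followup_age", "alternate_contact"
)

CHECKLIST_ITEMS <- c(
  "time_stamp", "age_comparison", "duplicate_check", "pattern_check",
  "social_media_check", "zip_check"
)

ITEM_OUTCOMES <- c("pass", "fail", "resolved_explainable", "not_applicable", "pending")

COHORT_SCHEMAS <- list(
  contacts = c(
    "participant_id", "preferred_name", "email", "phone_primary",
    "phone_alts", "house_number", "street", "city", "state", "zip",
    "social_handles", "submitted_at"
  ),
  screening = c(
    "screener_id", "participant_id", "reported_age_years",
    "sex_assigned_at_birth", "gender_identity", "same_sex_attracted",
    "hiv_status", "zip", "ip", "started_at", "ended_at", "code_verified",
    "consented", "meets_quota"
  ),
  baseline = c(
    "participant_id", "dob", "ip", "started_at", "ended_at",
    "random_subset_responses", "primary_outcome_responses"
  ),
  followup = c(
    "participant_id", "wave_months", "reported_dob", "reported_age",
    "alt_phone", "alt_email", "completed_at"
  ),
  geoip = c("ip", "country", "state"),
  gazetteer = c("street", "city", "state", "zip")
)

# ---- packing helpers ---------------------------------------------------

parse_responses <- function(x) {
  # sentinel keeps trailing skipped slots (strsplit drops trailing empties)
  lapply(strsplit(paste0(ifelse(is.na(x), "", x), "|\x01"), "|", fixed = TRUE),
         function(v) {
    v <- v[-length(v)]
    suppressWarnings(as.integer(ifelse(v == "", NA, v)))
  })
}

format_responses <- function(slots) {
  vapply(slots, function(v) paste(ifelse(is.na(v), "", as.character(v)), collapse = "|"), "")
}

parse_utc <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

format_utc <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

split_multi <- function(x) {
  strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";", fixed = TRUE)
}

read_table_checked <- function(path, table) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "authsieve_io_error")
  }
  dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(COHORT_SCHEMAS[[table]], names(dat))
  if (length(missing) > 0) {
    abort(
      sprintf("%s: missing required column(s): %s", table, paste(missing, collapse = ", ")),
      class = "authsieve_schema_error"
    )
  }
  dat[COHORT_SCHEMAS[[table]]]
}

is_zip5 <- function(x) !is.na(x) & grepl("^[0-9]{5}$", x)
blank_or <- function(x, ok) is.na(x) | x == "" | ok

# ---- row validation ----------------------------------------------------

collect_rejects <- function(dat, table, bad, reason) {
  if (!any(bad)) {
    return(tibble(table = character(), row = integer(), id = character(), reason = character()))
  }
  idcol <- if ("participant_id" %in% names(dat)) dat$participant_id else dat[[1]]
  tibble(
    table = table, row = which(bad),
    id = as.character(idcol[bad]), reason = reason
  )
}

validate_contacts <- function(raw) {
  rejects <- bind_rows(
    collect_rejects(raw, "contacts", is.na(raw$participant_id) | raw$participant_id == "",
                    "missing participant_id"),
    collect_rejects(raw, "contacts", duplicated(raw$participant_id) & !is.na(raw$participant_id),
                    "duplicate participant_id"),
    collect_rejects(raw, "contacts", !blank_or(raw$zip, is_zip5(raw$zip)),
                    "zip is not a 5-digit code"),
    collect_rejects(raw, "contacts", !blank_or(raw$state, raw$state %in% US_STATES),
                    "state not a US state/DC code")
  )
  list(valid = raw[!seq_len(nrow(raw)) %in% rejects$row, , drop = FALSE], rejects = rejects)
}

validate_screening <- function(raw) {
  age <- suppressWarnings(as.integer(raw$reported_age_years))
  started <- parse_utc(raw$started_at)
  ended <- parse_utc(raw$ended_at)
  rejects <- bind_rows(
    collect_rejects(raw, "screening", is.na(age) | age < 0 | age > 120,
                    "reported_age_years outside [0, 120]"),
    collect_rejects(raw, "screening", is.na(started) | is.na(ended),
                    "unparseable timestamp"),
    collect_rejects(raw, "screening", !is.na(started) & !is.na(ended) & ended < started,
                    "ended_at before started_at"),
    collect_rejects(raw, "screening", !is_zip5(raw$zip), "zip is not a 5-digit code")
  )
  list(valid = raw[!seq_len(nrow(raw)) %in% rejects$row, , drop = FALSE], rejects = rejects)
}

validate_baseline <- function(raw, config) {
  subset_slots <- parse_responses(raw$random_subset_responses)
  outcome_slots <- parse_responses(raw$primary_outcome_responses)
  n_sub <- lengths(subset_slots)
  n_out <- lengths(outcome_slots)
  in_scale <- function(slots) {
    vapply(slots, function(v) {
      v <- v[!is.na(v)]
      length(v) == 0 || all(v >= config$likert_min & v <= config$likert_max)
    }, TRUE)
  }
  started <- parse_utc(raw$started_at)
  ended <- parse_utc(raw$ended_at)
  rejects <- bind_rows(
    collect_rejects(raw, "baseline", n_sub != config$subset_n,
                    sprintf("subset length: expected %d slots", config$subset_n)),
    collect_rejects(raw, "baseline", n_out != config$outcome_n,
                    sprintf("outcome length: expected %d slots", config$outcome_n)),
    collect_rejects(raw, "baseline", !in_scale(subset_slots) | !in_scale(outcome_slots),
                    sprintf("Likert value outside %d-%d scale", config$likert_min, config$likert_max)),
    collect_rejects(raw, "baseline", is.na(started) | is.na(ended) | ended < started,
                    "invalid start/end timestamps"),
    collect_rejects(raw, "baseline", is.na(as.Date(raw$dob, format = "%Y-%m-%d")),
                    "unparseable dob")
  )
  list(valid = raw[!seq_len(nrow(raw)) %in% rejects$row, , drop = FALSE], rejects = rejects)
}

# ---- cohort reader -----------------------------------------------------

#' Read an enrollment cohort from delimited text files
#'
#' Joins the screening, baseline and contact tables into one dossier per
#' baseline row (the unit the pipeline judges) and loads the two offline
#' lookup tables. Rows violating type invariants are quarantined into the
#' `rejects` table with row-level diagnostics rather than aborting the
#' batch; a baseline row whose join partner is entirely absent from the
#' contact or screening table is an orphan-record error.
#'
#' @param paths Named character vector or list with elements `contacts`,
#'   `screening`, `baseline`, and optionally `followup`, `geoip`,
#'   `gazetteer`.
#' @param config An [auth_config()].
#' @return An object of class `auth_cohort`: a list with `dossiers` (one
#'   row per enrollment attempt), `followup`, `lookups` (list of `geoip`
#'   and `gazetteer` tibbles) and `rejects` (quarantined rows with
#'   diagnostics).
#' @seealso [write_cohort()] for the inverse, [simulate_cohort()] to
#'   generate one.
#' @export
read_cohort <- function(paths, config = auth_config()) {
  paths <- as.list(paths)
  stopifnot(all(c("contacts", "screening", "baseline") %in% names(paths)))

  contacts <- validate_contacts(read_table_checked(paths$contacts, "contacts"))
  screening <- validate_screening(read_table_checked(paths$screening, "screening"))
  baseline <- validate_baseline(read_table_checked(paths$baseline, "baseline"), config)
  rejects <- bind_rows(contacts$rejects, screening$rejects, baseline$rejects)

  raw_contact_ids <- read_table_checked(paths$contacts, "contacts")$participant_id
  raw_screen_ids <- read_table_checked(paths$screening, "screening")$participant_id
  orphans <- setdiff(
    baseline$valid$participant_id,
    intersect(raw_contact_ids, raw_screen_ids)
  )
  if (length(orphans) > 0) {
    abort(
      sprintf(
        "orphan baseline record(s): no contact/screening row for id(s) %s",
        paste(orphans, collapse = ", ")
      ),
      class = "authsieve_orphan_error"
    )
  }
  # partner rows that were themselves quarantined take the baseline row with them
  joinable <- intersect(contacts$valid$participant_id, screening$valid$participant_id)
  dropped <- !(baseline$valid$participant_id %in% joinable)
  rejects <- bind_rows(
    rejects,
    collect_rejects(baseline$valid, "baseline", dropped,
                    "join partner quarantined in contacts/screening")
  )
  base_ok <- baseline$valid[!dropped, , drop = FALSE]

  dossiers <- assemble_dossiers(contacts$valid, screening$valid, base_ok, config)

  followup <- NULL
  if (!is.null(paths$followup)) {
    fu <- read_table_checked(paths$followup, "followup")
    followup <- tibble(
      participant_id = fu$participant_id,
      wave_months = suppressWarnings(as.integer(fu$wave_months)),
      reported_dob = as.Date(fu$reported_dob, format = "%Y-%m-%d"),
      reported_age = suppressWarnings(as.integer(fu$reported_age)),
      alt_phone = fu$alt_phone,
      alt_email = fu$alt_email,
      completed_at = parse_utc(fu$completed_at)
    )
    bad_wave <- !followup$wave_months %in% c(3L, 6L, 9L, 12L, 15L)
    rejects <- bind_rows(rejects, collect_rejects(fu, "followup", bad_wave,
                                                  "wave_months not in {3,6,9,12,15}"))
    followup <- followup[!bad_wave, , drop = FALSE]
  }

  lookups <- list(geoip = NULL, gazetteer = NULL)
  if (!is.null(paths$geoip)) {
    lookups$geoip <- read_table_checked(paths$geoip, "geoip")
  }
  if (!is.null(paths$gazetteer)) {
    gz <- read_table_checked(paths$gazetteer, "gazetteer")
    lookups$gazetteer <- gz
  }

  new_auth_cohort(dossiers = dossiers, followup = followup,
                  lookups = lookups, rejects = rejects)
}

assemble_dossiers <- function(contacts, screening, baseline, config) {
  ct <- tibble(
    participant_id = contacts$participant_id,
    preferred_name = contacts$preferred_name,
    email = contacts$email,
    phone_primary = contacts$phone_primary,
    phone_alts = contacts$phone_alts,
    house_number = contacts$house_number,
    street = contacts$street,
    city = contacts$city,
    state = contacts$state,
    mailing_zip = contacts$zip,
    social_handles = contacts$social_handles,
    submitted_at = parse_utc(contacts$submitted_at)
  )
  sc <- tibble(
    participant_id = screening$participant_id,
    screener_id = screening$screener_id,
    reported_age_years = as.integer(screening$reported_age_years),
    sex_assigned_at_birth = screening$sex_assigned_at_birth,
    gender_identity = screening$gender_identity,
    same_sex_attracted = toupper(screening$same_sex_attracted) %in% c("TRUE", "T", "1", "YES"),
    hiv_status = screening$hiv_status,
    screening_zip = screening$zip,
    screen_ip = screening$ip,
    screen_started_at = parse_utc(screening$started_at),
    screen_ended_at = parse_utc(screening$ended_at),
    code_verified = toupper(screening$code_verified) %in% c("TRUE", "T", "1", "YES"),
    consented = toupper(screening$consented) %in% c("TRUE", "T", "1", "YES"),
    meets_quota = toupper(screening$meets_quota) %in% c("TRUE", "T", "1", "YES")
  )
  bl <- tibble(
    participant_id = baseline$participant_id,
    dob = as.Date(baseline$dob, format = "%Y-%m-%d"),
    baseline_ip = baseline$ip,
    baseline_started_at = parse_utc(baseline$started_at),
    baseline_ended_at = parse_utc(baseline$ended_at),
    subset_responses = parse_responses(baseline$random_subset_responses),
    outcome_responses = parse_responses(baseline$primary_outcome_responses)
  )
  bl %>%
    dplyr::inner_join(ct, by = "participant_id") %>%
    dplyr::inner_join(sc, by = "participant_id") %>%
    arrange(.data$baseline_started_at, .data$participant_id)
}

new_auth_cohort <- function(dossiers, followup = NULL, lookups = NULL,
                            rejects = NULL, registry = NULL, truth = NULL,
                            manual_evidence = NULL, funnel = NULL) {
  structure(
    list(
      dossiers = dossiers, followup = followup, lookups = lookups,
      rejects = rejects, registry = registry, truth = truth,
      manual_evidence = manual_evidence, funnel = funnel
    ),
    class = "auth_cohort"
  )
}

#' @export
print.auth_cohort <- function(x, ...) {
  cat(sprintf("<auth_cohort> %d dossier(s)", nrow(x$dossiers)))
  if (!is.null(x$rejects) && nrow(x$rejects) > 0) {
    cat(sprintf(", %d quarantined row(s)", nrow(x$rejects)))
  }
  if (!is.null(x$registry)) cat(sprintf(", registry of %d", nrow(x$registry)))
  if (!is.null(x$truth)) cat(", labelled")
  cat("\n")
  invisible(x)
}

#' Write a cohort back to delimited text files
#'
#' Inverse of [read_cohort()]: writes `contacts.csv`, `screening.csv`,
#' `baseline.csv` and, when present, `followup.csv`, `geoip.csv`,
#' `gazetteer.csv`, `registry.csv` and `truth.csv` under `dir`. The
#' round-trip through [read_cohort()] is lossless for every field.
#'
#' @param cohort An `auth_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- cohort$dossiers
  files <- c()
  w <- function(tbl, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tbl, path, na = "", progress = FALSE)
    files[[name]] <<- path
  }
  w(tibble(
    participant_id = d$participant_id, preferred_name = d$preferred_name,
    email = d$email, phone_primary = d$phone_primary, phone_alts = d$phone_alts,
    house_number = d$house_number, street = d$street, city = d$city,
    state = d$state, zip = d$mailing_zip, social_handles = d$social_handles,
    submitted_at = format_utc(d$submitted_at)
  ), "contacts")
  w(tibble(
    screener_id = d$screener_id, participant_id = d$participant_id,
    reported_age_years = d$reported_age_years,
    sex_assigned_at_birth = d$sex_assigned_at_birth,
    gender_identity = d$gender_identity,
    same_sex_attracted = d$same_sex_attracted, hiv_status = d$hiv_status,
    zip = d$screening_zip, ip = d$screen_ip,
    started_at = format_utc(d$screen_started_at),
    ended_at = format_utc(d$screen_ended_at),
    code_verified = d$code_verified, consented = d$consented,
    meets_quota = d$meets_quota
  ), "screening")
  w(tibble(
    participant_id = d$participant_id, dob = format(d$dob, "%Y-%m-%d"),
    ip = d$baseline_ip,
    started_at = format_utc(d$baseline_started_at),
    ended_at = format_utc(d$baseline_ended_at),
    random_subset_responses = format_responses(d$subset_responses),
    primary_outcome_responses = format_responses(d$outcome_responses)
  ), "baseline")
  if (!is.null(cohort$followup)) {
    fu <- cohort$followup
    w(tibble(
      participant_id = fu$participant_id, wave_months = fu$wave_months,
      reported_dob = ifelse(is.na(fu$reported_dob), "", format(fu$reported_dob, "%Y-%m-%d")),
      reported_age = fu$reported_age, alt_phone = fu$alt_phone,
      alt_email = fu$alt_email, completed_at = format_utc(fu$completed_at)
    ), "followup")
  }
  if (!is.null(cohort$lookups$geoip)) w(cohort$lookups$geoip, "geoip")
  if (!is.null(cohort$lookups$gazetteer)) w(cohort$lookups$gazetteer, "gazetteer")
  if (!is.null(cohort$registry)) w(cohort$registry, "registry")
  if (!is.null(cohort$truth)) w(cohort$truth, "truth")
  invisible(unlist(files))
}

# ---- decisions and audit log ------------------------------------------

#' Write pipeline decisions to CSV
#'
#' One row per participant, ordered by `participant_id`, with the status
#' vocabulary restricted to the automated statuses or the manual
#' dispositions. A duplicated `participant_id` is an error: the pipeline
#' issues exactly one decision per enrollment attempt.
#'
#' @param decisions A decisions tibble ([run_auto_battery()] output) or
#'   manual-cases tibble ([run_manual_stage()] output).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  stopifnot(nrow(decisions) > 0)
  if (anyDuplicated(decisions$participant_id)) {
    dup <- unique(decisions$participant_id[duplicated(decisions$participant_id)])
    abort(sprintf("duplicate decision for participant(s): %s", paste(dup, collapse = ", ")),
          class = "authsieve_decision_error")
  }
  statuses <- if ("status" %in% names(decisions)) decisions$status else decisions$disposition
  bad <- setdiff(unique(statuses), c(AUTO_STATUSES, DISPOSITIONS))
  if (length(bad) > 0) {
    abort(sprintf("unknown status value(s): %s", paste(bad, collapse = ", ")),
          class = "authsieve_decision_error")
  }
  out <- decisions %>% arrange(.data$participant_id)
  flat <- out[vapply(out, function(col) !is.list(col), TRUE)]
  if ("flags" %in% names(out)) {
    flat$flags <- vapply(out$flags, function(f) paste(f, collapse = ";"), "")
  }
  readr::write_csv(flat, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_decisions
#' @export
read_decisions <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if ("flags" %in% names(dat)) {
    dat$flags <- lapply(strsplit(ifelse(is.na(dat$flags), "", dat$flags), ";", fixed = TRUE),
                        function(v) v[v != ""])
  }
  as_tibble(dat)
}

#' Append check results to a JSON-lines audit log
#'
#' Each check outcome becomes one JSON object with the participant id,
#' check id, outcome, reason, evidence, a run id and a write timestamp.
#' The log is append-only; replaying it with [read_audit()] reconstructs
#' every outcome of every run.
#'
#' @param results Tibble with columns `participant_id`, `check_id`,
#'   `outcome`, `reason` and (optionally) a list column `evidence`.
#' @param path Log file path; created if absent, appended to otherwise.
#' @param run_id Identifier for this pipeline run.
#' @return `path`, invisibly.
#' @export
write_audit <- function(results, path, run_id = format(Sys.time(), "%Y%m%d%H%M%S")) {
  con <- tryCatch(file(path, open = "a", encoding = "UTF-8"),
                  error = function(e) abort(sprintf("cannot open audit log %s", path),
                                            class = "authsieve_io_error"))
  on.exit(close(con))
  if (nrow(results) == 0) return(invisible(path))
  stamp <- format_utc(Sys.time())
  for (i in seq_len(nrow(results))) {
    rec <- list(
      run_id = run_id,
      logged_at = stamp,
      participant_id = results$participant_id[i],
      check_id = results$check_id[i],
      outcome = results$outcome[i],
      reason = results$reason[i]
    )
    if ("evidence" %in% names(results)) rec$evidence <- results$evidence[[i]]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_audit
#' @export
read_audit <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    return(tibble(run_id = character(), logged_at = character(),
                  participant_id = character(), check_id = character(),
                  outcome = character(), reason = character(),
                  evidence = list()))
  }
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble(
    run_id = vapply(recs, `[[`, "", "run_id"),
    logged_at = vapply(recs, `[[`, "", "logged_at"),
    participant_id = vapply(recs, `[[`, "", "participant_id"),
    check_id = vapply(recs, `[[`, "", "check_id"),
    outcome = vapply(recs, `[[`, "", "outcome"),
    reason = vapply(recs, function(r) r$reason %||% "", ""),
    evidence = lapply(recs, function(r) r$evidence)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_result <- function(check_id, outcome, reason = "", evidence = list()) {
  stopifnot(check_id %in% CHECK_IDS, outcome %in% c("pass", "flag", "fail"))
  if (outcome != "pass" && !nzchar(reason)) {
    abort("flag/fail check results require a non-empty reason",
          class = "authsieve_contract_error")
  }
  tibble(check_id = check_id, outcome = outcome, reason = reason,
         evidence = list(evidence))
}
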