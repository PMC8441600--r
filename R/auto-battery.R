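# The automated (electronic) authentication battery. Every check runs and
# is audited for every dossier; a single mutually exclusive status is then
# assigned by precedence: eligibility_fail > duplicate > ip_foreign >
# completion_fail > cluster_case > referred_manual. Flag-level findings on
# referred records are carried into the manual stage.

#' Verify an SMS confirmation code entry log
#'
#' A screening attempt receives a short numeric code by SMS and must echo
#' it back to continue. The full entry log is judged: a finally-correct
#' entry passes (earlier wrong entries are recorded as support events,
#' since staff are notified and assist); a log ending in a wrong entry is
#' flagged; an empty log fails, because screening cannot proceed without
#' the code.
#'
#' @param issued The issued code (string of `code_digits` digits).
#' @param entered Character vector of entry attempts in order; may be
#'   empty.
#' @param config An [auth_config()].
#' @return A one-row check-result tibble (`check_id = "sms_code"`).
#' @export
verify_sms_code <- function(issued, entered = character(), config = auth_config()) {
  if (is.na(issued) || !grepl(sprintf("^[0-9]{%d}$", config$code_digits), issued)) {
    abort(sprintf("issued code must be %d digits, got '%s'", config$code_digits, issued),
          class = "authsieve_config_error")
  }
  entered <- entered[!is.na(entered)]
  wrong <- sum(entered != issued)
  if (length(entered) == 0) {
    check_result("sms_code", "fail", "no code entered; screening blocked")
  } else if (entered[length(entered)] == issued) {
    check_result("sms_code", "pass", evidence = list(support_events = wrong))
  } else {
    check_result("sms_code", "flag", "incorrect code entered; support notified",
                 evidence = list(support_events = wrong))
  }
}

#' Recheck study eligibility from screening answers
#'
#' Fails when any stated criterion is violated: age outside the eligible
#' range, not an assigned-male participant identifying as a man, no
#' same-sex attraction, HIV-positive status at baseline, or (when quota
#' gating is enabled) an unmet enrollment-quota predicate. A missing
#' answer flags rather than fails.
#'
#' @param dossier One-row dossier tibble.
#' @param config An [auth_config()].
#' @return A one-row check-result tibble (`check_id = "eligibility"`).
#' @export
recheck_eligibility <- function(dossier, config = auth_config()) {
  v <- eligibility_eval(dossier, config)
  if (v$outcome == "fail") {
    check_result("eligibility", "fail", v$reason)
  } else if (v$outcome == "flag") {
    check_result("eligibility", "flag", "incomplete eligibility")
  } else {
    check_result("eligibility", "pass")
  }
}

eligibility_eval <- function(d, config) {
  # vectorized over dossier rows; returns outcome + first failing reason
  n <- nrow(d)
  reason <- rep(NA_character_, n)
  set <- function(cond, code) {
    reason <<- ifelse(is.na(reason) & cond, code, reason)
  }
  incomplete <- is.na(d$reported_age_years) | is.na(d$sex_assigned_at_birth) |
    is.na(d$gender_identity) | is.na(d$same_sex_attracted) | is.na(d$hiv_status)
  set(!is.na(d$reported_age_years) &
        (d$reported_age_years < config$min_age | d$reported_age_years > config$max_age),
      "age_out_of_range")
  set(!is.na(d$sex_assigned_at_birth) & !is.na(d$gender_identity) &
        !(d$sex_assigned_at_birth == "male" & d$gender_identity == "man"),
      "not_cisgender_male")
  set(!is.na(d$same_sex_attracted) & !d$same_sex_attracted, "not_same_sex_attracted")
  set(!is.na(d$hiv_status) & d$hiv_status == "positive", "hiv_positive")
  if (config$quota_gating && "meets_quota" %in% names(d)) {
    set(!is.na(d$meets_quota) & !d$meets_quota, "quota_not_met")
  }
  outcome <- ifelse(!is.na(reason), "fail", ifelse(incomplete, "flag", "pass"))
  list(outcome = outcome, reason = reason)
}

#' Whole-year (civil) age at a date
#'
#' Calendar-year difference, decremented when the birthday has not yet
#' occurred by `at`. Negative for a future date of birth.
#'
#' @param dob,at Date vectors.
#' @return Integer vector of ages.
#' @export
civil_age <- function(dob, at) {
  dl <- as.POSIXlt(dob)
  al <- as.POSIXlt(at)
  age <- al$year - dl$year
  before_birthday <- (al$mon < dl$mon) | (al$mon == dl$mon & al$mday < dl$mday)
  as.integer(age - before_birthday)
}

#' Compare screener-reported age with the age implied by the baseline DOB
#'
#' Passes only when the whole-year age computed from the date of birth at
#' the baseline completion date equals the age reported in the screener.
#' Any discrepancy flags for manual review; a DOB up to 31 days in the
#' future is additionally annotated as explainable (a plausible year typo)
#' but still flagged.
#'
#' @param reported_age Integer, age reported on the screener.
#' @param dob Date of birth from the baseline questionnaire.
#' @param completed_at Baseline completion date.
#' @return A one-row check-result tibble (`check_id = "age_consistency"`).
#' @examples
#' check_age_consistency(16L, as.Date("2002-03-10"), as.Date("2018-06-01"))
#' @export
check_age_consistency <- function(reported_age, dob, completed_at) {
  dob <- as.Date(dob)
  completed_at <- as.Date(completed_at)
  if (as.numeric(completed_at - dob) > 120 * 366) {
    abort("dob more than 120 years before completion date",
          class = "authsieve_validation_error")
  }
  computed <- civil_age(dob, completed_at)
  if (!is.na(computed) && computed == reported_age) {
    return(check_result("age_consistency", "pass"))
  }
  future_days <- as.numeric(dob - completed_at)
  reason <- if (future_days > 0 && future_days <= 31) {
    "age mismatch (explainable: future DOB)"
  } else {
    "age mismatch"
  }
  check_result("age_consistency", "flag", reason,
               evidence = list(reported_age = reported_age, computed_age = computed,
                               dob = format(dob), completed_at = format(completed_at)))
}

geo_lookup <- function(ips, geoip) {
  i <- match(ips, geoip$ip)
  tibble(country = geoip$country[i], state = geoip$state[i])
}

#' IP-geolocation consistency checks
#'
#' Three results per attempt: (a) `ip_country` fails when the baseline IP
#' geolocates outside the US; (b) `ip_state_vs_mailing` flags when the IP
#' state differs from the mailing-address state; (c)
#' `ip_screen_vs_baseline` flags when the screening and baseline IPs
#' geolocate to different states. An IP absent from the lookup table flags
#' as unknown location, never fails: only a confirmed non-US location
#' excludes.
#'
#' @param screen_ip,baseline_ip Dotted-quad IP strings.
#' @param mailing_state Two-letter state code from the mailing address.
#' @param lookups List with a `geoip` tibble (columns `ip`, `country`,
#'   `state`).
#' @return A three-row check-result tibble.
#' @export
check_ip_location <- function(screen_ip, baseline_ip, mailing_state, lookups) {
  geo <- lookups$geoip
  b <- geo_lookup(baseline_ip, geo)
  s <- geo_lookup(screen_ip, geo)
  r1 <- if (is.na(b$country)) {
    check_result("ip_country", "flag", "unknown location",
                 evidence = list(ip = baseline_ip))
  } else if (b$country != "US") {
    check_result("ip_country", "fail", "IP outside the United States",
                 evidence = list(ip = baseline_ip, country = b$country))
  } else {
    check_result("ip_country", "pass")
  }
  r2 <- if (is.na(b$state) || b$state == "") {
    check_result("ip_state_vs_mailing", "flag", "unknown location",
                 evidence = list(ip = baseline_ip))
  } else if (!is.na(mailing_state) && nzchar(mailing_state) && b$state != mailing_state) {
    check_result("ip_state_vs_mailing", "flag", "IP state differs from mailing state",
                 evidence = list(ip_state = b$state, mailing_state = mailing_state))
  } else {
    check_result("ip_state_vs_mailing", "pass")
  }
  r3 <- if (is.na(s$state) || is.na(b$state)) {
    check_result("ip_screen_vs_baseline", "flag", "unknown location",
                 evidence = list(screen_ip = screen_ip, baseline_ip = baseline_ip))
  } else if (s$state != b$state) {
    check_result("ip_screen_vs_baseline", "flag",
                 "screening and baseline IPs in different states",
                 evidence = list(screen_state = s$state, baseline_state = b$state))
  } else {
    check_result("ip_screen_vs_baseline", "pass")
  }
  bind_rows(r1, r2, r3)
}

#' Baseline completion-time gate
#'
#' Flags completions strictly faster than `min_minutes` (speeders on an
#' instrument designed to take about `design_minutes`) and slower than
#' `max_hours` (unusually long); both go to manual review rather than
#' excluding outright.
#'
#' @param started_at,ended_at POSIXct timestamps (UTC).
#' @param config An [auth_config()].
#' @return A one-row check-result tibble (`check_id = "completion_time"`).
#' @export
check_completion_time <- function(started_at, ended_at, config = auth_config()) {
  mins <- as.numeric(difftime(ended_at, started_at, units = "mins"))
  if (is.na(mins) || mins < 0) {
    abort("negative or undefined completion duration",
          class = "authsieve_validation_error")
  }
  if (mins < config$min_minutes) {
    check_result("completion_time", "flag", "too fast",
                 evidence = list(minutes = mins))
  } else if (mins > config$max_hours * 60) {
    check_result("completion_time", "flag", "unusually long",
                 evidence = list(minutes = mins))
  } else {
    check_result("completion_time", "pass")
  }
}

#' Completion-score gates on the two designated question sets
#'
#' Counts answered items in the random question subset and the
#' primary-outcome set. Below the hard gates (`ceiling(0.60 * 27) = 17`
#' and `ceiling(0.70 * 62) = 44` answered at the defaults) the attempt is
#' not referred for enrollment; above them but below the 80% flag band
#' (22/27, 50/62) it is flagged for manual review.
#'
#' @param subset_responses,outcome_responses Integer vectors with `NA` for
#'   skipped slots; lengths must equal `subset_n` and `outcome_n`.
#' @param config An [auth_config()].
#' @return List with `result` (one-row check-result tibble,
#'   `check_id = "completion_score"`), `answered_subset`,
#'   `answered_outcome`.
#' @export
score_completion <- function(subset_responses, outcome_responses, config = auth_config()) {
  if (length(subset_responses) != config$subset_n ||
      length(outcome_responses) != config$outcome_n) {
    abort(sprintf("expected %d and %d response slots, got %d and %d",
                  config$subset_n, config$outcome_n,
                  length(subset_responses), length(outcome_responses)),
          class = "authsieve_validation_error")
  }
  g <- completion_gates(config)
  a27 <- sum(!is.na(subset_responses))
  a62 <- sum(!is.na(outcome_responses))
  ev <- list(answered_subset = a27, answered_outcome = a62)
  res <- if (a27 < g$subset_fail || a62 < g$outcome_fail) {
    check_result("completion_score", "fail", "below completion gate", ev)
  } else if (a27 < g$subset_flag || a62 < g$outcome_flag) {
    check_result("completion_score", "flag", "completion in flag band", ev)
  } else {
    check_result("completion_score", "pass")
  }
  list(result = res, answered_subset = a27, answered_outcome = a62)
}

# vectorized internals shared with run_auto_battery -----------------------

battery_vectors <- function(d, lookups, config) {
  g <- completion_gates(config)
  elig <- eligibility_eval(d, config)
  bgeo <- geo_lookup(d$baseline_ip, lookups$geoip)
  sgeo <- geo_lookup(d$screen_ip, lookups$geoip)
  mins <- as.numeric(difftime(d$baseline_ended_at, d$baseline_started_at, units = "mins"))
  a27 <- vapply(d$subset_responses, function(v) sum(!is.na(v)), 0L)
  a62 <- vapply(d$outcome_responses, function(v) sum(!is.na(v)), 0L)
  computed_age <- civil_age(d$dob, as.Date(d$baseline_ended_at))
  list(
    elig_outcome = elig$outcome,
    elig_reason = elig$reason,
    ip_foreign = !is.na(bgeo$country) & bgeo$country != "US",
    ip_unknown = is.na(bgeo$country),
    ip_state_flag = !is.na(bgeo$state) & nzchar(bgeo$state) &
      !is.na(d$state) & nzchar(d$state) & bgeo$state != d$state,
    ip_move_flag = !is.na(sgeo$state) & !is.na(bgeo$state) & sgeo$state != bgeo$state,
    time_fast = mins < config$min_minutes,
    time_slow = mins > config$max_hours * 60,
    minutes = mins,
    a27 = a27, a62 = a62,
    score_fail = a27 < g$subset_fail | a62 < g$outcome_fail,
    score_flag = !(a27 < g$subset_fail | a62 < g$outcome_fail) &
      (a27 < g$subset_flag | a62 < g$outcome_flag),
    age_flag = is.na(computed_age) | computed_age != d$reported_age_years,
    computed_age = computed_age
  )
}

#' Run the automated authentication battery over a cohort
#'
#' Processes dossiers in submission order. Each attempt is checked for
#' eligibility, duplication against the registry (exact and partial, all
#' six contact-field families), IP-location consistency, completion time
#' and completion scores, and address-cluster membership; its canonical
#' contact is then appended to the registry so later attempts are checked
#' against it too. One status is assigned by precedence (see module
#' header); flag-level findings travel with referred records into the
#' manual stage.
#'
#' @param cohort An `auth_cohort` (from [read_cohort()] or
#'   [simulate_cohort()]), or a dossiers tibble.
#' @param registry Canonical registry tibble of enrolled participants and
#'   prior attempts; defaults to the cohort's own registry (empty if
#'   none).
#' @param lookups List with `geoip` (and optionally `gazetteer`) tibbles;
#'   defaults to the cohort's.
#' @param config An [auth_config()].
#' @return An `auth_decisions` tibble: `participant_id`, `status`, `flags`
#'   (list of flagged check ids), `answered_subset`, `answered_outcome`,
#'   plus attributes `audit` (every check outcome), `registry` (the grown
#'   registry) and `config`.
#' @examples
#' cohort <- simulate_cohort(archetype_mix(clean = 5), seed = 1)
#' decisions <- run_auto_battery(cohort)
#' glance(decisions)
#' @export
run_auto_battery <- function(cohort, registry = NULL, lookups = NULL,
                             config = auth_config()) {
  d <- if (inherits(cohort, "auth_cohort")) cohort$dossiers else cohort
  if (is.null(registry) && inherits(cohort, "auth_cohort")) registry <- cohort$registry
  if (is.null(lookups) && inherits(cohort, "auth_cohort")) lookups <- cohort$lookups
  if (is.null(lookups$geoip)) {
    lookups$geoip <- tibble(ip = character(), country = character(), state = character())
  }
  n <- nrow(d)
  vec <- battery_vectors(d, lookups, config)
  can_all <- canonicalize_contacts(d, config, enrolled = FALSE)

  idx <- registry_index(registry, config)
  pre <- canonical_pre(can_all)
  status <- character(n)
  flags <- vector("list", n)
  dup_exact <- logical(n)
  dup_partial <- logical(n)
  cluster_hit <- logical(n)

  for (i in seq_len(n)) {
    sc <- registry_scan(idx, pre, i, config)
    dup_exact[i] <- any(lengths(sc$exact) > 0)
    dup_partial[i] <- any(lengths(sc$partial) > 0)
    cluster_hit[i] <- length(cluster_scan(idx, pre, i, config)) >= config$cluster_min_size
    registry_add_pre(idx, pre, i)

    fl <- character()
    if (vec$elig_outcome[i] == "flag") fl <- c(fl, "eligibility")
    if (dup_partial[i] && !dup_exact[i]) fl <- c(fl, "duplicate")
    if (vec$ip_unknown[i]) fl <- c(fl, "ip_country")
    if (vec$ip_state_flag[i]) fl <- c(fl, "ip_state_vs_mailing")
    if (vec$ip_move_flag[i]) fl <- c(fl, "ip_screen_vs_baseline")
    if (vec$age_flag[i]) fl <- c(fl, "age_consistency")
    if (vec$time_fast[i] || vec$time_slow[i]) fl <- c(fl, "completion_time")
    if (vec$score_flag[i]) fl <- c(fl, "completion_score")
    flags[[i]] <- fl

    status[i] <- if (vec$elig_outcome[i] == "fail") {
      "eligibility_fail"
    } else if (dup_exact[i]) {
      "duplicate"
    } else if (vec$ip_foreign[i]) {
      "ip_foreign"
    } else if (vec$score_fail[i]) {
      "completion_fail"
    } else if (cluster_hit[i]) {
      "cluster_case"
    } else {
      "referred_manual"
    }
  }

  decisions <- tibble(
    participant_id = d$participant_id,
    status = status,
    flags = flags,
    n_flags = lengths(flags),
    answered_subset = vec$a27,
    answered_outcome = vec$a62
  )
  audit <- battery_audit(d, vec, dup_exact, dup_partial, cluster_hit, config)
  registry_out <- bind_rows(registry, can_all)
  structure(
    decisions,
    audit = audit,
    registry = registry_out,
    config = config,
    class = c("auth_decisions", class(decisions))
  )
}

battery_audit <- function(d, vec, dup_exact, dup_partial, cluster_hit, config) {
  pid <- d$participant_id
  out <- function(check_id, outcome, reason) {
    tibble(participant_id = pid, check_id = check_id,
           outcome = outcome, reason = ifelse(outcome == "pass", "", reason))
  }
  bind_rows(
    out("eligibility",
        ifelse(vec$elig_outcome == "fail", "fail",
               ifelse(vec$elig_outcome == "flag", "flag", "pass")),
        ifelse(vec$elig_outcome == "flag", "incomplete eligibility",
               ifelse(is.na(vec$elig_reason), "", vec$elig_reason))),
    out("duplicate",
        ifelse(dup_exact, "fail", ifelse(dup_partial, "flag", "pass")),
        ifelse(dup_exact, "exact contact match in registry",
               "partial contact match in registry")),
    out("ip_country",
        ifelse(vec$ip_foreign, "fail", ifelse(vec$ip_unknown, "flag", "pass")),
        ifelse(vec$ip_foreign, "IP outside the United States", "unknown location")),
    out("ip_state_vs_mailing",
        ifelse(vec$ip_state_flag, "flag", "pass"),
        "IP state differs from mailing state"),
    out("ip_screen_vs_baseline",
        ifelse(vec$ip_move_flag, "flag", "pass"),
        "screening and baseline IPs in different states"),
    out("age_consistency",
        ifelse(vec$age_flag, "flag", "pass"), "age mismatch"),
    out("completion_time",
        ifelse(vec$time_fast | vec$time_slow, "flag", "pass"),
        ifelse(vec$time_fast, "too fast", "unusually long")),
    out("completion_score",
        ifelse(vec$score_fail, "fail", ifelse(vec$score_flag, "flag", "pass")),
        ifelse(vec$score_fail, "below completion gate", "completion in flag band")),
    out("duplicate",
        ifelse(cluster_hit, "flag", "pass"),
        "address cluster detected") %>%
      mutate(check_id = "zip_mismatch") # cluster evidence rides the address check
  ) %>%
    arrange(.data$participant_id, .data$check_id)
}
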