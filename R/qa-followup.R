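# Ongoing quality assurance after enrollment: follow-up age verification,
# periodic alternate-contact cross-matching against other participants'
# primary contacts, and administrative discontinuation. Discontinued
# participants' contacts stay in the registry so they can never re-enter.

DISCONTINUATION_REASONS <- c(
  "lost_contact", "voluntary_withdrawal", "enrollment_error",
  "incarceration", "deceased", "other_unanticipated", "fraud_confirmed"
)

#' Verify follow-up age reports against the baseline date of birth
#'
#' Each follow-up wave reports either a DOB or an integer age. The age it
#' implies at the wave's completion date must equal the whole-year age
#' computed from the baseline DOB; any discrepancy flags the participant
#' for a study-team determination. When a wave carries both a DOB and an
#' age, the DOB wins.
#'
#' @param baseline_dob Date of birth recorded at baseline.
#' @param followup One-row follow-up tibble (`reported_dob`,
#'   `reported_age`, `completed_at`).
#' @return A one-row check-result tibble (`check_id = "followup_age"`);
#'   outcome `"pass"` with reason `"not_applicable"` when the wave carries
#'   no age report.
#' @export
check_followup_age <- function(baseline_dob, followup) {
  at <- as.Date(followup$completed_at)
  expected <- civil_age(as.Date(baseline_dob), at)
  implied <- if (!is.na(followup$reported_dob)) {
    civil_age(as.Date(followup$reported_dob), at)
  } else if (!is.na(followup$reported_age)) {
    as.integer(followup$reported_age)
  } else {
    NA_integer_
  }
  if (is.na(implied)) {
    return(check_result("followup_age", "pass", evidence = list(note = "not_applicable")))
  }
  if (implied == expected) {
    check_result("followup_age", "pass")
  } else {
    check_result("followup_age", "flag", "follow-up age differs from baseline DOB age",
                 evidence = list(implied_age = implied, expected_age = expected,
                                 wave_months = followup$wave_months))
  }
}

#' Cross-match alternate contacts against other participants' primaries
#'
#' Sweeps the enrolled cohort for exact or partial matches between any
#' participant's alternate phone/email and any *other* participant's
#' primary phone/email, in either direction. Each hit is a dual-enrollment
#' review pair.
#'
#' @param cohort Tibble with `participant_id`, `phone_primary`, `email`
#'   and alternates (`alt_phone`, `alt_email`; `;`-joined multiples
#'   allowed).
#' @param config An [auth_config()].
#' @return Tibble of pairs: `participant_a`, `participant_b` (a < b),
#'   `field`, `kind`, `detail`.
#' @export
cross_match_alternates <- function(cohort, config = auth_config()) {
  n <- nrow(cohort)
  empty <- tibble(participant_a = character(), participant_b = character(),
                  field = character(), kind = character(), detail = character())
  if (n < 2) return(empty)
  get_multi <- function(x) {
    if (is.null(x)) return(rep(list(character()), n))
    lapply(ifelse(is.na(x), "", x), function(s) {
      v <- strsplit(s, ";", fixed = TRUE)[[1]]
      v[nzchar(v)]
    })
  }
  alt_phone <- lapply(get_multi(cohort$alt_phone), function(v) canonicalize_phone(v))
  alt_email <- lapply(get_multi(cohort$alt_email), function(v) {
    if (length(v)) canonicalize_email(v, config) else character()
  })
  pri_phone <- canonicalize_phone(cohort$phone_primary)
  pri_email <- canonicalize_email(cohort$email, config)

  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      for (p in alt_phone[[i]]) {
        m <- match_field(p, pri_phone[j], "phone", config)
        if (!is.null(m)) {
          out[[length(out) + 1]] <- tibble(
            participant_a = min(cohort$participant_id[i], cohort$participant_id[j]),
            participant_b = max(cohort$participant_id[i], cohort$participant_id[j]),
            field = "phone", kind = m$kind,
            detail = "alternate phone matches another primary phone"
          )
        }
      }
      for (e in alt_email[[i]]) {
        m <- match_field(e, pri_email[j], "email", config)
        if (!is.null(m)) {
          out[[length(out) + 1]] <- tibble(
            participant_a = min(cohort$participant_id[i], cohort$participant_id[j]),
            participant_b = max(cohort$participant_id[i], cohort$participant_id[j]),
            field = "email", kind = m$kind,
            detail = sprintf("alternate email %s-matches another primary email", m$kind)
          )
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) %>%
    distinct(.data$participant_a, .data$participant_b, .data$field, .data$kind,
             .keep_all = TRUE) %>%
    arrange(.data$participant_a, .data$participant_b, .data$field)
}

#' Discontinue an enrolled participant
#'
#' Appends a discontinuation record with a reason from the closed
#' administrative set and keeps the participant's canonical contact in
#' the registry (marked no longer enrolled) so any future enrollment
#' attempt matching their keys is caught as a duplicate. Repeating a
#' discontinuation is an idempotent no-op with a warning.
#'
#' @param participant_id Participant to remove.
#' @param reason One of `lost_contact`, `voluntary_withdrawal`,
#'   `enrollment_error`, `incarceration`, `deceased`,
#'   `other_unanticipated`, `fraud_confirmed`.
#' @param noted_on Date the removal was decided.
#' @param registry Canonical registry tibble containing the participant.
#' @param log Existing discontinuation tibble to append to (optional).
#' @return List with `record` (the appended log) and `registry` (updated).
#' @export
discontinue <- function(participant_id, reason, noted_on, registry,
                        log = NULL) {
  if (!reason %in% DISCONTINUATION_REASONS) {
    abort(sprintf("unknown discontinuation reason: %s", reason),
          class = "authsieve_validation_error")
  }
  if (!participant_id %in% registry$registry_id) {
    abort(sprintf("unknown participant: %s", participant_id),
          class = "authsieve_validation_error")
  }
  if (is.null(log)) {
    log <- tibble(participant_id = character(), reason = character(),
                  noted_on = as.Date(character()))
  }
  if (participant_id %in% log$participant_id) {
    warn(sprintf("participant %s already discontinued; no-op", participant_id))
    return(list(record = log, registry = registry))
  }
  log <- bind_rows(log, tibble(participant_id = participant_id, reason = reason,
                               noted_on = as.Date(noted_on)))
  registry$enrolled[registry$registry_id == participant_id] <- FALSE
  list(record = log, registry = registry)
}
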