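# Checklist-driven manual authentication stage. Every referred record gets
# a six-item checklist (time stamp, age comparison, duplicate check,
# pattern check, social media check, zip/location check). Automated flags
# pre-populate their item as pending; staff findings (supplied as
# structured evidence) resolve pending items as confirmed failures or
# explainable inconsistencies; survey pattern review and social-media
# evidence are applied; enrollment additionally requires a completed email
# verification within the window.

FLAG_TO_ITEM <- c(
  completion_time = "time_stamp",
  age_consistency = "age_comparison",
  duplicate = "duplicate_check",
  completion_score = "pattern_check",   # near-threshold completion triggers survey review
  ip_state_vs_mailing = "zip_check",    # location consistency reviewed with the address
  ip_screen_vs_baseline = "zip_check",
  ip_country = "zip_check",
  zip_mismatch = "zip_check",
  social_media = "social_media_check"
)

new_manual_case <- function(participant_id, items, email_state = NULL,
                            disposition = NA_character_, note = "") {
  structure(
    list(participant_id = participant_id, items = items,
         email_state = email_state, disposition = disposition, note = note),
    class = "manual_case"
  )
}

#' @export
print.manual_case <- function(x, ...) {
  cat(sprintf("<manual_case> %s  disposition: %s\n", x$participant_id,
              ifelse(is.na(x$disposition), "(open)", x$disposition)))
  for (i in seq_len(nrow(x$items))) {
    cat(sprintf("  %-18s %s\n", x$items$item[i], x$items$outcome[i]))
  }
  invisible(x)
}

#' Build the manual-review checklist for a referred record
#'
#' Each flag carried by the automated decision pre-populates its checklist
#' item as pending; unflagged items start as pass; the social-media item
#' is not applicable when no handle was provided (participation is not
#' contingent on one).
#'
#' @param decision One-row `auth_decisions` slice with
#'   `status == "referred_manual"`.
#' @param dossier Matching one-row dossier tibble.
#' @return A `manual_case` object.
#' @export
build_checklist <- function(decision, dossier) {
  if (!identical(decision$status, "referred_manual")) {
    abort("checklists are built only for referred_manual decisions",
          class = "authsieve_contract_error")
  }
  items <- tibble(item = CHECKLIST_ITEMS, outcome = "pass", note = "")
  has_handle <- !is.na(dossier$social_handles) && nzchar(dossier$social_handles)
  if (!has_handle) {
    items$outcome[items$item == "social_media_check"] <- "not_applicable"
  }
  pend <- unique(stats::na.omit(FLAG_TO_ITEM[decision$flags[[1]]]))
  items$outcome[items$item %in% pend] <- "pending"
  new_manual_case(decision$participant_id, items)
}

#' Verify a submitted zip code against the gazetteer
#'
#' Looks up the zip the gazetteer indexes for the submitted street and
#' city. A differing submitted zip flags the record and triggers a review
#' for similar addresses (partial-street matches against the registry); a
#' street unknown to the gazetteer flags as unknown.
#'
#' @param dossier One-row dossier tibble (street, city, state, zip
#'   fields).
#' @param lookups List with a `gazetteer` tibble.
#' @param registry Optional canonical registry for the similar-address
#'   review.
#' @param config An [auth_config()].
#' @return A one-row check-result tibble (`check_id = "zip_mismatch"`);
#'   on a mismatch its evidence carries the partial-street registry
#'   matches.
#' @export
verify_zip <- function(dossier, lookups, registry = NULL, config = auth_config()) {
  gz <- lookups$gazetteer
  zip <- if ("mailing_zip" %in% names(dossier)) dossier$mailing_zip else dossier$zip
  if (is.null(gz) || nrow(gz) == 0) {
    return(check_result("zip_mismatch", "flag", "unknown street",
                        evidence = list(street = dossier$street)))
  }
  key <- paste(normalize_street(gz$street), canonicalize_name(gz$city), sep = "\r")
  want <- paste(normalize_street(dossier$street), canonicalize_name(dossier$city), sep = "\r")
  hit <- match(want, key)
  if (is.na(hit)) {
    return(check_result("zip_mismatch", "flag", "unknown street",
                        evidence = list(street = dossier$street, city = dossier$city)))
  }
  indexed <- gz$zip[hit]
  if (identical(indexed, zip)) {
    return(check_result("zip_mismatch", "pass"))
  }
  similar <- character()
  if (!is.null(registry) && nrow(registry) > 0) {
    m <- find_duplicates(dossier, registry, config)
    similar <- m$other_id[m$field == "address"]
  }
  check_result("zip_mismatch", "flag", "submitted zip differs from indexed zip",
               evidence = list(submitted = zip, indexed = indexed,
                               similar_addresses = similar))
}

#' Apply social-media profile evidence to a manual case
#'
#' Social profiles are modelled as structured facts rather than live
#' platform access. A fact contradicting the dossier (age, gender or
#' location) fails the social-media item; facts that corroborate it pass;
#' a handle with no retrievable facts leaves the item pending for staff
#' resolution.
#'
#' @param case A `manual_case`.
#' @param evidence One-row tibble/list with any of `profile_age`,
#'   `profile_gender`, `profile_state`, `handle_exists`.
#' @param dossier Matching one-row dossier tibble.
#' @param config An [auth_config()].
#' @return The updated `manual_case`.
#' @export
apply_social_evidence <- function(case, evidence, dossier, config = auth_config()) {
  i <- which(case$items$item == "social_media_check")
  if (case$items$outcome[i] == "not_applicable") {
    return(case)
  }
  if (is.null(evidence) || (is.data.frame(evidence) && nrow(evidence) == 0)) {
    case$items$outcome[i] <- "pending"
    return(case)
  }
  get <- function(f) {
    v <- evidence[[f]]
    if (is.null(v) || length(v) == 0 || is.na(v)) NULL else v
  }
  contradictions <- character()
  corroborated <- FALSE
  pa <- get("profile_age")
  if (!is.null(pa)) {
    if (pa != dossier$reported_age_years || pa < config$min_age || pa > config$max_age) {
      contradictions <- c(contradictions, "age")
    }
    corroborated <- TRUE
  }
  pg <- get("profile_gender")
  if (!is.null(pg)) {
    if (pg != dossier$gender_identity) contradictions <- c(contradictions, "gender")
    corroborated <- TRUE
  }
  ps <- get("profile_state")
  if (!is.null(ps)) {
    if (ps != dossier$state) contradictions <- c(contradictions, "location")
    corroborated <- TRUE
  }
  if (length(contradictions) > 0) {
    case$items$outcome[i] <- "fail"
    case$items$note[i] <- paste("profile contradicts:", paste(contradictions, collapse = ", "))
  } else if (corroborated) {
    case$items$outcome[i] <- "pass"
    case$items$note[i] <- "profile corroborates demographics"
  } else {
    case$items$outcome[i] <- "pending"
  }
  case
}

#' Advance an email-verification state
#'
#' Participants have `email_window_days` (default 30) from issuance to
#' respond; weekly reminders are scheduled at each `reminder_period_days`
#' mark inside the window while no response has arrived. A response by
#' day 30 verifies; with no response the state expires the day after the
#' window closes and the participant is not enrolled.
#'
#' @param state List with `issued_on` (Date), optionally `responded_on`,
#'   `reminders_sent`, `status`.
#' @param now Date at which the state is evaluated.
#' @param response Date the response arrived, or `NULL`.
#' @param config An [auth_config()].
#' @return Updated state list with `status` in
#'   `c("pending", "verified", "expired")` and `reminders_sent` (Dates).
#' @examples
#' st <- list(issued_on = as.Date("2018-06-01"))
#' email_verification_step(st, now = as.Date("2018-07-03"))$status  # expired
#' @export
email_verification_step <- function(state, now, response = NULL, config = auth_config()) {
  issued <- as.Date(state$issued_on)
  window_end <- issued + config$email_window_days
  if (!is.null(response)) {
    response <- as.Date(response)
    if (response < issued) {
      abort("email response precedes issuance", class = "authsieve_validation_error")
    }
  }
  marks <- issued + seq(config$reminder_period_days, config$email_window_days - 1,
                        by = config$reminder_period_days)
  cutoff <- if (!is.null(response)) response else as.Date(now)
  state$reminders_sent <- marks[marks < cutoff]
  if (!is.null(response) && response <= window_end) {
    state$responded_on <- response
    state$status <- "verified"
  } else if (as.Date(now) > window_end) {
    state$status <- "expired"
  } else {
    state$status <- "pending"
  }
  state
}

#' Resolve a manual case to its final disposition
#'
#' Staff resolutions (one per pending item) are applied: a confirmed
#' failure fails the item; an explainable inconsistency (which requires a
#' note, preserving the audit trail) resolves it. Any failed item fails
#' the checklist; a duplicate confirmed before checklist completion
#' short-circuits to `failed_duplicate_no_checklist`; otherwise the case
#' enrolls iff every item passes or is resolved and the email
#' verification completed within the window (an expired verification
#' fails the checklist with a note).
#'
#' @param case A `manual_case` (with `email_state` set for enrollment).
#' @param resolutions Tibble with columns `item`, `outcome` (one of
#'   `pass`, `fail`, `resolved_explainable`), `note`.
#' @param duplicate_confirmed Logical: duplicate confirmed before the
#'   checklist was completed.
#' @return The `manual_case` with `disposition` set.
#' @export
resolve_case <- function(case, resolutions = NULL, duplicate_confirmed = FALSE) {
  if (isTRUE(duplicate_confirmed)) {
    case$items$outcome <- "not_applicable"
    case$disposition <- "failed_duplicate_no_checklist"
    case$note <- "duplicate confirmed before checklist completion"
    return(case)
  }
  if (!is.null(resolutions) && nrow(resolutions) > 0) {
    for (r in seq_len(nrow(resolutions))) {
      i <- which(case$items$item == resolutions$item[r])
      if (length(i) != 1) {
        abort(sprintf("resolution for unknown checklist item: %s", resolutions$item[r]),
              class = "authsieve_contract_error")
      }
      oc <- resolutions$outcome[r]
      nt <- resolutions$note[r] %||% ""
      if (oc == "resolved_explainable" && !nzchar(nt)) {
        abort("resolved_explainable requires a non-empty note",
              class = "authsieve_contract_error")
      }
      case$items$outcome[i] <- oc
      case$items$note[i] <- nt
    }
  }
  if (any(case$items$outcome == "pending")) {
    abort(sprintf("unresolved pending checklist item(s): %s",
                  paste(case$items$item[case$items$outcome == "pending"], collapse = ", ")),
          class = "authsieve_contract_error")
  }
  if (any(case$items$outcome == "fail")) {
    case$disposition <- "failed_checklist"
    return(case)
  }
  email_ok <- !is.null(case$email_state) && identical(case$email_state$status, "verified")
  if (email_ok) {
    case$disposition <- "enrolled"
  } else {
    case$disposition <- "failed_checklist"
    case$note <- "email verification not completed in window"
  }
  case
}

#' Run the manual authentication stage over referred decisions
#'
#' Drives [build_checklist()], [verify_zip()], the survey pattern review
#' (triggered by any carried flag), [apply_social_evidence()], staff
#' resolutions and the email-verification lifecycle for every record the
#' automated battery referred, and assigns each its final disposition.
#'
#' @param decisions An `auth_decisions` tibble from [run_auto_battery()].
#' @param cohort The `auth_cohort` the decisions came from (dossiers,
#'   lookups and — for simulated cohorts — manual evidence).
#' @param evidence Optional list with `resolutions`, `social_profiles`,
#'   `email_log` tibbles; defaults to `cohort$manual_evidence`.
#' @param config An [auth_config()].
#' @param rules Optional conflict-rules tibble for the survey review.
#' @return An `auth_manual_cases` tibble: one row per referred record with
#'   the six item outcomes as columns, `disposition`, `email_status` and
#'   `note`.
#' @export
run_manual_stage <- function(decisions, cohort, evidence = NULL,
                             config = auth_config(), rules = NULL) {
  d <- cohort$dossiers
  if (is.null(evidence)) evidence <- cohort$manual_evidence
  evidence <- evidence %||% list()
  resolutions <- evidence$resolutions %||%
    tibble(participant_id = character(), item = character(),
           finding = character(), note = character())
  social <- evidence$social_profiles %||%
    tibble(participant_id = character(), profile_age = integer(),
           profile_gender = character(), profile_state = character())
  email_log <- evidence$email_log %||%
    tibble(participant_id = character(), issued_on = as.Date(character()),
           responded_on = as.Date(character()))
  registry <- attr(decisions, "registry") %||% cohort$registry
  lookups <- cohort$lookups

  # gazetteer lookup precomputed once for the whole stage
  gz <- lookups$gazetteer
  gz_zip <- character()
  if (!is.null(gz) && nrow(gz) > 0) {
    gz_zip <- stats::setNames(
      gz$zip, paste(normalize_street(gz$street), canonicalize_name(gz$city), sep = "\r")
    )
  }
  d_gz_key <- paste(normalize_street(d$street), canonicalize_name(d$city), sep = "\r")
  d_zip <- if ("mailing_zip" %in% names(d)) d$mailing_zip else d$zip
  row_of <- stats::setNames(seq_len(nrow(d)), d$participant_id)

  referred <- decisions[decisions$status == "referred_manual", , drop = FALSE]
  rows <- vector("list", nrow(referred))
  for (k in seq_len(nrow(referred))) {
    dec <- referred[k, , drop = FALSE]
    pid <- dec$participant_id
    ridx <- row_of[[pid]]
    dos <- d[ridx, , drop = FALSE]
    res_k <- resolutions[resolutions$participant_id == pid, , drop = FALSE]

    if (any(res_k$finding == "pre_checklist_duplicate")) {
      case <- new_manual_case(pid, tibble(item = CHECKLIST_ITEMS,
                                          outcome = "not_applicable", note = ""))
      case <- resolve_case(case, duplicate_confirmed = TRUE)
      rows[[k]] <- case_to_row(case, email_status = "not_issued")
      next
    }

    case <- build_checklist(dec, dos)

    indexed_zip <- if (length(gz_zip)) gz_zip[d_gz_key[ridx]] else NA_character_
    if (is.na(indexed_zip) || !identical(unname(indexed_zip), d_zip[ridx])) {
      i <- which(case$items$item == "zip_check")
      if (case$items$outcome[i] == "pass") case$items$outcome[i] <- "pending"
    }

    triggered <- dec$n_flags > 0 ||
      any(case$items$outcome[case$items$item != "social_media_check"] == "pending")
    if (triggered) {
      pr <- pattern_review(dos, config, rules)
      i <- which(case$items$item == "pattern_check")
      case$items$outcome[i] <- if (pr$outcome == "fail") "fail" else "pass"
      if (pr$outcome == "fail") case$items$note[i] <- pr$reason
    }

    soc_k <- social[social$participant_id == pid, , drop = FALSE]
    case <- apply_social_evidence(case, soc_k, dos, config)

    staff <- res_k[res_k$finding %in% c("confirm_fail", "explainable", "corroborate"), ,
                   drop = FALSE]
    res_tbl <- NULL
    if (nrow(staff) > 0) {
      res_tbl <- tibble(
        item = staff$item,
        outcome = c(confirm_fail = "fail", explainable = "resolved_explainable",
                    corroborate = "pass")[staff$finding],
        note = staff$note
      )
      # only apply to items actually pending; extra staff notes are ignored
      pending_items <- case$items$item[case$items$outcome == "pending"]
      res_tbl <- res_tbl[res_tbl$item %in% pending_items, , drop = FALSE]
    }

    el <- email_log[email_log$participant_id == pid, , drop = FALSE]
    email_status <- "not_issued"
    if (nrow(el) == 1) {
      responded <- if (is.na(el$responded_on)) NULL else el$responded_on
      st <- email_verification_step(
        list(issued_on = el$issued_on),
        now = el$issued_on + config$email_window_days + 1,
        response = responded, config = config
      )
      case$email_state <- st
      email_status <- st$status
    }

    case <- resolve_case(case, res_tbl)
    rows[[k]] <- case_to_row(case, email_status = email_status)
  }

  out <- bind_rows(rows)
  structure(out, config = config,
            class = c("auth_manual_cases", class(out)))
}

case_to_row <- function(case, email_status) {
  oc <- stats::setNames(case$items$outcome, case$items$item)
  notes <- case$items$note[nzchar(case$items$note)]
  tibble(
    participant_id = case$participant_id,
    time_stamp = oc[["time_stamp"]],
    age_comparison = oc[["age_comparison"]],
    duplicate_check = oc[["duplicate_check"]],
    pattern_check = oc[["pattern_check"]],
    social_media_check = oc[["social_media_check"]],
    zip_check = oc[["zip_check"]],
    disposition = case$disposition,
    email_status = email_status,
    note = paste(c(case$note[nzchar(case$note)], notes), collapse = " | ")
  )
}
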