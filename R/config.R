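#' Pipeline threshold configuration
#'
#' Bundles every tunable threshold used by the automated battery, the
#' matching rules, the pattern detectors and the manual stage. Defaults are
#' the operating values of the authentication protocol the package
#' implements; all are overridable per run.
#'
#' Completion-score gates are derived as `ceiling(frac * n)` answered items:
#' with the default fractions this yields hard-fail gates of 17/27 (random
#' question subset) and 44/62 (primary outcomes) and a manual-review flag
#' band below 22/27 and 50/62.
#'
#' @param min_age,max_age Eligible age range in whole years (inclusive).
#' @param subset_n Number of slots in the random question subset block.
#' @param outcome_n Number of slots in the primary-outcome block.
#' @param subset_fail_frac Answered fraction below which the subset block
#'   hard-fails (default 0.60).
#' @param outcome_fail_frac Answered fraction below which the outcome block
#'   hard-fails (default 0.70).
#' @param manual_flag_frac Answered fraction below which (but above the fail
#'   gates) a record is flagged for manual review (default 0.80).
#' @param min_minutes Baseline completions faster than this are flagged as
#'   speeders (strictly less than; default 20, for an instrument designed to
#'   take about `design_minutes`).
#' @param design_minutes Nominal instrument length, minutes (metadata).
#' @param max_hours Completions longer than this are flagged as unusually
#'   long (default 72).
#' @param email_window_days Days allowed to answer the verification email
#'   (default 30).
#' @param reminder_period_days Reminder cadence during the email window
#'   (default 7).
#' @param code_digits Length of the SMS verification code (default 3).
#' @param cluster_min_size Number of registry records sharing a street
#'   (different house numbers) at which an address cluster is declared.
#' @param name_edit_max,email_edit_max Maximum edit distance for a partial
#'   name / email local-part match (default 1; same domain required for
#'   emails).
#' @param likert_min,likert_max Likert response scale bounds (default 1-5).
#' @param strip_plus_tags Strip `+tag` suffixes from email local parts
#'   during canonicalization (default `TRUE`).
#' @param straightline_threshold Longest-constant-run fraction at or above
#'   which a block counts as straight-lined (default 0.95).
#' @param zigzag_threshold Alternation index at or above which a block
#'   counts as a high-amplitude zigzag ("Christmas tree") pattern.
#' @param pattern_min_items Minimum answered items for pattern detection.
#' @param quota_gating Enforce the generic enrollment-quota predicate
#'   (a logical `meets_quota` column on screening records) during the
#'   eligibility recheck.
#' @param blocking_threshold Registry size above which partial matching is
#'   restricted to blocked candidate pairs rather than a full scan.
#'
#' @return A named list with class `auth_config`.
#' @examples
#' cfg <- auth_config()
#' completion_gates(cfg)
#' @export
auth_config <- function(min_age = 13L,
                        max_age = 18L,
                        subset_n = 27L,
                        outcome_n = 62L,
                        subset_fail_frac = 0.60,
                        outcome_fail_frac = 0.70,
                        manual_flag_frac = 0.80,
                        min_minutes = 20,
                        design_minutes = 30,
                        max_hours = 72,
                        email_window_days = 30L,
                        reminder_period_days = 7L,
                        code_digits = 3L,
                        cluster_min_size = 3L,
                        name_edit_max = 1L,
                        email_edit_max = 1L,
                        likert_min = 1L,
                        likert_max = 5L,
                        strip_plus_tags = TRUE,
                        straightline_threshold = 0.95,
                        zigzag_threshold = 0.9,
                        pattern_min_items = 10L,
                        quota_gating = TRUE,
                        blocking_threshold = 10000L) {
  cfg <- list(
    min_age = as.integer(min_age), max_age = as.integer(max_age),
    subset_n = as.integer(subset_n), outcome_n = as.integer(outcome_n),
    subset_fail_frac = subset_fail_frac,
    outcome_fail_frac = outcome_fail_frac,
    manual_flag_frac = manual_flag_frac,
    min_minutes = min_minutes, design_minutes = design_minutes,
    max_hours = max_hours,
    email_window_days = as.integer(email_window_days),
    reminder_period_days = as.integer(reminder_period_days),
    code_digits = as.integer(code_digits),
    cluster_min_size = as.integer(cluster_min_size),
    name_edit_max = as.integer(name_edit_max),
    email_edit_max = as.integer(email_edit_max),
    likert_min = as.integer(likert_min), likert_max = as.integer(likert_max),
    strip_plus_tags = isTRUE(strip_plus_tags),
    straightline_threshold = straightline_threshold,
    zigzag_threshold = zigzag_threshold,
    pattern_min_items = as.integer(pattern_min_items),
    quota_gating = isTRUE(quota_gating),
    blocking_threshold = as.integer(blocking_threshold)
  )
  validate_auth_config(cfg)
  structure(cfg, class = "auth_config")
}

validate_auth_config <- function(cfg) {
  stopifnot(
    cfg$min_age <= cfg$max_age,
    cfg$subset_fail_frac > 0, cfg$outcome_fail_frac > 0,
    cfg$subset_fail_frac < cfg$manual_flag_frac,
    cfg$outcome_fail_frac < cfg$manual_flag_frac,
    cfg$manual_flag_frac <= 1,
    cfg$likert_min < cfg$likert_max,
    cfg$min_minutes >= 0, cfg$max_hours > 0,
    cfg$code_digits >= 1, cfg$cluster_min_size >= 1
  )
  invisible(cfg)
}

#' @export
print.auth_config <- function(x, ...) {
  cat("<auth_config>\n")
  gates <- completion_gates(x)
  cat(sprintf(
    "  eligible age %d-%d; completion gates %d/%d and %d/%d (flag band < %d, < %d)\n",
    x$min_age, x$max_age, gates$subset_fail, x$subset_n,
    gates$outcome_fail, x$outcome_n, gates$subset_flag, gates$outcome_flag
  ))
  cat(sprintf(
    "  time gate < %g min (long > %g h); email window %d d, reminders every %d d\n",
    x$min_minutes, x$max_hours, x$email_window_days, x$reminder_period_days
  ))
  invisible(x)
}

#' Answered-item gates implied by a configuration
#'
#' @param config An [auth_config()].
#' @return A list with integer elements `subset_fail`, `outcome_fail`,
#'   `subset_flag`, `outcome_flag`: the minimum answered counts at which the
#'   corresponding gate no longer fires.
#' @export
completion_gates <- function(config = auth_config()) {
  list(
    subset_fail = as.integer(ceiling(config$subset_fail_frac * config$subset_n)),
    outcome_fail = as.integer(ceiling(config$outcome_fail_frac * config$outcome_n)),
    subset_flag = as.integer(ceiling(config$manual_flag_frac * config$subset_n)),
    outcome_flag = as.integer(ceiling(config$manual_flag_frac * config$outcome_n))
  )
}

#' Read / write a configuration as YAML
#'
#' @param path File path of the YAML configuration.
#' @return `read_auth_config()` returns an [auth_config()];
#'   `write_auth_config()` returns `path` invisibly.
#' @export
read_auth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(auth_config, vals)
}

#' @param config An [auth_config()].
#' @rdname read_auth_config
#' @export
write_auth_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
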