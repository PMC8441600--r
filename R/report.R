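# Funnel and status-table reporting. Percentages are computed with exact
# integer arithmetic under an explicit convention (round-half-up or
# truncate); published enrollment tables mix the two conventions, so the
# mode is pinned per table rather than guessed.

#' Format an exact percentage
#'
#' Computes `100 * numerator / denominator` to `places` decimals using
#' integer arithmetic (no floating-point rounding), either rounding half
#' away from zero or truncating toward zero.
#'
#' @param numerator,denominator Nonnegative integers with
#'   `numerator <= denominator`, `denominator > 0`. Vectorized.
#' @param places Decimal places (default 2).
#' @param mode `"round_half_up"` (default) or `"truncate"`.
#' @return Character vector of formatted percentages in `[0, 100]`.
#' @examples
#' percent_format(13931, 19709)                     # "70.68"
#' percent_format(1224, 1324, mode = "truncate")    # "92.44"
#' @export
percent_format <- function(numerator, denominator, places = 2,
                           mode = c("round_half_up", "truncate")) {
  mode <- match.arg(mode)
  if (any(denominator == 0)) {
    abort("zero denominator in percent_format", class = "authsieve_validation_error")
  }
  if (any(numerator < 0 | numerator > denominator)) {
    abort("numerator must lie in [0, denominator]",
          class = "authsieve_validation_error")
  }
  p10 <- 10^places
  scaled <- as.numeric(numerator) * 100 * p10
  q <- scaled %/% denominator
  r <- scaled %% denominator
  if (mode == "round_half_up") {
    q <- q + (2 * r >= denominator)
  }
  if (places == 0) {
    sprintf("%d", as.integer(q))
  } else {
    sprintf("%d.%0*d", as.integer(q %/% p10), as.integer(places),
            as.integer(q %% p10))
  }
}

new_report_table <- function(rows, denominator, places, mode, title) {
  structure(rows, denominator = denominator, places = places, mode = mode,
            title = title, class = c("auth_report_table", class(rows)))
}

#' @export
print.auth_report_table <- function(x, ...) {
  cat(sprintf("%s (N=%d)\n", attr(x, "title"), attr(x, "denominator")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-42s %6d (%s)\n", x$label[i], x$count[i], x$percent[i]))
  }
  invisible(x)
}

#' Enrollment funnel report
#'
#' Stage-over-stage percentages down the enrollment funnel, each stage
#' against its predecessor (completed screening over site visitors,
#' eligible over screened, consented over eligible, started baseline over
#' contact-verified, and so on).
#'
#' @param counts Tibble with columns `stage` and `count` in funnel order
#'   (see [default_funnel_counts()]), or a named integer vector.
#' @param places,mode Passed to [percent_format()].
#' @return An `auth_report_table` with `label`, `count`, `denominator`,
#'   `percent` columns.
#' @examples
#' funnel_report(default_funnel_counts())
#' @export
funnel_report <- function(counts, places = 2, mode = "round_half_up") {
  if (!is.data.frame(counts)) {
    counts <- tibble(stage = names(counts), count = as.integer(counts))
  }
  if (any(diff(counts$count) > 0)) {
    abort("funnel counts must be non-increasing down the stages",
          class = "authsieve_validation_error")
  }
  denom <- c(counts$count[1], counts$count[-nrow(counts)])
  rows <- tibble(
    label = counts$stage,
    count = counts$count,
    denominator = denom,
    percent = percent_format(counts$count, denom, places, mode)
  )
  new_report_table(rows, counts$count[1], places, mode, "Enrollment funnel")
}

#' Status tables for one pipeline run
#'
#' Builds the three standard reporting tables: automated statuses over
#' all processed attempts, manual dispositions over referred attempts,
#' and checklist failure reasons over checklist failures (reasons are not
#' mutually exclusive, so that table has no sum constraint). Percent
#' conventions are pinned per table to match conventional reporting:
#' round-half-up at 2 decimals for the automated table, truncation at 1
#' decimal for dispositions, round-half-up at 1 decimal for reasons.
#'
#' @param decisions `auth_decisions` tibble.
#' @param manual_cases `auth_manual_cases` tibble (optional).
#' @return Named list of `auth_report_table`s: `automated`, `manual`,
#'   `reasons` (the latter two `NULL` without manual cases).
#' @export
status_tables <- function(decisions, manual_cases = NULL) {
  n <- nrow(decisions)
  auto_counts <- vapply(AUTO_STATUSES, function(s) sum(decisions$status == s), 0L)
  automated <- new_report_table(
    tibble(label = AUTO_STATUSES, count = as.integer(auto_counts),
           denominator = n,
           percent = percent_format(auto_counts, n, 2, "round_half_up")),
    n, 2, "round_half_up", "Automated authentication status"
  )
  manual <- reasons <- NULL
  if (!is.null(manual_cases) && nrow(manual_cases) > 0) {
    m <- nrow(manual_cases)
    disp_order <- c("failed_duplicate_no_checklist", "failed_checklist", "enrolled")
    disp_counts <- vapply(disp_order, function(s) sum(manual_cases$disposition == s), 0L)
    manual <- new_report_table(
      tibble(label = disp_order, count = as.integer(disp_counts), denominator = m,
             percent = percent_format(disp_counts, m, 1, "truncate")),
      m, 1, "truncate", "Manual authentication status"
    )
    failed <- manual_cases[manual_cases$disposition == "failed_checklist", , drop = FALSE]
    k <- nrow(failed)
    reason_items <- c("time_stamp", "age_comparison", "duplicate_check",
                      "pattern_check", "social_media_check")
    reason_counts <- vapply(reason_items, function(it) sum(failed[[it]] == "fail"), 0L)
    reasons <- new_report_table(
      tibble(label = reason_items, count = as.integer(reason_counts),
             denominator = k,
             percent = if (k > 0) percent_format(reason_counts, k, 1, "round_half_up")
                       else rep("", length(reason_items))),
      k, 1, "round_half_up", "Manual checklist failure reasons (non-exclusive)"
    )
  }
  list(automated = automated, manual = manual, reasons = reasons)
}

#' Enrollments prevented across both stages
#'
#' @param decisions `auth_decisions` tibble.
#' @param manual_cases `auth_manual_cases` tibble.
#' @return List with `automated` (attempts excluded by the battery),
#'   `manual` (referred attempts not enrolled), `total`, and
#'   `automated_share_pct` (automated share of all prevented
#'   enrollments, percent rounded to integer precision).
#' @export
prevented_enrollments <- function(decisions, manual_cases) {
  automated <- sum(decisions$status != "referred_manual")
  manual <- sum(manual_cases$disposition != "enrolled")
  total <- automated + manual
  list(
    automated = automated, manual = manual, total = total,
    automated_share_pct = as.numeric(percent_format(automated, total, 0))
  )
}
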