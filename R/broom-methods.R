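# broom-style accessors and ggplot2 autoplot methods for the pipeline's
# result objects.

#' @export
print.auth_decisions <- function(x, ...) {
  cat(sprintf("<auth_decisions> %d attempt(s): %s\n", nrow(x),
              paste(sprintf("%s %d", names(table(x$status)), table(x$status)),
                    collapse = ", ")))
  NextMethod()
}

#' Tidy automated decisions into a plain tibble
#'
#' @param x An `auth_decisions` object.
#' @param ... Unused.
#' @return A tibble with one row per attempt and flags flattened to a
#'   `;`-separated string.
#' @method tidy auth_decisions
#' @export
tidy.auth_decisions <- function(x, ...) {
  tibble(
    participant_id = x$participant_id,
    status = x$status,
    flags = vapply(x$flags, paste, "", collapse = ";"),
    n_flags = x$n_flags,
    answered_subset = x$answered_subset,
    answered_outcome = x$answered_outcome
  )
}

#' One-row summary of a battery run
#'
#' @param x An `auth_decisions` object.
#' @param ... Unused.
#' @return A one-row tibble: total attempts, one column per automated
#'   status, and the number of flag-carrying referred records.
#' @method glance auth_decisions
#' @export
glance.auth_decisions <- function(x, ...) {
  out <- tibble(n = nrow(x))
  for (s in AUTO_STATUSES) out[[s]] <- sum(x$status == s)
  out$referred_with_flags <- sum(x$status == "referred_manual" & x$n_flags > 0)
  out
}

#' @method tidy auth_manual_cases
#' @export
tidy.auth_manual_cases <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of the manual stage
#'
#' @param x An `auth_manual_cases` object.
#' @param ... Unused.
#' @return A one-row tibble with case counts per disposition.
#' @method glance auth_manual_cases
#' @export
glance.auth_manual_cases <- function(x, ...) {
  tibble(
    n = nrow(x),
    enrolled = sum(x$disposition == "enrolled"),
    failed_checklist = sum(x$disposition == "failed_checklist"),
    failed_duplicate_no_checklist = sum(x$disposition == "failed_duplicate_no_checklist")
  )
}

#' Plot automated status counts
#'
#' @param object An `auth_decisions` object.
#' @param ... Unused.
#' @return A ggplot bar chart of attempts per automated status.
#' @method autoplot auth_decisions
#' @export
autoplot.auth_decisions <- function(object, ...) {
  dat <- count(as_tibble(object), .data$status)
  dat$status <- factor(dat$status, levels = AUTO_STATUSES)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "attempts",
                  title = "Automated authentication statuses") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot manual dispositions
#'
#' @param object An `auth_manual_cases` object.
#' @param ... Unused.
#' @return A ggplot bar chart of cases per disposition.
#' @method autoplot auth_manual_cases
#' @export
autoplot.auth_manual_cases <- function(object, ...) {
  dat <- count(as_tibble(object), .data$disposition)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$disposition, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "cases", title = "Manual authentication dispositions") +
    ggplot2::theme_minimal()
}

#' Plot an enrollment funnel or status report table
#'
#' @param object An `auth_report_table`.
#' @param ... Unused.
#' @return A ggplot horizontal bar chart with the reported percentages.
#' @method autoplot auth_report_table
#' @export
autoplot.auth_report_table <- function(object, ...) {
  dat <- as_tibble(object)
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$count, y = .data$label)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%s%%)", .data$count, .data$percent)),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(x = "count", y = NULL, title = attr(object, "title")) +
    ggplot2::theme_minimal()
}
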