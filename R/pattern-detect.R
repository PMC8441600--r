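# Suspicious response-pattern operators used during manual survey review:
# straight-lining (one response for nearly every item), high-amplitude
# alternation (the "Christmas tree" zigzag of non-engaged responding), and
# rule-based conflicting answers.

#' Detect straight-lining in a Likert block
#'
#' The statistic is the length of the longest constant run among answered
#' items divided by the number of answered items; a block straight-lines
#' when the fraction reaches `straightline_threshold` (default 0.95, so 19
#' identical responses out of 20 answered already trip it).
#'
#' @param block Integer vector of ordered Likert responses; `NA` = skipped.
#' @param config An [auth_config()].
#' @return List with `is_straightline` (logical) and `fraction`. An
#'   all-missing or too-short block returns `FALSE` with fraction 0.
#' @examples
#' detect_straightline(rep(3L, 20))
#' @export
detect_straightline <- function(block, config = auth_config()) {
  x <- block[!is.na(block)]
  if (length(x) < config$pattern_min_items) {
    return(list(is_straightline = FALSE, fraction = 0))
  }
  runs <- rle(x)$lengths
  frac <- max(runs) / length(x)
  list(is_straightline = frac >= config$straightline_threshold, fraction = frac)
}

#' Detect a high-amplitude zigzag ("Christmas tree") pattern
#'
#' Computed over the answered items in order. With consecutive differences
#' `d[i] = x[i+1] - x[i]`, the alternation index is the fraction of
#' adjacent difference pairs `(d[i-1], d[i])` that reverse sign with both
#' magnitudes at least half the scale span. A perfect 1,5,1,5,... block on
#' a 1-5 scale scores 1; monotone or random responding scores near 0. The
#' block zigzags when the index reaches `zigzag_threshold` (default 0.9).
#'
#' @inheritParams detect_straightline
#' @return List with `is_zigzag` (logical) and `index`.
#' @examples
#' detect_zigzag(rep(c(1L, 5L), 12))
#' @export
detect_zigzag <- function(block, config = auth_config()) {
  x <- block[!is.na(block)]
  if (length(x) < config$pattern_min_items) {
    return(list(is_zigzag = FALSE, index = 0))
  }
  span <- config$likert_max - config$likert_min
  d <- diff(x)
  big <- abs(d) >= span / 2
  flips <- sign(d[-1]) == -sign(d[-length(d)]) & big[-1] & big[-length(d)] &
    sign(d[-1]) != 0
  idx <- sum(flips) / (length(x) - 2)
  list(is_zigzag = idx >= config$zigzag_threshold, index = idx)
}

#' Detect conflicting (illogical) answer pairs
#'
#' Applies a list of incompatibility rules to a named response vector and
#' reports every violated rule with both observed values. Rule predicates
#' come from a fixed vocabulary:
#' \describe{
#'   \item{mutually_exclusive}{violation when both items are answered (and,
#'     if `param` is given, item A equals `param`).}
#'   \item{requires}{violation when item A is answered but item B is not.}
#'   \item{max_abs_difference}{violation when both answered and
#'     `|a - b| > param`.}
#' }
#'
#' @param responses Named integer vector (or named list) of item responses;
#'   `NA` = not answered.
#' @param rules Tibble (or data frame) with columns `item_a`, `item_b`,
#'   `predicate` and optionally `param`; see [read_conflict_rules()].
#' @return Tibble of violations with the rule and both values; zero rows
#'   when nothing conflicts or no rules are configured.
#' @export
detect_conflicts <- function(responses, rules) {
  empty <- tibble(item_a = character(), item_b = character(),
                  predicate = character(), value_a = integer(), value_b = integer())
  if (is.null(rules) || nrow(rules) == 0) return(empty)
  responses <- unlist(responses)
  missing_items <- setdiff(unique(c(rules$item_a, rules$item_b)), names(responses))
  if (length(missing_items) > 0) {
    abort(sprintf("conflict rule references missing item(s): %s",
                  paste(missing_items, collapse = ", ")),
          class = "authsieve_config_error")
  }
  if (!"param" %in% names(rules)) rules$param <- NA_real_
  out <- list()
  for (r in seq_len(nrow(rules))) {
    a <- responses[[rules$item_a[r]]]
    b <- responses[[rules$item_b[r]]]
    hit <- switch(rules$predicate[r],
      mutually_exclusive = !is.na(a) && !is.na(b) &&
        (is.na(rules$param[r]) || a == rules$param[r]),
      requires = !is.na(a) && is.na(b),
      max_abs_difference = !is.na(a) && !is.na(b) && abs(a - b) > rules$param[r],
      abort(sprintf("unknown conflict predicate: %s", rules$predicate[r]),
            class = "authsieve_config_error")
    )
    if (isTRUE(hit)) {
      out[[length(out) + 1]] <- tibble(
        item_a = rules$item_a[r], item_b = rules$item_b[r],
        predicate = rules$predicate[r],
        value_a = if (is.na(a)) NA_integer_ else as.integer(a),
        value_b = if (is.na(b)) NA_integer_ else as.integer(b)
      )
    }
  }
  if (length(out) == 0) empty else bind_rows(out)
}

#' Read conflict rules from YAML
#'
#' Each rule is a mapping with `item_a`, `item_b`, `predicate` (one of
#' `mutually_exclusive`, `requires`, `max_abs_difference`) and optional
#' `param`.
#'
#' @param path YAML file path.
#' @return A rules tibble for [detect_conflicts()].
#' @export
read_conflict_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  bind_rows(lapply(raw, function(r) {
    tibble(item_a = r$item_a, item_b = r$item_b, predicate = r$predicate,
           param = r$param %||% NA_real_)
  }))
}

#' Review a baseline record's response blocks for suspicious patterns
#'
#' Runs the straight-line and zigzag detectors over each Likert block and
#' the conflict rules over the named responses; any finding fails the
#' check (the record is documented on the manual checklist and not
#' enrolled).
#'
#' @param dossier One-row dossier tibble with `subset_responses` and
#'   `outcome_responses` list columns (each one Likert block).
#' @param config An [auth_config()].
#' @param rules Optional conflict-rules tibble.
#' @return A one-row check-result tibble (`check_id = "pattern"`).
#' @export
pattern_review <- function(dossier, config = auth_config(), rules = NULL) {
  blocks <- list(subset = dossier$subset_responses[[1]],
                 outcome = dossier$outcome_responses[[1]])
  findings <- character()
  ev <- list()
  for (bn in names(blocks)) {
    sl <- detect_straightline(blocks[[bn]], config)
    if (sl$is_straightline) {
      findings <- c(findings, sprintf("straightline:%s", bn))
      ev[[paste0(bn, "_straightline_fraction")]] <- sl$fraction
    }
    zz <- detect_zigzag(blocks[[bn]], config)
    if (zz$is_zigzag) {
      findings <- c(findings, sprintf("zigzag:%s", bn))
      ev[[paste0(bn, "_zigzag_index")]] <- zz$index
    }
  }
  if (!is.null(rules) && nrow(rules) > 0) {
    named <- stats::setNames(
      c(blocks$subset, blocks$outcome),
      c(sprintf("subset_%02d", seq_along(blocks$subset)),
        sprintf("outcome_%02d", seq_along(blocks$outcome)))
    )
    viol <- detect_conflicts(named, rules)
    if (nrow(viol) > 0) {
      findings <- c(findings, sprintf("conflicts:%d", nrow(viol)))
      ev$conflicts <- viol
    }
  }
  if (length(findings) == 0) {
    check_result("pattern", "pass")
  } else {
    check_result("pattern", "fail", paste(findings, collapse = ";"), ev)
  }
}
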