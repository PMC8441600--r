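# Canonicalization of contact fields and exact/partial duplicate detection
# against a registry of prior enrollment attempts and enrolled participants.
# Six field families are compared: email, phone, ip, address, handle, name.
# Phones, IPs and handles match exact-only; names and email local parts
# also match at edit distance <= the configured maximum (default 1, same
# domain required for emails); addresses match exactly or as partial-street
# (same street/city/state/zip, different house number).

STREET_SUFFIXES <- c(
  st = "street", rd = "road", ave = "avenue", blvd = "boulevard",
  ln = "lane", dr = "drive", ct = "court"
)

#' Canonicalize an email address
#'
#' Lowercases and trims the address and (by default) strips a `+tag`
#' suffix from the local part, so aliases of one mailbox collide on the
#' same key. Canonicalization is idempotent.
#'
#' @param raw Character vector of addresses; each must contain exactly one
#'   `@`.
#' @param config An [auth_config()]; `strip_plus_tags` controls tag
#'   stripping.
#' @return Character vector of canonical addresses.
#' @examples
#' canonicalize_email(" A.B+x@Mail.COM ")
#' @export
canonicalize_email <- function(raw, config = auth_config()) {
  x <- tolower(trimws(raw))
  n_at <- stringr::str_count(x, stringr::fixed("@"))
  bad <- !is.na(x) & n_at != 1
  if (any(bad)) {
    abort(sprintf("malformed email address: %s", paste(unique(raw[bad]), collapse = ", ")),
          class = "authsieve_validation_error")
  }
  if (config$strip_plus_tags) {
    x <- sub("\\+[^@]*@", "@", x)
  }
  x
}

#' Canonicalize a phone number to a 10-digit key
#'
#' Strips every non-digit and a leading US country code `1`; the result
#' must be exactly 10 digits.
#'
#' @param raw Character vector of raw phone strings.
#' @return Character vector of 10-digit keys.
#' @examples
#' canonicalize_phone("(404) 555-0123")
#' canonicalize_phone("+1 404 555 0123")
#' @export
canonicalize_phone <- function(raw) {
  x <- gsub("[^0-9]", "", raw)
  x <- sub("^1(?=[0-9]{10}$)", "", x, perl = TRUE)
  bad <- !is.na(x) & nchar(x) != 10
  if (any(bad)) {
    abort(sprintf("phone does not canonicalize to 10 digits: %s",
                  paste(unique(raw[bad]), collapse = ", ")),
          class = "authsieve_validation_error")
  }
  x
}

#' Canonicalize a preferred name
#'
#' Lowercases, strips punctuation and collapses internal whitespace. An
#' empty input yields an empty key, which never participates in matching.
#'
#' @param raw Character vector of names.
#' @return Character vector of name keys.
#' @examples
#' canonicalize_name("  J.  Doe ")
#' @export
canonicalize_name <- function(raw) {
  x <- tolower(ifelse(is.na(raw), "", raw))
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

normalize_street <- function(street) {
  key <- canonicalize_name(street)
  toks <- strsplit(key, " ", fixed = TRUE)
  vapply(toks, function(tk) {
    if (length(tk) == 0) return("")
    hit <- match(tk, names(STREET_SUFFIXES))
    tk[!is.na(hit)] <- STREET_SUFFIXES[hit[!is.na(hit)]]
    paste(tk, collapse = " ")
  }, "")
}

#' Parse address components into a comparable key
#'
#' Normalizes street-suffix tokens from a fixed synonym table
#' (st/street, rd/road, ave/avenue, blvd/boulevard, ln/lane, dr/drive,
#' ct/court) and lowercases the city, so "Wisteria St" and
#' "Wisteria Street" produce the same street key. Blank components reduce
#' match specificity rather than erroring.
#'
#' @param house_number,street,city,state,zip Character vectors (recycled to
#'   a common length).
#' @return A tibble with columns `house_number`, `street_key`, `city_key`,
#'   `state`, `zip`.
#' @export
parse_address <- function(house_number, street, city, state, zip) {
  tibble(
    house_number = trimws(ifelse(is.na(house_number), "", house_number)),
    street_key = normalize_street(street),
    city_key = canonicalize_name(city),
    state = toupper(trimws(ifelse(is.na(state), "", state))),
    zip = trimws(ifelse(is.na(zip), "", zip))
  )
}

address_full_key <- function(ak) {
  ifelse(ak$street_key == "", NA_character_,
         paste(ak$house_number, ak$street_key, ak$city_key, ak$state, ak$zip, sep = "\r"))
}

address_street_key <- function(ak) {
  ifelse(ak$street_key == "", NA_character_,
         paste(ak$street_key, ak$city_key, ak$state, ak$zip, sep = "\r"))
}

#' Compare two parsed addresses
#'
#' @param a,b Single-row tibbles from [parse_address()].
#' @return `"exact"` if all five components are equal, `"partial_street"`
#'   if street/city/state/zip are equal but the house number differs,
#'   otherwise `"none"`.
#' @examples
#' a <- parse_address("12", "Wisteria St", "Springfield", "GA", "30301")
#' b <- parse_address("14", "Wisteria Street", "Springfield", "GA", "30301")
#' partial_match_address(a, b)
#' @export
partial_match_address <- function(a, b) {
  if (a$street_key == "" || b$street_key == "") return("none")
  same_street <- a$street_key == b$street_key && a$city_key == b$city_key &&
    a$state == b$state && a$zip == b$zip
  if (!same_street) return("none")
  if (a$house_number == b$house_number) "exact" else "partial_street"
}

#' Canonicalize a contact table for the registry
#'
#' Vectorized over a contacts (or dossier) table; produces the canonical
#' key columns the matcher consumes. Multi-valued keys (phones, IPs,
#' handles) are `;`-joined.
#'
#' @param contacts Tibble with columns `participant_id`, `preferred_name`,
#'   `email`, `phone_primary`, `phone_alts`, `house_number`, `street`,
#'   `city`, `state`, `zip` (or `mailing_zip`), `social_handles`, and
#'   optionally IP columns (`screen_ip`, `baseline_ip` or `ip_keys`).
#' @param config An [auth_config()].
#' @param enrolled Logical, recycled: whether each row is an enrolled
#'   participant (vs a prior attempt). Both block re-entry.
#' @return A canonical registry tibble.
#' @export
canonicalize_contacts <- function(contacts, config = auth_config(), enrolled = FALSE) {
  zip <- if ("mailing_zip" %in% names(contacts)) contacts$mailing_zip else contacts$zip
  ak <- parse_address(contacts$house_number, contacts$street, contacts$city,
                      contacts$state, zip)
  phone_keys <- mapply(function(p, alts) {
    ks <- c(p, if (!is.na(alts) && nzchar(alts)) strsplit(alts, ";", fixed = TRUE)[[1]])
    ks <- ks[!is.na(ks) & nzchar(ks)]
    paste(canonicalize_phone(ks), collapse = ";")
  }, contacts$phone_primary, contacts$phone_alts %||% NA_character_, USE.NAMES = FALSE)
  handle_keys <- vapply(contacts$social_handles, function(h) {
    if (is.na(h) || !nzchar(h)) return("")
    paste(tolower(trimws(strsplit(h, ";", fixed = TRUE)[[1]])), collapse = ";")
  }, "", USE.NAMES = FALSE)
  ip_keys <- if ("ip_keys" %in% names(contacts)) {
    contacts$ip_keys
  } else {
    sip <- contacts$screen_ip %||% rep(NA_character_, nrow(contacts))
    bip <- contacts$baseline_ip %||% rep(NA_character_, nrow(contacts))
    mapply(function(a, b) paste(unique(stats::na.omit(c(a, b))), collapse = ";"),
           sip, bip, USE.NAMES = FALSE)
  }
  tibble(
    registry_id = contacts$participant_id,
    name_key = canonicalize_name(contacts$preferred_name),
    email_key = canonicalize_email(contacts$email, config),
    phone_keys = phone_keys,
    house_number = ak$house_number,
    street_key = ak$street_key,
    city_key = ak$city_key,
    state = ak$state,
    zip = ak$zip,
    handle_keys = handle_keys,
    ip_keys = ip_keys,
    enrolled = rep_len(enrolled, nrow(contacts))
  )
}

#' Compare two canonical keys within one field family
#'
#' Exact on equality for every family; names and emails additionally match
#' partially when within the configured edit distance (for emails: on the
#' local part, same domain). Phones, IPs and handles are exact-only. The
#' comparison is symmetric. An exact match always has similarity 1; a
#' partial match always has similarity < 1 (`1 - d / max(nchar)`).
#'
#' @param a,b Canonical keys (single strings).
#' @param field One of `"email"`, `"phone"`, `"ip"`, `"address"`,
#'   `"handle"`, `"name"`.
#' @param config An [auth_config()].
#' @return A one-row tibble with columns `kind`, `field`, `similarity`,
#'   `detail`, or `NULL` when the keys do not match.
#' @export
match_field <- function(a, b, field, config = auth_config()) {
  if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) return(NULL)
  mk <- function(kind, sim, detail = "") {
    tibble(kind = kind, field = field, similarity = sim, detail = detail)
  }
  if (identical(a, b)) return(mk("exact", 1))
  if (field == "name" && config$name_edit_max > 0) {
    d <- adist(a, b)[1, 1]
    if (d <= config$name_edit_max) {
      return(mk("partial", 1 - d / max(nchar(a), nchar(b)),
                sprintf("name within %d edit(s)", d)))
    }
  }
  if (field == "email" && config$email_edit_max > 0) {
    pa <- strsplit(a, "@", fixed = TRUE)[[1]]
    pb <- strsplit(b, "@", fixed = TRUE)[[1]]
    if (length(pa) == 2 && length(pb) == 2 && pa[2] == pb[2]) {
      d <- adist(pa[1], pb[1])[1, 1]
      if (d <= config$email_edit_max) {
        return(mk("partial", 1 - d / max(nchar(a), nchar(b)),
                  sprintf("local part within %d edit(s), same domain", d)))
      }
    }
  }
  NULL
}

#' Find duplicate matches for one enrollment attempt
#'
#' Compares a dossier's canonical contact against every registry entry
#' (enrolled participants and prior attempts alike) across all six field
#' families, including cross-slot phone matches (new primary vs a registry
#' entry's alternate number and vice versa: all of an entry's phone keys
#' live in one set). An empty result means the attempt is unique.
#'
#' @param dossier A one-row dossier tibble (see [read_cohort()]) or a
#'   one-row canonical tibble from [canonicalize_contacts()].
#' @param registry Canonical registry tibble.
#' @param config An [auth_config()].
#' @return Tibble of matches with columns `kind` (`exact`/`partial`),
#'   `field`, `other_id`, `similarity`, `detail`.
#' @export
find_duplicates <- function(dossier, registry, config = auth_config()) {
  can <- if ("name_key" %in% names(dossier)) dossier else canonicalize_contacts(dossier, config)
  idx <- registry_index(registry, config)
  registry_query(idx, can, config)
}

#' Detect an address cluster around one enrollment attempt
#'
#' Counts registry records whose address is partial-street-equal to the
#' dossier's (same street/city/state/zip, different house number). A
#' cluster is declared when the count reaches `cluster_min_size`:
#' the signature of coordinated enrollment attempts walking one street.
#'
#' @inheritParams find_duplicates
#' @return List with `is_cluster` (logical) and `members` (registry ids).
#' @export
detect_cluster <- function(dossier, registry, config = auth_config()) {
  can <- if ("name_key" %in% names(dossier)) dossier else canonicalize_contacts(dossier, config)
  idx <- registry_index(registry, config)
  cluster_query(idx, can, config)
}
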