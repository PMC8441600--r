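# Shared fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's index structures: plain loops and
# utils::adist over every pair.

# one fully valid dossier row, overridable field by field
make_dossier <- function(...) {
  base <- tibble::tibble(
    participant_id = "P00001",
    dob = as.Date("2002-03-10"),
    baseline_ip = "73.0.0.1",
    baseline_started_at = as.POSIXct("2018-06-01 10:00:00", tz = "UTC"),
    baseline_ended_at = as.POSIXct("2018-06-01 10:35:00", tz = "UTC"),
    subset_responses = list(rep(3L, 27)),
    outcome_responses = list(rep(c(1L, 2L, 3L, 4L), length.out = 62)),
    preferred_name = "Alex Rivera",
    email = "alex.rivera@example.com",
    phone_primary = "4045550123",
    phone_alts = NA_character_,
    house_number = "12",
    street = "Maple Grove St",
    city = "Springfield",
    state = "GA",
    mailing_zip = "30301",
    social_handles = NA_character_,
    submitted_at = as.POSIXct("2018-06-01 09:50:00", tz = "UTC"),
    screener_id = "S00001",
    reported_age_years = 16L,
    sex_assigned_at_birth = "male",
    gender_identity = "man",
    same_sex_attracted = TRUE,
    hiv_status = "negative",
    screening_zip = "30301",
    screen_ip = "73.0.0.1",
    screen_started_at = as.POSIXct("2018-06-01 09:40:00", tz = "UTC"),
    screen_ended_at = as.POSIXct("2018-06-01 09:49:00", tz = "UTC"),
    code_verified = TRUE,
    consented = TRUE,
    meets_quota = TRUE
  )
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- if (nm %in% c("subset_responses", "outcome_responses")) {
      list(over[[nm]])
    } else {
      over[[nm]]
    }
  }
  base
}

make_lookups <- function(dossiers) {
  authsieve::generate_lookup_tables(dossiers)
}

# random canonical registry rows over tiny value pools so that exact and
# one-edit collisions occur often
random_canonical <- function(n, prefix = "X") {
  nm <- replicate(n, paste(sample(letters[1:3], 3, replace = TRUE), collapse = ""))
  loc <- replicate(n, paste(sample(letters[1:4], 3, replace = TRUE), collapse = ""))
  dom <- sample(c("a.com", "b.org"), n, replace = TRUE)
  phone_pool <- sprintf("404555%04d", 0:14)
  ip_pool <- sprintf("73.0.0.%d", 1:12)
  handle_pool <- sprintf("instagram:h%d", 1:10)
  street_pool <- c("maple street", "oak avenue", "pine road")
  tibble::tibble(
    registry_id = sprintf("%s%04d", prefix, seq_len(n)),
    name_key = nm,
    email_key = paste0(loc, "@", dom),
    phone_keys = vapply(seq_len(n), function(i) {
      paste(sample(phone_pool, sample(1:2, 1)), collapse = ";")
    }, ""),
    house_number = as.character(sample(1:5, n, replace = TRUE)),
    street_key = sample(street_pool, n, replace = TRUE),
    city_key = sample(c("springfield", "riverton"), n, replace = TRUE),
    state = "GA",
    zip = sample(c("30301", "30302"), n, replace = TRUE),
    handle_keys = vapply(seq_len(n), function(i) {
      if (runif(1) < 0.3) "" else sample(handle_pool, 1)
    }, ""),
    ip_keys = vapply(seq_len(n), function(i) {
      paste(sample(ip_pool, sample(1:2, 1)), collapse = ";")
    }, ""),
    enrolled = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}

# quadratic all-pairs, all-families duplicate oracle
brute_find_duplicates <- function(can, registry, config = authsieve::auth_config()) {
  split1 <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
  }
  hits <- list()
  add <- function(kind, field, id) {
    hits[[length(hits) + 1]] <<- tibble::tibble(kind = kind, field = field, other_id = id)
  }
  for (j in seq_len(nrow(registry))) {
    r <- registry[j, ]
    if (nzchar(can$name_key) && nzchar(r$name_key)) {
      if (can$name_key == r$name_key) {
        add("exact", "name", r$registry_id)
      } else if (config$name_edit_max > 0 &&
                 utils::adist(can$name_key, r$name_key)[1, 1] <= config$name_edit_max) {
        add("partial", "name", r$registry_id)
      }
    }
    if (!is.na(can$email_key) && !is.na(r$email_key)) {
      if (can$email_key == r$email_key) {
        add("exact", "email", r$registry_id)
      } else if (config$email_edit_max > 0) {
        a <- strsplit(can$email_key, "@", fixed = TRUE)[[1]]
        b <- strsplit(r$email_key, "@", fixed = TRUE)[[1]]
        if (length(a) == 2 && length(b) == 2 && a[2] == b[2] &&
            utils::adist(a[1], b[1])[1, 1] <= config$email_edit_max) {
          add("partial", "email", r$registry_id)
        }
      }
    }
    if (length(intersect(split1(can$phone_keys), split1(r$phone_keys))) > 0) {
      add("exact", "phone", r$registry_id)
    }
    if (length(intersect(split1(can$ip_keys), split1(r$ip_keys))) > 0) {
      add("exact", "ip", r$registry_id)
    }
    if (length(intersect(split1(can$handle_keys), split1(r$handle_keys))) > 0) {
      add("exact", "handle", r$registry_id)
    }
    if (nzchar(can$street_key) && nzchar(r$street_key)) {
      same_street <- can$street_key == r$street_key && can$city_key == r$city_key &&
        can$state == r$state && can$zip == r$zip
      if (same_street) {
        if (can$house_number == r$house_number) {
          add("exact", "address", r$registry_id)
        } else {
          add("partial", "address", r$registry_id)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(kind = character(), field = character(), other_id = character()))
  }
  dplyr::distinct(dplyr::bind_rows(hits))
}

match_set <- function(m) {
  paste(m$kind, m$field, m$other_id, sep = "|") |> sort()
}

# string long-division percentage oracle (independent of percent_format's
# integer arithmetic): builds the digits one by one
oracle_percent <- function(n, d, places, mode) {
  digits <- integer(0)
  rem <- n * 100
  for (k in 0:(places + 1)) { # integer part, `places` decimals, one lookahead
    digits <- c(digits, rem %/% d)
    rem <- (rem %% d) * 10
  }
  kept <- digits[seq_len(places + 1)]
  val <- sum(kept * 10^(places:0))
  if (mode == "round_half_up" && digits[places + 2] >= 5) {
    val <- val + 1
  }
  if (places == 0) {
    sprintf("%d", val)
  } else {
    sprintf("%d.%0*d", val %/% 10^places, places, val %% 10^places)
  }
}
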