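# Seeded synthetic-cohort generator with planted, labelled anomaly
# archetypes. Clean records satisfy every automated and manual check;
# each non-clean record violates exactly the check(s) its archetype names
# and nothing else, so pipeline output can be compared against truth
# labels record by record. Identity fields (names, emails, streets) are
# drawn from deterministic word lists keyed by the seed; constructed so
# that two distinct generated values are never within one edit of each
# other, which keeps partial matching free of accidental hits. No real
# personal data is ever produced.

SYN_FIRST <- c(
  "liam", "noah", "oliver", "elijah", "mateo", "lucas", "levi", "asher",
  "james", "ethan", "leon", "roman", "hudson", "ezra", "aiden", "sebastian",
  "carter", "daniel", "julian", "anthony", "wyatt", "gabriel", "isaac",
  "dylan", "nathan", "caleb", "ryan", "adrian", "miles", "jonah",
  "theodore", "maverick", "elias", "silas", "weston", "everett", "micah",
  "vincent", "marcus", "felix"
)

SYN_LAST <- c(
  "garcia", "martinez", "johnson", "williams", "brown", "jones", "miller",
  "davis", "rodriguez", "wilson", "anderson", "taylor", "thomas", "moore",
  "jackson", "martin", "leeson", "perez", "thompson", "white", "harris",
  "sanchez", "clark", "ramirez", "lewis", "robinson", "walker", "young",
  "allen", "king", "wright", "scott", "torres", "nguyen", "hill", "flores",
  "green", "adams", "nelson", "baker"
)

SYN_STREET_A <- c(
  "maple", "oak", "cedar", "pine", "elm", "birch", "walnut", "chestnut",
  "willow", "aspen", "sycamore", "magnolia", "juniper", "laurel", "poplar",
  "hickory", "spruce", "alder", "hawthorn", "linden", "mulberry", "dogwood",
  "redwood", "cypress", "beech", "locust", "catalpa", "sumac", "buckeye",
  "basswood", "ironwood", "cottonwood", "tamarack", "larch", "hemlock",
  "pecan", "sequoia", "palmetto", "mesquite", "acacia"
)

SYN_STREET_B <- c(
  "ridge", "hollow", "meadow", "grove", "crest", "valley", "brook",
  "summit", "glen", "knoll", "park", "garden", "harbor", "landing", "point",
  "bend", "crossing", "run", "trace", "view", "spring", "field", "forest",
  "lake", "creek", "bluff", "cove", "dale", "gate", "haven", "heights",
  "hollowside", "orchard", "prairie", "shore", "slope", "terrace", "trail",
  "vista", "walk"
)

SYN_SUFFIX <- c("St", "Ave", "Rd", "Blvd", "Ln", "Dr", "Ct")

SYN_CITY <- c(
  "springfield", "riverton", "fairview", "greenville", "bristol", "clinton",
  "ashland", "burlington", "manchester", "milton", "auburn", "dayton",
  "clayton", "lexington", "milford", "salem", "oxford", "arlington",
  "georgetown", "madison"
)

SYN_STATE <- c("GA", "NY", "CA", "TX", "FL", "MI", "PA", "IL", "OH", "NC")
SYN_DOMAIN <- c("example.com", "mailbox.org", "inboxly.net", "postbin.io",
                "webmailer.us", "mailhub.co", "letterdrop.me")
SYN_AREA <- c("404", "212", "310", "734", "215", "312", "614", "919")

ARCHETYPES <- c(
  "clean", "underage", "overage", "not_same_sex_attracted", "hiv_positive",
  "quota_fail", "exact_duplicate", "partial_duplicate", "foreign_ip",
  "state_mismatch_ip", "speeder", "slow_outlier", "low_completion_subset",
  "low_completion_outcome", "flag_band_completion", "age_inconsistent",
  "straightliner", "zigzagger", "conflicted", "wisteria_index",
  "wisteria_cluster", "social_contradicted", "email_nonresponder",
  "late_duplicate", "speeder_straightliner", "age_social_contradicted",
  "partial_duplicate_zigzagger"
)

# encode an integer as doubled letters (0 -> "aa", 12 -> "bbcc"); any two
# distinct codes differ by at least two edits
letter_code <- function(i) {
  vapply(i, function(k) {
    ds <- strsplit(sprintf("%d", k), "", fixed = TRUE)[[1]]
    paste(strrep(letters[as.integer(ds) + 1], 2), collapse = "")
  }, "")
}

title_case <- function(s) gsub("\\b([a-z])", "\\U\\1", s, perl = TRUE)

syn_name <- function(uid) {
  f <- SYN_FIRST[(uid - 1) %% 40 + 1]
  l <- SYN_LAST[((uid - 1) %/% 40) %% 40 + 1]
  k <- (uid - 1) %/% 1600
  title_case(ifelse(k == 0, paste(f, l), paste(f, l, letter_code(k))))
}

syn_email <- function(uid) {
  f <- SYN_FIRST[(uid - 1) %% 40 + 1]
  l <- SYN_LAST[((uid - 1) %/% 40) %% 40 + 1]
  paste0(f, ".", l, ".", letter_code(uid), "@", SYN_DOMAIN[(uid - 1) %% 7 + 1])
}

syn_phone <- function(idx) {
  paste0(SYN_AREA[(idx - 1) %% 8 + 1], sprintf("%07d", 1000000 + idx))
}

syn_street <- function(uid) {
  a <- SYN_STREET_A[(uid - 1) %% 40 + 1]
  b <- SYN_STREET_B[((uid - 1) %/% 40) %% 40 + 1]
  k <- (uid - 1) %/% 1600
  base <- ifelse(k == 0, paste(a, b), paste(a, b, letter_code(k)))
  paste(title_case(base), SYN_SUFFIX[(uid - 1) %% 7 + 1])
}

syn_city <- function(uid) title_case(SYN_CITY[(uid - 1) %% 20 + 1])
syn_state <- function(uid) SYN_STATE[(uid - 1) %% 10 + 1]
syn_other_state <- function(uid) SYN_STATE[uid %% 10 + 1]
syn_zip <- function(uid) sprintf("%05d", 30000 + uid)
syn_us_ip <- function(uid) {
  paste("73", (uid %/% 65536) %% 256, (uid %/% 256) %% 256, uid %% 256, sep = ".")
}
syn_foreign_ip <- function(uid) {
  paste("81", "2", (uid %/% 256) %% 256, uid %% 256, sep = ".")
}
syn_handle <- function(name) paste0("instagram:", gsub(" ", "_", tolower(name)))

WISTERIA <- list(street = "Wisteria St", city = "Springfield", state = "GA",
                 zip = "30301")

#' Specify an archetype mix for the synthetic generator
#'
#' @param ... Named nonnegative integer counts, e.g.
#'   `archetype_mix(clean = 10, speeder = 2)`. Names must be known
#'   archetypes.
#' @return A tibble with columns `archetype`, `count` (order preserved:
#'   the generator emits records in mix order).
#' @seealso [default_archetype_mix()] for the full study composition.
#' @export
archetype_mix <- function(...) {
  counts <- c(...)
  bad <- setdiff(names(counts), ARCHETYPES)
  if (length(bad) > 0) {
    abort(sprintf("unknown archetype(s): %s", paste(bad, collapse = ", ")),
          class = "authsieve_config_error")
  }
  tibble(archetype = names(counts), count = as.integer(counts))
}

#' The default archetype mix
#'
#' The composition that emulates the reference enrollment cohort of 1224
#' baseline-starting attempts: 492 automated exclusions (32 eligibility,
#' 177 duplicates including the cluster's index attempt, 8 foreign IPs,
#' 252 completion failures, 23 street-cluster attempts) and 732 referred
#' records (600 that resolve and enroll, 123 checklist failures whose
#' overlapping failure reasons tally 33 time-stamp / 20 age / 28
#' duplicate / 33 pattern / 20 social, and 9 late-surfacing duplicates
#' caught before checklist completion).
#'
#' @return An archetype-mix tibble (total count 1224).
#' @export
default_archetype_mix <- function() {
  archetype_mix(
    quota_fail = 30, hiv_positive = 2,
    exact_duplicate = 176, wisteria_index = 1,
    foreign_ip = 8,
    low_completion_subset = 126, low_completion_outcome = 126,
    wisteria_cluster = 23,
    clean = 560, state_mismatch_ip = 20, slow_outlier = 20,
    speeder = 28, age_inconsistent = 17, partial_duplicate = 25,
    straightliner = 13, zigzagger = 12, social_contradicted = 17,
    speeder_straightliner = 5, age_social_contradicted = 3,
    partial_duplicate_zigzagger = 3,
    late_duplicate = 9
  )
}

#' The enrollment-funnel stage counts the default cohort emulates
#'
#' @return A tibble of funnel stages and counts, from site visitors down
#'   to enrolled participants.
#' @export
default_funnel_counts <- function() {
  tibble(
    stage = c("visitors", "screened", "eligible", "consented",
              "contact_verified", "started_baseline", "referred_manual",
              "enrolled"),
    count = c(19709L, 13931L, 3253L, 2544L, 1324L, 1224L, 732L, 600L)
  )
}

build_registry_contacts <- function(n_reg) {
  uid <- seq_len(n_reg)
  name <- syn_name(uid)
  ct <- tibble(
    participant_id = sprintf("R%05d", uid),
    preferred_name = name,
    email = syn_email(uid),
    phone_primary = syn_phone(uid),
    phone_alts = syn_phone(400000 + uid),
    house_number = as.character(100 + (uid * 3) %% 899),
    street = syn_street(uid),
    city = syn_city(uid),
    state = syn_state(uid),
    zip = syn_zip(uid),
    social_handles = syn_handle(name),
    ip_keys = syn_us_ip(uid)
  )
  # two already-enrolled participants on Wisteria Street (houses 10 and 12);
  # the first one's secondary phone is the number the index attempt reuses
  ct$house_number[1:2] <- c("10", "12")
  ct$street[1:2] <- WISTERIA$street
  ct$city[1:2] <- WISTERIA$city
  ct$state[1:2] <- WISTERIA$state
  ct$zip[1:2] <- WISTERIA$zip
  ct
}

#' Generate lookup tables consistent with a set of dossiers
#'
#' Builds the IP-geolocation table (every IP present, mapped to the
#' country/state its record's archetype requires) and the street/zip
#' gazetteer (every street present with its own zip; one row per distinct
#' street+city). With no truth labels every IP maps to the record's
#' mailing state inside the US.
#'
#' @param dossiers Dossier tibble.
#' @param truth Optional truth tibble (`participant_id`, `archetype`).
#' @return List with `geoip` and `gazetteer` tibbles.
#' @export
generate_lookup_tables <- function(dossiers, truth = NULL) {
  d <- dossiers
  arch <- rep("clean", nrow(d))
  if (!is.null(truth)) {
    arch <- truth$archetype[match(d$participant_id, truth$participant_id)]
    arch[is.na(arch)] <- "clean"
  }
  geo_country <- ifelse(arch == "foreign_ip", "GB", "US")
  geo_state <- ifelse(arch == "foreign_ip", "",
                      ifelse(arch == "state_mismatch_ip",
                             syn_other_state(seq_len(nrow(d))), d$state))
  # avoid declaring a "mismatch" state equal to the mailing state
  fix <- arch == "state_mismatch_ip" & geo_state == d$state
  geo_state[fix] <- SYN_STATE[(match(d$state[fix], SYN_STATE) + 4) %% 10 + 1]
  geoip <- bind_rows(
    tibble(ip = d$baseline_ip, country = geo_country, state = geo_state),
    tibble(ip = d$screen_ip, country = geo_country, state = geo_state)
  ) %>% distinct(.data$ip, .keep_all = TRUE)
  gazetteer <- tibble(street = d$street, city = d$city, state = d$state,
                      zip = d$mailing_zip) %>%
    mutate(.key = paste(normalize_street(.data$street),
                        canonicalize_name(.data$city), sep = "\r")) %>%
    distinct(.data$.key, .keep_all = TRUE) %>%
    select(-".key")
  list(geoip = geoip, gazetteer = gazetteer)
}

#' Simulate an enrollment cohort with planted anomalies
#'
#' Generates a fully reproducible cohort: the same mix, seed and
#' configuration always produce byte-identical output. Clean records pass
#' every check in both stages; each planted archetype violates exactly
#' its intended check(s). The returned `auth_cohort` carries the
#' registry of prior attempts/enrolled participants the archetypes
#' reference, the matched lookup tables, the manual-stage evidence
#' (staff resolutions, social-profile facts, email-verification log) and
#' per-record truth labels with the expected automated status, manual
#' disposition and failure reasons. Truth labels are never read by the
#' pipeline.
#'
#' @param mix An archetype-mix tibble; see [archetype_mix()].
#' @param seed Integer RNG seed; field values vary with the seed, the
#'   satisfied checks never do.
#' @param config An [auth_config()].
#' @return An `auth_cohort` (see [read_cohort()]) with `registry`,
#'   `truth`, `manual_evidence` and (for a 1224-record mix) `funnel`
#'   populated.
#' @examples
#' cohort <- simulate_cohort(archetype_mix(clean = 3, speeder = 1), seed = 7)
#' cohort$truth
#' @export
simulate_cohort <- function(mix = default_archetype_mix(), seed = 20210831,
                            config = auth_config()) {
  stopifnot(is.data.frame(mix), all(mix$count >= 0))
  if (any(mix$archetype %in% c("underage", "overage")) && config$min_age < 1) {
    abort("age archetypes require a positive eligible age range",
          class = "authsieve_config_error")
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)

  arch <- rep(mix$archetype, mix$count)
  n <- length(arch)
  n_exact <- sum(arch == "exact_duplicate")
  n_partial <- sum(arch %in% c("partial_duplicate", "partial_duplicate_zigzagger"))
  n_late <- sum(arch == "late_duplicate")
  n_reg <- 2L + n_exact + n_partial + n_late + 10L
  reg_ct <- build_registry_contacts(n_reg)

  uid <- n_reg + seq_len(n)
  pos <- seq_len(n)

  name <- syn_name(uid)
  email <- syn_email(uid)
  phone <- syn_phone(uid)
  house <- as.character(100 + (uid * 3) %% 899)
  street <- syn_street(uid)
  city <- syn_city(uid)
  state <- syn_state(uid)
  zip <- syn_zip(uid)
  ip <- syn_us_ip(uid)
  handle <- rep(NA_character_, n)

  # timing: attempts arrive in generation order, three minutes apart
  t0 <- as.POSIXct("2018-06-01 08:00:00", tz = "UTC")
  screen_start <- t0 + (pos - 1) * 180
  screen_end <- screen_start + 300 + (uid %% 120)
  base_start <- screen_end + 60
  minutes <- 25 + (uid %% 30) + round(stats::runif(n), 2)

  reported_age <- 13L + (uid %% 6L)
  dob_age <- reported_age
  hiv <- rep("negative", n)
  same_sex <- rep(TRUE, n)
  sex <- rep("male", n)
  gender <- rep("man", n)
  quota <- rep(TRUE, n)
  a27 <- 24L + (uid %% 4L)
  a62 <- 56L + (uid %% 7L)
  block_pattern <- rep("none", n)

  is_type <- function(...) arch %in% c(...)

  # --- eligibility archetypes
  reported_age[is_type("underage")] <- 11L
  dob_age[is_type("underage")] <- 11L
  reported_age[is_type("overage")] <- 19L + (uid[is_type("overage")] %% 4L)
  dob_age[is_type("overage")] <- reported_age[is_type("overage")]
  same_sex[is_type("not_same_sex_attracted")] <- FALSE
  hiv[is_type("hiv_positive")] <- "positive"
  quota[is_type("quota_fail")] <- FALSE

  # --- exact duplicates: copy one contact-field family from a registry entry
  ed <- which(arch == "exact_duplicate")
  if (length(ed) > 0) {
    tgt <- 2L + seq_along(ed)
    fam <- rep(c("email", "phone", "ip", "address", "handle", "name"),
               length.out = length(ed))
    email[ed[fam == "email"]] <- reg_ct$email[tgt[fam == "email"]]
    # cross-slot: alternate copies take the registry entry's secondary number
    ph <- ed[fam == "phone"]
    ph_t <- tgt[fam == "phone"]
    take_alt <- seq_along(ph) %% 2 == 0
    phone[ph[!take_alt]] <- reg_ct$phone_primary[ph_t[!take_alt]]
    phone[ph[take_alt]] <- reg_ct$phone_alts[ph_t[take_alt]]
    ip[ed[fam == "ip"]] <- reg_ct$ip_keys[tgt[fam == "ip"]]
    ad <- ed[fam == "address"]
    ad_t <- tgt[fam == "address"]
    house[ad] <- reg_ct$house_number[ad_t]
    street[ad] <- reg_ct$street[ad_t]
    city[ad] <- reg_ct$city[ad_t]
    state[ad] <- reg_ct$state[ad_t]
    zip[ad] <- reg_ct$zip[ad_t]
    handle[ed[fam == "handle"]] <- reg_ct$social_handles[tgt[fam == "handle"]]
    name[ed[fam == "name"]] <- reg_ct$preferred_name[tgt[fam == "name"]]
  }

  # --- partial duplicates: one edit on a registry email's local part
  pd <- which(is_type("partial_duplicate", "partial_duplicate_zigzagger"))
  if (length(pd) > 0) {
    tgt <- 2L + n_exact + seq_along(pd)
    email[pd] <- vapply(reg_ct$email[tgt], function(e) {
      p <- strsplit(e, "@", fixed = TRUE)[[1]]
      last <- substr(p[1], nchar(p[1]), nchar(p[1]))
      sub_ch <- if (last == "b") "c" else "b"
      paste0(substr(p[1], 1, nchar(p[1]) - 1), sub_ch, "@", p[2])
    }, "", USE.NAMES = FALSE)
  }

  # --- late duplicates: recognizably similar, beyond automated thresholds
  ld <- which(arch == "late_duplicate")
  if (length(ld) > 0) {
    tgt <- 2L + n_exact + n_partial + seq_along(ld)
    nm <- tolower(reg_ct$preferred_name[tgt])
    name[ld] <- title_case(paste0(substr(nm, 1, nchar(nm) - 2), "qx"))
    email[ld] <- vapply(seq_along(ld), function(k) {
      p <- strsplit(reg_ct$email[tgt[k]], "@", fixed = TRUE)[[1]]
      dom <- SYN_DOMAIN[(match(p[2], SYN_DOMAIN)) %% 7 + 1]
      paste0(p[1], "@", dom)
    }, "", USE.NAMES = FALSE)
  }

  # --- Wisteria street: the index attempt reuses an enrolled participant's
  #     secondary phone; the additional attempts walk the street
  wi <- which(arch == "wisteria_index")
  wc <- which(arch == "wisteria_cluster")
  for (w in c(wi, wc)) {
    street[w] <- WISTERIA$street
    city[w] <- WISTERIA$city
    state[w] <- WISTERIA$state
    zip[w] <- WISTERIA$zip
  }
  if (length(wi) > 0) {
    house[wi] <- "14"
    phone[wi] <- reg_ct$phone_alts[1]
  }
  if (length(wc) > 0) house[wc] <- as.character(14 + 2 * seq_along(wc))

  # --- IP archetypes
  fi <- is_type("foreign_ip")
  ip[fi] <- syn_foreign_ip(uid[fi])

  # --- timing archetypes
  sp <- is_type("speeder", "speeder_straightliner")
  minutes[sp] <- 8 + (uid[sp] %% 12)
  sl <- is_type("slow_outlier")
  minutes[sl] <- 60 * (73 + (uid[sl] %% 24))

  # --- completion archetypes
  lcs <- is_type("low_completion_subset")
  a27[lcs] <- 5L + (uid[lcs] %% 12L)
  lco <- is_type("low_completion_outcome")
  a62[lco] <- 20L + (uid[lco] %% 24L)
  # near-threshold completion is the survey-review trigger for records
  # whose anomaly lives inside the response pattern itself
  fb <- is_type("flag_band_completion", "straightliner", "zigzagger", "conflicted")
  a27[fb] <- 17L + (uid[fb] %% 5L)

  # --- age inconsistency (screener age vs baseline DOB)
  ai <- is_type("age_inconsistent", "age_social_contradicted")
  dob_age[ai] <- reported_age[ai] + 6L

  # --- response patterns
  block_pattern[is_type("straightliner", "speeder_straightliner")] <- "straight"
  block_pattern[is_type("zigzagger", "partial_duplicate_zigzagger")] <- "zigzag"
  # a skipped item splices two equal responses together and breaks the
  # planted alternation, so zigzag archetypes answer the block fully
  a62[block_pattern == "zigzag"] <- config$outcome_n
  block_pattern[is_type("conflicted")] <- "conflict"

  # --- social handles and profiles
  social_types <- is_type("social_contradicted", "age_social_contradicted")
  referred_types <- is_type("clean", "state_mismatch_ip", "slow_outlier",
                            "flag_band_completion", "email_nonresponder")
  with_handle <- social_types | (referred_types & uid %% 3 != 0)
  handle[with_handle] <- syn_handle(name[with_handle])

  base_end <- base_start + round(minutes * 60)
  dob <- as.Date(sprintf("%d-01-15", as.POSIXlt(base_end)$year + 1900 - dob_age))

  lk_min <- config$likert_min
  lk_max <- config$likert_max
  gen_block <- function(len, answered, pattern = "none") {
    v <- sample(seq(lk_min, lk_max), len, replace = TRUE)
    if (pattern == "straight") v <- rep(sample(seq(lk_min, lk_max), 1), len)
    if (pattern == "zigzag") v <- rep(c(lk_min, lk_max), length.out = len)
    if (answered < len) v[sample(len, len - answered)] <- NA
    as.integer(v)
  }
  subset_responses <- lapply(seq_len(n), function(i) {
    gen_block(config$subset_n, a27[i],
              if (block_pattern[i] == "conflict") "none" else "none")
  })
  outcome_responses <- lapply(seq_len(n), function(i) {
    gen_block(config$outcome_n, a62[i], block_pattern[i])
  })
  cf <- which(block_pattern == "conflict")
  for (i in cf) { # conflict rules in tests reference the first two subset slots
    subset_responses[[i]][1:2] <- c(lk_max, lk_max)
  }

  pid <- sprintf("P%05d", pos)
  dossiers <- tibble(
    participant_id = pid,
    dob = dob,
    baseline_ip = ip,
    baseline_started_at = base_start,
    baseline_ended_at = base_end,
    subset_responses = subset_responses,
    outcome_responses = outcome_responses,
    preferred_name = name,
    email = email,
    phone_primary = phone,
    phone_alts = NA_character_,
    house_number = house,
    street = street,
    city = city,
    state = state,
    mailing_zip = zip,
    social_handles = handle,
    submitted_at = screen_end + 30,
    screener_id = sprintf("S%05d", pos),
    reported_age_years = reported_age,
    sex_assigned_at_birth = sex,
    gender_identity = gender,
    same_sex_attracted = same_sex,
    hiv_status = hiv,
    screening_zip = zip,
    screen_ip = ip,
    screen_started_at = screen_start,
    screen_ended_at = screen_end,
    code_verified = TRUE,
    consented = TRUE,
    meets_quota = quota
  )

  truth <- build_truth(pid, arch)
  lookups <- build_sim_lookups(dossiers, reg_ct, arch, uid)
  registry <- canonicalize_contacts(reg_ct, config,
                                    enrolled = c(TRUE, TRUE, (seq_len(n_reg) %% 2 == 0)[-(1:2)]))
  manual_evidence <- build_manual_evidence(dossiers, arch, truth, config)
  funnel <- if (n == 1224L) default_funnel_counts() else NULL

  new_auth_cohort(
    dossiers = dossiers,
    lookups = lookups,
    rejects = tibble(table = character(), row = integer(), id = character(),
                     reason = character()),
    registry = registry,
    truth = truth,
    manual_evidence = manual_evidence,
    funnel = funnel
  )
}

build_sim_lookups <- function(dossiers, reg_ct, arch, uid) {
  lk <- generate_lookup_tables(dossiers, tibble(participant_id = dossiers$participant_id,
                                                archetype = arch))
  reg_geo <- tibble(ip = reg_ct$ip_keys, country = "US", state = reg_ct$state)
  reg_gaz <- tibble(street = reg_ct$street, city = reg_ct$city,
                    state = reg_ct$state, zip = reg_ct$zip)
  geoip <- bind_rows(lk$geoip, reg_geo) %>% distinct(.data$ip, .keep_all = TRUE)
  gazetteer <- bind_rows(lk$gazetteer, reg_gaz) %>%
    mutate(.key = paste(normalize_street(.data$street),
                        canonicalize_name(.data$city), sep = "\r")) %>%
    distinct(.data$.key, .keep_all = TRUE) %>%
    select(-".key")
  list(geoip = geoip, gazetteer = gazetteer)
}

build_truth <- function(pid, arch) {
  status <- dplyr::case_when(
    arch %in% c("underage", "overage", "not_same_sex_attracted",
                "hiv_positive", "quota_fail") ~ "eligibility_fail",
    arch %in% c("exact_duplicate", "wisteria_index") ~ "duplicate",
    arch == "foreign_ip" ~ "ip_foreign",
    arch %in% c("low_completion_subset", "low_completion_outcome") ~ "completion_fail",
    arch == "wisteria_cluster" ~ "cluster_case",
    TRUE ~ "referred_manual"
  )
  disposition <- dplyr::case_when(
    status != "referred_manual" ~ NA_character_,
    arch %in% c("clean", "state_mismatch_ip", "slow_outlier",
                "flag_band_completion") ~ "enrolled",
    arch == "late_duplicate" ~ "failed_duplicate_no_checklist",
    TRUE ~ "failed_checklist"
  )
  reasons <- dplyr::case_when(
    arch == "speeder" ~ "time_stamp",
    arch == "speeder_straightliner" ~ "time_stamp;pattern_check",
    arch == "age_inconsistent" ~ "age_comparison",
    arch == "age_social_contradicted" ~ "age_comparison;social_media_check",
    arch == "partial_duplicate" ~ "duplicate_check",
    arch == "partial_duplicate_zigzagger" ~ "duplicate_check;pattern_check",
    arch %in% c("straightliner", "zigzagger", "conflicted") ~ "pattern_check",
    arch == "social_contradicted" ~ "social_media_check",
    arch == "email_nonresponder" ~ "email_verification",
    TRUE ~ ""
  )
  tibble(participant_id = pid, archetype = arch, expected_status = status,
         expected_disposition = disposition, expected_reasons = reasons)
}

build_manual_evidence <- function(dossiers, arch, truth, config) {
  pid <- dossiers$participant_id
  referred <- truth$expected_status == "referred_manual"

  res <- list()
  add_res <- function(sel, item, finding, note) {
    if (!any(sel)) return(invisible())
    res[[length(res) + 1]] <<- tibble(participant_id = pid[sel], item = item,
                                      finding = finding, note = note)
  }
  add_res(arch %in% c("speeder", "speeder_straightliner"), "time_stamp",
          "confirm_fail", "implausibly fast; no explanation on contact")
  add_res(arch == "slow_outlier", "time_stamp", "explainable",
          "long completion explained by breaks; confirmed by contact")
  add_res(arch %in% c("age_inconsistent", "age_social_contradicted"),
          "age_comparison", "confirm_fail",
          "age discrepancy unresolved after contact attempts")
  add_res(arch %in% c("partial_duplicate", "partial_duplicate_zigzagger"),
          "duplicate_check", "confirm_fail",
          "partial contact match confirmed as same person")
  add_res(arch == "state_mismatch_ip", "zip_check", "explainable",
          "IP state differs from mailing state; travel confirmed by contact")
  add_res(arch == "late_duplicate", "duplicate_check", "pre_checklist_duplicate",
          "recognized as an existing participant during processing")
  resolutions <- if (length(res)) bind_rows(res) else {
    tibble(participant_id = character(), item = character(),
           finding = character(), note = character())
  }

  has_handle <- !is.na(dossiers$social_handles) & nzchar(dossiers$social_handles)
  soc_sel <- referred & has_handle
  contradicted <- arch %in% c("social_contradicted", "age_social_contradicted")
  social_profiles <- tibble(
    participant_id = pid[soc_sel],
    profile_age = ifelse(contradicted[soc_sel],
                         config$max_age + 5L,
                         dossiers$reported_age_years[soc_sel]),
    profile_gender = dossiers$gender_identity[soc_sel],
    profile_state = dossiers$state[soc_sel]
  )

  email_sel <- referred & truth$expected_disposition %in%
    c("enrolled") | arch == "email_nonresponder"
  issued <- as.Date(dossiers$baseline_ended_at) + 1
  uidm <- seq_along(pid)
  email_log <- tibble(
    participant_id = pid[email_sel],
    issued_on = issued[email_sel],
    responded_on = dplyr::if_else(arch[email_sel] == "email_nonresponder",
                                  as.Date(NA),
                                  issued[email_sel] + 1 + (uidm[email_sel] %% 20))
  )

  list(resolutions = resolutions, social_profiles = social_profiles,
       email_log = email_log)
}
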