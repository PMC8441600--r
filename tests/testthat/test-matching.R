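test_that("email canonicalization lowercases, trims and strips plus tags", {
  expect_equal(canonicalize_email(" A.B+x@Mail.COM "), "a.b@mail.com")
  expect_equal(canonicalize_email("a@b.com"), "a@b.com")
  cfg_keep <- auth_config(strip_plus_tags = FALSE)
  expect_equal(canonicalize_email("a+tag@b.com", cfg_keep), "a+tag@b.com")
  expect_error(canonicalize_email("no-at-sign"), class = "authsieve_validation_error")
  expect_error(canonicalize_email("two@at@signs"), class = "authsieve_validation_error")
})

test_that("phone canonicalization yields exactly ten digits, country code stripped", {
  expect_equal(canonicalize_phone("(404) 555-0123"), "4045550123")
  expect_equal(canonicalize_phone("+1 404 555 0123"), "4045550123")
  expect_equal(canonicalize_phone("14045550123"), "4045550123")
  expect_error(canonicalize_phone("55501"), class = "authsieve_validation_error")
})

test_that("name canonicalization collapses whitespace and punctuation; empty never matches", {
  expect_equal(canonicalize_name("  J.  Doe "), "j doe")
  expect_equal(canonicalize_name("JDOE"), canonicalize_name("jdoe"))
  expect_equal(canonicalize_name(""), "")
  reg <- random_canonical(5)
  reg$name_key <- ""
  can <- random_canonical(1, prefix = "Q")
  can$name_key <- ""
  m <- find_duplicates(can, reg)
  expect_false("name" %in% m$field)
})

test_that("canonicalizers are idempotent", {
  set.seed(404)
  raw_names <- c("  J.  Doe ", "ALLCAPS NAME", "o'neil, jr.", "x")
  for (r in raw_names) {
    once <- canonicalize_name(r)
    expect_identical(canonicalize_name(once), once)
  }
  raw_emails <- c(" A.B+x@Mail.COM ", "simple@x.org")
  for (r in raw_emails) {
    once <- canonicalize_email(r)
    expect_identical(canonicalize_email(once), once)
  }
  raw_phones <- c("(404) 555-0123", "+1 734 555 9999")
  for (r in raw_phones) {
    once <- canonicalize_phone(r)
    expect_identical(canonicalize_phone(once), once)
  }
})

test_that("address parsing normalizes street suffixes from the synonym table", {
  a <- parse_address("12", "Wisteria St", "Springfield", "GA", "30301")
  expect_equal(a$street_key, "wisteria street")
  b <- parse_address("12", "Wisteria Street", "SPRINGFIELD", "ga", "30301")
  expect_equal(a$street_key, b$street_key)
  expect_equal(a$city_key, b$city_key)
  blank <- parse_address("12", "", "Springfield", "GA", "30301")
  expect_equal(blank$street_key, "")
})

test_that("address comparison distinguishes exact, partial-street and none", {
  a <- parse_address("12", "Wisteria St", "Springfield", "GA", "30301")
  b <- parse_address("14", "Wisteria Street", "Springfield", "GA", "30301")
  expect_equal(partial_match_address(a, b), "partial_street")
  expect_equal(partial_match_address(a, a), "exact")
  c2 <- parse_address("12", "Oak St", "Springfield", "GA", "30301")
  expect_equal(partial_match_address(a, c2), "none")
})

test_that("field matching is exact-only for phones/handles, edit-bounded for names/emails", {
  m <- match_field("jdoe1@x.com", "jdoe2@x.com", "email")
  expect_equal(m$kind, "partial")
  expect_lt(m$similarity, 1)
  expect_null(match_field("jdoe1@x.com", "jdoe1@y.com", "email")) # different domain
  expect_null(match_field("4045550123", "4045550124", "phone"))
  expect_equal(match_field("instagram:abc", "instagram:abc", "handle")$kind, "exact")
  expect_equal(match_field("j doe", "j doe", "name")$similarity, 1)
  expect_equal(match_field("j doe", "j dof", "name")$kind, "partial")
  expect_null(match_field("j doe", "x roe", "name"))
})

test_that("field matching is symmetric on random keys", {
  set.seed(77)
  for (i in 1:50) {
    a <- paste(sample(letters[1:4], 4, replace = TRUE), collapse = "")
    b <- paste(sample(letters[1:4], 4, replace = TRUE), collapse = "")
    for (f in c("name", "phone", "handle")) {
      ab <- match_field(a, b, f)
      ba <- match_field(b, a, f)
      expect_identical(is.null(ab), is.null(ba))
      if (!is.null(ab)) expect_equal(ab$kind, ba$kind)
    }
    ea <- paste0(a, "@z.com")
    eb <- paste0(b, "@z.com")
    ab <- match_field(ea, eb, "email")
    ba <- match_field(eb, ea, "email")
    expect_identical(is.null(ab), is.null(ba))
  }
})

test_that("find_duplicates equals the all-pairs brute-force oracle on random cohorts", {
  set.seed(1001)
  registry <- random_canonical(120, prefix = "R")
  probes <- random_canonical(100, prefix = "N")
  for (i in seq_len(nrow(probes))) {
    got <- find_duplicates(probes[i, ], registry)
    want <- brute_find_duplicates(probes[i, ], registry)
    expect_setequal(match_set(got), match_set(want))
    # similarity invariants
    expect_true(all(got$similarity[got$kind == "exact"] == 1))
    expect_true(all(got$similarity[got$kind == "partial"] < 1))
  }
})

test_that("a new primary phone matching an enrolled participant's secondary phone is caught", {
  reg <- canonicalize_contacts(tibble::tibble(
    participant_id = "R1", preferred_name = "Sam Pine", email = "sam.pine@x.org",
    phone_primary = "4045550100", phone_alts = "4045550199",
    house_number = "1", street = "Oak St", city = "Springfield", state = "GA",
    zip = "30301", social_handles = NA_character_, ip_keys = "73.1.1.1"
  ), enrolled = TRUE)
  d <- make_dossier(phone_primary = "4045550199")
  m <- find_duplicates(d, reg)
  expect_true(any(m$field == "phone" & m$kind == "exact" & m$other_id == "R1"))
})

test_that("empty registry yields no matches", {
  d <- make_dossier()
  m <- find_duplicates(d, canonicalize_contacts(make_dossier())[0, ])
  expect_equal(nrow(m), 0)
})

test_that("address clusters are declared at the configured street count", {
  mk <- function(id, house) {
    canonicalize_contacts(make_dossier(participant_id = id, house_number = house,
                                       email = paste0(id, "@x.org"),
                                       phone_primary = sprintf("404555%04d", as.integer(house)),
                                       preferred_name = paste("Res", house)))
  }
  registry <- dplyr::bind_rows(lapply(1:2, function(i) mk(paste0("R", i), as.character(10 + 2 * i))))
  probe <- make_dossier(participant_id = "N1", house_number = "99")
  cl <- detect_cluster(probe, registry)
  expect_false(cl$is_cluster) # two matches, threshold three
  expect_equal(sort(cl$members), c("R1", "R2"))

  registry3 <- dplyr::bind_rows(registry, mk("R3", "20"))
  cl3 <- detect_cluster(probe, registry3)
  expect_true(cl3$is_cluster)

  loose <- auth_config(cluster_min_size = 1)
  expect_true(detect_cluster(probe, registry, loose)$is_cluster)
})

test_that("wide edit limits fall back to a scan and still match the oracle", {
  set.seed(321)
  cfg <- auth_config(name_edit_max = 2, email_edit_max = 2)
  registry <- random_canonical(60, prefix = "R")
  probes <- random_canonical(30, prefix = "N")
  for (i in seq_len(nrow(probes))) {
    got <- find_duplicates(probes[i, ], registry, cfg)
    want <- brute_find_duplicates(probes[i, ], registry, cfg)
    expect_setequal(match_set(got), match_set(want))
  }
})
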