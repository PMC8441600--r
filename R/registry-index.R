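# Internal incremental index over canonical registry entries.
#
# Exact families (email, phone, ip, handle, full address, exact name) are
# hash lookups. Partial matching at edit distance 1 (the default for names
# and email local parts) uses a deletion-variant index: two strings are
# within one edit iff they are equal, one is a single-deletion variant of
# the other, or they share a single-deletion variant at the same position
# (a substitution). That keeps each insert/query O(key length) instead of
# scanning the registry, and is exactly equivalent to the quadratic
# edit-distance comparison. Non-default edit limits fall back to a scan
# (blocked by email domain for emails).

new_registry_index <- function(config = auth_config()) {
  idx <- new.env(parent = emptyenv())
  idx$config <- config
  idx$n <- 0L
  idx$ids <- character()
  idx$name_keys <- character()
  idx$email_keys <- character()
  idx$house_numbers <- character()
  idx$maps <- list(
    email = new.env(parent = emptyenv()),
    name = new.env(parent = emptyenv()),
    phone = new.env(parent = emptyenv()),
    ip = new.env(parent = emptyenv()),
    handle = new.env(parent = emptyenv()),
    addr_full = new.env(parent = emptyenv()),
    addr_street = new.env(parent = emptyenv()),
    name_sub = new.env(parent = emptyenv()),
    name_del = new.env(parent = emptyenv()),
    email_sub = new.env(parent = emptyenv()),
    email_del = new.env(parent = emptyenv())
  )
  idx
}

env_push <- function(map, key, i) {
  if (is.na(key) || !nzchar(key)) return(invisible())
  map[[key]] <- c(map[[key]], i)
  invisible()
}

env_get <- function(map, key) {
  if (is.na(key) || !nzchar(key)) return(integer())
  map[[key]] %||% integer()
}

del_variants <- function(s) {
  n <- nchar(s)
  if (n == 0) return(character())
  vapply(seq_len(n), function(i) paste0(substr(s, 1, i - 1), substr(s, i + 1, n)), "")
}

split_keyset <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

# precompute per-row key pieces from a canonical registry tibble
canonical_pre <- function(can) {
  no_street <- can$street_key == "" | is.na(can$street_key)
  full_key <- ifelse(no_street, NA_character_,
                     paste(can$house_number, can$street_key, can$city_key,
                           can$state, can$zip, sep = "\r"))
  street_key <- ifelse(no_street, NA_character_,
                       paste(can$street_key, can$city_key, can$state, can$zip,
                             sep = "\r"))
  email_local <- sub("@.*$", "", can$email_key)
  email_domain <- sub("^[^@]*@", "", can$email_key)
  list(
    ids = can$registry_id,
    name_key = can$name_key,
    email_key = can$email_key,
    email_local = email_local,
    email_domain = email_domain,
    phone_sets = lapply(can$phone_keys, split_keyset),
    ip_sets = lapply(can$ip_keys, split_keyset),
    handle_sets = lapply(can$handle_keys, split_keyset),
    full_key = full_key,
    street_key = street_key,
    house = can$house_number
  )
}

registry_add_pre <- function(idx, p, i) {
  j <- idx$n + 1L
  idx$n <- j
  idx$ids[j] <- p$ids[i]
  idx$name_keys[j] <- p$name_key[i]
  idx$email_keys[j] <- p$email_key[i]
  idx$house_numbers[j] <- p$house[i]
  m <- idx$maps
  env_push(m$name, p$name_key[i], j)
  env_push(m$email, p$email_key[i], j)
  for (k in p$phone_sets[[i]]) env_push(m$phone, k, j)
  for (k in p$ip_sets[[i]]) env_push(m$ip, k, j)
  for (k in p$handle_sets[[i]]) env_push(m$handle, k, j)
  env_push(m$addr_full, p$full_key[i], j)
  env_push(m$addr_street, p$street_key[i], j)
  cfg <- idx$config
  if (cfg$name_edit_max == 1L && nzchar(p$name_key[i])) {
    dv <- del_variants(p$name_key[i])
    for (k in seq_along(dv)) env_push(m$name_sub, paste0(k, "\r", dv[k]), j)
    for (v in unique(dv)) env_push(m$name_del, v, j)
  }
  if (cfg$email_edit_max == 1L && !is.na(p$email_local[i]) &&
      nzchar(p$email_local[i]) && p$email_domain[i] != p$email_key[i]) {
    dv <- del_variants(p$email_local[i])
    dom <- p$email_domain[i]
    for (k in seq_along(dv)) env_push(m$email_sub, paste0(dom, "\r", k, "\r", dv[k]), j)
    for (v in unique(dv)) env_push(m$email_del, paste0(dom, "\r", v), j)
  }
  invisible(idx)
}

#' @keywords internal
registry_add <- function(idx, can) {
  registry_add_pre(idx, canonical_pre(can), 1L)
}

#' @keywords internal
registry_index <- function(registry, config = auth_config()) {
  idx <- new_registry_index(config)
  if (!is.null(registry) && nrow(registry) > 0) {
    p <- canonical_pre(registry)
    for (i in seq_len(nrow(registry))) registry_add_pre(idx, p, i)
  }
  idx
}

partial_name_candidates <- function(idx, key) {
  if (!nzchar(key)) return(integer())
  m <- idx$maps
  dv <- del_variants(key)
  hits <- integer()
  for (k in seq_along(dv)) {
    hits <- c(hits, env_get(m$name_sub, paste0(k, "\r", dv[k])))   # substitution
    hits <- c(hits, env_get(m$name, dv[k]))                        # query has extra char
  }
  hits <- c(hits, env_get(m$name_del, key))                        # entry has extra char
  unique(hits)
}

partial_email_candidates <- function(idx, local, domain) {
  if (!nzchar(local)) return(integer())
  m <- idx$maps
  dv <- del_variants(local)
  hits <- integer()
  for (k in seq_along(dv)) {
    hits <- c(hits, env_get(m$email_sub, paste0(domain, "\r", k, "\r", dv[k])))
    hits <- c(hits, env_get(m$email, paste0(dv[k], "@", domain)))
  }
  hits <- c(hits, env_get(m$email_del, paste0(domain, "\r", local)))
  unique(hits)
}

# core scan: integer candidate indices per family, exact and partial
registry_scan <- function(idx, p, i, config = idx$config) {
  m <- idx$maps
  exact <- list(
    name = env_get(m$name, p$name_key[i]),
    email = env_get(m$email, p$email_key[i]),
    phone = unique(unlist(lapply(p$phone_sets[[i]], env_get, map = m$phone))),
    ip = unique(unlist(lapply(p$ip_sets[[i]], env_get, map = m$ip))),
    handle = unique(unlist(lapply(p$handle_sets[[i]], env_get, map = m$handle))),
    address = env_get(m$addr_full, p$full_key[i])
  )
  partial <- list(name = integer(), email = integer(), address = integer())
  partial_d <- list(name = integer(), email = integer())

  street_hits <- env_get(m$addr_street, p$street_key[i])
  street_hits <- setdiff(street_hits, exact$address)
  partial$address <- street_hits[idx$house_numbers[street_hits] != p$house[i]]

  if (config$name_edit_max > 0 && nzchar(p$name_key[i])) {
    cand <- if (config$name_edit_max == 1L) {
      partial_name_candidates(idx, p$name_key[i])
    } else if (idx$n > 0) {
      which(adist(p$name_key[i], idx$name_keys[seq_len(idx$n)])[1, ] <= config$name_edit_max)
    } else integer()
    cand <- setdiff(cand, exact$name)
    if (length(cand) > 0) {
      d <- adist(p$name_key[i], idx$name_keys[cand])[1, ]
      keep <- d <= config$name_edit_max & d > 0
      partial$name <- cand[keep]
      partial_d$name <- d[keep]
    }
  }

  if (config$email_edit_max > 0 && !is.na(p$email_local[i]) &&
      nzchar(p$email_local[i]) && p$email_domain[i] != p$email_key[i]) {
    cand <- if (config$email_edit_max == 1L) {
      partial_email_candidates(idx, p$email_local[i], p$email_domain[i])
    } else if (idx$n > 0) {
      same_dom <- endsWith(idx$email_keys[seq_len(idx$n)], paste0("@", p$email_domain[i]))
      w <- which(same_dom)
      if (length(w)) {
        w[adist(p$email_key[i], idx$email_keys[w])[1, ] <= config$email_edit_max]
      } else integer()
    } else integer()
    cand <- setdiff(cand, exact$email)
    if (length(cand) > 0) {
      locals <- sub("@.*$", "", idx$email_keys[cand])
      d <- adist(p$email_local[i], locals)[1, ]
      keep <- d <= config$email_edit_max & d > 0
      partial$email <- cand[keep]
      partial_d$email <- d[keep]
    }
  }
  list(exact = exact, partial = partial, partial_d = partial_d)
}

#' @keywords internal
registry_query <- function(idx, can, config = idx$config) {
  p <- canonical_pre(can)
  sc <- registry_scan(idx, p, 1L, config)
  out <- list()
  details <- c(
    name = "same preferred name", email = "same email address",
    phone = "shared phone number (any slot)", ip = "shared IP address",
    handle = "same handle on same platform", address = "same mailing address"
  )
  for (f in names(sc$exact)) {
    ids <- sc$exact[[f]]
    if (length(ids)) {
      out[[length(out) + 1]] <- tibble(kind = "exact", field = f,
                                       other_id = idx$ids[ids], similarity = 1,
                                       detail = details[[f]])
    }
  }
  if (length(sc$partial$address)) {
    out[[length(out) + 1]] <- tibble(
      kind = "partial", field = "address", other_id = idx$ids[sc$partial$address],
      similarity = 0.8, detail = "same street, different house number"
    )
  }
  if (length(sc$partial$name)) {
    d <- sc$partial_d$name
    other <- idx$name_keys[sc$partial$name]
    out[[length(out) + 1]] <- tibble(
      kind = "partial", field = "name", other_id = idx$ids[sc$partial$name],
      similarity = 1 - d / pmax(nchar(p$name_key[1]), nchar(other)),
      detail = sprintf("name within %d edit(s)", d)
    )
  }
  if (length(sc$partial$email)) {
    d <- sc$partial_d$email
    other <- idx$email_keys[sc$partial$email]
    out[[length(out) + 1]] <- tibble(
      kind = "partial", field = "email", other_id = idx$ids[sc$partial$email],
      similarity = 1 - d / pmax(nchar(p$email_key[1]), nchar(other)),
      detail = sprintf("local part within %d edit(s), same domain", d)
    )
  }
  if (length(out) == 0) {
    return(tibble(kind = character(), field = character(), other_id = character(),
                  similarity = double(), detail = character()))
  }
  bind_rows(out) %>% distinct(.data$field, .data$other_id, .keep_all = TRUE)
}

cluster_scan <- function(idx, p, i, config = idx$config) {
  hits <- env_get(idx$maps$addr_street, p$street_key[i])
  hits[idx$house_numbers[hits] != p$house[i]]
}

#' @keywords internal
cluster_query <- function(idx, can, config = idx$config) {
  p <- canonical_pre(can)
  hits <- cluster_scan(idx, p, 1L, config)
  list(is_cluster = length(hits) >= config$cluster_min_size,
       members = idx$ids[hits])
}
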