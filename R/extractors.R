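# The five text-based extractor services: dictionary-based scientific names,
# botanist names and locations (with country assignment), and regular
# expression dates (with category) and geographic coordinates.

# ---- shared helpers --------------------------------------------------------

# Tokenize with character offsets (0-based, half-open). A token is an
# alphanumeric run, optionally with internal hyphens/apostrophes and one
# trailing period (so "leg.", "L." and "Humboldt" are single tokens).
tokenize <- function(text) {
  loc <- stringr::str_locate_all(text, "[[:alnum:]][[:alnum:]'’-]*\\.?")[[1]]
  if (nrow(loc) == 0) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  tibble::tibble(
    token = stringr::str_sub(text, loc[, 1], loc[, 2]),
    start = as.integer(loc[, 1] - 1), end = as.integer(loc[, 2]))
}

strip_dot <- function(token) sub("\\.$", "", token)

# Per-token fuzzy match: edit distance within the dictionary tolerance for
# entry tokens of >= 5 characters, exact (case-insensitive) otherwise.
token_matches <- function(token, entry_token, tolerance) {
  tol <- if (nchar(entry_token) >= 5) tolerance else 0L
  utils::adist(tolower(token), tolower(entry_token)) <= tol
}

# Greedy longest-match-first overlap resolution on a tibble with start/end.
resolve_overlaps <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start), ]
  keep <- logical(nrow(cand))
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    clash <- nrow(taken) > 0 && any(s < taken[, 2] & e > taken[, 1])
    if (!clash) {
      keep[i] <- TRUE
      taken <- rbind(taken, c(s, e))
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

# Nearest preceding cue token whose end lies within `window` characters of
# position `start` (0-based); the single separator character following the
# cue is not counted against the window.
preceding_cue <- function(text, start, cues, window = 12) {
  best <- NULL; best_end <- -1
  for (cue in names(cues)) {
    loc <- stringr::str_locate_all(stringr::str_to_lower(text),
      stringr::fixed(tolower(cue)))[[1]]
    if (nrow(loc) == 0) next
    ends <- loc[, 2]  # 1-based inclusive end == 0-based half-open end
    ends <- ends + (substring(text, ends + 1, ends + 1) %in% c(" ", "\t"))
    ok <- ends <= start & (start - ends) <= window
    if (any(ok)) {
      e <- max(ends[ok])
      if (e > best_end) { best_end <- e; best <- cues[[cue]] }
    }
  }
  best
}

check_dict <- function(dict, kind) {
  if (!inherits(dict, "herb_dictionary") || dict$kind != kind) {
    rlang::abort(paste0("expected a dictionary of kind '", kind, "'"),
      class = "herbsheet_contract_error")
  }
}

# ---- scientific names ------------------------------------------------------

AUTHOR_TOKEN_RE <- "^[A-Z][A-Za-z]{0,12}\\.$"

#' Extract scientific plant names from label text
#'
#' Scans capitalized (or, within the fuzzy tolerance, OCR-mangled) tokens
#' against a scientific-name dictionary. A genus token optionally followed by
#' a lowercase epithet token forms a candidate; it is kept when genus (and
#' epithet, when present) match dictionary entries within the per-token edit
#' tolerance. Trailing authorship tokens (e.g. `"L."`, `"(L.) Benth."`) are
#' captured in the payload but excluded from the surface. Overlapping
#' candidates are resolved longest-match-first.
#'
#' @param text Source text.
#' @param dict A [read_dictionary()] of kind `"scientific_names"`.
#' @return An [entity_tibble()] of `scientific_name` mentions ordered by
#'   offset, with payload columns `genus`, `epithet`, `author`,
#'   `matched_entry`.
#' @export
extract_scientific_names <- function(text, dict) {
  check_dict(dict, "scientific_names")
  if (length(dict$entries) == 0 || !nzchar(text)) return(entity_tibble())
  toks <- tokenize(text)
  if (nrow(toks) == 0) return(entity_tibble())
  entry_tokens <- strsplit(dict$entries, " ", fixed = TRUE)
  binomials <- dict$entries[lengths(entry_tokens) >= 2]
  bino_tok <- entry_tokens[lengths(entry_tokens) >= 2]
  genera <- dict$entries[lengths(entry_tokens) == 1]
  tol <- dict$match_tolerance

  cands <- list()
  for (i in seq_len(nrow(toks))) {
    core_i <- strip_dot(toks$token[i])
    if (nchar(core_i) < 3 || grepl("^\\d+$", core_i)) next
    # binomial candidates
    if (i < nrow(toks)) {
      core_j <- strip_dot(toks$token[i + 1])
      for (k in seq_along(binomials)) {
        bt <- bino_tok[[k]]
        if (token_matches(core_i, bt[1], tol) && token_matches(core_j, bt[2], tol)) {
          cands[[length(cands) + 1]] <- list(
            start = toks$start[i], end = toks$end[i + 1], last_tok = i + 1L,
            genus = bt[1], epithet = bt[2], matched_entry = binomials[k])
          break
        }
      }
    }
    # uninomial (genus-only) candidates
    for (g in genera) {
      if (token_matches(core_i, g, tol)) {
        cands[[length(cands) + 1]] <- list(
          start = toks$start[i], end = toks$end[i], last_tok = i,
          genus = g, epithet = NA_character_, matched_entry = g)
        break
      }
    }
  }
  if (length(cands) == 0) return(entity_tibble())
  cand <- dplyr::bind_rows(lapply(cands, tibble::as_tibble))
  cand <- resolve_overlaps(cand)
  # trailing authorship tokens, recorded in the payload only
  authors <- vapply(cand$last_tok, function(j) {
    auth <- character(0)
    while (j < nrow(toks) && grepl(AUTHOR_TOKEN_RE, toks$token[j + 1])) {
      auth <- c(auth, toks$token[j + 1]); j <- j + 1
    }
    if (length(auth) == 0) NA_character_ else paste(auth, collapse = " ")
  }, character(1))
  entity_tibble(category = "scientific_name",
    surface = substr_many(text, cand$start, cand$end),
    start = cand$start, end = cand$end,
    genus = cand$genus, epithet = cand$epithet, author = authors,
    matched_entry = cand$matched_entry)
}

substr_many <- function(text, start0, end0) {
  vapply(seq_along(start0), function(i) substr(text, start0[i] + 1, end0[i]), character(1))
}

# ---- botanist names --------------------------------------------------------

COLLECTOR_CUES <- c("leg." = "collector", "legit" = "collector", "coll." = "collector",
  "det." = "determiner", "rev." = "determiner")

#' Extract botanist (collector/determiner) names from label text
#'
#' Matches dictionary surnames, extending leftward over initial tokens
#' (`"A."`), within the per-token fuzzy tolerance. A collector cue
#' (`leg.`, `legit`, `coll.`) or determiner cue (`det.`, `rev.`) ending
#' within 12 characters before the mention sets the `role` payload;
#' otherwise the role is `"unspecified"`.
#'
#' @param text Source text.
#' @param dict A [read_dictionary()] of kind `"botanists"`.
#' @return An [entity_tibble()] of `botanist` mentions with payload columns
#'   `surname`, `initials`, `role`, `matched_entry`.
#' @export
extract_botanist_names <- function(text, dict) {
  check_dict(dict, "botanists")
  if (length(dict$entries) == 0 || !nzchar(text)) return(entity_tibble())
  toks <- tokenize(text)
  if (nrow(toks) == 0) return(entity_tibble())
  tol <- dict$match_tolerance
  rows <- list()
  for (j in seq_len(nrow(toks))) {
    core <- strip_dot(toks$token[j])
    if (nchar(core) < 3 || grepl("^\\d+$", core)) next
    hit <- NULL
    best_d <- Inf
    for (s in dict$entries) {
      if (token_matches(core, s, tol)) {
        d <- utils::adist(tolower(core), tolower(s))
        if (d < best_d) { best_d <- d; hit <- s }
      }
    }
    if (is.null(hit)) next
    k <- j
    while (k > 1 && grepl("^[A-Z]\\.$", toks$token[k - 1]) &&
           toks$start[k] - toks$end[k - 1] <= 2) {
      k <- k - 1
    }
    initials <- if (k < j) paste(toks$token[k:(j - 1)], collapse = " ") else NA_character_
    start <- toks$start[k]; end <- toks$end[j]
    role <- preceding_cue(text, start, COLLECTOR_CUES, window = 12) %||% "unspecified"
    rows[[length(rows) + 1]] <- tibble::tibble(start = start, end = end,
      surname = hit, initials = initials, role = role, matched_entry = hit)
  }
  if (length(rows) == 0) return(entity_tibble())
  cand <- resolve_overlaps(dplyr::bind_rows(rows))
  entity_tibble(category = "botanist",
    surface = substr_many(text, cand$start, cand$end),
    start = cand$start, end = cand$end,
    surname = cand$surname, initials = cand$initials, role = cand$role,
    matched_entry = cand$matched_entry)
}

# ---- dates -----------------------------------------------------------------

DATE_CUES <- c("leg." = "collection", "legit" = "collection", "coll." = "collection",
  "det." = "determination", "rev." = "determination",
  "acc." = "accession", "accession" = "accession")

default_month_table <- function() {
  en_full <- c("january", "february", "march", "april", "may", "june", "july",
    "august", "september", "october", "november", "december")
  en_ab <- c("jan", "feb", "mar", "apr", "may", "jun", "jul", "aug", "sep",
    "oct", "nov", "dec")
  latin <- c("ian", "febr", "mart", "apr", "mai", "iun", "iul", "aug", "sept",
    "oct", "nov", "dec")
  stats::setNames(c(1:12, 1:12, 1:12), c(en_full, en_ab, latin))
}

valid_day_date <- function(y, m, d) {
  iso <- sprintf("%04d-%02d-%02d", y, m, d)
  if (is.na(as.Date(iso, format = "%Y-%m-%d", optional = TRUE))) NA_character_ else iso
}

#' Extract dates from label text
#'
#' Supported grammars: `d.m.yyyy`, `d.R.yyyy` with a Roman-numeral month
#' (I-XII, the herbarium-label convention), `yyyy-mm-dd` (or `yyyy-mm`),
#' `d/m/yyyy` (day-first by default), `d Month yyyy` (English and Latin
#' month names/abbreviations) and a bare year. Matches are normalized to
#' ISO-8601 at day, month or year precision; near-matches that fail calendar
#' validation are skipped. The date kind (`collection`, `determination`,
#' `accession`, `unspecified`) comes from the nearest preceding cue token
#' (`leg.`/`legit`/`coll.`, `det.`/`rev.`, `acc.`/`accession`) ending within
#' 12 characters.
#'
#' @param text Source text.
#' @param day_first Interpret ambiguous `d/m/yyyy` slash dates day-first.
#' @return An [entity_tibble()] of `date` mentions with payload columns
#'   `iso_date` and `date_kind`.
#' @export
extract_dates <- function(text, day_first = TRUE) {
  if (!nzchar(text)) return(entity_tibble())
  months <- default_month_table()
  pats <- list(
    numeric_dot = "(?<![\\d.])(\\d{1,2})\\.\\s?(\\d{1,2})\\.(\\d{4})(?!\\d)",
    roman = "(?<![\\d.])(\\d{1,2})\\.\\s?([IVXivx]{1,4})\\.(\\d{4})(?!\\d)",
    iso = "(?<!\\d)(\\d{4})-(\\d{1,2})(?:-(\\d{1,2}))?(?![\\d-])",
    slash = "(?<![\\d/])(\\d{1,2})/(\\d{1,2})/(\\d{4})(?!\\d)",
    textual = "(?<!\\d)(\\d{1,2})\\.?\\s([A-Za-z]{3,12})\\.?\\s?(\\d{4})(?!\\d)",
    year = "(?<!\\d)(1[5-9]\\d{2}|20\\d{2})(?!\\d)"
  )
  rows <- list()
  for (nm in names(pats)) {
    m <- gregexpr(pats[[nm]], text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    for (q in seq_along(m)) {
      grab <- function(g) {
        if (g > ncol(cs) || cs[q, g] == 0) return(NA_character_)
        substr(text, cs[q, g], cs[q, g] + cl[q, g] - 1)
      }
      iso <- switch(nm,
        numeric_dot = {
          d <- as.integer(grab(1)); mo <- as.integer(grab(2)); y <- as.integer(grab(3))
          if (mo >= 1 && mo <= 12) valid_day_date(y, mo, d) else NA_character_
        },
        roman = {
          mo <- suppressWarnings(as.integer(utils::as.roman(toupper(grab(2)))))
          if (!is.na(mo) && mo >= 1 && mo <= 12) {
            valid_day_date(as.integer(grab(3)), mo, as.integer(grab(1)))
          } else NA_character_
        },
        iso = {
          y <- as.integer(grab(1)); mo <- as.integer(grab(2)); d <- grab(3)
          if (is.na(d)) {
            if (mo >= 1 && mo <= 12) sprintf("%04d-%02d", y, mo) else NA_character_
          } else {
            valid_day_date(y, mo, as.integer(d))
          }
        },
        slash = {
          a <- as.integer(grab(1)); b <- as.integer(grab(2)); y <- as.integer(grab(3))
          d <- if (day_first) a else b; mo <- if (day_first) b else a
          if (mo >= 1 && mo <= 12) valid_day_date(y, mo, d) else NA_character_
        },
        textual = {
          mo <- unname(months[tolower(grab(2))])
          if (!is.na(mo)) valid_day_date(as.integer(grab(3)), mo, as.integer(grab(1)))
          else NA_character_
        },
        year = sprintf("%04d", as.integer(grab(1)))
      )
      if (is.na(iso)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        start = as.integer(m[q] - 1), end = as.integer(m[q] + attr(m, "match.length")[q] - 1),
        iso_date = iso)
    }
  }
  if (length(rows) == 0) return(entity_tibble())
  cand <- resolve_overlaps(dplyr::bind_rows(rows))
  kinds <- vapply(cand$start, function(s) {
    preceding_cue(text, s, DATE_CUES, window = 12) %||% "unspecified"
  }, character(1))
  entity_tibble(category = "date",
    surface = substr_many(text, cand$start, cand$end),
    start = cand$start, end = cand$end,
    iso_date = cand$iso_date, date_kind = kinds)
}

# ---- geographic coordinates ------------------------------------------------

#' Extract latitude/longitude pairs from label text
#'
#' Recognizes degree-minute-second forms (`52°27'30"N`),
#' degrees-decimal-minutes (`52°27.5'N`), decimals with a hemisphere letter
#' (`33.92 S`) and signed decimals (`-33.92`). A latitude is paired with the
#' nearest following longitude starting within 40 characters; values are
#' converted to decimal degrees as `deg + min/60 + sec/3600`, negated for
#' southern/western hemispheres. Pairs with out-of-range values are skipped.
#'
#' @param text Source text.
#' @return An [entity_tibble()] of `coordinate` mentions (one per pair) with
#'   payload columns `latitude` and `longitude`; the surface spans from the
#'   latitude atom to the longitude atom.
#' @export
extract_geocoords <- function(text) {
  if (!nzchar(text)) return(entity_tibble())
  prime <- "['′’]"; dbl <- "[\"″]"
  pats <- list(
    dms = paste0("(\\d{1,3})°(?:\\s?(\\d{1,2}(?:\\.\\d+)?)", prime,
      "(?:\\s?(\\d{1,2}(?:\\.\\d+)?)", dbl, ")?)?(?:\\s?([NSEW])(?![A-Za-z]))?"),
    dec_hemi = "(?<![\\d.])(\\d{1,3}(?:\\.\\d+)?)\\s?([NSEW])(?![A-Za-z])",
    signed = "(?<![\\d.\\w])([−-]\\d{1,3}(?:\\.\\d+)?)(?![\\d])"
  )
  atoms <- list()
  spans <- matrix(numeric(0), ncol = 2)
  for (nm in names(pats)) {
    m <- gregexpr(pats[[nm]], text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    for (q in seq_along(m)) {
      s0 <- m[q] - 1; e0 <- m[q] + attr(m, "match.length")[q] - 1
      if (nrow(spans) > 0 && any(s0 < spans[, 2] & e0 > spans[, 1])) next
      grab <- function(g) {
        if (g > ncol(cs) || cs[q, g] == 0) return(NA_character_)
        substr(text, cs[q, g], cs[q, g] + cl[q, g] - 1)
      }
      atom <- switch(nm,
        dms = {
          d <- as.numeric(grab(1))
          mi <- as.numeric(grab(2)); se <- as.numeric(grab(3))
          v <- d + ifelse(is.na(mi), 0, mi) / 60 + ifelse(is.na(se), 0, se) / 3600
          letter <- grab(4)
          list(value = v, letter = letter, signed = FALSE)
        },
        dec_hemi = list(value = as.numeric(grab(1)), letter = grab(2), signed = FALSE),
        signed = list(value = as.numeric(sub("−", "-", grab(1))),
          letter = NA_character_, signed = TRUE)
      )
      atom$start <- as.integer(s0); atom$end <- as.integer(e0)
      atoms[[length(atoms) + 1]] <- atom
      spans <- rbind(spans, c(s0, e0))
    }
  }
  if (length(atoms) < 2) return(entity_tibble())
  ord <- order(vapply(atoms, function(a) a$start, integer(1)))
  atoms <- atoms[ord]
  axis_of <- function(a) {
    if (is.na(a$letter)) "unknown"
    else if (a$letter %in% c("N", "S")) "lat" else "lon"
  }
  used <- logical(length(atoms))
  rows <- list()
  for (i in seq_along(atoms)) {
    if (used[i]) next
    a <- atoms[[i]]
    ax <- axis_of(a)
    if (ax == "lon") next
    lat_raw <- if (!is.na(a$letter) && a$letter == "S") -a$value else a$value
    if (abs(lat_raw) > 90) next
    for (j in seq_along(atoms)) {
      if (j <= i || used[j]) next
      b <- atoms[[j]]
      if (b$start - a$end > 40) break
      bx <- axis_of(b)
      if (bx == "lat") next
      lon_raw <- if (!is.na(b$letter) && b$letter == "W") -b$value else b$value
      if (abs(lon_raw) > 180) next
      used[i] <- TRUE; used[j] <- TRUE
      rows[[length(rows) + 1]] <- tibble::tibble(
        start = a$start, end = b$end, latitude = lat_raw, longitude = lon_raw)
      break
    }
  }
  if (length(rows) == 0) return(entity_tibble())
  cand <- dplyr::bind_rows(rows)
  cand <- cand[order(cand$start), ]
  entity_tibble(category = "coordinate",
    surface = substr_many(text, cand$start, cand$end),
    start = cand$start, end = cand$end,
    latitude = cand$latitude, longitude = cand$longitude)
}

# ---- locations -------------------------------------------------------------

#' Extract place names and assign countries
#'
#' Case-insensitive longest-match scan of the text against the gazetteer
#' place names at token boundaries; each match carries the place's gazetteer
#' country.
#'
#' @param text Source text.
#' @param gaz A [read_gazetteer()] table.
#' @return An [entity_tibble()] of `location` mentions with payload columns
#'   `place_name` (canonical gazetteer form) and `country`.
#' @export
extract_locations <- function(text, gaz) {
  if (!nzchar(text) || nrow(gaz) == 0) return(entity_tibble())
  gaz <- gaz[order(-nchar(gaz$place_name)), ]
  rows <- list()
  spans <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(gaz))) {
    pat <- paste0("(?<![[:alnum:]])", escape_regex(gaz$place_name[i]), "(?![[:alnum:]])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) next
    for (q in seq_along(m)) {
      s0 <- m[q] - 1; e0 <- m[q] + attr(m, "match.length")[q] - 1
      if (nrow(spans) > 0 && any(s0 < spans[, 2] & e0 > spans[, 1])) next
      spans <- rbind(spans, c(s0, e0))
      rows[[length(rows) + 1]] <- tibble::tibble(start = as.integer(s0),
        end = as.integer(e0), place_name = gaz$place_name[i], country = gaz$country[i])
    }
  }
  if (length(rows) == 0) return(entity_tibble())
  cand <- dplyr::bind_rows(rows)
  cand <- cand[order(cand$start), ]
  entity_tibble(category = "location",
    surface = substr_many(text, cand$start, cand$end),
    start = cand$start, end = cand$end,
    place_name = cand$place_name, country = cand$country)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# ---- aggregate -------------------------------------------------------------

#' Run all five extractors on one text
#'
#' Applies the scientific-name, botanist, date, coordinate and location
#' extractors and aggregates their mentions into one canonically ordered
#' table. The result is identical for any execution order of the five
#' extractors.
#'
#' @param text Source text.
#' @param resources A [load_resources()] bundle.
#' @param order Execution order, a permutation of the five category names
#'   (result-invariant; exposed for testing the order-independence property).
#' @return An [entity_tibble()] with all mentions, sorted by offset and
#'   category.
#' @export
extract_all <- function(text, resources,
                        order = ENTITY_CATEGORIES) {
  stopifnot(setequal(order, ENTITY_CATEGORIES))
  parts <- list()
  for (cat in order) {
    parts[[cat]] <- switch(cat,
      scientific_name = extract_scientific_names(text, resources$names),
      botanist = extract_botanist_names(text, resources$botanists),
      date = extract_dates(text),
      coordinate = extract_geocoords(text),
      location = extract_locations(text, resources$gazetteer))
  }
  sort_entities(dplyr::bind_rows(parts))
}
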