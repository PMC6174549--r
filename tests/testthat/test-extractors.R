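make_dict <- function(entries, kind, tolerance = 1) {
  read_dictionary(write_dict_file(entries), kind, match_tolerance = tolerance)
}

test_that("scientific names: binomial match, offsets, authorship payload", {
  dict <- make_dict(c("Ocimum", "Ocimum basilicum"), "scientific_names", 0)
  out <- extract_scientific_names("Ocimum basilicum L., Berlin", dict)
  expect_equal(nrow(out), 1)
  expect_equal(out$surface, "Ocimum basilicum")
  expect_equal(c(out$start, out$end), c(0L, 16L))
  expect_equal(out$genus, "Ocimum")
  expect_equal(out$epithet, "basilicum")
  expect_equal(out$author, "L.")
  # longest match beat the genus-only candidate; brute-force windows agree
  brute <- brute_dict_windows("Ocimum basilicum L., Berlin",
    c("Ocimum", "Ocimum basilicum"), 0)
  expect_true(any(brute$entry == "Ocimum basilicum" & brute$start == 0 & brute$end == 16))
})

test_that("scientific names: empty dictionary and OCR-mangled genus", {
  empty <- make_dict(character(0), "scientific_names")
  expect_equal(nrow(extract_scientific_names("Ocimum basilicum", empty)), 0)
  dict <- make_dict("Ocimum basilicum", "scientific_names", 1)
  out <- extract_scientific_names("0cimum basilicum", dict)
  expect_equal(out$matched_entry, "Ocimum basilicum")
  brute <- brute_dict_windows("0cimum basilicum", "Ocimum basilicum", 1)
  expect_equal(c(out$start, out$end), c(brute$start[1], brute$end[1]))
  # at tolerance 0 the mangled form must NOT match (dictionary soundness)
  dict0 <- make_dict("Ocimum basilicum", "scientific_names", 0)
  expect_equal(nrow(extract_scientific_names("0cimum basilicum", dict0)), 0)
})

test_that("wrong dictionary kind is a contract violation", {
  dict <- make_dict("Humboldt", "botanists")
  expect_error(extract_scientific_names("x", dict), class = "herbsheet_contract_error")
  dict2 <- make_dict("Ocimum", "scientific_names")
  expect_error(extract_botanist_names("x", dict2), class = "herbsheet_contract_error")
})

test_that("botanists: initials, collector and determiner cues", {
  dict <- make_dict(c("Humboldt", "Koch"), "botanists")
  out <- extract_botanist_names("leg. A. Humboldt 1803", dict)
  expect_equal(out$surface, "A. Humboldt")
  expect_equal(out$role, "collector")
  expect_equal(out$initials, "A.")
  brute <- brute_dict_windows("leg. A. Humboldt 1803", "Humboldt", 1)
  expect_equal(out$end, brute$end[1])

  out2 <- extract_botanist_names("det. K. Koch", dict)
  expect_equal(out2$role, "determiner")
  expect_equal(out2$surname, "Koch")

  out3 <- extract_botanist_names("somewhere else entirely", dict)
  expect_equal(nrow(out3), 0)

  out4 <- extract_botanist_names("herbarium of Humboldt", dict)
  expect_equal(out4$role, "unspecified")
})

test_that("dates: supported grammars normalize to ISO with cue-based kinds", {
  cases <- list(
    list("leg. 12.4.1987", "1987-04-12", "collection"),
    list("det. 3.V.1990", "1990-05-03", "determination"),
    list("acc. 1944-06-27", "1944-06-27", "accession"),
    list("12/4/1987", "1987-04-12", "unspecified"),
    list("6 May 1976", "1976-05-06", "unspecified"),
    list("coll. 1923", "1923", "collection"),
    list("rev. 28 Febr. 1901", "1901-02-28", "determination")
  )
  for (cs in cases) {
    out <- extract_dates(cs[[1]])
    expect_equal(nrow(out), 1, info = cs[[1]])
    expect_equal(out$iso_date, cs[[2]], info = cs[[1]])
    expect_equal(out$date_kind, cs[[3]], info = cs[[1]])
  }
  expect_equal(nrow(extract_dates("")), 0)
})

test_that("dates: calendar-invalid near matches are skipped, offsets verbatim", {
  expect_equal(nrow(extract_dates("31.2.1987")), 1)  # falls back to the bare year
  expect_equal(extract_dates("31.2.1987")$iso_date, "1987")
  expect_equal(nrow(extract_dates("30 February 1988")), 1)
  expect_equal(extract_dates("30 February 1988")$iso_date, "1988")
  out <- extract_dates("collected 12.4.1987 near Berlin")
  expect_equal(substr("collected 12.4.1987 near Berlin", out$start + 1, out$end),
    out$surface)
  # every emitted day-precision date survives a calendar validator
  for (s in 0:40) {
    lt <- generate_label_text(s, fixture_resources())
    for (d in extract_dates(lt$text)$iso_date) {
      if (nchar(d) == 10) expect_false(is.na(as.Date(d, "%Y-%m-%d")))
    }
  }
})

test_that("coordinates: DMS, decimal-minute, hemisphere and signed forms", {
  out <- extract_geocoords("52°27'N, 13°18'E")
  expect_equal(out$latitude, 52 + 27 / 60, tolerance = 1e-12)
  expect_equal(out$longitude, 13 + 18 / 60, tolerance = 1e-12)
  expect_equal(out$surface, "52°27'N, 13°18'E")

  out2 <- extract_geocoords("33.92 S 18.42 E")
  expect_equal(out2$latitude, -33.92)
  expect_equal(out2$longitude, 18.42)

  out3 <- extract_geocoords("52°27'30\"N, 13°18'45\"E")
  expect_equal(out3$latitude, 52 + 27 / 60 + 30 / 3600, tolerance = 1e-12)

  out4 <- extract_geocoords("-73.92 -88.32")
  expect_equal(c(out4$latitude, out4$longitude), c(-73.92, -88.32))

  expect_equal(nrow(extract_geocoords("altitude 520 m")), 0)
  expect_equal(nrow(extract_geocoords("")), 0)
})

test_that("coordinates: DMS conversion agrees with the arithmetic to 1e-9", {
  set.seed(11)
  for (i in 1:25) {
    d <- sample(0:89, 1); m <- sample(0:59, 1); s <- sample(0:59, 1)
    dl <- sample(0:179, 1); ml <- sample(0:59, 1); sl <- sample(0:59, 1)
    txt <- sprintf("%d°%d'%d\"N, %d°%d'%d\"W", d, m, s, dl, ml, sl)
    out <- extract_geocoords(txt)
    expect_equal(out$latitude, d + m / 60 + s / 3600, tolerance = 1e-9)
    expect_equal(out$longitude, -(dl + ml / 60 + sl / 3600), tolerance = 1e-9)
    expect_lte(abs(out$latitude), 90)
    expect_lte(abs(out$longitude), 180)
  }
})

test_that("coordinates: out-of-range pairs are skipped", {
  expect_equal(nrow(extract_geocoords("95.50 N 13.30 E")), 0)
  expect_equal(nrow(extract_geocoords("-12.00 -333.00")), 0)
})

test_that("locations: gazetteer lookup with longest match and country", {
  gaz_file <- tempfile(fileext = ".tsv")
  writeLines(c("Berlin\tGermany", "East Berlin\tGermany"), gaz_file)
  gaz <- read_gazetteer(gaz_file)
  out <- extract_locations("Berlin, Grunewald", gaz)
  expect_equal(out$place_name, "Berlin")
  expect_equal(out$country, "Germany")
  out2 <- extract_locations("near East Berlin", gaz)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$surface, "East Berlin")
  expect_equal(nrow(extract_locations("nothing here", gaz)), 0)
  # token boundaries: no match inside a longer word
  expect_equal(nrow(extract_locations("Berliner", gaz)), 0)
})

test_that("offset fidelity holds for every extractor on generated labels", {
  res <- fixture_resources()
  for (s in 50:99) {
    lt <- generate_label_text(s, res)
    ents <- extract_all(lt$text, res)
    expect_true(herbsheet:::check_offset_fidelity(ents, lt$text), info = s)
  }
})

test_that("extract_all is invariant under extractor execution order", {
  res <- fixture_resources()
  lt <- generate_label_text(123, res)
  base <- extract_all(lt$text, res)
  set.seed(5)
  for (i in 1:5) {
    perm <- sample(c("scientific_name", "botanist", "date", "coordinate", "location"))
    expect_identical(extract_all(lt$text, res, order = perm), base)
  }
  expect_equal(nrow(extract_all("", res)), 0)
})

test_that("tolerance-0 dictionary matches are literal dictionary entries", {
  res <- fixture_resources(match_tolerance = 0)
  genera <- vapply(strsplit(res$names$entries, " "), `[`, "", 1)
  for (s in 0:30) {
    lt <- generate_label_text(s, res)
    ents <- extract_all(lt$text, res)
    sci <- ents[ents$category == "scientific_name", ]
    expect_true(all(sci$genus %in% genera))
    bot <- ents[ents$category == "botanist", ]
    expect_true(all(bot$surname %in% res$botanists$entries))
  }
})
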