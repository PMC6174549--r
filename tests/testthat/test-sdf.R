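test_that("a fresh SDF is empty and independent per call", {
  s1 <- create_sdf(specimen_ref("urn:x:sheet1", "s1.png"))
  expect_identical(s1$specimen$guid, "urn:x:sheet1")
  expect_null(s1$dpi)
  expect_null(s1$scale_region)
  expect_null(s1$text_regions)
  expect_null(s1$texts)
  expect_length(s1$entities, 0)
  expect_length(s1$history, 0)

  s2 <- create_sdf(specimen_ref("urn:x:sheet1", "s1.png"))
  s2 <- record_result(s2, "dpi_service", 300)
  expect_null(s1$dpi)  # value semantics, no shared state
  expect_equal(s2$dpi, 300)
})

test_that("an empty guid is rejected", {
  expect_error(specimen_ref("", "s1.png"), class = "herbsheet_invalid_identifier")
})

test_that("record_result writes fields, appends history in call order", {
  s <- create_sdf(specimen_ref("urn:x:1", "a.png"))
  s <- record_result(s, "dpi_service", 300, parameters = list(note = "first"))
  expect_equal(s$dpi, 300)
  expect_length(s$history, 1)
  s <- record_result(s, "text_region_service", region(0, 0, 10, 10))
  expect_length(s$history, 2)
  expect_equal(vapply(s$history, `[[`, "", "service_name"),
    c("dpi_service", "text_region_service"))
  # previously recorded fields untouched
  expect_equal(s$dpi, 300)
})

test_that("re-running a service replaces its field and extends history", {
  s <- create_sdf(specimen_ref("urn:x:1", "a.png"))
  s <- record_result(s, "dpi_service", 300)
  s <- record_result(s, "dpi_service", 600)
  expect_equal(s$dpi, 600)
  expect_length(s$history, 2)
})

test_that("unknown services and malformed payloads are refused", {
  s <- create_sdf(specimen_ref("urn:x:1", "a.png"))
  expect_error(record_result(s, "bogus", 1), class = "herbsheet_unknown_service")
  expect_error(record_result(s, "dpi_service", -5), class = "herbsheet_contract_error")
  expect_error(record_result(s, "scale_matching_service", data.frame(x = 1)),
    class = "herbsheet_contract_error")
  expect_error(record_result(s, "date_extractor",
    entity_tibble(category = "location", surface = "x", start = 0L, end = 1L)),
    class = "herbsheet_contract_error")
})

fully_populated_sdf <- function() {
  s <- create_sdf(specimen_ref("urn:x:full", "full.png"))
  s <- record_result(s, "scale_matching_service", tibble::tibble(
    x = 10L, y = 20L, width = 120L, height = 40L, score = 0.987654321,
    magnification = 1.189207, flagged = FALSE))
  s <- record_result(s, "dpi_service", list(dpi = 312.5, flagged = FALSE),
    parameters = list(sri_resolution = 300))
  s <- record_result(s, "text_region_service",
    tibble::tibble(x = c(5L, 50L), y = c(5L, 80L), width = c(40L, 60L),
      height = c(20L, 25L), contrast = c(0.11, 0.22)))
  s <- record_result(s, "ocr_service", tibble::tibble(
    region_index = 1:2, x = c(5L, 50L), y = c(5L, 80L), width = c(40L, 60L),
    height = c(20L, 25L), text = c("Ocimum basilicum L.", "52°27'N, 13°18'E"),
    engine = "fixture", error = FALSE))
  s <- record_result(s, "geocoord_extractor", entity_tibble(
    category = "coordinate", surface = "52°27'N, 13°18'E", start = 0L, end = 16L,
    region_index = 2L, latitude = 52 + 27 / 60, longitude = 13 + 18 / 60))
  s
}

test_that("SDF files round-trip field-for-field", {
  dir <- withr::local_tempdir()
  full <- fully_populated_sdf()
  p <- file.path(dir, "full.sdf.json")
  write_sdf(full, p)
  expect_equal(read_sdf(p), full)

  empty <- create_sdf(specimen_ref("urn:x:empty", "e.png"))
  p2 <- file.path(dir, "empty.sdf.json")
  write_sdf(empty, p2)
  expect_equal(read_sdf(p2), empty)
})

test_that("serialization is canonical and byte-stable", {
  j <- sdf_to_json(fully_populated_sdf())
  expect_identical(sdf_to_json(sdf_from_json(j)), j)
  # canonical key order: reserializing a key-scrambled document restores it
  doc <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  scrambled <- jsonlite::toJSON(rev(doc), auto_unbox = TRUE, digits = NA)
  expect_identical(sdf_to_json(sdf_from_json(scrambled)), j)
})

test_that("parse errors name the offending field, wrong versions are refused", {
  expect_error(sdf_from_json('{"schema_version":"1.0","specimen":{"image_uri":"a"}}'),
    regexp = "guid", class = "herbsheet_parse_error")
  expect_error(sdf_from_json('{"specimen":{"guid":"g"}}'),
    class = "herbsheet_parse_error")
  expect_error(
    sdf_from_json('{"schema_version":"9.9","specimen":{"guid":"g","image_uri":"a"}}'),
    class = "herbsheet_version_error")
  expect_error(sdf_from_json("{not json"), class = "herbsheet_parse_error")
})
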