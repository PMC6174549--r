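make_sheet_batch <- function(n, dir, seed = 400, n_labels = 1, ...) {
  sri <- make_synthetic_sri()
  man <- synth_sheets(n, dir, seed = seed, sri = sri,
    resources = fixture_resources(), n_labels = n_labels, ...)
  list(sri = sri, manifest = man,
    specimens = tibble::tibble(guid = man$guid, image_uri = man$image))
}

test_that("pre-OCR populates scale, dpi and text regions with full provenance", {
  dir <- withr::local_tempdir()
  b <- make_sheet_batch(1, dir, seed = 401)
  sdfs <- run_pre_ocr(b$specimens, b$sri, search = 1)
  s <- sdfs[[1]]
  expect_false(is.null(s$scale_region))
  expect_equal(s$dpi, 300)
  expect_false(s$dpi_flagged)
  expect_gte(nrow(s$text_regions), 1)
  expect_equal(vapply(s$history, `[[`, "", "service_name"),
    c("scale_matching_service", "dpi_service", "text_region_service"))
  expect_equal(workflow_report(sdfs)$status, "ok")
})

test_that("empty specimen lists and unreadable images are handled per specimen", {
  sri <- make_synthetic_sri()
  empty <- run_pre_ocr(tibble::tibble(guid = character(), image_uri = character()), sri)
  expect_length(empty, 0)

  dir <- withr::local_tempdir()
  b <- make_sheet_batch(1, dir, seed = 402)
  specimens <- dplyr::bind_rows(b$specimens,
    tibble::tibble(guid = "urn:herbsheet:gone", image_uri = file.path(dir, "gone.png")))
  sdfs <- run_pre_ocr(specimens, b$sri, search = 1)
  rep <- workflow_report(sdfs)
  expect_equal(rep$status, c("ok", "failed"))
  # isolation: the failing specimen never touches the other SDF
  expect_equal(sdfs[[1]]$dpi, 300)
  expect_null(sdfs[[2]]$dpi)
})

test_that("OCR workflow needs pre-OCR output and tolerates empty region sets", {
  fresh <- create_sdf(specimen_ref("urn:x:noregions", "nowhere.png"))
  out <- run_ocr(list(fresh), engine = ocr_engine("nop", function(r) ""))
  expect_equal(workflow_report(out)$status, "flagged")

  withregions <- record_result(fresh, "text_region_service",
    region(integer(), integer(), integer(), integer()))
  # empty region list: vacuous OCR, no image read needed
  out2 <- run_ocr(list(withregions), engine = ocr_engine("nop", function(r) ""))
  expect_equal(workflow_report(out2)$status, "ok")
  expect_equal(nrow(out2[[1]]$texts), 0)
})

test_that("the extractor workflow records per-region entities and is idempotent", {
  res <- fixture_resources()
  s <- create_sdf(specimen_ref("urn:x:label", "l.png"))
  s <- record_result(s, "text_region_service", region(0, 0, 100, 40))
  s <- record_result(s, "ocr_service", tibble::tibble(
    region_index = 1L, x = 0L, y = 0L, width = 100L, height = 40L,
    text = "Ocimum basilicum L. leg. A. Humboldt 12.4.1987, Berlin, 52°27'N 13°18'E",
    engine = "fixture", error = FALSE))
  out <- run_extractors(list(s), res)
  g <- glance(out[[1]])
  expect_equal(unlist(g[paste0("n_", c("scientific_name", "botanist", "date",
    "coordinate", "location"))], use.names = FALSE), rep(1L, 5))
  ents <- tidy(out[[1]])
  expect_equal(ents$iso_date[ents$category == "date"], "1987-04-12")
  expect_equal(ents$date_kind[ents$category == "date"], "collection")
  expect_equal(ents$role[ents$category == "botanist"], "collector")
  expect_equal(ents$latitude[ents$category == "coordinate"], 52.45)
  expect_equal(ents$longitude[ents$category == "coordinate"], 13.3)
  expect_equal(ents$country[ents$category == "location"], "Germany")
  expect_true(all(ents$region_index == 1L))

  again <- run_extractors(out, res)
  expect_identical(tidy(again[[1]]), ents)
  expect_length(again[[1]]$history, length(out[[1]]$history) + 5)
})

test_that("missing resources abort the extractor run as a configuration error", {
  expect_error(run_extractors(list(), resources = list(names = NULL)),
    class = "herbsheet_invalid_input")
})

test_that("dispatch enforces the registered input contracts", {
  reg <- service_contracts()
  expect_error(dispatch_service(reg, "nope", list()),
    class = "herbsheet_unknown_service")
  expect_error(dispatch_service(reg, "scale_matching_service",
    list(image = "not a matrix", sri = tiny_sri())),
    class = "herbsheet_contract_error")
  expect_error(dispatch_service(reg, "date_extractor", list(text = 42)),
    class = "herbsheet_contract_error")
  expect_error(dispatch_service(reg, "ocr_service",
    list(image = matrix(0, 2, 2), regions = "x", engine = "y")),
    class = "herbsheet_contract_error")
})

test_that("a contract-identical stub can replace text detection", {
  dir <- withr::local_tempdir()
  b <- make_sheet_batch(1, dir, seed = 403)
  stub <- function(input) {
    tibble::tibble(x = integer(), y = integer(), width = integer(),
      height = integer(), contrast = double())
  }
  reg <- rebind_service(service_contracts(), "text_region_service", stub)
  sdfs <- run_pre_ocr(b$specimens, b$sri, search = 1, registry = reg)
  expect_equal(workflow_report(sdfs)$status, "ok")
  expect_equal(nrow(sdfs[[1]]$text_regions), 0)
})

test_that("the full pipeline recovers every planted entity on a clean sheet", {
  dir <- withr::local_tempdir()
  b <- make_sheet_batch(2, dir, seed = 404, n_labels = c(1, 2))
  sdfs <- run_pipeline(b$specimens, b$sri, fixture_resources(),
    engine = "fixture", search = 1)
  expect_equal(workflow_report(sdfs)$status, c("ok", "ok"))
  # history completeness: one entry per invoked service, in invocation order
  expect_equal(vapply(sdfs[[1]]$history, `[[`, "", "service_name"),
    c("scale_matching_service", "dpi_service", "text_region_service",
      "ocr_service", unname(herbsheet:::EXTRACTOR_SERVICES)))
  for (i in 1:2) {
    truth <- read_sheet_truth(b$manifest$truth[i])
    sc <- score_extraction(truth$planted_entities, tidy(sdfs[[i]]))
    expect_true(all(sc$recovered))
    expect_equal(sc$spurious, 0)
  }
})

test_that("the CLI validates flags and composes workflows end to end", {
  expect_equal(cli(c("extract", "--sdf", "x", "--out", "y")), 2L)
  expect_equal(cli("frobnicate"), 2L)
  expect_equal(cli(character(0)), 2L)

  dir <- withr::local_tempdir()
  img_dir <- file.path(dir, "img")
  b <- make_sheet_batch(1, img_dir, seed = 405)
  write_sheet_image(b$sri$image, file.path(img_dir, "sri.png"))
  rs <- function(f) system.file("extdata", f, package = "herbsheet")

  out1 <- file.path(dir, "seq1"); out2 <- file.path(dir, "seq2")
  code <- cli(c("pre-ocr", "--images", img_dir, "--sri", file.path(img_dir, "sri.png"),
    "--sri-dpi", "300", "--out", out1))
  expect_equal(code, 0L)
  expect_equal(cli(c("ocr", "--sdf", out1, "--out", out2)), 0L)
  seq_out <- file.path(dir, "seq3")
  expect_equal(cli(c("extract", "--sdf", out2, "--out", seq_out,
    "--names", rs("names.txt"), "--botanists", rs("botanists.txt"),
    "--gazetteer", rs("gazetteer.tsv"))), 0L)

  all_out <- file.path(dir, "all")
  expect_equal(cli(c("run-all", "--images", img_dir,
    "--sri", file.path(img_dir, "sri.png"), "--sri-dpi", "300",
    "--out", all_out, "--names", rs("names.txt"),
    "--botanists", rs("botanists.txt"), "--gazetteer", rs("gazetteer.tsv"))), 0L)

  fs <- list.files(seq_out)
  expect_identical(fs, list.files(all_out))
  for (f in fs) {
    expect_identical(readBin(file.path(seq_out, f), "raw", 1e6),
      readBin(file.path(all_out, f), "raw", 1e6), label = f)
  }
})
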