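blank_engine <- ocr_engine("blank", function(raster) {
  if (all(abs(raster - raster[1, 1]) < 1e-12)) "" else "ink"
})

test_that("recognize_regions handles empty input and blank crops", {
  img <- matrix(1, 100, 100)
  expect_equal(nrow(recognize_regions(region(integer(), integer(), integer(), integer()),
    img, blank_engine)), 0)
  out <- recognize_regions(region(10, 10, 20, 20), img, blank_engine)
  expect_equal(out$text, "")
  expect_false(out$error)
})

test_that("out-of-bounds regions are rejected with the offending index", {
  img <- matrix(1, 50, 50)
  expect_error(
    recognize_regions(region(c(0, 40), c(0, 40), c(10, 20), c(10, 20)), img, blank_engine),
    regexp = "region 2", class = "herbsheet_invalid_region")
})

test_that("output preserves input region order and isolates engine failures", {
  img <- matrix(seq(0, 1, length.out = 2500), 50, 50)
  n <- 0
  flaky <- ocr_engine("flaky", function(raster) {
    n <<- n + 1
    if (n == 2) stop("boom")
    paste0("crop", n)
  })
  regs <- region(c(0, 10, 20), c(0, 10, 20), c(5, 5, 5), c(5, 5, 5))
  out <- recognize_regions(regs, img, flaky)
  expect_equal(out$region_index, 1:3)
  expect_equal(out$text, c("crop1", "", "crop3"))
  expect_equal(out$error, c(FALSE, TRUE, FALSE))
})

test_that("the fixture engine returns planted text by region overlap", {
  sri <- make_synthetic_sri()
  res <- fixture_resources()
  sh <- generate_sheet(sheet_spec(seed = 9, n_labels = 2), sri, res)
  eng <- make_fixture_engine(sh$truth)
  out <- recognize_regions(sh$truth$label_boxes, sh$image, eng)
  expect_identical(out$text, sh$truth$label_texts)
  # a region with negligible overlap to every planted box reads as blank
  far <- recognize_regions(region(0, 0, 30, 30), sh$image, eng)
  expect_equal(far$text, "")
})

test_that("pixels outside the requested regions never influence the result", {
  sri <- make_synthetic_sri()
  sh <- generate_sheet(sheet_spec(seed = 10, n_labels = 1, clutter_density = 0),
    sri, fixture_resources())
  eng <- make_fixture_engine(sh$truth)
  base <- recognize_regions(sh$truth$label_boxes, sh$image, eng)
  noisy <- sh$image
  box <- sh$truth$label_boxes[1, ]
  outside_y <- if (box$y > 60) 1:40 else (nrow(noisy) - 40):nrow(noisy)
  set.seed(4)
  noisy[outside_y, ] <- matrix(stats::runif(length(outside_y) * ncol(noisy)),
    length(outside_y), ncol(noisy))
  again <- recognize_regions(sh$truth$label_boxes, noisy, eng)
  expect_identical(again$text, base$text)
})

test_that("seeded corruption is deterministic and Binomial-consistent", {
  truth <- list(label_boxes = region(0, 0, 100, 40),
    label_texts = "Berlin 12.4.1987")
  reg <- region(0, 0, 100, 40)
  img <- matrix(0.5, 40, 100)
  e1 <- make_fixture_engine(truth, corruption_p = 0.05, seed = 7)
  e2 <- make_fixture_engine(truth, corruption_p = 0.05, seed = 7)
  t1 <- recognize_regions(reg, img, e1)$text
  t2 <- recognize_regions(reg, img, e2)$text
  expect_identical(t1, t2)
  expect_equal(nchar(t1), 16)  # substitution-only model preserves length
  d <- utils::adist("Berlin 12.4.1987", t1)
  expect_lte(d, stats::qbinom(1 - 1e-9, 16, 0.05))
  # across many labels the corruption rate concentrates near p
  texts <- vapply(1:200, function(i) strrep("a", 50), character(1))
  truth2 <- list(label_boxes = region(0, (0:199) * 50, 40, 40), label_texts = texts)
  e3 <- make_fixture_engine(truth2, corruption_p = 0.05, seed = 3)
  dd <- vapply(1:200, function(i) {
    crop <- img
    attr(crop, "region") <- region(0, (i - 1) * 50, 40, 40)
    utils::adist(strrep("a", 50), e3$recognize(crop))
  }, numeric(1))
  expect_gt(mean(dd) / 50, 0.02)
  expect_lt(mean(dd) / 50, 0.09)
})

test_that("zero-probability corruption returns planted text verbatim", {
  truth <- list(label_boxes = region(5, 5, 60, 20), label_texts = "Ocimum basilicum L.")
  eng <- make_fixture_engine(truth, corruption_p = 0)
  crop <- matrix(0.5, 20, 60)
  attr(crop, "region") <- region(5, 5, 60, 20)
  expect_identical(eng$recognize(crop), "Ocimum basilicum L.")
})
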