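test_that("an image identical to the SRI matches itself exactly", {
  sri <- tiny_sri()
  m <- match_scale(sri$image, sri, search = c(0.5, 1, 2))
  expect_equal(unlist(m[, c("x", "y", "width", "height")]),
    c(x = 0L, y = 0L, width = ncol(sri$image), height = nrow(sri$image)))
  expect_equal(m$score, 1, tolerance = 1e-6)
  expect_equal(m$magnification, 1)
  expect_false(m$flagged)
})

test_that("fast NCC agrees with the exhaustive sliding-window oracle", {
  set.seed(42)
  img <- matrix(stats::runif(80 * 100), 80, 100)
  img <- (img + t(herbsheet:::box_density(t(img), 5, 5))) / 2  # smooth a bit
  templ <- img[31:42, 51:68]
  fast <- herbsheet:::ncc_valid(img, templ)
  brute <- ncc_brute(img, templ)
  expect_equal(fast, brute, tolerance = 1e-8)
  hit <- which(fast == max(fast), arr.ind = TRUE)
  expect_equal(unname(hit[1, ]), c(31, 51))
})

test_that("a pasted SRI is found at the paste position", {
  sri <- tiny_sri()
  img <- matrix(0.75, 500, 700)
  img[201:(200 + nrow(sri$image)), 101:(100 + ncol(sri$image))] <- sri$image
  m <- match_scale(img, sri, search = 1)
  expect_equal(c(m$x, m$y), c(100L, 200L))
  expect_gte(m$score, 0.99)
})

test_that("the magnification grid recovers a 2x paste", {
  sri <- tiny_sri()
  big <- herbsheet:::rescale_raster(sri$image, 2)
  img <- matrix(0.75, 600, 800)
  img[381:(380 + nrow(big)), 101:(100 + ncol(big))] <- big
  m <- match_scale(img, sri, search = c(0.5, 1, 2))
  expect_equal(m$magnification, 2)
  expect_lte(abs(m$x - 100), 2)
  expect_lte(abs(m$y - 380), 2)
})

test_that("match_scale errors when no magnification fits the image", {
  sri <- tiny_sri()
  expect_error(match_scale(matrix(0.5, 5, 5), sri, search = c(1, 2)),
    class = "herbsheet_no_match")
})

test_that("a weak match is flagged, not raised", {
  sri <- tiny_sri()
  set.seed(1)
  img <- matrix(stats::runif(200 * 300), 200, 300)
  m <- match_scale(img, sri, search = 1, accept_threshold = 0.6)
  expect_true(m$flagged)
  expect_lt(m$score, 0.6)
})

test_that("compute_dpi implements pixel width / physical length and is linear", {
  sri <- scale_reference(matrix(c(0, 1), 60, 600), 300)
  expect_equal(compute_dpi(tibble::tibble(width = 600), sri), 300)
  # physical length = 600 px / 300 dpi = 2 in; 1200 px / 2 in = 600 dpi
  expect_equal(compute_dpi(tibble::tibble(width = 1200), sri), 600)
  w <- 137
  for (k in c(2, 3.5, 10)) {
    expect_equal(compute_dpi(tibble::tibble(width = k * w), sri),
      k * compute_dpi(tibble::tibble(width = w), sri))
  }
  expect_error(compute_dpi(tibble::tibble(width = 0), sri),
    class = "herbsheet_invalid_input")
})

test_that("a uniform blank image yields no text regions", {
  expect_equal(nrow(detect_text_regions(matrix(0.9, 300, 300), 300)), 0)
  expect_error(detect_text_regions(matrix(0.9, 10, 10), -1),
    class = "herbsheet_invalid_input")
})

test_that("a single rendered label is detected with IoU >= 0.5", {
  p <- plain_text_image(c("Ocimum basilicum L.", "leg. A. Humboldt", "Berlin"))
  regs <- detect_text_regions(p$image, 300)
  expect_equal(nrow(regs), 1)
  expect_gte(region_iou(p$box, regs[1, ]), 0.5)
})

test_that("two labels separated by twice the merge radius stay separate", {
  img <- matrix(0.82, 500, 600)
  b1 <- herbsheet:::render_text_block(c("Quercus robur L.", "leg. K. Engler"), 3)
  b2 <- herbsheet:::render_text_block(c("Betula pendula", "Potsdam 1901"), 3)
  img[61:(60 + nrow(b1)), 41:(40 + ncol(b1))] <- 1 - 0.92 * b1
  y2 <- 60 + nrow(b1) + 2 * 30 + 40  # >= 2 x merge radius apart
  img[(y2 + 1):(y2 + nrow(b2)), 41:(40 + ncol(b2))] <- 1 - 0.92 * b2
  regs <- detect_text_regions(img, 300)
  expect_equal(nrow(regs), 2)
  expect_gte(best_iou(region(40, 60, ncol(b1), nrow(b1)), regs), 0.5)
  expect_gte(best_iou(region(40, y2, ncol(b2), nrow(b2)), regs), 0.5)
})

test_that("detection is invariant under added white margin, up to the offset", {
  # a white margin abutting a white sheet border adds no contrast seam, so
  # the output must be exactly the coordinate-shifted original
  p <- plain_text_image(c("Salvia officinalis", "Innsbruck, 1907"), shade = 1)
  base <- detect_text_regions(p$image, 300)
  pad <- 40
  big <- matrix(1, nrow(p$image) + 2 * pad, ncol(p$image) + 2 * pad)
  big[(pad + 1):(pad + nrow(p$image)), (pad + 1):(pad + ncol(p$image))] <- p$image
  shifted <- detect_text_regions(big, 300)
  expect_equal(nrow(shifted), nrow(base))
  expect_equal(shifted$x - pad, base$x)
  expect_equal(shifted$y - pad, base$y)
  expect_equal(shifted$width, base$width)
  expect_equal(shifted$height, base$height)
})

test_that("all detected regions lie within the image bounds", {
  sri <- make_synthetic_sri()
  sh <- generate_sheet(sheet_spec(seed = 5, n_labels = 2), sri, fixture_resources())
  regs <- detect_text_regions(sh$image, 300)
  expect_silent(validate_regions(regs, nrow(sh$image), ncol(sh$image)))
})
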