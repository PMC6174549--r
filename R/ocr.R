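# OCR over detected regions through a pluggable engine interface. Recognition
# is restricted to image parts given by coordinates: only the cropped region
# pixels ever reach the engine.

#' Define an OCR engine
#'
#' An engine is a name plus a `recognize` function mapping a grayscale crop
#' (matrix `[y, x]`, values in `[0, 1]`) to a character string. Engines must
#' be deterministic for a fixed raster and return `""` for a blank raster.
#' [recognize_regions()] attaches the crop's source region as the `region`
#' attribute of the raster; engines that need it (such as the fixture
#' engine) may read it, pixel-based engines simply ignore it.
#'
#' @param name Engine name, recorded with every recognized text.
#' @param recognize `function(raster) -> string`.
#' @return An `ocr_engine` object.
#' @export
ocr_engine <- function(name, recognize) {
  stopifnot(is.character(name), length(name) == 1, is.function(recognize))
  structure(list(name = name, recognize = recognize), class = "ocr_engine")
}

#' Recognize text in each region of an image
#'
#' Crops every region (half-open pixel convention) and passes the crop to the
#' engine, returning one row per region in input order. An engine failure on
#' one crop is recorded as empty text with `error = TRUE` and the run
#' continues; pixels outside the requested regions never reach the engine.
#'
#' @param regions Region tibble (`x`, `y`, `width`, `height`), e.g. the
#'   `text_regions` of an SDF.
#' @param image Grayscale matrix `[y, x]`.
#' @param engine An [ocr_engine()].
#' @return A tibble with columns `region_index`, `x`, `y`, `width`,
#'   `height`, `text`, `engine`, `error`.
#' @export
recognize_regions <- function(regions, image, engine) {
  stopifnot(inherits(engine, "ocr_engine"))
  out <- tibble::tibble(region_index = integer(), x = integer(), y = integer(),
    width = integer(), height = integer(), text = character(),
    engine = character(), error = logical())
  if (nrow(regions) == 0) return(out)
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    ok <- tryCatch({ validate_regions(reg, nrow(image), ncol(image)); TRUE },
      herbsheet_invalid_region = function(e) FALSE)
    if (!ok) {
      rlang::abort(paste0("region ", i, " lies outside the image bounds"),
        class = "herbsheet_invalid_region")
    }
    crop <- crop_region(image, reg)
    attr(crop, "region") <- reg
    res <- tryCatch(list(text = engine$recognize(crop), error = FALSE),
      error = function(e) list(text = "", error = TRUE))
    txt <- res$text
    if (!is.character(txt) || length(txt) != 1 || is.na(txt)) {
      txt <- ""
      res$error <- TRUE
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      region_index = i, x = reg$x, y = reg$y, width = reg$width,
      height = reg$height, text = txt, engine = engine$name, error = res$error))
  }
  out
}

# Deterministic per-label character corruption: substitution with probability
# p per character, seeded from (seed, label index) so identical inputs give
# identical noisy strings. The caller's RNG state is preserved.
corrupt_text <- function(text, p, seed, idx) {
  if (p <= 0 || nchar(text) == 0) return(text)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) * 7919L + as.integer(idx) * 104729L) %% 2147483647L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    pool <- c(letters, LETTERS, 0:9)
    repl <- sample(pool, sum(hit), replace = TRUE)
    # never replace a character with itself, so the edit distance is exact
    same <- repl == chars[hit]
    while (any(same)) {
      repl[same] <- sample(pool, sum(same), replace = TRUE)
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Fixture OCR engine backed by synthetic-sheet ground truth
#'
#' A test double standing in for a real OCR binary: given a crop, it returns
#' the planted text of the ground-truth label whose box has maximal
#' intersection-over-union with the crop's source region, provided that IoU
#' reaches `min_iou`; otherwise `""`. With `corruption_p > 0` a seeded
#' per-character substitution model emulates OCR noise deterministically.
#'
#' @param truth A `sheet_truth` object (or a list with `label_boxes` and
#'   `label_texts`), e.g. from [generate_sheet()] or [read_sheet_truth()].
#' @param corruption_p Per-character substitution probability.
#' @param seed Integer seed for the corruption model.
#' @param min_iou Minimum region/label IoU for a match (default 0.3).
#' @return An [ocr_engine()] named `"fixture"`.
#' @export
make_fixture_engine <- function(truth, corruption_p = 0, seed = 0, min_iou = 0.3) {
  boxes <- tibble::as_tibble(truth$label_boxes)
  texts <- truth$label_texts
  ocr_engine("fixture", function(raster) {
    reg <- attr(raster, "region")
    if (is.null(reg) || nrow(boxes) == 0) return("")
    ious <- region_iou_many(reg, boxes)
    best <- which.max(ious)
    if (length(best) == 0 || ious[best] < min_iou) return("")
    corrupt_text(texts[[best]], corruption_p, seed, best)
  })
}

#' Tesseract adapter engine
#'
#' Optional adapter around a locally installed `tesseract` binary; each crop
#' is written to a temporary PNG and recognized via the command line. Never
#' required by the test suite — use the fixture engine for reproducible runs.
#'
#' @param language Tesseract language code.
#' @return An [ocr_engine()] named `"tesseract"`.
#' @export
make_tesseract_engine <- function(language = "eng") {
  if (!nzchar(Sys.which("tesseract"))) {
    rlang::abort("tesseract binary not found on PATH", class = "herbsheet_invalid_input")
  }
  ocr_engine("tesseract", function(raster) {
    tmp <- tempfile(fileext = ".png")
    on.exit(unlink(tmp))
    png::writePNG(pmin(pmax(raster, 0), 1), tmp)
    out <- suppressWarnings(system2("tesseract",
      c(tmp, "stdout", "-l", language, "--psm", "6"),
      stdout = TRUE, stderr = FALSE))
    trimws(paste(out, collapse = "\n"))
  })
}
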