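#' Read a specimen image as a grayscale matrix
#'
#' Decodes PNG, TIFF or JPEG and returns a plain numeric matrix indexed
#' `[y, x]` with intensities in `[0, 1]`. Colour images are converted to
#' luma with ITU-R BT.601 weights (0.299 R + 0.587 G + 0.114 B); an alpha
#' channel, if present, is dropped.
#'
#' @param path Image file path (`.png`, `.tif(f)`, `.jpg`/`.jpeg`).
#' @return A numeric matrix, rows = image height, columns = image width.
#' @export
read_sheet_image <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("image file not found: ", path), class = "herbsheet_invalid_input")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    arr <- as.array(img)
    # EBImage stores dim (x, y[, c]); transpose to [y, x]
    arr <- if (length(dim(arr)) == 2) t(arr) else aperm(arr, c(2, 1, 3))
  }
  to_gray(arr)
}

# BT.601 luma conversion for [y, x(, channel)] arrays in [0, 1].
to_gray <- function(arr) {
  if (length(dim(arr)) == 2 || is.null(dim(arr))) {
    return(matrix(as.numeric(arr), nrow = dim(arr)[1]))
  }
  nc <- dim(arr)[3]
  if (nc >= 3) {
    g <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  } else {
    g <- arr[, , 1]
  }
  matrix(g, nrow = dim(arr)[1])
}

#' Write a grayscale matrix as a PNG file
#'
#' @param image Numeric matrix `[y, x]`, values clipped to `[0, 1]`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_sheet_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
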