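#' Build a region tibble
#'
#' A region is an axis-aligned pixel rectangle on an image, stored one per row
#' with columns `x`, `y`, `width`, `height`. Coordinates are 0-based with the
#' origin at the top-left pixel, x growing rightward and y downward; a region
#' covers the half-open pixel ranges `[x, x + width)` by `[y, y + height)`.
#'
#' @param x,y Integer top-left corner (0-based), vectorised.
#' @param width,height Positive integer extents, vectorised.
#' @return A tibble with one row per region.
#' @export
#' @examples
#' region(10, 20, 100, 40)
region <- function(x, y, width, height) {
  out <- tibble::tibble(
    x = as.integer(x), y = as.integer(y),
    width = as.integer(width), height = as.integer(height)
  )
  validate_regions(out)
  out
}

#' Validate region invariants
#'
#' Checks that widths and heights are positive, corners non-negative and,
#' when image dimensions are given, that every region lies fully inside the
#' image.
#'
#' @param regions A region tibble (columns `x`, `y`, `width`, `height`).
#' @param image_height,image_width Optional image extent in pixels.
#' @return `regions`, invisibly.
#' @export
validate_regions <- function(regions, image_height = NULL, image_width = NULL) {
  stopifnot(is.data.frame(regions))
  need <- c("x", "y", "width", "height")
  miss <- setdiff(need, names(regions))
  if (length(miss) > 0) {
    rlang::abort(paste0("region table lacks column(s): ", paste(miss, collapse = ", ")),
      class = "herbsheet_invalid_region")
  }
  if (nrow(regions) == 0) return(invisible(regions))
  bad <- regions$width <= 0 | regions$height <= 0 | regions$x < 0 | regions$y < 0
  if (!is.null(image_height)) {
    bad <- bad | (regions$y + regions$height > image_height) |
      (regions$x + regions$width > image_width)
  }
  if (any(bad)) {
    rlang::abort(
      paste0("invalid region at row(s) ", paste(which(bad), collapse = ", "),
        ": must have positive extent, non-negative corner",
        if (!is.null(image_height)) " and lie within the image bounds" else ""),
      class = "herbsheet_invalid_region"
    )
  }
  invisible(regions)
}

#' Intersection-over-union of two regions
#'
#' @param a,b Single-row region tibbles (or lists with `x`, `y`, `width`,
#'   `height`).
#' @return IoU in `[0, 1]`.
#' @export
region_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$width, b$x + b$width) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$height, b$y + b$height) - max(a$y, b$y))
  inter <- as.numeric(ix) * as.numeric(iy)
  union <- as.numeric(a$width) * a$height + as.numeric(b$width) * b$height - inter
  if (union <= 0) return(0)
  inter / union
}

# IoU of one region against each row of a region table
region_iou_many <- function(a, regions) {
  if (nrow(regions) == 0) return(numeric(0))
  vapply(seq_len(nrow(regions)), function(i) region_iou(a, regions[i, ]), numeric(1))
}

# Do two regions overlap at all (pixel intersection non-empty)?
regions_intersect <- function(a, b) {
  region_iou(a, b) > 0
}

# Crop a [y, x] image matrix to a single region (half-open convention).
crop_region <- function(image, reg) {
  validate_regions(reg, nrow(image), ncol(image))
  image[(reg$y + 1):(reg$y + reg$height), (reg$x + 1):(reg$x + reg$width), drop = FALSE]
}
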