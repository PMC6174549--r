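# Printed-text region detection by the line-contrast profile: text lines show
# high horizontal contrast with dark and bright pixels alternating quickly, so
# windows dense in strong horizontal transitions are text candidates.

#' Parameters for line-contrast text detection
#'
#' All lengths are physical (inches) and converted to pixels through the
#' image DPI, so one parameter set works across scan resolutions.
#'
#' @param contrast_threshold Minimum horizontal gradient magnitude (on the
#'   `[0, 1]` intensity scale) for a pixel step to count as a dark/bright
#'   transition. Default 40/255.
#' @param window_width_in,window_height_in Sliding window size in inches over
#'   which transition density is measured.
#' @param density_threshold Minimum transitions per window pixel.
#' @param merge_radius_in Radius (inches) of the disc used to morphologically
#'   close accepted windows into label-sized rectangles.
#' @param min_text_height_in Rectangles whose smaller dimension falls below
#'   this physical size are discarded.
#' @return A `text_detect_params` list.
#' @export
text_detect_params <- function(contrast_threshold = 40 / 255,
                               window_width_in = 0.25,
                               window_height_in = 0.083,
                               density_threshold = 0.08,
                               merge_radius_in = 0.1,
                               min_text_height_in = 0.07) {
  structure(list(
    contrast_threshold = contrast_threshold,
    window_width_in = window_width_in,
    window_height_in = window_height_in,
    density_threshold = density_threshold,
    merge_radius_in = merge_radius_in,
    min_text_height_in = min_text_height_in
  ), class = "text_detect_params")
}

# Box mean with "same" output size and zero padding outside the image.
box_density <- function(e, win_h, win_w) {
  H <- nrow(e); W <- ncol(e)
  pad <- matrix(0, H + win_h - 1, W + win_w - 1)
  oy <- (win_h - 1) %/% 2; ox <- (win_w - 1) %/% 2
  pad[(oy + 1):(oy + H), (ox + 1):(ox + W)] <- e
  window_sums(pad, win_h, win_w) / (win_h * win_w)
}

#' Detect printed-text regions on a specimen image
#'
#' Computes the horizontal gradient magnitude, binarizes it at
#' `contrast_threshold`, measures the transition density in a sliding window
#' (dpi-scaled physical size), keeps windows above `density_threshold`,
#' merges them by morphological closing with a disc of `merge_radius_in`, and
#' returns the bounding rectangle of each connected component whose smaller
#' dimension reaches `min_text_height_in`.
#'
#' @param image Grayscale matrix `[y, x]`, values in `[0, 1]`.
#' @param dpi Image resolution in dots per inch (> 0), typically from
#'   [compute_dpi()].
#' @param params A [text_detect_params()] list.
#' @return A tibble of regions (`x`, `y`, `width`, `height`) plus a
#'   `contrast` column (mean horizontal gradient inside the region), ordered
#'   by (`y`, `x`).
#' @export
detect_text_regions <- function(image, dpi, params = text_detect_params()) {
  if (!is.numeric(dpi) || length(dpi) != 1 || is.na(dpi) || dpi <= 0) {
    rlang::abort("dpi must be a single positive number", class = "herbsheet_invalid_input")
  }
  if (!is.matrix(image) || length(image) == 0) {
    rlang::abort("image must be a non-empty matrix", class = "herbsheet_invalid_input")
  }
  H <- nrow(image); W <- ncol(image)
  empty <- tibble::tibble(x = integer(), y = integer(), width = integer(),
    height = integer(), contrast = double())
  if (W < 3 || H < 3) return(empty)

  g <- image[, -1, drop = FALSE] - image[, -W, drop = FALSE]
  gx <- abs(g)
  # binarized signed gradient: -1 entering a dark run, +1 leaving it, 0 flat
  s <- sign(g) * (gx > params$contrast_threshold)
  # a transition is a sign ALTERNATION between consecutive strong gradients
  # along a row (dark->bright followed by bright->dark and vice versa); a
  # lone edge pair, e.g. a single plant stem, contributes only one
  edge <- matrix(0, H, W)
  for (r in seq_len(H)) {
    srow <- s[r, ]
    nz <- which(srow != 0)
    if (length(nz) < 2) next
    alt <- nz[-1][srow[nz][-1] != srow[nz][-length(nz)]]
    edge[r, alt] <- 1
  }

  win_w <- max(3L, as.integer(round(params$window_width_in * dpi)))
  win_h <- max(3L, as.integer(round(params$window_height_in * dpi)))
  dens <- box_density(edge, win_h, win_w)
  mask <- dens > params$density_threshold
  if (!any(mask)) return(empty)

  r <- max(1L, as.integer(round(params$merge_radius_in * dpi)))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  closed <- EBImage::closing(mask * 1, brush)
  lab <- EBImage::bwlabel(closed)
  nlab <- max(lab)
  if (nlab == 0) return(empty)

  min_dim <- as.integer(round(params$min_text_height_in * dpi))
  gxf <- cbind(gx, 0)
  rows <- lapply(seq_len(nlab), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
    if (min(w, h) < min_dim) return(NULL)
    tibble::tibble(x = x0 - 1L, y = y0 - 1L, width = w, height = h,
      contrast = mean(gxf[y0:y1, x0:x1]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out <- out[order(out$y, out$x), ]
  validate_regions(out, H, W)
  out
}
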