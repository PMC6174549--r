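# Scale localization by normalized cross-correlation (NCC) template matching,
# and DPI derivation from the matched scale. The NCC numerator is computed in
# the frequency domain (one image FFT shared across all template
# magnifications); window means and variances come from integral images, the
# standard fast-NCC decomposition.

#' Describe a Scale Reference Image (SRI)
#'
#' An SRI is an image of the physical scale mounted on specimen sheets,
#' captured at a known resolution. Its physical length (pixel width divided by
#' resolution, in inches) anchors the DPI computation.
#'
#' @param image Grayscale matrix `[y, x]` of the scale template, values in
#'   `[0, 1]`.
#' @param resolution Resolution of the SRI in dots per inch (> 0).
#' @return A `scale_reference` object with fields `image`, `resolution` and
#'   `pixel_size` (width, height).
#' @export
scale_reference <- function(image, resolution) {
  if (!is.matrix(image) || !is.numeric(image) || any(dim(image) < 2)) {
    rlang::abort("SRI image must be a numeric matrix of at least 2x2 pixels",
      class = "herbsheet_invalid_input")
  }
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0) {
    rlang::abort("SRI resolution must be a single positive number (dpi)",
      class = "herbsheet_invalid_input")
  }
  structure(
    list(image = image, resolution = as.double(resolution),
      pixel_size = c(width = ncol(image), height = nrow(image))),
    class = "scale_reference")
}

#' @export
print.scale_reference <- function(x, ...) {
  cat("<scale_reference> ", x$pixel_size[["width"]], "x", x$pixel_size[["height"]],
    " px at ", x$resolution, " dpi (",
    format(x$pixel_size[["width"]] / x$resolution, digits = 4), " in wide)\n", sep = "")
  invisible(x)
}

#' Default magnification search grid
#'
#' Geometric grid used by [match_scale()] when the specimen's resolution is
#' unknown: `min` to `max` with successive ratio `ratio`.
#'
#' @param min,max Grid bounds (linear magnification of the template).
#' @param ratio Successive ratio between grid points.
#' @return Numeric vector of magnifications.
#' @export
default_magnifications <- function(min = 0.5, max = 2, ratio = 2^0.25) {
  n_lo <- round(log(min) / log(ratio))
  n_hi <- round(log(max) / log(ratio))
  ratio^(seq(n_lo, n_hi))
}

# Nearest-neighbour rescale of a [y, x] matrix by a linear factor. Shared by
# the synthetic generator and the matcher so that exact-magnification pastes
# are recovered exactly.
rescale_raster <- function(m, factor) {
  if (factor == 1) return(m)
  nh <- max(1L, as.integer(round(nrow(m) * factor)))
  nw <- max(1L, as.integer(round(ncol(m) * factor)))
  yi <- pmin(nrow(m), floor((seq_len(nh) - 0.5) * nrow(m) / nh) + 1)
  xi <- pmin(ncol(m), floor((seq_len(nw) - 0.5) * ncol(m) / nw) + 1)
  m[yi, xi, drop = FALSE]
}

# Smallest 5-smooth integer >= n (keeps FFT sizes fast).
next_fast_size <- function(n) {
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

# Windowed sums of `m` over ht x wt windows at every valid position, via
# padded cumulative sums. Returns an (H-ht+1) x (W-wt+1) matrix.
window_sums <- function(m, ht, wt) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # cs[x, y] after second apply
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))                 # (H+1) x (W+1), cs[y+1, x+1] = sum up to (y, x)
  H <- nrow(m); W <- ncol(m)
  ys <- 1:(H - ht + 1); xs <- 1:(W - wt + 1)
  cs[ys + ht, xs + wt, drop = FALSE] - cs[ys, xs + wt, drop = FALSE] -
    cs[ys + ht, xs, drop = FALSE] + cs[ys, xs, drop = FALSE]
}

# Zero-mean NCC of `template` against every valid window of `image`.
# `image_fft` may carry a precomputed FFT of the zero-padded image.
ncc_valid <- function(image, template, image_fft = NULL, pad = NULL) {
  H <- nrow(image); W <- ncol(image)
  ht <- nrow(template); wt <- ncol(template)
  t0 <- template - mean(template)
  denom_t <- sqrt(sum(t0^2))
  nh <- H - ht + 1; nw <- W - wt + 1
  if (denom_t < 1e-12) return(matrix(0, nh, nw))
  if (is.null(pad)) pad <- c(next_fast_size(H), next_fast_size(W))
  if (is.null(image_fft)) {
    ip <- matrix(0, pad[1], pad[2]); ip[1:H, 1:W] <- image
    image_fft <- stats::fft(ip)
  }
  tp <- matrix(0, pad[1], pad[2]); tp[1:ht, 1:wt] <- t0
  corr <- Re(stats::fft(image_fft * Conj(stats::fft(tp)), inverse = TRUE)) /
    (pad[1] * pad[2])
  corr <- corr[1:nh, 1:nw, drop = FALSE]
  n <- ht * wt
  s1 <- window_sums(image, ht, wt)
  s2 <- window_sums(image^2, ht, wt)
  var_win <- pmax(s2 - s1^2 / n, 0)
  denom <- sqrt(var_win) * denom_t
  score <- corr / pmax(denom, 1e-12)
  score[denom < 1e-9] <- 0
  pmin(pmax(score, -1), 1)
}

#' Locate the scale on a specimen image by template matching
#'
#' Rescales the SRI over a magnification grid, slides each rescaled template
#' over the image and returns the position and magnification maximizing the
#' zero-mean normalized cross-correlation. Ties (within 1e-9) are broken by
#' the magnification closest to 1.0, then by the smallest (y, x). A best
#' score below `accept_threshold` is returned flagged, not raised: downstream
#' DPI is then marked low-confidence.
#'
#' @param image Grayscale specimen matrix `[y, x]`.
#' @param sri A [scale_reference()].
#' @param search Magnifications to try (default [default_magnifications()]).
#' @param accept_threshold NCC score below which the match is flagged.
#' @return A one-row tibble: `x`, `y`, `width`, `height` (matched region),
#'   `score`, `magnification`, `flagged`.
#' @export
match_scale <- function(image, sri, search = default_magnifications(),
                        accept_threshold = 0.6) {
  stopifnot(inherits(sri, "scale_reference"))
  if (length(search) == 0) {
    rlang::abort("magnification search list is empty", class = "herbsheet_invalid_input")
  }
  # try magnifications nearest 1.0 first so the tie-break is a simple "keep first"
  search <- search[order(abs(log(search)), search)]
  H <- nrow(image); W <- ncol(image)
  pad <- c(next_fast_size(H), next_fast_size(W))
  image_fft <- NULL
  best <- NULL
  for (mag in search) {
    templ <- rescale_raster(sri$image, mag)
    if (nrow(templ) > H || ncol(templ) > W) next
    if (is.null(image_fft)) {
      ip <- matrix(0, pad[1], pad[2]); ip[1:H, 1:W] <- image
      image_fft <- stats::fft(ip)
    }
    sc <- ncc_valid(image, templ, image_fft = image_fft, pad = pad)
    smax <- max(sc)
    hits <- which(sc >= smax - 1e-9, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    cand <- list(score = smax, y = hits[1, 1] - 1L, x = hits[1, 2] - 1L,
      width = ncol(templ), height = nrow(templ), magnification = mag)
    if (is.null(best) || cand$score > best$score + 1e-9) best <- cand
  }
  if (is.null(best)) {
    rlang::abort("image is smaller than the scale template at every searched magnification",
      class = "herbsheet_no_match")
  }
  tibble::tibble(
    x = as.integer(best$x), y = as.integer(best$y),
    width = as.integer(best$width), height = as.integer(best$height),
    score = best$score, magnification = best$magnification,
    flagged = best$score < accept_threshold)
}

#' Compute image DPI from a matched scale
#'
#' The physical length of the scale is `sri$pixel_size["width"] /
#' sri$resolution` inches; the specimen's DPI is the matched pixel width
#' divided by that length, i.e. `match$width * sri$resolution /
#' sri$pixel_size["width"]`. Exactly linear in the matched width.
#'
#' @param match One-row match tibble from [match_scale()] (any data frame
#'   with a positive `width` works).
#' @param sri A [scale_reference()].
#' @return DPI as a positive double.
#' @export
compute_dpi <- function(match, sri) {
  stopifnot(inherits(sri, "scale_reference"))
  w <- match$width
  if (!is.numeric(w) || length(w) != 1 || is.na(w) || w <= 0) {
    rlang::abort("matched scale width must be a single positive number",
      class = "herbsheet_invalid_input")
  }
  if (sri$resolution <= 0 || sri$pixel_size[["width"]] <= 0) {
    rlang::abort("SRI resolution and pixel width must be positive",
      class = "herbsheet_invalid_input")
  }
  as.double(w) * sri$resolution / sri$pixel_size[["width"]]
}
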