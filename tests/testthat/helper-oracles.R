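# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (exhaustive loops) and never share code with the
# implementation they check.

fixture_resources <- function(match_tolerance = 1) {
  load_resources(match_tolerance = match_tolerance)
}

tiny_sri <- function() {
  make_synthetic_sri(resolution = 100, width_in = 0.6, height_in = 0.2)
}

# Exhaustive sliding-window zero-mean normalized cross-correlation.
ncc_brute <- function(image, template) {
  ht <- nrow(template); wt <- ncol(template)
  t0 <- template - mean(template)
  dt <- sqrt(sum(t0^2))
  nh <- nrow(image) - ht + 1; nw <- ncol(image) - wt + 1
  out <- matrix(0, nh, nw)
  for (u in seq_len(nh)) {
    for (v in seq_len(nw)) {
      win <- image[u:(u + ht - 1), v:(v + wt - 1)]
      w0 <- win - mean(win)
      den <- sqrt(sum(w0^2)) * dt
      out[u, v] <- if (den < 1e-9) 0 else sum(w0 * t0) / den
    }
  }
  out
}

# Brute-force token-window scan: every window of `width` consecutive tokens
# compared against dictionary entries at the given per-token edit tolerance.
brute_dict_windows <- function(text, entries, tolerance) {
  m <- gregexpr("[[:alnum:]][[:alnum:]'-]*\\.?", text)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer(), entry = character()))
  toks <- regmatches(text, list(m))[[1]]
  starts <- as.integer(m) - 1
  ends <- starts + attr(m, "match.length")
  hits <- list()
  for (e in entries) {
    et <- strsplit(e, " ", fixed = TRUE)[[1]]
    k <- length(et)
    if (length(toks) < k) next
    for (i in seq_len(length(toks) - k + 1)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        tok <- sub("\\.$", "", toks[i + j - 1])
        tol <- if (nchar(et[j]) >= 5) tolerance else 0
        if (utils::adist(tolower(tok), tolower(et[j])) > tol) { ok <- FALSE; break }
      }
      if (ok) {
        hits[[length(hits) + 1]] <- data.frame(
          start = starts[i], end = ends[i + k - 1], entry = e)
      }
    }
  }
  if (length(hits) == 0) return(data.frame(start = integer(), end = integer(), entry = character()))
  do.call(rbind, hits)
}

write_dict_file <- function(entries, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("dict-", tmpdir = dir, fileext = ".txt")
  writeLines(entries, path)
  path
}

# Small deterministic sheet-like test image: one rendered text block pasted
# on a uniform background at a known box. Returns image plus the text box.
plain_text_image <- function(lines, H = 400, W = 600, at = c(80, 120),
                             scale = 3, shade = 0.82) {
  img <- matrix(shade, H, W)
  block <- herbsheet:::render_text_block(lines, scale)
  bh <- nrow(block); bw <- ncol(block)
  y0 <- at[1]; x0 <- at[2]
  pad <- 10
  img[(y0 - pad):(y0 + bh + pad - 1), (x0 - pad):(x0 + bw + pad - 1)] <- 1
  img[y0:(y0 + bh - 1), x0:(x0 + bw - 1)] <- 1 - 0.92 * block
  list(image = img,
    box = region(x0 - 1 - pad, y0 - 1 - pad, bw + 2 * pad, bh + 2 * pad))
}

best_iou <- function(box, regions) {
  if (nrow(regions) == 0) return(0)
  max(vapply(seq_len(nrow(regions)), function(j) region_iou(box, regions[j, ]), numeric(1)))
}
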