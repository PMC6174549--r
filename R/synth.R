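# Synthetic herbarium sheets with complete ground truth: a light paper
# background, dark plant-like clutter strokes, printed-text labels whose text
# comes from a grammar covering all supported entity formats, and the scale
# reference image pasted at a known position and magnification. Every
# generated artifact is reproducible from its seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% 2147483647L)
  force(code)
}

#' Synthetic sheet specification
#'
#' @param canvas_width,canvas_height Sheet size in pixels.
#' @param background_shade Paper gray level in `[0, 1]`.
#' @param n_labels Number of printed labels to plant.
#' @param label_font_height_in Physical glyph height of label text, in
#'   inches; rendered pixel size scales with the sheet's DPI like real
#'   printed labels do.
#' @param scale_magnification Linear magnification at which the scale
#'   reference image is pasted; the sheet's effective DPI is the SRI
#'   resolution times this factor.
#' @param clutter_density Amount of plant-like dark strokes in `[0, 1]`
#'   (about `100 * clutter_density` strokes).
#' @param seed Integer seed controlling every random choice.
#' @return A `sheet_spec` list.
#' @export
sheet_spec <- function(canvas_width = 1000, canvas_height = 1400,
                       background_shade = 0.82, n_labels = 2,
                       label_font_height_in = 0.08,
                       scale_magnification = 1.0,
                       clutter_density = 0.1, seed = 1) {
  stopifnot(canvas_width >= 100, canvas_height >= 100,
    background_shade >= 0, background_shade <= 1,
    n_labels >= 0, scale_magnification > 0,
    clutter_density >= 0, clutter_density <= 1)
  structure(list(canvas_width = as.integer(canvas_width),
    canvas_height = as.integer(canvas_height),
    background_shade = background_shade, n_labels = as.integer(n_labels),
    label_font_height_in = label_font_height_in,
    scale_magnification = scale_magnification,
    clutter_density = clutter_density, seed = as.integer(seed)),
    class = "sheet_spec")
}

#' Build a synthetic Scale Reference Image
#'
#' A schematic ruler: black frame, alternating tick marks every 0.1 inch and
#' an asymmetric solid triangle so the template has a single unambiguous
#' orientation and position.
#'
#' @param resolution Resolution of the SRI in dpi.
#' @param width_in,height_in Physical size in inches.
#' @return A [scale_reference()].
#' @export
make_synthetic_sri <- function(resolution = 300, width_in = 1.2, height_in = 0.25) {
  w <- round(width_in * resolution); h <- round(height_in * resolution)
  m <- matrix(1, h, w)
  b <- max(2L, round(h / 24))
  m[c(1:b, (h - b + 1):h), ] <- 0
  m[, c(1:b, (w - b + 1):w)] <- 0
  n_ticks <- floor(width_in / 0.1)
  for (i in seq_len(n_ticks)) {
    x <- round(i * 0.1 * resolution)
    if (x + 1 >= w) next
    tick_h <- if (i %% 2 == 0) round(h * 0.6) else round(h * 0.35)
    m[(h - tick_h):h, x:(x + 1)] <- 0
  }
  tri <- round(h * 0.55)
  for (dy in seq_len(tri)) {
    x1 <- b + 2; x2 <- min(w, b + 2 + round(dy * 0.8))
    m[b + 1 + dy, x1:x2] <- 0
  }
  scale_reference(m, resolution)
}

ROMAN_MONTHS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
  "X", "XI", "XII")
MONTH_NAMES <- c("January", "February", "March", "April", "May", "June",
  "July", "August", "September", "October", "November", "December")
AUTHOR_POOL <- c("L.", "Mill.", "Lam.", "DC.", "Benth.", "Willd.", "Hook.")

#' Generate one label text with its planted entities
#'
#' Samples a four-line label from a grammar covering all supported entity
#' formats: a scientific name with an author token, a collector line
#' (`leg.` + initials + surname), a locality line (gazetteer place,
#' optionally followed by a coordinate pair in one of four formats) and a
#' date line (optionally prefixed by a collection/determination/accession
#' cue) in one of five date formats. Returns the text and the exact entity
#' payloads a perfect extraction would produce, with offsets into the text
#' (0-based, half-open).
#'
#' @param seed Integer seed.
#' @param resources A [load_resources()] bundle.
#' @return A list with elements `text` and `entities` (an [entity_tibble()]).
#' @export
generate_label_text <- function(seed, resources) {
  with_seed(seed, {
    binomials <- resources$names$entries[grepl(" ", resources$names$entries)]
    name <- sample(binomials, 1)
    name_tok <- strsplit(name, " ", fixed = TRUE)[[1]]
    author <- sample(AUTHOR_POOL, 1)
    surname <- sample(resources$botanists$entries, 1)
    ini <- paste0(sample(setdiff(LETTERS, c("N", "S", "E", "W")), 1), ".")
    place_i <- sample(nrow(resources$gazetteer), 1)
    place <- resources$gazetteer$place_name[place_i]
    country <- resources$gazetteer$country[place_i]

    line1 <- paste(name, author)
    line2 <- paste("leg.", ini, surname)

    with_coords <- stats::runif(1) < 0.5
    coord <- NULL
    line3 <- place
    if (with_coords) {
      fmt <- sample(c("dms", "dms_sec", "ddm", "dec", "signed"), 1)
      dlat <- sample(0:89, 1); mlat <- sample(0:59, 1); slat <- sample(0:59, 1)
      dlon <- sample(0:179, 1); mlon <- sample(0:59, 1); slon <- sample(0:59, 1)
      hlat <- sample(c("N", "S"), 1); hlon <- sample(c("E", "W"), 1)
      sg_lat <- if (hlat == "S") -1 else 1
      sg_lon <- if (hlon == "W") -1 else 1
      if (fmt == "dms") {
        cstr <- sprintf("%d°%d'%s, %d°%d'%s", dlat, mlat, hlat, dlon, mlon, hlon)
        lat <- sg_lat * (dlat + mlat / 60); lon <- sg_lon * (dlon + mlon / 60)
      } else if (fmt == "dms_sec") {
        cstr <- sprintf("%d°%d'%d\"%s, %d°%d'%d\"%s",
          dlat, mlat, slat, hlat, dlon, mlon, slon, hlon)
        lat <- sg_lat * (dlat + mlat / 60 + slat / 3600)
        lon <- sg_lon * (dlon + mlon / 60 + slon / 3600)
      } else if (fmt == "ddm") {
        ml <- sprintf("%.1f", stats::runif(1, 0, 59.9))
        mo <- sprintf("%.1f", stats::runif(1, 0, 59.9))
        cstr <- sprintf("%d°%s'%s, %d°%s'%s", dlat, ml, hlat, dlon, mo, hlon)
        lat <- sg_lat * (dlat + as.numeric(ml) / 60)
        lon <- sg_lon * (dlon + as.numeric(mo) / 60)
      } else if (fmt == "dec") {
        la <- sprintf("%.2f", stats::runif(1, 0, 89.99))
        lo <- sprintf("%.2f", stats::runif(1, 0, 179.99))
        cstr <- sprintf("%s %s, %s %s", la, hlat, lo, hlon)
        lat <- sg_lat * as.numeric(la); lon <- sg_lon * as.numeric(lo)
      } else {
        la <- sprintf("-%.2f", stats::runif(1, 0.01, 89.99))
        lo <- sprintf("-%.2f", stats::runif(1, 0.01, 179.99))
        cstr <- sprintf("%s %s", la, lo)
        lat <- as.numeric(la); lon <- as.numeric(lo)
      }
      coord <- list(str = cstr, lat = lat, lon = lon)
    }

    dfmt <- sample(c("dmy", "roman", "iso", "textual", "year"), 1)
    d <- sample(1:28, 1); mo <- sample(1:12, 1); y <- sample(1880:2010, 1)
    dstr <- switch(dfmt,
      dmy = sprintf("%d.%d.%d", d, mo, y),
      roman = sprintf("%d.%s.%d", d, ROMAN_MONTHS[mo], y),
      iso = sprintf("%04d-%02d-%02d", y, mo, d),
      textual = sprintf("%d %s %d", d, MONTH_NAMES[mo], y),
      year = sprintf("%d", y))
    iso <- if (dfmt == "year") sprintf("%04d", y) else sprintf("%04d-%02d-%02d", y, mo, d)
    cue <- sample(c("leg.", "det.", "acc.", ""), 1)
    kind <- switch(cue, "leg." = "collection", "det." = "determination",
      "acc." = "accession", "unspecified")
    date_line <- if (nzchar(cue)) paste(cue, dstr) else dstr

    # one entity per label line, so no line runs much wider than the rest
    lines <- c(line1, line2, line3)
    if (!is.null(coord)) lines <- c(lines, coord$str)
    lines <- c(lines, date_line)
    text <- paste(lines, collapse = "\n")
    off <- cumsum(c(0, nchar(lines) + 1))  # 0-based start of each line
    date_off <- off[length(lines)]

    ents <- list(
      entity_tibble(category = "scientific_name", surface = name,
        start = off[1], end = off[1] + nchar(name),
        genus = name_tok[1], epithet = name_tok[2], author = author,
        matched_entry = name),
      entity_tibble(category = "botanist",
        surface = paste(ini, surname),
        start = off[2] + 5L, end = off[2] + nchar(line2),
        surname = surname, initials = ini, role = "collector",
        matched_entry = surname),
      entity_tibble(category = "location", surface = place,
        start = off[3], end = off[3] + nchar(place),
        place_name = place, country = country),
      entity_tibble(category = "date", surface = dstr,
        start = date_off + if (nzchar(cue)) nchar(cue) + 1L else 0L,
        end = date_off + nchar(date_line),
        iso_date = iso, date_kind = kind)
    )
    if (!is.null(coord)) {
      ents[[length(ents) + 1]] <- entity_tibble(category = "coordinate",
        surface = coord$str, start = off[4], end = off[4] + nchar(coord$str),
        latitude = coord$lat, longitude = coord$lon)
    }
    list(text = text, entities = sort_entities(dplyr::bind_rows(ents)))
  })
}

# Place `sizes` (list of c(h, w)) into an H x W canvas without overlap,
# keeping `sep` pixels between boxes and `border` from the canvas edge.
place_boxes <- function(sizes, H, W, sep, border = 10, tries = 500) {
  placed <- list()
  for (i in seq_along(sizes)) {
    h <- sizes[[i]][1]; w <- sizes[[i]][2]
    ok <- FALSE
    for (t in seq_len(tries)) {
      if (W - w - 2 * border < 1 || H - h - 2 * border < 1) break
      x <- border + sample.int(W - w - 2 * border, 1) - 1
      y <- border + sample.int(H - h - 2 * border, 1) - 1
      cand <- list(x = x, y = y, width = w, height = h)
      clash <- any(vapply(placed, function(p) {
        regions_intersect(
          list(x = cand$x - sep, y = cand$y - sep,
            width = cand$width + 2 * sep, height = cand$height + 2 * sep), p)
      }, logical(1)))
      if (!clash) { placed[[i]] <- cand; ok <- TRUE; break }
    }
    if (!ok) {
      rlang::abort("could not place labels and scale without overlap at the requested sizes",
        class = "herbsheet_placement_error")
    }
  }
  placed
}

#' Generate a synthetic herbarium sheet with ground truth
#'
#' Renders the paper background, seeded clutter strokes (kept clear of
#' labels and scale), `n_labels` printed labels from [generate_label_text()]
#' and the SRI pasted at `scale_magnification`, recording everything in a
#' `sheet_truth` object. If `dir` is given, writes `<stem>.png` and a
#' ground-truth sidecar `<stem>.truth.json` consumable by
#' [make_fixture_engine()].
#'
#' @param spec A [sheet_spec()].
#' @param sri A [scale_reference()].
#' @param resources A [load_resources()] bundle.
#' @param dir Optional output directory.
#' @param stem File stem (default `sheet-<seed>`).
#' @return A `herb_sheet` list: `image` (matrix), `truth` (`sheet_truth`),
#'   `guid`, and — when written — `image_path` and `truth_path`.
#' @export
generate_sheet <- function(spec, sri, resources, dir = NULL,
                           stem = sprintf("sheet-%06d", spec$seed)) {
  stopifnot(inherits(spec, "sheet_spec"), inherits(sri, "scale_reference"))
  dpi <- sri$resolution * spec$scale_magnification
  H <- spec$canvas_height; W <- spec$canvas_width
  scale_img <- rescale_raster(sri$image, spec$scale_magnification)
  if (nrow(scale_img) + 20 > H || ncol(scale_img) + 20 > W) {
    rlang::abort("SRI does not fit the canvas at the requested magnification",
      class = "herbsheet_placement_error")
  }
  font_scale <- max(1L, as.integer(round(spec$label_font_height_in * dpi / 8)))
  margin <- max(4L, as.integer(round(0.04 * dpi)))

  labels <- lapply(seq_len(spec$n_labels), function(i) {
    lt <- generate_label_text((spec$seed * 131L + i * 17L) %% 2147483647L, resources)
    block <- render_text_block(strsplit(lt$text, "\n", fixed = TRUE)[[1]], font_scale)
    c(lt, list(block = block))
  })

  with_seed(spec$seed, {
    canvas <- matrix(spec$background_shade, H, W)
    sizes <- c(list(dim(scale_img)),
      lapply(labels, function(l) dim(l$block) + 2 * margin))
    sep <- max(40L, as.integer(round(0.25 * dpi)))
    placed <- place_boxes(sizes, H, W, sep = sep)

    # clutter: dark plant-like strokes, clipped away from labels and scale
    protected <- matrix(FALSE, H, W)
    buffer <- max(10L, as.integer(round(0.12 * dpi)))
    for (p in placed) {
      y0 <- max(1, p$y - buffer + 1); y1 <- min(H, p$y + p$height + buffer)
      x0 <- max(1, p$x - buffer + 1); x1 <- min(W, p$x + p$width + buffer)
      protected[y0:y1, x0:x1] <- TRUE
    }
    # gently curved continuous arcs, like stems and twigs: unit steps along
    # the path so strokes never rasterize as dashes (dashes would mimic the
    # rapid dark/bright alternation of text)
    n_strokes <- round(spec$clutter_density * 100)
    for (s in seq_len(n_strokes)) {
      yy <- stats::runif(1, 1, H); xx <- stats::runif(1, 1, W)
      theta <- stats::runif(1, 0, 2 * pi)
      kappa <- stats::runif(1, -0.002, 0.002)
      n_steps <- round(stats::runif(1, 0.3, 0.9) * H)
      shade <- stats::runif(1, 0.15, 0.45)
      r <- sample(1:3, 1)
      for (k in seq_len(n_steps)) {
        yy <- yy + sin(theta); xx <- xx + cos(theta); theta <- theta + kappa
        yi <- round(yy); xi <- round(xx)
        if (yi < 1 || yi > H || xi < 1 || xi > W) break
        ys <- max(1, yi - r):min(H, yi + r)
        xs <- max(1, xi - r):min(W, xi + r)
        if (!any(protected[ys, xs])) canvas[ys, xs] <- shade
      }
    }

    # paste labels and scale
    scale_pos <- placed[[1]]
    canvas[(scale_pos$y + 1):(scale_pos$y + scale_pos$height),
           (scale_pos$x + 1):(scale_pos$x + scale_pos$width)] <- scale_img
    label_boxes <- list()
    for (i in seq_along(labels)) {
      p <- placed[[i + 1]]
      lab_img <- matrix(1, p$height, p$width)
      bh <- nrow(labels[[i]]$block); bw <- ncol(labels[[i]]$block)
      lab_img[(margin + 1):(margin + bh), (margin + 1):(margin + bw)] <-
        1 - 0.92 * labels[[i]]$block
      canvas[(p$y + 1):(p$y + p$height), (p$x + 1):(p$x + p$width)] <- lab_img
      label_boxes[[i]] <- region(p$x, p$y, p$width, p$height)
    }

    planted <- dplyr::bind_rows(lapply(seq_along(labels), function(i) {
      e <- labels[[i]]$entities
      if (nrow(e) > 0) e$region_index <- i
      e
    }))
    if (is.null(planted) || nrow(planted) == 0) planted <- entity_tibble()

    truth <- structure(list(
      scale_region = region(scale_pos$x, scale_pos$y, scale_pos$width, scale_pos$height),
      magnification = spec$scale_magnification,
      dpi = dpi,
      label_boxes = if (length(label_boxes)) dplyr::bind_rows(label_boxes) else region(integer(), integer(), integer(), integer()),
      label_texts = vapply(labels, function(l) l$text, character(1)),
      planted_entities = planted,
      seed = spec$seed
    ), class = "sheet_truth")

    out <- list(image = canvas, truth = truth,
      guid = paste0("urn:herbsheet:", stem))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$image_path <- file.path(dir, paste0(stem, ".png"))
      out$truth_path <- file.path(dir, paste0(stem, ".truth.json"))
      write_sheet_image(canvas, out$image_path)
      write_sheet_truth(truth, out$truth_path)
    }
    structure(out, class = "herb_sheet")
  })
}

#' Write / read a ground-truth sidecar file
#'
#' @param truth A `sheet_truth` object.
#' @param path Sidecar path (conventionally `<image stem>.truth.json`).
#' @return `write_sheet_truth` returns `path` invisibly; `read_sheet_truth`
#'   the parsed `sheet_truth`.
#' @export
write_sheet_truth <- function(truth, path) {
  doc <- list(
    scale_region = as.list(truth$scale_region),
    magnification = truth$magnification,
    dpi = truth$dpi,
    label_boxes = lapply(seq_len(nrow(truth$label_boxes)), function(i)
      as.list(truth$label_boxes[i, ])),
    label_texts = as.list(truth$label_texts),
    planted_entities = lapply(seq_len(nrow(truth$planted_entities)), function(i)
      entity_row_to_list(truth$planted_entities[i, ])),
    seed = truth$seed
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))),
    con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sheet_truth
#' @export
read_sheet_truth <- function(path) {
  doc <- jsonlite::fromJSON(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
    collapse = "\n"), simplifyVector = FALSE)
  boxes <- if (length(doc$label_boxes) == 0) {
    region(integer(), integer(), integer(), integer())
  } else {
    dplyr::bind_rows(lapply(doc$label_boxes, function(b)
      region(b$x, b$y, b$width, b$height)))
  }
  planted <- if (length(doc$planted_entities) == 0) entity_tibble() else {
    dplyr::bind_rows(lapply(doc$planted_entities, function(r) {
      do.call(entity_tibble, r[intersect(names(r), names(entity_cols()))])
    }))
  }
  structure(list(
    scale_region = region(doc$scale_region$x, doc$scale_region$y,
      doc$scale_region$width, doc$scale_region$height),
    magnification = doc$magnification, dpi = doc$dpi,
    label_boxes = boxes,
    label_texts = vapply(doc$label_texts, identity, character(1)),
    planted_entities = planted, seed = doc$seed
  ), class = "sheet_truth")
}

#' Generate a batch of synthetic sheets with a manifest
#'
#' @param n Number of sheets.
#' @param out_dir Output directory (PNG + truth sidecar per sheet, plus
#'   `manifest.json`).
#' @param seed Base seed; sheet i uses `seed + i - 1`.
#' @param sri A [scale_reference()] (default [make_synthetic_sri()]).
#' @param resources A [load_resources()] bundle (default bundled fixtures).
#' @param n_labels Labels per sheet: a single value or one per sheet.
#' @param magnification Scale magnification: a single value or one per sheet.
#' @param clutter_density Clutter level, recycled likewise.
#' @return A tibble manifest (guid, paths, seed, magnification, n_labels).
#' @export
synth_sheets <- function(n, out_dir, seed = 1, sri = make_synthetic_sri(),
                         resources = load_resources(), n_labels = 2,
                         magnification = 1.0, clutter_density = 0.1) {
  n_labels <- rep(n_labels, length.out = n)
  magnification <- rep(magnification, length.out = n)
  clutter_density <- rep(clutter_density, length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    spec <- sheet_spec(n_labels = n_labels[i], scale_magnification = magnification[i],
      clutter_density = clutter_density[i], seed = seed + i - 1)
    sh <- generate_sheet(spec, sri, resources, dir = out_dir)
    tibble::tibble(guid = sh$guid, image = sh$image_path, truth = sh$truth_path,
      seed = spec$seed, magnification = magnification[i], n_labels = n_labels[i])
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}
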