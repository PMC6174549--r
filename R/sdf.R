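# Specimen Description File (SDF): the single accumulating record that all
# workflow stages read and write. An SDF is a nested document (serialized as
# one JSON file per specimen), not a table; tidy()/glance() methods give the
# tabular views.

SDF_SCHEMA_VERSION <- "1.0"

# The nine services and which SDF field each one fills.
SERVICE_FIELDS <- c(
  scale_matching_service = "scale_region",
  dpi_service = "dpi",
  text_region_service = "text_regions",
  ocr_service = "texts",
  scientific_name_extractor = "scientific_name",
  botanist_name_extractor = "botanist",
  date_extractor = "date",
  geocoord_extractor = "coordinate",
  location_extractor = "location"
)

EXTRACTOR_SERVICES <- c(
  scientific_name = "scientific_name_extractor",
  botanist = "botanist_name_extractor",
  date = "date_extractor",
  coordinate = "geocoord_extractor",
  location = "location_extractor"
)

#' Reference a specimen image by GUID
#'
#' @param guid Non-empty globally unique identifier (URI string) for the
#'   specimen.
#' @param image_uri URI or filesystem path of the specimen image.
#' @return A `specimen_ref` object.
#' @export
#' @examples
#' specimen_ref("urn:herbsheet:sheet-0001", "sheet-0001.png")
specimen_ref <- function(guid, image_uri) {
  if (!is.character(guid) || length(guid) != 1 || is.na(guid) || !nzchar(guid)) {
    rlang::abort("specimen guid must be a non-empty string",
      class = "herbsheet_invalid_identifier")
  }
  structure(list(guid = guid, image_uri = as.character(image_uri)),
    class = "specimen_ref")
}

#' Create an empty Specimen Description File
#'
#' Initializes the per-specimen record with the given reference, no results
#' and an empty provenance history. Workflow stages add their output through
#' [record_result()].
#'
#' @param specimen A [specimen_ref()].
#' @return An object of class `sdf`.
#' @export
create_sdf <- function(specimen) {
  if (!inherits(specimen, "specimen_ref")) {
    specimen <- specimen_ref(specimen$guid, specimen$image_uri)
  }
  structure(
    list(
      specimen = specimen,
      scale_region = NULL,
      dpi = NULL,
      dpi_flagged = NULL,
      text_regions = NULL,
      texts = NULL,
      entities = list(),
      history = list()
    ),
    class = "sdf"
  )
}

#' @export
print.sdf <- function(x, ...) {
  cat("<sdf> ", x$specimen$guid, "\n", sep = "")
  cat("  image:       ", x$specimen$image_uri, "\n", sep = "")
  cat("  dpi:         ", if (is.null(x$dpi)) "<unset>" else
    paste0(format(x$dpi), if (isTRUE(x$dpi_flagged)) " (low confidence)" else ""), "\n", sep = "")
  cat("  text regions:", if (is.null(x$text_regions)) "<unset>" else nrow(x$text_regions), "\n")
  cat("  texts:       ", if (is.null(x$texts)) "<unset>" else nrow(x$texts), "\n")
  n_ent <- sum(vapply(x$entities, nrow, integer(1)))
  cat("  entities:    ", if (length(x$entities) == 0) "<unset>" else n_ent, "\n")
  cat("  history:     ", length(x$history), " service call(s)\n", sep = "")
  invisible(x)
}

validate_service_payload <- function(service_name, payload) {
  fail <- function(msg) rlang::abort(
    paste0("payload for service '", service_name, "' violates its contract: ", msg),
    class = "herbsheet_contract_error")
  switch(service_name,
    scale_matching_service = {
      if (!is.data.frame(payload) || nrow(payload) != 1) fail("expected a one-row match table")
      need <- c("x", "y", "width", "height", "score", "magnification", "flagged")
      if (!all(need %in% names(payload))) fail(paste0("missing column(s): ",
        paste(setdiff(need, names(payload)), collapse = ", ")))
      validate_regions(payload)
      if (abs(payload$score) > 1 + 1e-9) fail("score outside [-1, 1]")
      if (payload$magnification <= 0) fail("magnification must be positive")
    },
    dpi_service = {
      dpi <- if (is.list(payload) && !is.data.frame(payload)) payload$dpi else payload
      if (!is.numeric(dpi) || length(dpi) != 1 || is.na(dpi) || dpi <= 0) {
        fail("dpi must be a single positive number")
      }
    },
    text_region_service = {
      if (!is.data.frame(payload)) fail("expected a region table")
      validate_regions(payload)
    },
    ocr_service = {
      if (!is.data.frame(payload)) fail("expected a region-text table")
      need <- c("region_index", "x", "y", "width", "height", "text", "engine", "error")
      if (!all(need %in% names(payload))) fail(paste0("missing column(s): ",
        paste(setdiff(need, names(payload)), collapse = ", ")))
      if (nrow(payload) > 0) validate_regions(payload)
    },
    {
      cat <- names(EXTRACTOR_SERVICES)[match(service_name, EXTRACTOR_SERVICES)]
      if (!is.data.frame(payload) || !all(names(entity_cols()) %in% names(payload))) {
        fail("expected an entity mention table")
      }
      if (nrow(payload) > 0 && !all(payload$category == cat)) {
        fail(paste0("all mentions must have category '", cat, "'"))
      }
    }
  )
  invisible(TRUE)
}

#' Record a service result in an SDF
#'
#' Sets (or, on a re-run of the same service, replaces) the SDF field owned by
#' `service_name` and appends exactly one provenance entry. All previously
#' recorded fields are left untouched, so results accumulate monotonically.
#'
#' @param sdf An [create_sdf()] object.
#' @param service_name One of the nine registered service names (see
#'   [service_contracts()]).
#' @param payload The service output; its shape is checked against the
#'   service's declared contract.
#' @param parameters Named list of scalar parameters to log with the call.
#' @param timestamp ISO-8601 timestamp string for the provenance entry. The
#'   default is a fixed epoch string so that identical runs produce
#'   byte-identical SDF files; pass e.g.
#'   `format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")` for wall-clock
#'   provenance.
#' @return The updated `sdf` (value semantics; the input is not modified).
#' @export
record_result <- function(sdf, service_name, payload, parameters = list(),
                          timestamp = "1970-01-01T00:00:00Z") {
  stopifnot(inherits(sdf, "sdf"))
  if (!service_name %in% names(SERVICE_FIELDS)) {
    rlang::abort(paste0("unknown service: '", service_name, "'"),
      class = "herbsheet_unknown_service")
  }
  validate_service_payload(service_name, payload)
  field <- SERVICE_FIELDS[[service_name]]
  # image-derived floats are rounded to the SDF's serialized precision at
  # record time, so the in-memory record always equals its file form
  if (service_name == "scale_matching_service") {
    sr <- tibble::as_tibble(payload)
    sr$score <- num6(sr$score)
    sr$magnification <- num6(sr$magnification)
    sdf$scale_region <- sr
  } else if (service_name == "dpi_service") {
    if (is.list(payload) && !is.data.frame(payload)) {
      sdf$dpi <- num6(payload$dpi)
      sdf$dpi_flagged <- isTRUE(payload$flagged)
    } else {
      sdf$dpi <- num6(payload)
      sdf$dpi_flagged <- FALSE
    }
  } else if (service_name == "text_region_service") {
    tr <- tibble::as_tibble(payload)
    if (!"contrast" %in% names(tr)) tr$contrast <- rep(NA_real_, nrow(tr))
    tr$contrast <- num6(tr$contrast)
    sdf$text_regions <- tr[, c("x", "y", "width", "height", "contrast")]
  } else if (service_name == "ocr_service") {
    sdf$texts <- tibble::as_tibble(payload)
  } else {
    sdf$entities[[field]] <- tibble::as_tibble(payload)
    sdf$entities <- sdf$entities[order(names(sdf$entities))]
  }
  entry <- list(
    service_name = service_name,
    parameters = parameters,
    timestamp = timestamp,
    software_version = as.character(utils::packageVersion("herbsheet"))
  )
  sdf$history <- c(sdf$history, list(entry))
  sdf
}

# ---- canonical JSON serialization ------------------------------------------

num6 <- function(x) signif(as.double(x), 6)

# Recursively sort object keys so serialization is canonical.
canon_keys <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x) > 0) x <- x[order(names(x))]
    x <- lapply(x, canon_keys)
  }
  x
}

region_row_to_list <- function(row, extra = character()) {
  out <- list(x = as.integer(row$x), y = as.integer(row$y),
    width = as.integer(row$width), height = as.integer(row$height))
  for (nm in extra) {
    v <- row[[nm]]
    if (!is.na(v)) out[[nm]] <- if (is.numeric(v)) num6(v) else v
  }
  out
}

entity_row_to_list <- function(row) {
  out <- list(category = row$category, surface = row$surface,
    start = as.integer(row$start), end = as.integer(row$end))
  if (!is.na(row$region_index)) out$region_index <- as.integer(row$region_index)
  # coordinate payloads keep full double precision; rounding them would
  # break the deg + min/60 + sec/3600 identity downstream consumers check
  for (nm in setdiff(names(entity_cols()),
      c("category", "surface", "start", "end", "region_index"))) {
    v <- row[[nm]]
    if (!is.na(v)) out[[nm]] <- v
  }
  out
}

sdf_to_list <- function(sdf) {
  out <- list(schema_version = SDF_SCHEMA_VERSION,
    specimen = list(guid = sdf$specimen$guid, image_uri = sdf$specimen$image_uri))
  if (!is.null(sdf$scale_region)) {
    sr <- sdf$scale_region
    out$scale_region <- list(
      x = as.integer(sr$x), y = as.integer(sr$y),
      width = as.integer(sr$width), height = as.integer(sr$height),
      score = num6(sr$score), magnification = num6(sr$magnification),
      flagged = isTRUE(sr$flagged))
  }
  if (!is.null(sdf$dpi)) {
    out$dpi <- num6(sdf$dpi)
    out$dpi_flagged <- isTRUE(sdf$dpi_flagged)
  }
  if (!is.null(sdf$text_regions)) {
    out$text_regions <- lapply(seq_len(nrow(sdf$text_regions)), function(i) {
      region_row_to_list(sdf$text_regions[i, ], extra = "contrast")
    })
  }
  if (!is.null(sdf$texts)) {
    out$texts <- lapply(seq_len(nrow(sdf$texts)), function(i) {
      row <- sdf$texts[i, ]
      list(region_index = as.integer(row$region_index),
        x = as.integer(row$x), y = as.integer(row$y),
        width = as.integer(row$width), height = as.integer(row$height),
        text = row$text, engine = row$engine, error = isTRUE(row$error))
    })
  }
  if (length(sdf$entities) > 0) {
    out$entities <- lapply(sdf$entities, function(tb) {
      lapply(seq_len(nrow(tb)), function(i) entity_row_to_list(tb[i, ]))
    })
  } else {
    out$entities <- structure(list(), names = character(0))
  }
  out$history <- lapply(sdf$history, function(e) {
    pars <- e$parameters
    pars <- lapply(pars, function(v) if (is.numeric(v)) num6(v) else v)
    if (length(pars) == 0) pars <- structure(list(), names = character(0))
    list(service_name = e$service_name, parameters = pars,
      timestamp = e$timestamp, software_version = e$software_version)
  })
  canon_keys(out)
}

#' Serialize an SDF to canonical JSON
#'
#' One JSON document per specimen, UTF-8, schema-versioned, with sorted keys
#' and floats rendered at up to 6 significant digits, so that
#' serialize-parse-serialize is byte-stable.
#'
#' @param sdf An `sdf` object.
#' @return A single JSON string.
#' @export
sdf_to_json <- function(sdf) {
  as.character(jsonlite::toJSON(sdf_to_list(sdf), auto_unbox = TRUE,
    digits = NA, null = "null"))
}

#' Write / read an SDF file
#'
#' SDF files use the extension `.sdf.json`. `read_sdf(write_sdf(x, p))`
#' reproduces `x` field-for-field.
#'
#' @param sdf An `sdf` object.
#' @param path Destination (for `write_sdf`) or source (for `read_sdf`) file
#'   path.
#' @return `write_sdf` returns `path` invisibly; `read_sdf` returns the
#'   parsed `sdf`.
#' @export
write_sdf <- function(sdf, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(sdf_to_json(sdf)), con, useBytes = TRUE)
  invisible(path)
}

parse_fail <- function(field) {
  rlang::abort(paste0("malformed SDF document: missing or invalid field '", field, "'"),
    class = "herbsheet_parse_error")
}

#' @rdname write_sdf
#' @export
read_sdf <- function(path) {
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  sdf_from_json(txt)
}

#' @rdname sdf_to_json
#' @param json A JSON string produced by `sdf_to_json`.
#' @export
sdf_from_json <- function(json) {
  doc <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
    error = function(e) rlang::abort(paste0("malformed SDF document: ", conditionMessage(e)),
      class = "herbsheet_parse_error"))
  if (is.null(doc$schema_version)) parse_fail("schema_version")
  if (!identical(doc$schema_version, SDF_SCHEMA_VERSION)) {
    rlang::abort(paste0("unsupported SDF schema version: ", doc$schema_version),
      class = "herbsheet_version_error")
  }
  if (is.null(doc$specimen) || is.null(doc$specimen$guid) || !nzchar(doc$specimen$guid)) {
    parse_fail("guid")
  }
  sdf <- create_sdf(specimen_ref(doc$specimen$guid, doc$specimen$image_uri %||% ""))
  if (!is.null(doc$scale_region)) {
    sr <- doc$scale_region
    for (f in c("x", "y", "width", "height", "score", "magnification")) {
      if (is.null(sr[[f]])) parse_fail(paste0("scale_region.", f))
    }
    sdf$scale_region <- tibble::tibble(
      x = as.integer(sr$x), y = as.integer(sr$y),
      width = as.integer(sr$width), height = as.integer(sr$height),
      score = as.double(sr$score), magnification = as.double(sr$magnification),
      flagged = isTRUE(sr$flagged))
  }
  if (!is.null(doc$dpi)) {
    sdf$dpi <- as.double(doc$dpi)
    sdf$dpi_flagged <- isTRUE(doc$dpi_flagged)
  }
  if (!is.null(doc$text_regions)) {
    sdf$text_regions <- tibble::tibble(
      x = vapply(doc$text_regions, function(r) as.integer(r$x %||% parse_fail("text_regions.x")), integer(1)),
      y = vapply(doc$text_regions, function(r) as.integer(r$y), integer(1)),
      width = vapply(doc$text_regions, function(r) as.integer(r$width), integer(1)),
      height = vapply(doc$text_regions, function(r) as.integer(r$height), integer(1)),
      contrast = vapply(doc$text_regions, function(r) as.double(r$contrast %||% NA_real_), double(1)))
  }
  if (!is.null(doc$texts)) {
    sdf$texts <- tibble::tibble(
      region_index = vapply(doc$texts, function(r) as.integer(r$region_index), integer(1)),
      x = vapply(doc$texts, function(r) as.integer(r$x), integer(1)),
      y = vapply(doc$texts, function(r) as.integer(r$y), integer(1)),
      width = vapply(doc$texts, function(r) as.integer(r$width), integer(1)),
      height = vapply(doc$texts, function(r) as.integer(r$height), integer(1)),
      text = vapply(doc$texts, function(r) as.character(r$text %||% ""), character(1)),
      engine = vapply(doc$texts, function(r) as.character(r$engine %||% ""), character(1)),
      error = vapply(doc$texts, function(r) isTRUE(r$error), logical(1)))
  }
  if (!is.null(doc$entities) && length(doc$entities) > 0) {
    sdf$entities <- lapply(doc$entities, function(rows) {
      if (length(rows) == 0) return(entity_tibble())
      dplyr::bind_rows(lapply(rows, function(r) {
        args <- r[intersect(names(r), names(entity_cols()))]
        do.call(entity_tibble, args)
      }))
    })
    sdf$entities <- sdf$entities[order(names(sdf$entities))]
  }
  if (!is.null(doc$history)) {
    sdf$history <- lapply(doc$history, function(e) {
      if (is.null(e$service_name)) parse_fail("history.service_name")
      pars <- lapply(e$parameters, identity)
      if (length(pars) == 0) pars <- list()
      list(service_name = e$service_name,
        parameters = pars,
        timestamp = e$timestamp %||% "",
        software_version = e$software_version %||% "")
    })
  }
  sdf
}
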