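# The coordinator: an in-process service registry with contract checking at
# dispatch, plus the three documented workflows (pre-OCR, OCR, extraction)
# chained over batches of specimens. As long as a service's input and output
# contracts stay the same, its implementation can be swapped without touching
# the workflows.

#' Service contracts of the pipeline
#'
#' Returns the registry of the nine services with their input and output
#' contracts and the default implementation of each. Input contracts are
#' checked at dispatch; outputs are validated against the same payload
#' contracts [record_result()] enforces.
#'
#' @return A named list (class `service_registry`); one entry per service
#'   with elements `input_check` and `fn`.
#' @export
service_contracts <- function() {
  check_image <- function(input) {
    if (!is.matrix(input$image) || !is.numeric(input$image)) {
      stop("input 'image' must be a numeric matrix")
    }
  }
  check_text <- function(input) {
    if (!is.character(input$text) || length(input$text) != 1) {
      stop("input 'text' must be a single string")
    }
  }
  reg <- list(
    scale_matching_service = list(
      input_check = function(input) {
        check_image(input)
        if (!inherits(input$sri, "scale_reference")) stop("input 'sri' must be a scale_reference")
      },
      fn = function(input) match_scale(input$image, input$sri,
        search = input$search %||% default_magnifications(),
        accept_threshold = input$accept_threshold %||% 0.6)
    ),
    dpi_service = list(
      input_check = function(input) {
        if (!is.data.frame(input$match) || is.null(input$match$width)) {
          stop("input 'match' must be a scale-match table")
        }
        if (!inherits(input$sri, "scale_reference")) stop("input 'sri' must be a scale_reference")
      },
      fn = function(input) list(dpi = compute_dpi(input$match, input$sri),
        flagged = isTRUE(input$match$flagged))
    ),
    text_region_service = list(
      input_check = function(input) {
        check_image(input)
        if (!is.numeric(input$dpi) || length(input$dpi) != 1 || input$dpi <= 0) {
          stop("input 'dpi' must be a positive number")
        }
      },
      fn = function(input) detect_text_regions(input$image, input$dpi,
        input$params %||% text_detect_params())
    ),
    ocr_service = list(
      input_check = function(input) {
        check_image(input)
        if (!is.data.frame(input$regions)) stop("input 'regions' must be a region table")
        if (!inherits(input$engine, "ocr_engine")) stop("input 'engine' must be an ocr_engine")
      },
      fn = function(input) recognize_regions(input$regions, input$image, input$engine)
    ),
    scientific_name_extractor = list(
      input_check = function(input) {
        check_text(input)
        if (!inherits(input$resources$names, "herb_dictionary")) {
          stop("input 'resources$names' must be a dictionary")
        }
      },
      fn = function(input) extract_scientific_names(input$text, input$resources$names)
    ),
    botanist_name_extractor = list(
      input_check = function(input) {
        check_text(input)
        if (!inherits(input$resources$botanists, "herb_dictionary")) {
          stop("input 'resources$botanists' must be a dictionary")
        }
      },
      fn = function(input) extract_botanist_names(input$text, input$resources$botanists)
    ),
    date_extractor = list(
      input_check = check_text,
      fn = function(input) extract_dates(input$text)
    ),
    geocoord_extractor = list(
      input_check = check_text,
      fn = function(input) extract_geocoords(input$text)
    ),
    location_extractor = list(
      input_check = function(input) {
        check_text(input)
        if (!inherits(input$resources$gazetteer, "herb_gazetteer")) {
          stop("input 'resources$gazetteer' must be a gazetteer")
        }
      },
      fn = function(input) extract_locations(input$text, input$resources$gazetteer)
    )
  )
  structure(reg, class = "service_registry")
}

#' Dispatch a service call through the registry
#'
#' Validates the input against the service's input contract, runs the bound
#' implementation and validates the payload against the output contract.
#' Contract violations raise a `herbsheet_contract_error`.
#'
#' @param registry A [service_contracts()] registry.
#' @param name Service name.
#' @param input Named list of inputs for the service.
#' @return The validated payload.
#' @export
dispatch_service <- function(registry, name, input) {
  if (!name %in% names(registry)) {
    rlang::abort(paste0("unknown service: '", name, "'"),
      class = "herbsheet_unknown_service")
  }
  entry <- registry[[name]]
  tryCatch(entry$input_check(input), error = function(e) {
    rlang::abort(paste0("input for service '", name, "' violates its contract: ",
      conditionMessage(e)), class = "herbsheet_contract_error")
  })
  payload <- entry$fn(input)
  validate_service_payload(name, payload)
  payload
}

#' Swap a service implementation, keeping its contracts
#'
#' Rebinding replaces only the callable; input and output contracts are
#' unchanged, so workflows keep running against the new implementation.
#'
#' @param registry A [service_contracts()] registry.
#' @param name Service to rebind.
#' @param fn New implementation, `function(input) -> payload`.
#' @return The modified registry.
#' @export
rebind_service <- function(registry, name, fn) {
  if (!name %in% names(registry)) {
    rlang::abort(paste0("unknown service: '", name, "'"),
      class = "herbsheet_unknown_service")
  }
  registry[[name]]$fn <- fn
  registry
}

new_report_row <- function(guid, status, message = "") {
  counts <- stats::setNames(as.list(rep(0L, length(ENTITY_CATEGORIES))),
    paste0("n_", ENTITY_CATEGORIES))
  tibble::as_tibble(c(list(guid = guid, status = status, message = message), counts))
}

#' Per-run workflow report
#'
#' @param sdfs A workflow result (list of SDFs with an attached report).
#' @return A tibble with one row per specimen: `guid`, `status`
#'   (`ok`/`flagged`/`failed`), `message` and per-category entity counts.
#' @export
workflow_report <- function(sdfs) {
  rep <- attr(sdfs, "report")
  if (is.null(rep)) {
    rep <- dplyr::bind_rows(lapply(sdfs, function(s) new_report_row(s$specimen$guid, "ok")))
  }
  rep
}

set_report <- function(sdfs, report) {
  attr(sdfs, "report") <- report
  class(sdfs) <- unique(c("sdf_list", class(sdfs)))
  sdfs
}

count_entities <- function(sdf, row) {
  for (cat in ENTITY_CATEGORIES) {
    tb <- sdf$entities[[cat]]
    row[[paste0("n_", cat)]] <- if (is.null(tb)) 0L else nrow(tb)
  }
  row
}

#' Run the pre-OCR workflow
#'
#' Per specimen: create the SDF, locate the scale ([match_scale()]), derive
#' the DPI ([compute_dpi()]) and detect text regions
#' ([detect_text_regions()]), recording each result with its provenance. A
#' specimen whose scale match falls below the acceptance threshold keeps its
#' (flagged) DPI recorded but text detection proceeds with `fallback_dpi`. An
#' unreadable image marks that specimen failed; the run continues.
#'
#' @param specimens A tibble/data frame with columns `guid` and `image_uri`.
#' @param sri A [scale_reference()].
#' @param search Magnification grid for the scale match.
#' @param accept_threshold NCC acceptance threshold.
#' @param fallback_dpi DPI used for text detection on flagged sheets.
#' @param text_params A [text_detect_params()].
#' @param registry Service registry (swap implementations via
#'   [rebind_service()]).
#' @return List of SDFs (class `sdf_list`) with a [workflow_report()]
#'   attached.
#' @export
run_pre_ocr <- function(specimens, sri, search = default_magnifications(),
                        accept_threshold = 0.6, fallback_dpi = 300,
                        text_params = text_detect_params(),
                        registry = service_contracts()) {
  sdfs <- list(); report <- list()
  for (i in seq_len(NROW(specimens))) {
    guid <- specimens$guid[i]
    sdf <- create_sdf(specimen_ref(guid, specimens$image_uri[i]))
    row <- new_report_row(guid, "ok")
    res <- tryCatch({
      image <- read_sheet_image(specimens$image_uri[i])
      match <- dispatch_service(registry, "scale_matching_service",
        list(image = image, sri = sri, search = search,
          accept_threshold = accept_threshold))
      sdf <- record_result(sdf, "scale_matching_service", match,
        parameters = list(accept_threshold = accept_threshold,
          n_magnifications = length(search)))
      dpi_payload <- dispatch_service(registry, "dpi_service",
        list(match = match, sri = sri))
      sdf <- record_result(sdf, "dpi_service", dpi_payload,
        parameters = list(sri_resolution = sri$resolution,
          sri_width = unname(sri$pixel_size[["width"]])))
      dpi_use <- if (isTRUE(dpi_payload$flagged)) fallback_dpi else dpi_payload$dpi
      regions <- dispatch_service(registry, "text_region_service",
        list(image = image, dpi = dpi_use, params = text_params))
      sdf <- record_result(sdf, "text_region_service", regions,
        parameters = list(dpi = dpi_use))
      if (isTRUE(dpi_payload$flagged)) row$status <- "flagged"
      "ok"
    }, error = function(e) conditionMessage(e))
    if (!identical(res, "ok")) {
      row$status <- "failed"; row$message <- res
    }
    sdfs[[i]] <- sdf
    report[[i]] <- row
  }
  set_report(sdfs, dplyr::bind_rows(report))
}

resolve_engine <- function(engine, sdf, corruption_p = 0, seed = 0) {
  if (inherits(engine, "ocr_engine")) return(engine)
  if (identical(engine, "fixture")) {
    truth_path <- sub("\\.(png|tif|tiff|jpg|jpeg)$", ".truth.json",
      sdf$specimen$image_uri, ignore.case = TRUE)
    if (!file.exists(truth_path)) {
      rlang::abort(paste0("ground-truth sidecar not found: ", truth_path),
        class = "herbsheet_invalid_input")
    }
    return(make_fixture_engine(read_sheet_truth(truth_path),
      corruption_p = corruption_p, seed = seed))
  }
  if (identical(engine, "tesseract")) return(make_tesseract_engine())
  rlang::abort("engine must be an ocr_engine, \"fixture\" or \"tesseract\"",
    class = "herbsheet_invalid_input")
}

#' Run the OCR workflow
#'
#' For each SDF with text regions from the pre-OCR workflow, recognizes the
#' text of every region (recognition is restricted to the region crops) and
#' records it. Several SDFs are processed in one call with per-specimen
#' isolation; an SDF without text regions is flagged and skipped.
#'
#' @param sdfs List of SDFs (pre-OCR done).
#' @param engine An [ocr_engine()], or `"fixture"` (ground-truth sidecar
#'   next to each image) or `"tesseract"`.
#' @param corruption_p,seed Fixture-engine noise model (see
#'   [make_fixture_engine()]).
#' @return Updated list of SDFs with a report attached.
#' @export
run_ocr <- function(sdfs, engine = "fixture", corruption_p = 0, seed = 0) {
  report <- list()
  out <- list()
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    row <- new_report_row(sdf$specimen$guid, "ok")
    if (is.null(sdf$text_regions)) {
      row$status <- "flagged"
      row$message <- "no text regions: run the pre-OCR workflow first"
    } else {
      res <- tryCatch({
        if (nrow(sdf$text_regions) == 0) {
          texts <- recognize_regions(sdf$text_regions, matrix(1, 1, 1),
            ocr_engine("none", function(r) ""))
          sdf <- record_result(sdf, "ocr_service", texts,
            parameters = list(engine = "none", corruption_p = corruption_p))
        } else {
          eng <- resolve_engine(engine, sdf, corruption_p, seed)
          image <- read_sheet_image(sdf$specimen$image_uri)
          texts <- recognize_regions(sdf$text_regions, image, eng)
          sdf <- record_result(sdf, "ocr_service", texts,
            parameters = list(engine = eng$name, corruption_p = corruption_p))
        }
        "ok"
      }, error = function(e) conditionMessage(e))
      if (!identical(res, "ok")) { row$status <- "failed"; row$message <- res }
    }
    out[[i]] <- sdf
    report[[i]] <- row
  }
  set_report(out, dplyr::bind_rows(report))
}

#' Run the extractor workflow
#'
#' Applies all five text-based extractors to every recognized region text of
#' every SDF; mention offsets are relative to each region's text, with the
#' region index recorded alongside. Missing resources abort before any
#' specimen is processed (configuration error); re-running replaces the
#' previously extracted entities.
#'
#' @param sdfs List of SDFs (OCR done).
#' @param resources A [load_resources()] bundle.
#' @return Updated list of SDFs with a report attached.
#' @export
run_extractors <- function(sdfs, resources) {
  if (!inherits(resources, "herb_resources")) {
    rlang::abort("resources must be a load_resources() bundle",
      class = "herbsheet_invalid_input")
  }
  registry <- service_contracts()
  report <- list(); out <- list()
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    row <- new_report_row(sdf$specimen$guid, "ok")
    if (is.null(sdf$texts)) {
      row$status <- "flagged"
      row$message <- "no recognized text: run the OCR workflow first"
    } else {
      res <- tryCatch({
        per_service <- lapply(EXTRACTOR_SERVICES, function(sv) entity_tibble())
        for (r in seq_len(nrow(sdf$texts))) {
          txt <- sdf$texts$text[r]
          for (cat in ENTITY_CATEGORIES) {
            ents <- dispatch_service(registry, EXTRACTOR_SERVICES[[cat]],
              list(text = txt, resources = resources))
            if (nrow(ents) > 0) {
              ents$region_index <- sdf$texts$region_index[r]
              per_service[[cat]] <- dplyr::bind_rows(per_service[[cat]], ents)
            }
          }
        }
        for (cat in ENTITY_CATEGORIES) {
          sdf <- record_result(sdf, EXTRACTOR_SERVICES[[cat]],
            sort_entities(per_service[[cat]]),
            parameters = list(n_regions = nrow(sdf$texts)))
        }
        "ok"
      }, error = function(e) conditionMessage(e))
      if (!identical(res, "ok")) { row$status <- "failed"; row$message <- res }
    }
    row <- count_entities(sdf, row)
    out[[i]] <- sdf
    report[[i]] <- row
  }
  set_report(out, dplyr::bind_rows(report))
}

merge_reports <- function(...) {
  reps <- list(...)
  out <- reps[[1]]
  for (r in reps[-1]) {
    for (i in seq_len(nrow(out))) {
      if (out$status[i] == "failed") next
      if (r$status[i] == "failed" || r$status[i] == "flagged") {
        out$status[i] <- r$status[i]
        out$message[i] <- r$message[i]
      }
      for (cat in ENTITY_CATEGORIES) {
        out[[paste0("n_", cat)]][i] <- r[[paste0("n_", cat)]][i]
      }
    }
  }
  out
}

#' Run the full pipeline (pre-OCR, OCR, extraction)
#'
#' Composition of [run_pre_ocr()], [run_ocr()] and [run_extractors()] with a
#' merged report.
#'
#' @inheritParams run_pre_ocr
#' @inheritParams run_ocr
#' @inheritParams run_extractors
#' @return List of SDFs with the merged [workflow_report()] attached.
#' @export
run_pipeline <- function(specimens, sri, resources, engine = "fixture",
                         corruption_p = 0, seed = 0,
                         search = default_magnifications(),
                         accept_threshold = 0.6, fallback_dpi = 300,
                         text_params = text_detect_params(),
                         registry = service_contracts()) {
  s1 <- run_pre_ocr(specimens, sri, search = search,
    accept_threshold = accept_threshold, fallback_dpi = fallback_dpi,
    text_params = text_params, registry = registry)
  s2 <- run_ocr(s1, engine = engine, corruption_p = corruption_p, seed = seed)
  s3 <- run_extractors(s2, resources)
  set_report(unclass(s3)[seq_along(s3)],
    merge_reports(workflow_report(s1), workflow_report(s2), workflow_report(s3)))
}
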