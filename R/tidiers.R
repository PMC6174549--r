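#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an SDF into its entity mentions
#'
#' @param x An `sdf` object.
#' @param ... Unused.
#' @return A tibble of entity mentions (one row per mention) with a `guid`
#'   column prepended; zero rows if extraction has not run.
#' @exportS3Method generics::tidy
tidy.sdf <- function(x, ...) {
  ents <- if (length(x$entities) == 0) entity_tibble() else
    sort_entities(dplyr::bind_rows(x$entities))
  dplyr::bind_cols(tibble::tibble(guid = rep(x$specimen$guid, nrow(ents))), ents)
}

#' @exportS3Method generics::tidy
tidy.sdf_list <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy))
}

#' One-row summary of an SDF
#'
#' @param x An `sdf` object.
#' @param ... Unused.
#' @return A one-row tibble: guid, dpi (and its confidence flag), scale
#'   match score, region/text counts, per-category entity counts and the
#'   number of recorded service calls.
#' @exportS3Method generics::glance
glance.sdf <- function(x, ...) {
  counts <- lapply(ENTITY_CATEGORIES, function(cat) {
    tb <- x$entities[[cat]]
    if (is.null(tb)) 0L else nrow(tb)
  })
  names(counts) <- paste0("n_", ENTITY_CATEGORIES)
  tibble::as_tibble(c(list(
    guid = x$specimen$guid,
    dpi = x$dpi %||% NA_real_,
    dpi_flagged = x$dpi_flagged %||% NA,
    scale_score = if (is.null(x$scale_region)) NA_real_ else x$scale_region$score,
    n_text_regions = if (is.null(x$text_regions)) 0L else nrow(x$text_regions),
    n_texts = if (is.null(x$texts)) 0L else nrow(x$texts)),
    counts,
    list(n_services = length(x$history))))
}

#' @exportS3Method generics::glance
glance.sdf_list <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance))
}
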