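# Shared schema for extracted entity mentions. Every extractor returns this
# shape so results can be bound, compared and serialized uniformly.

ENTITY_CATEGORIES <- c("scientific_name", "botanist", "date", "coordinate", "location")

entity_cols <- function() {
  list(
    category = character(), surface = character(),
    start = integer(), end = integer(), region_index = integer(),
    genus = character(), epithet = character(), author = character(),
    surname = character(), initials = character(), role = character(),
    iso_date = character(), date_kind = character(),
    latitude = double(), longitude = double(),
    place_name = character(), country = character(),
    matched_entry = character()
  )
}

#' Construct an entity mention tibble
#'
#' The common shape for all extractor output: one row per mention with the
#' category, the verbatim surface string, half-open 0-based character offsets
#' into the source text, and category-specific payload columns (`NA`
#' elsewhere). `region_index` ties a mention to the OCR region its text came
#' from once a specimen has been processed; it is `NA` for free-standing text.
#'
#' @param ... Named vectors matching the entity schema columns.
#' @return A tibble with the full entity column set.
#' @export
entity_tibble <- function(...) {
  given <- list(...)
  proto <- entity_cols()
  unknown <- setdiff(names(given), names(proto))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown entity column(s): ", paste(unknown, collapse = ", ")),
      class = "herbsheet_contract_error")
  }
  n <- if (length(given) == 0) 0L else max(vapply(given, length, integer(1)))
  cols <- lapply(names(proto), function(nm) {
    v <- given[[nm]]
    if (is.null(v)) v <- rep(proto[[nm]][NA_integer_][0], 0)
    mode_fill <- proto[[nm]]
    if (length(v) == 0 && n > 0) v <- rep(NA, n)
    if (length(v) < n) v <- rep(v, length.out = n)
    cast <- switch(class(mode_fill)[1],
      integer = as.integer, numeric = as.double, as.character)
    cast(v)
  })
  names(cols) <- names(proto)
  tibble::as_tibble(cols)
}

# Canonical sort used so extractor execution order never shows in results.
sort_entities <- function(entities) {
  if (nrow(entities) == 0) return(entities)
  ord <- order(
    ifelse(is.na(entities$region_index), -1L, entities$region_index),
    entities$start, match(entities$category, ENTITY_CATEGORIES), entities$end
  )
  entities[ord, ]
}

# Check surface == substring(text, start, end) for every mention (0-based,
# half-open). Used both in validation and the test-suite property.
check_offset_fidelity <- function(entities, text) {
  if (nrow(entities) == 0) return(TRUE)
  all(vapply(seq_len(nrow(entities)), function(i) {
    substr(text, entities$start[i] + 1, entities$end[i]) == entities$surface[i]
  }, logical(1)))
}

# Split a combined entity tibble into the per-category list stored in an SDF.
entities_to_list <- function(entities) {
  out <- lapply(ENTITY_CATEGORIES, function(cat) {
    entities[entities$category == cat, , drop = FALSE]
  })
  names(out) <- ENTITY_CATEGORIES
  out
}
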