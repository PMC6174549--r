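# Scoring extracted entities against planted ground truth: payload-level
# matching (surfaces may legitimately differ under OCR noise).

payload_matches <- function(planted, got) {
  if (planted$category != got$category) return(FALSE)
  same <- function(a, b) !is.na(a) && !is.na(b) && a == b
  switch(planted$category,
    scientific_name = same(tolower(planted$genus), tolower(got$genus)) &&
      (is.na(planted$epithet) || same(tolower(planted$epithet), tolower(got$epithet))),
    botanist = same(tolower(planted$surname), tolower(got$surname)),
    date = same(planted$iso_date, got$iso_date) &&
      same(planted$date_kind, got$date_kind),
    coordinate = !is.na(got$latitude) && !is.na(got$longitude) &&
      abs(planted$latitude - got$latitude) < 1e-9 &&
      abs(planted$longitude - got$longitude) < 1e-9,
    location = same(tolower(planted$place_name), tolower(got$place_name)) &&
      same(planted$country, got$country),
    FALSE)
}

#' Score extracted entities against planted ground truth
#'
#' Matches each planted entity to extracted mentions of the same category by
#' payload equality (genus/epithet for names, surname for botanists,
#' ISO date and kind for dates, coordinates to 1e-9 degrees, place and
#' country for locations). Each extracted mention can satisfy at most one
#' planted entity.
#'
#' @param planted Planted [entity_tibble()] (e.g. `truth$planted_entities`).
#' @param extracted Extracted [entity_tibble()] (e.g. from [tidy.sdf()] or
#'   [extract_all()]).
#' @return A list: `recovered` (logical per planted row), `spurious` (count
#'   of extracted mentions matching no planted entity), and per-category
#'   tallies in `by_category` (tibble with `category`, `planted`,
#'   `recovered`, `extracted`).
#' @export
score_extraction <- function(planted, extracted) {
  used <- rep(FALSE, nrow(extracted))
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    for (j in seq_len(nrow(extracted))) {
      if (!used[j] && payload_matches(planted[i, ], extracted[j, ])) {
        used[j] <<- TRUE
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  by_cat <- dplyr::bind_rows(lapply(ENTITY_CATEGORIES, function(cat) {
    pi <- planted$category == cat
    tibble::tibble(category = cat,
      planted = sum(pi),
      recovered = sum(recovered[pi]),
      extracted = sum(extracted$category == cat))
  }))
  list(recovered = recovered, spurious = sum(!used), by_category = by_cat)
}
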