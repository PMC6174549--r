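# Dictionary and gazetteer resources for the text-based extractors. Bundled
# fixture files (synthetic content) stand in for the live resources a
# production deployment would export (a scientific-name index, a botanist
# database, a place-name gazetteer).

#' Load a dictionary for entity extraction
#'
#' Dictionaries are UTF-8 plain text, one entry per line; blank lines and
#' lines starting with `#` are ignored. Entries are whitespace-collapsed on
#' load and matched case-insensitively.
#'
#' @param path File path.
#' @param kind `"scientific_names"` or `"botanists"`.
#' @param match_tolerance Maximum per-token edit distance for fuzzy matches;
#'   applied only to tokens of 5 or more characters (shorter tokens always
#'   match exactly). Default 1, tolerating single-character OCR errors.
#' @return A `herb_dictionary` object.
#' @export
read_dictionary <- function(path, kind = c("scientific_names", "botanists"),
                            match_tolerance = 1) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- stringr::str_squish(lines)
  entries <- entries[nzchar(entries) & !startsWith(entries, "#")]
  structure(list(entries = unique(entries), kind = kind,
    match_tolerance = as.integer(match_tolerance)), class = "herb_dictionary")
}

#' @export
print.herb_dictionary <- function(x, ...) {
  cat("<herb_dictionary> kind=", x$kind, ", ", length(x$entries),
    " entries, tolerance ", x$match_tolerance, "\n", sep = "")
  invisible(x)
}

#' Load a gazetteer (place name to country)
#'
#' Tab-separated, two columns (`place_name`, `country`), no header, UTF-8.
#' Lookup is case-insensitive and longest-match at token boundaries.
#'
#' @param path File path.
#' @return A tibble with columns `place_name` and `country`, class
#'   `herb_gazetteer`.
#' @export
read_gazetteer <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2 || !nzchar(trimws(p[1])), logical(1))
  if (any(bad)) {
    rlang::abort(paste0("gazetteer rows without place and country: line(s) ",
      paste(which(bad), collapse = ", ")), class = "herbsheet_parse_error")
  }
  out <- tibble::tibble(
    place_name = vapply(parts, function(p) trimws(p[1]), character(1)),
    country = vapply(parts, function(p) trimws(p[2]), character(1)))
  if (anyDuplicated(tolower(out$place_name))) {
    rlang::abort("gazetteer contains duplicate place names", class = "herbsheet_parse_error")
  }
  class(out) <- c("herb_gazetteer", class(out))
  out
}

#' Bundle extractor resources
#'
#' Collects the scientific-name dictionary, botanist dictionary and gazetteer
#' used by the extractor services. With no arguments, loads the small
#' synthetic fixture resources shipped with the package.
#'
#' @param names_path,botanists_path,gazetteer_path Paths to the resource
#'   files; defaults are the bundled fixtures.
#' @param match_tolerance Per-token edit-distance tolerance for both
#'   dictionaries.
#' @return A `herb_resources` list with elements `names`, `botanists`,
#'   `gazetteer`.
#' @export
load_resources <- function(names_path = NULL, botanists_path = NULL,
                           gazetteer_path = NULL, match_tolerance = 1) {
  names_path <- names_path %||%
    system.file("extdata", "names.txt", package = "herbsheet", mustWork = TRUE)
  botanists_path <- botanists_path %||%
    system.file("extdata", "botanists.txt", package = "herbsheet", mustWork = TRUE)
  gazetteer_path <- gazetteer_path %||%
    system.file("extdata", "gazetteer.tsv", package = "herbsheet", mustWork = TRUE)
  structure(list(
    names = read_dictionary(names_path, "scientific_names", match_tolerance),
    botanists = read_dictionary(botanists_path, "botanists", match_tolerance),
    gazetteer = read_gazetteer(gazetteer_path)
  ), class = "herb_resources")
}
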