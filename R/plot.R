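# ggplot2 views of sheets and pipeline results.

raster_layer <- function(image) {
  H <- nrow(image); W <- ncol(image)
  ggplot2::annotation_raster(
    grDevices::as.raster(pmin(pmax(image, 0), 1)),
    xmin = 0, xmax = W, ymin = -H, ymax = 0)
}

#' @importFrom rlang .data %||%
NULL

rect_layer <- function(regions, label) {
  if (is.null(regions) || nrow(regions) == 0) return(NULL)
  df <- tibble::tibble(
    xmin = regions$x, xmax = regions$x + regions$width,
    ymin = -(regions$y + regions$height), ymax = -regions$y,
    what = label)
  ggplot2::geom_rect(data = df,
    ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
      ymin = .data$ymin, ymax = .data$ymax, colour = .data$what),
    fill = NA, linewidth = 0.5)
}

sheet_canvas <- function(image) {
  ggplot2::ggplot() +
    raster_layer(image) +
    ggplot2::coord_fixed(xlim = c(0, ncol(image)), ylim = c(-nrow(image), 0),
      expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic sheet with its ground truth
#'
#' @param object A `herb_sheet` from [generate_sheet()].
#' @param ... Unused.
#' @return A ggplot showing the rendered sheet with the planted label boxes
#'   and scale region outlined.
#' @exportS3Method ggplot2::autoplot
autoplot.herb_sheet <- function(object, ...) {
  sheet_canvas(object$image) +
    rect_layer(object$truth$label_boxes, label = "planted label") +
    rect_layer(object$truth$scale_region, label = "scale") +
    ggplot2::scale_colour_manual(
      values = c("planted label" = "#1b9e77", "scale" = "#d95f02"))
}

#' Plot an SDF's detected regions over its specimen image
#'
#' @param object An `sdf` whose `image_uri` is readable.
#' @param ... Unused.
#' @return A ggplot of the specimen image with the matched scale region and
#'   detected text regions outlined.
#' @exportS3Method ggplot2::autoplot
autoplot.sdf <- function(object, ...) {
  image <- read_sheet_image(object$specimen$image_uri)
  sheet_canvas(image) +
    rect_layer(object$text_regions, label = "text region") +
    rect_layer(object$scale_region, label = "scale match") +
    ggplot2::scale_colour_manual(
      values = c("text region" = "#1b9e77", "scale match" = "#d95f02")) +
    ggplot2::ggtitle(object$specimen$guid)
}

#' Bar chart of entity counts per specimen
#'
#' @param sdfs An `sdf_list` (or plain list of SDFs).
#' @return A ggplot with one bar group per specimen, split by entity
#'   category.
#' @export
plot_entity_counts <- function(sdfs) {
  tb <- dplyr::bind_rows(lapply(sdfs, glance))
  long <- tidyr::pivot_longer(tb,
    dplyr::all_of(paste0("n_", ENTITY_CATEGORIES)),
    names_to = "category", values_to = "n", names_prefix = "n_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$guid, y = .data$n,
    fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mentions extracted", fill = NULL) +
    ggplot2::theme_minimal()
}
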