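# Spatial ploidy maps: recolor a segmentation label image by assigned
# ploidy class and project class ranks to 2D for display.

#' Default ordered class palette
#'
#' A colorblind-safe ordered ramp (viridis) with a neutral gray for
#' filtered/unassigned objects. Fully configurable: any named vector of
#' colors (one per class, plus optionally `"filtered"`) can be passed to
#' [render_ploidy_map()] instead.
#'
#' @param classes character vector of class names in ladder order.
#' @return named character vector of hex colors (classes + `"filtered"`).
#' @export
default_palette <- function(classes) {
  cols <- grDevices::hcl.colors(max(3L, length(classes)), "Viridis")[seq_along(classes)]
  c(stats::setNames(cols, classes), filtered = "#808080")
}

#' Recolor a label image by ploidy class
#'
#' Every pixel of an object takes the class rank (and color) of that
#' object's assignment; filtered or unassigned objects take the neutral
#' `"filtered"` entry; background (0) stays background.
#'
#' @param label_img a [label_image()].
#' @param assignment a [classify()] result carrying `object_id`s.
#' @param palette named color vector as from [default_palette()]; must
#'   cover every class present.
#' @return a `ploidy_map_image`: `class_raster` (integer ranks, 0
#'   background, classes 1..K in ladder order, filtered = K+1), `rgb`
#'   (H x W x 3 array of unit-range values, 2D inputs only — 3D rasters are rendered
#'   after [project_classes()]), `palette`, `legend` (rank -> class name).
#' @export
render_ploidy_map <- function(label_img, assignment, palette = NULL) {
  stopifnot(inherits(label_img, "label_image"), inherits(assignment, "ploidy_assignment"))
  classes <- assignment$class_map$classes
  if (is.null(palette)) palette <- default_palette(classes)
  missing_cols <- setdiff(c(classes, "filtered"), names(palette))
  if (length(missing_cols) > 0) {
    stop(
      "palette lacks entries for: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  n_cls <- length(classes)
  rank_of_class <- stats::setNames(seq_len(n_cls), classes)
  filtered_rank <- n_cls + 1L
  df <- assignment$df
  obj_rank <- ifelse(df$filtered, filtered_rank, rank_of_class[df$class])
  ids <- df$object_id
  if (anyNA(ids)) stop("assignment lacks object_ids; cannot map to the raster", call. = FALSE)
  arr <- label_img$array
  present <- object_ids(label_img)
  unassigned <- setdiff(present, ids)
  if (length(unassigned) > 0) {
    np_log("ploidy_map", "info", sprintf(
      "%d object(s) in the raster have no assignment; rendered as filtered",
      length(unassigned)
    ))
  }
  # lookup table over 0..max(label): 0 -> 0, known ids -> rank, others -> filtered
  lut <- rep.int(filtered_rank, max(arr) + 1L)
  lut[1L] <- 0L
  lut[ids + 1L] <- obj_rank
  class_raster <- array(lut[arr + 1L], dim = dim(arr))
  legend <- c(stats::setNames(classes, seq_len(n_cls)), stats::setNames("filtered", filtered_rank))
  rgb <- NULL
  if (length(dim(class_raster)) == 2L) {
    rgb <- raster_to_rgb(class_raster, classes, palette)
  }
  structure(
    list(
      class_raster = class_raster, rgb = rgb, palette = palette,
      legend = legend, classes = classes
    ),
    class = "ploidy_map_image"
  )
}

raster_to_rgb <- function(class_raster, classes, palette) {
  n_cls <- length(classes)
  colors <- c("#000000", unname(palette[classes]), unname(palette[["filtered"]]))
  comp <- grDevices::col2rgb(colors) / 255
  h <- nrow(class_raster)
  w <- ncol(class_raster)
  rgb <- array(0, dim = c(h, w, 3))
  idx <- as.vector(class_raster) + 1L
  for (ch in 1:3) rgb[, , ch] <- matrix(comp[ch, idx], h, w)
  rgb
}

#' @export
print.ploidy_map_image <- function(x, ...) {
  cat(sprintf(
    "<ploidy_map_image> %s, %d class(es) + filtered\n",
    paste(dim(x$class_raster), collapse = "x"), length(x$classes)
  ))
  invisible(x)
}

#' Maximum-rank projection of a class-coded volume
#'
#' Projects a 3D class raster to 2D by taking the per-pixel maximum class
#' rank along `axis`, so a high-ploidy nucleus is never hidden behind a
#' low-ploidy one. Input must be class-coded (small integer ranks), not
#' intensity. 2D input is returned unchanged with a warning.
#'
#' @param class_volume integer array, 2D or 3D.
#' @param axis projection axis for 3D input (default 3, the z axis of a
#'   `(y, x, z)` raster).
#' @return 2D integer matrix of class ranks.
#' @export
project_classes <- function(class_volume, axis = 3L) {
  nd <- length(dim(class_volume))
  if (nd == 2L) {
    warning("input is already 2D; returning it unchanged", call. = FALSE)
    return(class_volume)
  }
  stopifnot(nd == 3L, axis %in% 1:3)
  apply(class_volume, setdiff(1:3, axis), max)
}

#' Write a ploidy map to disk
#'
#' Writes the class-coded raster as a 16-bit TIFF, the RGB rendering
#' (after max-rank projection for 3D input) as PNG, and the palette plus
#' rank legend as a JSON sidecar.
#'
#' @param pm a `ploidy_map_image`.
#' @param path_raster class raster TIFF path (NULL to skip).
#' @param path_png RGB PNG path (NULL to skip).
#' @param path_legend JSON sidecar path (NULL to skip).
#' @return invisible list of written paths.
#' @export
write_ploidy_map <- function(pm, path_raster = NULL, path_png = NULL,
                             path_legend = NULL) {
  stopifnot(inherits(pm, "ploidy_map_image"))
  written <- list()
  if (!is.null(path_raster)) {
    write_tiff_gray(pm$class_raster, path_raster, bits = 16L)
    written$raster <- path_raster
  }
  if (!is.null(path_png)) {
    raster2d <- pm$class_raster
    if (length(dim(raster2d)) == 3L) raster2d <- project_classes(raster2d)
    rgb <- pm$rgb %||% raster_to_rgb(raster2d, pm$classes, pm$palette)
    png::writePNG(rgb, path_png)
    written$png <- path_png
  }
  if (!is.null(path_legend)) {
    jsonlite::write_json(
      list(palette = as.list(pm$palette), legend = as.list(pm$legend)),
      path_legend,
      auto_unbox = TRUE, pretty = TRUE
    )
    written$legend <- path_legend
  }
  invisible(written)
}
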