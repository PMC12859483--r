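# Object-level feature tables and segmentation label images: the two
# artifacts a segmentation tool (e.g. ilastik object classification)
# exports, and the CSV the pipeline writes back out.

#' Construct a feature table
#'
#' A feature table holds one row per segmented object (nucleus) with the
#' measurements downstream modules consume: total marker intensity, size in
#' pixels/voxels, per-object variance of intensity, a free-text group, a
#' categorical user label, and the object centroid in image index space
#' (0-based, pixel units).
#'
#' @param records data.frame with columns `object_id`, `total_intensity`,
#'   `size`, and optionally `group`, `user_label`, `mean_intensity`,
#'   `variance_of_intensity`, `physical_size`, `normalized_intensity`,
#'   `centroid_1` ... `centroid_d`.
#' @param dimensionality 2 or 3 (image dimensionality).
#' @param intensity_channel name of the quantified marker, e.g. `"Hoechst"`.
#' @param calibration optional numeric vector of physical pixel/voxel size
#'   per axis, in micrometres.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(records, dimensionality = 2L, intensity_channel = NULL,
                          calibration = NULL) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  mandatory <- c("object_id", "total_intensity", "size")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols) > 0 && nrow(records) > 0) {
    stop("feature table records lack mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in setdiff(mandatory, names(records))) records[[col]] <- numeric(0)
  if (nrow(records) > 0) {
    if (anyDuplicated(records$object_id)) {
      stop("object_id values must be unique within a feature table", call. = FALSE)
    }
    if (any(records$size <= 0)) stop("size must be > 0 for every record", call. = FALSE)
    if (!"mean_intensity" %in% names(records)) {
      records$mean_intensity <- records$total_intensity / records$size
    }
    if ("variance_of_intensity" %in% names(records) &&
      any(records$variance_of_intensity < 0, na.rm = TRUE)) {
      stop("variance_of_intensity must be >= 0", call. = FALSE)
    }
    cons <- abs(records$total_intensity - records$mean_intensity * records$size)
    bad <- cons > 1e-3 * pmax(abs(records$total_intensity), .Machine$double.eps)
    if (any(bad, na.rm = TRUE)) {
      stop(
        "total_intensity != mean_intensity * size (beyond 0.1% tolerance) for object_id ",
        paste(utils::head(records$object_id[which(bad)], 3), collapse = ", "),
        call. = FALSE
      )
    }
    cent <- grep("^centroid_", names(records), value = TRUE)
    if (length(cent) > 0 && length(cent) != dimensionality) {
      stop(
        "centroid columns (", length(cent), ") inconsistent with dimensionality (",
        dimensionality, ")",
        call. = FALSE
      )
    }
  }
  if (!"group" %in% names(records)) records$group <- rep("all", nrow(records))
  if (!"user_label" %in% names(records)) records$user_label <- rep(NA_character_, nrow(records))
  structure(
    list(
      records = records,
      dimensionality = as.integer(dimensionality),
      intensity_channel = intensity_channel,
      calibration = calibration
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d records, %dD%s\n", nrow(x$records), x$dimensionality,
    if (is.null(x$intensity_channel)) "" else paste0(", channel ", x$intensity_channel)
  ))
  invisible(x)
}

#' Number of records in a feature table
#' @param x a `feature_table`.
#' @export
n_records <- function(x) nrow(x$records)

#' Default ilastik column dialect
#'
#' Maps the semantic fields of a nucleus record to candidate CSV column
#' names as exported by ilastik object classification; the first candidate
#' present in the file wins. Both `"Total Intensity"` and
#' `"Total Intensity_0"` spellings are accepted automatically because
#' different tool versions emit either. Override any entry to adapt to a
#' different export dialect.
#'
#' @param ... named character vectors overriding individual entries, e.g.
#'   `total_intensity = "SumIntensity"`.
#' @return named list of candidate column-name vectors.
#' @export
ilastik_dialect <- function(...) {
  dialect <- list(
    object_id = c("object_id", "Object ID", "labelimage_oid"),
    total_intensity = c("Total Intensity", "Total Intensity_0", "total_intensity"),
    size = c("Size in pixels", "Size in pixels_0", "Size", "size"),
    variance_of_intensity = c(
      "Variance of Intensity", "Variance of Intensity_0", "variance_of_intensity"
    ),
    mean_intensity = c("Mean Intensity", "Mean Intensity_0", "mean_intensity"),
    user_label = c("User Labels", "Predicted Class", "user_label"),
    group = c("group", "Group"),
    physical_size = c("physical_size"),
    normalized_intensity = c("normalized_intensity", "Normalized Hoechst Intensity"),
    centroid = c("Center of the object_%d", "Center of the object_0_%d"),
    centroid_base1 = c("centroid_%d")
  )
  overrides <- list(...)
  for (nm in names(overrides)) dialect[[nm]] <- overrides[[nm]]
  dialect
}

resolve_column <- function(candidates, available) {
  hit <- candidates[candidates %in% available]
  if (length(hit) == 0) NA_character_ else hit[[1L]]
}

#' Read a segmentation feature table from CSV
#'
#' Reads an object-feature CSV (one row per segmented object) using a
#' column dialect. Rows without an object identifier are rejected; the
#' "User Labels" column (falling back to "Predicted Class") populates
#' `user_label`.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param dialect column mapping as produced by [ilastik_dialect()].
#' @param dimensionality 2 or 3; inferred from centroid columns when `NULL`.
#' @param intensity_channel,calibration stored as metadata.
#' @param group group identifier applied to all rows when the file has no
#'   group column.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, dialect = ilastik_dialect(),
                               dimensionality = NULL, intensity_channel = NULL,
                               calibration = NULL, group = NULL) {
  if (!file.exists(path)) stop("feature table file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- names(raw)
  take <- function(field) resolve_column(dialect[[field]], cols)
  id_col <- take("object_id")
  ti_col <- take("total_intensity")
  sz_col <- take("size")
  for (pair in list(
    c("object id", id_col), c("total intensity", ti_col), c("size", sz_col)
  )) {
    if (nrow(raw) > 0 && is.na(pair[2])) {
      stop(
        "mandatory ", pair[1], " column not found in ", path,
        " (tried: ", paste(dialect[[sub(" ", "_", pair[1])]], collapse = ", "), ")",
        call. = FALSE
      )
    }
  }
  if (nrow(raw) == 0) {
    return(feature_table(
      data.frame(
        object_id = integer(0), total_intensity = numeric(0),
        size = numeric(0)
      ),
      dimensionality = dimensionality %||% 2L,
      intensity_channel = intensity_channel, calibration = calibration
    ))
  }
  ids <- raw[[id_col]]
  if (any(is.na(ids) | ids == "")) {
    stop(
      "rows without an object identifier: row(s) ",
      paste(utils::head(which(is.na(ids) | ids == ""), 5), collapse = ", "),
      call. = FALSE
    )
  }
  ti <- suppressWarnings(as.numeric(raw[[ti_col]]))
  if (anyNA(ti)) {
    stop(
      "non-numeric total intensity in '", ti_col, "' at row(s) ",
      paste(utils::head(which(is.na(ti)), 5), collapse = ", "),
      call. = FALSE
    )
  }
  rec <- data.frame(
    object_id = as.integer(ids),
    total_intensity = ti,
    size = as.numeric(raw[[sz_col]]),
    stringsAsFactors = FALSE
  )
  for (field in c(
    "variance_of_intensity", "mean_intensity", "physical_size",
    "normalized_intensity"
  )) {
    col <- take(field)
    if (!is.na(col)) rec[[field]] <- as.numeric(raw[[col]])
  }
  ul_col <- take("user_label")
  if (!is.na(ul_col)) rec$user_label <- as.character(raw[[ul_col]])
  gr_col <- take("group")
  rec$group <- if (!is.na(gr_col)) as.character(raw[[gr_col]]) else rep(group %||% "all", nrow(rec))
  # centroid columns: sprintf patterns over the axis index, either 0-based
  # (ilastik exports) or 1-based (this package's own writers)
  axis <- 0L
  repeat {
    col <- resolve_column(
      c(
        sprintf(dialect$centroid %||% character(0), axis),
        sprintf(dialect$centroid_base1 %||% character(0), axis + 1L)
      ),
      cols
    )
    if (is.na(col)) break
    rec[[paste0("centroid_", axis + 1L)]] <- as.numeric(raw[[col]])
    axis <- axis + 1L
  }
  if (is.null(dimensionality)) dimensionality <- if (axis > 0L) axis else 2L
  feature_table(rec,
    dimensionality = dimensionality,
    intensity_channel = intensity_channel, calibration = calibration
  )
}

#' Construct a label image
#'
#' @param array integer array, 2D `(y, x)` or 3D `(y, x, z)`; 0 is
#'   background, each positive value is one object's id.
#' @param calibration optional physical pixel/voxel size per axis (um).
#' @param axes axis order string, `"yx"` or `"yxz"`.
#' @return an object of class `label_image`.
#' @export
label_image <- function(array, calibration = NULL, axes = NULL) {
  nd <- length(dim(array))
  stopifnot(nd %in% c(2L, 3L))
  if (any(array < 0)) stop("label image values must be >= 0", call. = FALSE)
  if (any(array != round(array))) {
    stop(
      "label image holds non-integer values; export object predictions, ",
      "not probability maps",
      call. = FALSE
    )
  }
  storage.mode(array) <- "integer"
  structure(
    list(
      array = array,
      calibration = calibration,
      axes = axes %||% if (nd == 2L) "yx" else "yxz"
    ),
    class = "label_image"
  )
}

#' @export
print.label_image <- function(x, ...) {
  ids <- object_ids(x)
  cat(sprintf(
    "<label_image> %s (%s), %d object(s)\n",
    paste(dim(x$array), collapse = "x"), x$axes, length(ids)
  ))
  invisible(x)
}

#' Object ids present in a label image
#' @param x a `label_image`.
#' @export
object_ids <- function(x) {
  v <- sort(unique(as.vector(x$array)))
  v[v != 0L]
}

#' Read a label image (TIFF or HDF5)
#'
#' TIFF files are decoded by the built-in uncompressed grayscale codec;
#' `.h5`/`.hdf5` files are read through the rhdf5 package (first dataset,
#' or `name` when given). Integer labels are preserved exactly; a
#' floating-point raster is rejected with a hint that object predictions,
#' not probability maps, should be exported.
#'
#' @param path file path.
#' @param name HDF5 dataset name (default: the first dataset found).
#' @param calibration optional per-axis physical size, passed through.
#' @return a [label_image()].
#' @export
read_label_image <- function(path, name = NULL, calibration = NULL) {
  if (!file.exists(path)) stop("label image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5", "he5")) {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("reading HDF5 label images requires the rhdf5 package", call. = FALSE)
    }
    if (is.null(name)) {
      ls <- rhdf5::h5ls(path)
      ds <- ls[ls$otype == "H5I_DATASET", ]
      if (nrow(ds) == 0) stop("no dataset in HDF5 file ", path, call. = FALSE)
      name <- paste0(sub("/$", "", ds$group[1]), "/", ds$name[1])
    }
    arr <- rhdf5::h5read(path, name)
    arr <- drop(arr)
  } else {
    arr <- read_tiff_gray(path)
    if (identical(attr(arr, "sample_format"), "float") &&
      any(arr != round(arr))) {
      stop(
        "label image ", path, " holds floating-point values; export object ",
        "predictions, not probabilities",
        call. = FALSE
      )
    }
    attributes(arr) <- list(dim = dim(arr))
  }
  if (is.null(dim(arr))) dim(arr) <- c(1L, length(arr))
  label_image(arr, calibration = calibration)
}

#' Write a label image (TIFF or HDF5)
#'
#' @param img a [label_image()].
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.h5`/`.hdf5`).
#' @param bits bits per sample for TIFF output (8, 16 or 32).
#' @param name HDF5 dataset name.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(img, path, bits = 16L, name = "exported_data") {
  stopifnot(inherits(img, "label_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("writing HDF5 label images requires the rhdf5 package", call. = FALSE)
    }
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(img$array, path, name)
    rhdf5::h5closeAll()
  } else {
    mx <- max(0, img$array)
    if (mx > 2^bits - 1) stop("labels exceed ", bits, "-bit range; raise `bits`", call. = FALSE)
    write_tiff_gray(img$array, path, bits = bits, sample_format = "uint")
  }
  invisible(path)
}

#' Write per-nucleus ploidy assignments to CSV
#'
#' Emits one row per record of `table`: identifiers, features, the assigned
#' mixture component and ploidy class, the full posterior vector, and the
#' confidence flags. Records not covered by the assignment (removed before
#' modelling, e.g. non-positive features under log2) are written with class
#' `"filtered"` and empty posteriors.
#'
#' @param table the [feature_table()] the assignment was computed from.
#' @param assignment a `ploidy_assignment` (see [classify()]); its `index`
#'   maps assignment rows to `table` rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(table, assignment, path) {
  stopifnot(inherits(table, "feature_table"), inherits(assignment, "ploidy_assignment"))
  n <- n_records(table)
  idx <- assignment$index %||% seq_len(nrow(assignment$df))
  if (length(idx) != nrow(assignment$df) || (length(idx) > 0 && max(idx) > n)) {
    stop("assignment does not align with the feature table (length mismatch)", call. = FALSE)
  }
  rec <- table$records
  K <- ncol(assignment$posteriors)
  post <- matrix(NA_real_, nrow = n, ncol = K)
  if (length(idx) > 0) post[idx, ] <- assignment$posteriors
  out <- rec[, intersect(
    c(
      "object_id", "group", "user_label", "total_intensity", "size",
      "physical_size", "mean_intensity", "variance_of_intensity",
      "normalized_intensity", grep("^centroid_", names(rec), value = TRUE)
    ),
    names(rec)
  ), drop = FALSE]
  out$component <- rep(NA_integer_, n)
  out$class <- rep("filtered", n)
  out$confident <- rep(NA, n)
  out$ambiguous_second <- rep(NA, n)
  if (length(idx) > 0) {
    out$component[idx] <- assignment$df$component
    out$class[idx] <- assignment$df$class
    out$confident[idx] <- assignment$df$confident
    out$ambiguous_second[idx] <- assignment$df$ambiguous_second
    out$class[idx][assignment$df$filtered] <- "filtered"
  }
  for (k in seq_len(K)) out[[sprintf("posterior_%d", k)]] <- post[, k]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back an assignment CSV written by [write_assignments()]
#'
#' Convenience reader used for round-trips and external re-analysis.
#'
#' @param path CSV path.
#' @return data.frame with one row per original record.
#' @export
read_assignments <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
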