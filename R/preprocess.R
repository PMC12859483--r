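# Record-level filters, the haploid-standard normalization with its QC
# gates, and the log2 feature transform feeding the mixture model.

#' Population variance of per-voxel intensities
#'
#' The per-object "variance of intensity" used to separate epidermal from
#' sub-epidermal nuclei: for an object with voxel intensities S_1..S_n and
#' mean mu, returns (1/n) * sum_j (S_j - mu)^2 — the population variance
#' (divide by n, not n-1).
#'
#' @param intensities numeric vector of per-voxel intensities, length >= 1.
#' @return non-negative scalar.
#' @export
variance_of_intensity <- function(intensities) {
  if (length(intensities) == 0) {
    stop("variance_of_intensity needs at least one voxel intensity", call. = FALSE)
  }
  mu <- mean(intensities)
  mean((intensities - mu)^2)
}

#' Keep or drop records by user label
#'
#' Mirrors hand-selection in the segmentation tool: records carrying an
#' excluded label (e.g. `"incomplete"`) are removed; with `include` given,
#' only those labels are kept.
#'
#' @param table a [feature_table()].
#' @param exclude character vector of labels to drop.
#' @param include optional character vector of labels to keep exclusively.
#' @return filtered `feature_table`; kept/removed counts are logged.
#' @export
select_by_label <- function(table, exclude = character(0), include = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(include) && length(intersect(include, exclude)) > 0) {
    stop(
      "labels cannot be both included and excluded: ",
      paste(intersect(include, exclude), collapse = ", "),
      call. = FALSE
    )
  }
  lab <- table$records$user_label
  keep <- !(lab %in% exclude)
  if (!is.null(include)) keep <- keep & (lab %in% include)
  out <- table
  out$records <- table$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  np_log(
    "select_by_label", "info",
    sprintf("kept %d of %d records (%d removed)", sum(keep), length(keep), sum(!keep))
  )
  out
}

#' Filter records by a feature threshold
#'
#' Retains records strictly on the kept side of `cutoff`; ties (value equal
#' to the cutoff) are retained. The epidermal filter keeps variance of
#' intensity above 2^8.3; the guard-cell filter on flow tables keeps total
#' intensity above 2^9.
#'
#' @param table a [feature_table()].
#' @param feature record field name, e.g. `"variance_of_intensity"`.
#' @param cutoff numeric threshold.
#' @param keep `"above"` or `"below"`.
#' @return filtered `feature_table`.
#' @export
threshold_filter <- function(table, feature, cutoff, keep = c("above", "below")) {
  stopifnot(inherits(table, "feature_table"))
  keep <- match.arg(keep)
  if (n_records(table) == 0) {
    return(table)
  }
  if (!feature %in% names(table$records)) {
    stop("feature '", feature, "' not present in the table", call. = FALSE)
  }
  v <- table$records[[feature]]
  if (anyNA(v)) stop("feature '", feature, "' has missing values", call. = FALSE)
  sel <- if (keep == "above") v >= cutoff else v <= cutoff
  out <- table
  out$records <- table$records[sel, , drop = FALSE]
  rownames(out$records) <- NULL
  np_log(
    "threshold_filter", "info",
    sprintf(
      "%s %s %g: kept %d of %d (%d removed)", feature, keep, cutoff,
      sum(sel), length(sel), sum(!sel)
    )
  )
  out
}

#' Quality-control gates for the haploid reference population
#'
#' Checks the internal-standard (spermatid) nuclei of one experiment
#' against three gates before their median is trusted as a 1C anchor:
#' at least `min_n` reference nuclei; a median intensity within
#' `median_range`; and at least `min_fraction` of the median-normalized
#' intensities within `band`. All endpoints are inclusive.
#'
#' @param reference_intensities numeric vector of reference total intensities.
#' @param min_n minimum reference count (default 10).
#' @param median_range allowed median intensity range (default 2000..6000,
#'   arbitrary units).
#' @param band allowed band of intensity/median (default 0.5..1.5).
#' @param min_fraction minimum fraction within `band` (default 0.9).
#' @return a `qc_report` list: `n_reference`, `median_intensity`,
#'   `fraction_in_band`, `passed`, `reasons` (failed gate names), and the
#'   per-gate verdicts.
#' @export
reference_qc <- function(reference_intensities, min_n = 10L,
                         median_range = c(2000, 6000), band = c(0.5, 1.5),
                         min_fraction = 0.9) {
  n <- length(reference_intensities)
  med <- if (n > 0) stats::median(reference_intensities) else NA_real_
  frac <- if (n > 0) {
    ratio <- reference_intensities / med
    mean(ratio >= band[1] & ratio <= band[2])
  } else {
    NA_real_
  }
  gates <- c(
    count = n >= min_n,
    median = !is.na(med) && med >= median_range[1] && med <= median_range[2],
    band = !is.na(frac) && frac >= min_fraction
  )
  structure(
    list(
      n_reference = n,
      median_intensity = med,
      fraction_in_band = frac,
      gates = gates,
      passed = all(gates),
      reasons = names(gates)[!gates]
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %s: n=%d, median=%.1f, fraction in band=%.3f%s\n",
    if (x$passed) "PASSED" else "FAILED", x$n_reference, x$median_intensity,
    x$fraction_in_band,
    if (x$passed) "" else paste0(" (failed: ", paste(x$reasons, collapse = ", "), ")")
  ))
  invisible(x)
}

#' Normalize total intensities by a reference median
#'
#' Divides each record's total intensity by the median intensity of the
#' haploid internal standard, yielding a `normalized_intensity` on the
#' C-value ladder: 2^0 = 1 corresponds to 1C, 2^1 to 2C, and so on. The
#' original intensity is retained.
#'
#' @param table a [feature_table()].
#' @param reference_median positive scalar (median reference intensity).
#' @return `feature_table` with a `normalized_intensity` column.
#' @export
normalize_by_reference <- function(table, reference_median) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(reference_median) || length(reference_median) != 1 ||
    is.na(reference_median) || reference_median <= 0) {
    stop("reference_median must be a positive scalar", call. = FALSE)
  }
  out <- table
  out$records$normalized_intensity <- table$records$total_intensity / reference_median
  out
}

#' Log2 feature matrix for mixture fitting
#'
#' Builds the (records x features) matrix of log2-transformed values the
#' Gaussian mixture is fitted to: genome doublings become +1 steps. Records
#' with any non-positive selected value cannot be log-scaled and are
#' dropped with a warning; the returned `index` attribute maps surviving
#' rows back to the input records.
#'
#' @param table a [feature_table()].
#' @param features ordered character vector of record field names.
#' @return numeric matrix with `colnames = features` and attribute `index`
#'   (integer vector of surviving record rows).
#' @export
log2_features <- function(table, features) {
  stopifnot(inherits(table, "feature_table"), length(features) >= 1)
  absent <- setdiff(features, names(table$records))
  if (length(absent) > 0) {
    stop("feature(s) not present: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  raw <- as.matrix(table$records[, features, drop = FALSE])
  ok <- rowSums(!is.finite(raw) | raw <= 0) == 0
  if (!all(ok)) {
    np_log(
      "log2_features", "warning",
      sprintf("dropping %d record(s) with non-positive feature values", sum(!ok))
    )
  }
  if (!any(ok)) stop("no records with all-positive feature values remain", call. = FALSE)
  X <- log2(raw[ok, , drop = FALSE])
  colnames(X) <- features
  attr(X, "index") <- which(ok)
  X
}
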