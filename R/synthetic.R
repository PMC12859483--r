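# Synthetic feature tables and label images with the doubling-cluster
# structure the method assumes: within each ploidy class, total intensity
# (and size) is log2-normal, and class means double between consecutive
# classes. Provides ground truth for every test and a no-download
# stand-in for deposited microscopy data.

#' Simulation configuration
#'
#' The stated world of the generator: class means double between
#' consecutive ploidy classes (`intensity_fold = 2`, `size_fold = 2`),
#' and within-class linear-scale spread is a coefficient of variation
#' (default 10%) of a log2-normal law — so the log2 features the pipeline
#' fits are exactly Gaussian.
#'
#' @param classes named numeric vector of class weights (must sum to 1),
#'   e.g. `c("2C" = 0.4, "4C" = 0.3, "8C" = 0.2, "16C" = 0.1)`.
#' @param n total nucleus count.
#' @param base_intensity mean total intensity of the lowest class
#'   (arbitrary units).
#' @param intensity_fold mean ratio between consecutive classes.
#' @param intensity_cv linear-scale coefficient of variation within a class.
#' @param base_size,size_fold,size_cv same three knobs for size
#'   (pixel/voxel count).
#' @param reference_n number of haploid-reference (spermatid-like) nuclei;
#'   their mean intensity is `base_intensity / intensity_fold` (one rung
#'   below the lowest class, i.e. 1C when the base class is 2C).
#' @param reference_cv reference population CV.
#' @param group group name stamped on the records.
#' @param spatial list for [simulate_label_image()]: `shape` (image dim,
#'   `c(y, x)` or `c(y, x, z)`), `margin` (minimum center spacing factor),
#'   `max_tries` (placement cap per nucleus).
#' @param seed integer seed; generation is deterministic given the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(classes = c("2C" = 0.4, "4C" = 0.3, "8C" = 0.2, "16C" = 0.1),
                       n = 500L, base_intensity = 6000, intensity_fold = 2,
                       intensity_cv = 0.1, base_size = 200, size_fold = 2,
                       size_cv = 0.1, reference_n = 0L, reference_cv = 0.1,
                       group = "synthetic", spatial = NULL, seed = 0L) {
  if (abs(sum(classes) - 1) > 1e-9) {
    stop("class weights must sum to 1 (got ", sum(classes), ")", call. = FALSE)
  }
  stopifnot(
    intensity_fold > 1, size_fold > 1, intensity_cv > 0, size_cv > 0,
    n >= 0, reference_n >= 0
  )
  structure(
    list(
      classes = classes, n = as.integer(n), base_intensity = base_intensity,
      intensity_fold = intensity_fold, intensity_cv = intensity_cv,
      base_size = base_size, size_fold = size_fold, size_cv = size_cv,
      reference_n = as.integer(reference_n), reference_cv = reference_cv,
      group = group, spatial = spatial, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# linear-scale CV -> sd of log2(value); exact for the log-normal law
cv_to_sd_log2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

# draw log2-normal values with E[log2 X] = log2(mean_linear) and the given CV
rlog2norm <- function(n, mean_linear, cv) {
  2^stats::rnorm(n, mean = log2(mean_linear), sd = cv_to_sd_log2(cv))
}

#' Simulate a feature table with doubling clusters
#'
#' Draws each nucleus's class from the configured weights, then its total
#' intensity and size from class-specific log2-normal laws whose log2
#' means sit `log2(fold)` apart. Reference (haploid-standard) nuclei are
#' appended with `user_label = "reference"` when requested.
#'
#' @param config a [sim_config()].
#' @return list with `table` (a [feature_table()]), `truth` (a
#'   `ground_truth`: per-nucleus true class, the true per-class
#'   proportions, log2 means and fold ladder).
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cl_names <- names(config$classes)
  n_cl <- length(cl_names)
  int_means <- config$base_intensity * config$intensity_fold^(seq_len(n_cl) - 1)
  size_means <- config$base_size * config$size_fold^(seq_len(n_cl) - 1)
  with_private_seed(config$seed, {
    cls <- sample.int(n_cl, config$n, replace = TRUE, prob = config$classes)
    intensity <- rlog2norm(config$n, int_means[cls], config$intensity_cv)
    size <- pmax(1, round(rlog2norm(config$n, size_means[cls], config$size_cv)))
    ref_intensity <- if (config$reference_n > 0) {
      rlog2norm(
        config$reference_n, config$base_intensity / config$intensity_fold,
        config$reference_cv
      )
    } else {
      numeric(0)
    }
    ref_size <- if (config$reference_n > 0) {
      pmax(1, round(rlog2norm(
        config$reference_n, config$base_size / config$size_fold, config$reference_cv
      )))
    } else {
      numeric(0)
    }
  })
  n_tot <- config$n + config$reference_n
  rec <- data.frame(
    object_id = seq_len(n_tot),
    total_intensity = c(intensity, ref_intensity),
    size = c(size, ref_size),
    user_label = c(rep("nucleus", config$n), rep("reference", config$reference_n)),
    group = rep(config$group, n_tot),
    stringsAsFactors = FALSE
  )
  truth <- structure(
    list(
      class = cl_names[cls],
      class_index = cls,
      proportions = as.numeric(table(factor(cls, levels = seq_len(n_cl)))) / max(1, config$n),
      class_names = cl_names,
      log2_intensity_means = log2(int_means),
      log2_size_means = log2(size_means),
      intensity_fold = config$intensity_fold,
      size_fold = config$size_fold,
      sd_log2_intensity = cv_to_sd_log2(config$intensity_cv),
      config = config
    ),
    class = "ground_truth"
  )
  list(
    table = feature_table(rec, dimensionality = if (is.null(config$spatial)) 2L else length(config$spatial$shape)),
    truth = truth
  )
}

#' Simulate a label image consistent with a feature table
#'
#' Places non-overlapping disks (2D) or spheres (3D) whose radii scale as
#' the square/cube root of each nucleus's size, fills them with noisy
#' per-voxel intensities, then measures total intensity, size and
#' variance of intensity directly from the image — so the emitted feature
#' table matches the raster exactly by construction.
#'
#' @param config a [sim_config()] with a `spatial` block.
#' @return list with `label_image`, `intensity_image` (numeric array),
#'   `table` (measured [feature_table()]), `truth`.
#' @export
simulate_label_image <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$spatial)) stop("config$spatial is required", call. = FALSE)
  shape <- config$spatial$shape
  nd <- length(shape)
  stopifnot(nd %in% c(2L, 3L))
  margin <- config$spatial$margin %||% 1.1
  max_tries <- config$spatial$max_tries %||% 200L
  sim <- simulate_feature_table(config)
  rec <- sim$table$records
  n_obj <- nrow(rec)
  radius <- if (nd == 2L) sqrt(rec$size / pi) else (3 * rec$size / (4 * pi))^(1 / 3)
  labels <- array(0L, dim = shape)
  intensity_img <- array(0, dim = shape)
  centers <- matrix(NA_real_, n_obj, nd)
  with_private_seed(config$seed + 1L, {
    for (i in seq_len(n_obj)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        ctr <- vapply(seq_len(nd), function(a) {
          stats::runif(1, min = radius[i] + 1, max = shape[a] - radius[i])
        }, numeric(1))
        if (any(ctr < radius[i]) || any(ctr > shape - radius[i])) next
        ok <- TRUE
        if (i > 1) {
          prev <- which(!is.na(centers[, 1]))
          if (length(prev) > 0) {
            dist <- sqrt(rowSums((centers[prev, , drop = FALSE] -
              matrix(ctr, length(prev), nd, byrow = TRUE))^2))
            ok <- all(dist > margin * (radius[i] + radius[prev]))
          }
        }
        if (ok) {
          centers[i, ] <- ctr
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(
          "could not place nucleus ", i, " after ", max_tries,
          " tries; use a larger image shape",
          call. = FALSE
        )
      }
    }
    # rasterize and fill with noisy voxel intensities
    for (i in seq_len(n_obj)) {
      lo <- pmax(1, floor(centers[i, ] - radius[i]))
      hi <- pmin(shape, ceiling(centers[i, ] + radius[i]))
      coords <- as.matrix(expand.grid(lapply(seq_len(nd), function(a) lo[a]:hi[a])))
      inside <- rowSums(sweep(coords, 2L, centers[i, ], "-")^2) <= radius[i]^2
      coords <- coords[inside, , drop = FALSE]
      if (nrow(coords) == 0) { # tiny nucleus: claim the nearest voxel
        coords <- matrix(round(centers[i, ]), 1L, nd)
      }
      k <- nrow(coords)
      mu <- rec$total_intensity[i] / k
      vox <- pmax(0, stats::rnorm(k, mean = mu, sd = 0.1 * mu))
      labels[coords] <- rec$object_id[i]
      intensity_img[coords] <- vox
    }
  })
  # measure the image back into the emitted feature table
  measured <- measure_labels(labels, intensity_img)
  m <- measured[match(rec$object_id, measured$object_id), ]
  rec$total_intensity <- m$total_intensity
  rec$size <- m$size
  rec$mean_intensity <- m$mean_intensity
  rec$variance_of_intensity <- m$variance_of_intensity
  for (a in seq_len(nd)) rec[[paste0("centroid_", a)]] <- m[[paste0("centroid_", a)]] - 1
  table <- feature_table(rec, dimensionality = nd)
  list(
    label_image = label_image(labels),
    intensity_image = intensity_img,
    table = table,
    truth = sim$truth
  )
}

#' Measure per-object features from a label + intensity image pair
#'
#' The reference accumulator used both by the simulator and as an oracle:
#' per label, the voxel count, summed intensity, mean, population variance
#' of voxel intensities and the centroid (1-based voxel index space).
#'
#' @param labels integer array (0 = background).
#' @param intensity numeric array, same shape.
#' @return data.frame sorted by `object_id`.
#' @export
measure_labels <- function(labels, intensity) {
  stopifnot(all(dim(labels) == dim(intensity)))
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0]
  nd <- length(dim(labels))
  coords <- arrayInd(which(labels != 0), dim(labels))
  vals <- intensity[labels != 0]
  labs <- labels[labels != 0]
  out <- data.frame(object_id = ids)
  out$size <- as.numeric(tapply(vals, labs, length)[as.character(ids)])
  out$total_intensity <- as.numeric(tapply(vals, labs, sum)[as.character(ids)])
  out$mean_intensity <- out$total_intensity / out$size
  out$variance_of_intensity <- as.numeric(
    tapply(vals, labs, function(v) mean((v - mean(v))^2))[as.character(ids)]
  )
  for (a in seq_len(nd)) {
    out[[paste0("centroid_", a)]] <- as.numeric(
      tapply(coords[, a], labs, mean)[as.character(ids)]
    )
  }
  out
}
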