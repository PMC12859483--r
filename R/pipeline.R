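# Configuration-driven composition of the whole workflow:
# read -> filter -> (QC + normalize) -> log2 -> model scan -> class map ->
# classify -> uncertainty -> summaries -> maps, with a reproducible run
# manifest.

#' Shipped per-system pipeline presets
#'
#' Three recipes are shipped as starting points:
#' \describe{
#'   \item{`arabidopsis_2d`}{3D segmentation; epidermal filter keeping
#'     variance of intensity at or above 2^8.3; 2D features (total
#'     intensity + size/volume); K scan 1..8; lowest component dropped as
#'     `<2C/Unclassified`.}
#'   \item{`drosophila_2d`}{2D segmentation; haploid-spermatid QC and
#'     normalization; 2D features (normalized intensity + projected
#'     area); K scan 1..5; open-top `>=16C` ladder with dropped lowest.}
#'   \item{`cardiomyocyte_2d`}{2D segmentation; hand-label selection of
#'     cardiomyocyte nuclei; 2D features; K scan 1..3; relative ladder
#'     2aC/4aC/8aC (base ploidy alpha unknown).}
#' }
#'
#' @param name preset name.
#' @return a config list for [run_pipeline()].
#' @export
preset_config <- function(name = c("arabidopsis_2d", "drosophila_2d", "cardiomyocyte_2d")) {
  name <- match.arg(name)
  base <- list(
    preset = name,
    dialect = list(),
    filters = list(),
    normalization = NULL,
    features = c("total_intensity", "size"),
    mixture = list(
      K_range = 1:8, families = c("spherical", "diagonal"),
      criterion = "bic", tol = NULL, max_iter = NULL, n_init = NULL,
      reg_covar = 1e-6
    ),
    ladder = list(base_class = "2C", drop_lowest = TRUE, open_top = FALSE),
    uncertainty = list(conf_threshold = 0.8, second_threshold = 0.2),
    map = list(palette = NULL),
    seed = 0L
  )
  switch(name,
    arabidopsis_2d = {
      base$filters <- list(
        list(
          op = "threshold", feature = "variance_of_intensity",
          cutoff = 2^8.3, keep = "above"
        )
      )
      base
    },
    drosophila_2d = {
      base$filters <- list(
        list(op = "select_label", exclude = list("incomplete"))
      )
      base$normalization <- list(
        reference_label = "reference",
        min_n = 10L, median_range = c(2000, 6000),
        band = c(0.5, 1.5), min_fraction = 0.9
      )
      base$features <- c("normalized_intensity", "size")
      base$mixture$K_range <- 1:5
      base$ladder <- list(base_class = "2C", drop_lowest = TRUE, open_top = TRUE)
      base
    },
    cardiomyocyte_2d = {
      base$filters <- list(
        list(op = "select_label", include = list("cardiomyocyte"))
      )
      base$mixture$K_range <- 1:3
      base$ladder <- list(
        base_class = "2αC", drop_lowest = FALSE, open_top = FALSE
      )
      base
    }
  )
}

#' Read a pipeline config from YAML or JSON
#'
#' @param path config file; format chosen by extension (`.yml`/`.yaml`
#'   or `.json`).
#' @return config list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$preset)) {
    base <- preset_config(cfg$preset)
    merged <- utils::modifyList(base, cfg)
    # the filter chain and ladder replace the preset's wholesale (an empty
    # chain must be able to clear the preset's filters)
    for (key in c("filters", "ladder")) {
      if (key %in% names(cfg)) merged[[key]] <- cfg[[key]]
    }
    cfg <- merged
  }
  cfg
}

apply_filters <- function(table, filters) {
  for (f in filters) {
    table <- switch(f$op,
      threshold = threshold_filter(table, f$feature, f$cutoff, f$keep %||% "above"),
      select_label = select_by_label(
        table,
        exclude = as.character(unlist(f$exclude %||% character(0))),
        include = if (is.null(f$include)) NULL else as.character(unlist(f$include))
      ),
      stop("unknown filter op '", f$op, "'", call. = FALSE)
    )
  }
  table
}

#' Run the full ploidy-inference pipeline
#'
#' Executes every stage on a feature table (given in-memory or as a CSV
#' path in `config$input`), optionally renders a spatial ploidy map when
#' a label image is supplied, writes all artifacts under
#' `config$output_dir` (assignment CSV, summary JSON, model JSON, map
#' TIFF/PNG, manifest JSON) and returns the manifest. All warnings
#' raised along the way (QC failures, AIC/BIC disagreement, monotonic
#' criterion) are recorded in the manifest.
#'
#' @param config config list (see [preset_config()] for shape); only
#'   `features`, `mixture` and `ladder` are strictly required.
#' @param table optional [feature_table()] overriding `config$input`.
#' @param label_img optional [label_image()] (or `config$label_input`
#'   path) for map rendering.
#' @return the run manifest (list), invisibly; artifacts on disk when
#'   `config$output_dir` is set.
#' @export
run_pipeline <- function(config, table = NULL, label_img = NULL) {
  np_log_start()
  stage <- "read"
  result <- tryCatch(
    {
      if (is.null(table)) {
        if (is.null(config$input)) stop("no input table (config$input or `table`)", call. = FALSE)
        dialect <- do.call(ilastik_dialect, config$dialect %||% list())
        table <- read_feature_table(config$input, dialect = dialect)
      }
      if (is.null(label_img) && !is.null(config$label_input)) {
        label_img <- read_label_image(config$label_input)
      }
      if (n_records(table) == 0) stop("input table has no records", call. = FALSE)

      stage <- "filter"
      reference_tbl <- NULL
      norm <- config$normalization
      if (!is.null(norm)) {
        reference_tbl <- select_by_label(table, include = norm$reference_label)
        table <- select_by_label(table, exclude = norm$reference_label)
      }
      table <- apply_filters(table, config$filters %||% list())
      if (n_records(table) == 0) stop("no records left after filtering", call. = FALSE)

      stage <- "normalize"
      qc <- NULL
      if (!is.null(norm)) {
        ref_int <- reference_tbl$records$total_intensity
        qc <- reference_qc(
          ref_int,
          min_n = norm$min_n %||% 10L,
          median_range = norm$median_range %||% c(2000, 6000),
          band = norm$band %||% c(0.5, 1.5),
          min_fraction = norm$min_fraction %||% 0.9
        )
        if (!qc$passed) {
          stop(
            "reference QC failed (", paste(qc$reasons, collapse = ", "),
            "); experiment not considered",
            call. = FALSE
          )
        }
        table <- normalize_by_reference(table, qc$median_intensity)
      }

      stage <- "log2"
      X <- log2_features(table, config$features)
      idx <- attr(X, "index")

      stage <- "model_scan"
      mix <- config$mixture
      params <- fit_params(
        dims = ncol(X),
        tol = mix$tol, max_iter = mix$max_iter, n_init = mix$n_init,
        seed = config$seed %||% 0L, reg_covar = mix$reg_covar %||% 1e-6
      )
      scan <- model_scan(
        X,
        K_range = mix$K_range,
        families = mix$families %||% c("spherical", "diagonal"),
        params = params
      )
      criterion <- mix$criterion %||% "bic"
      model <- best_model(scan, criterion)

      stage <- "classify"
      lad <- config$ladder
      anchor <- lad$anchor_feature %||% config$features[1]
      cmap <- map_components_to_classes(
        model,
        base_class = lad$base_class %||% "2C",
        drop_lowest = isTRUE(lad$drop_lowest),
        open_top = isTRUE(lad$open_top),
        anchor_feature = if (anchor %in% colnames(X)) anchor else 1L
      )
      post <- posteriors(model, X)
      unc <- config$uncertainty %||% list()
      assignment <- classify(
        post, cmap,
        object_ids = table$records$object_id[idx], index = idx,
        conf_threshold = unc$conf_threshold %||% 0.8,
        second_threshold = unc$second_threshold %||% 0.2
      )

      stage <- "summarize"
      summary_cs <- uncertainty_intervals(
        assignment,
        conf_threshold = unc$conf_threshold %||% 0.8,
        second_threshold = unc$second_threshold %||% 0.2
      )
      props <- class_proportions(assignment, table$records$group[idx])
      stats <- class_means_and_folds(table, assignment, config$features)

      stage <- "render"
      pm <- NULL
      if (!is.null(label_img)) {
        pm <- render_ploidy_map(label_img, assignment, config$map$palette)
      }

      stage <- "write"
      outputs <- list()
      if (!is.null(config$output_dir)) {
        dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
        p <- function(f) file.path(config$output_dir, f)
        write_assignments(table, assignment, p("assignments.csv"))
        write_model(model, p("model.json"))
        summary_doc <- list(
          selection = list(
            criterion = criterion,
            best_by_aic = as.list(scan$best_by_aic),
            best_by_bic = as.list(scan$best_by_bic),
            K = model$K, family = model$family,
            aic = model$aic, bic = model$bic,
            log_likelihood = model$log_likelihood, n = model$n, d = model$d
          ),
          classes = cmap$class_names[cmap$order],
          proportions = props,
          intervals = as.data.frame(summary_cs),
          means = as.data.frame(as.table(stats$means), stringsAsFactors = FALSE),
          folds = stats$folds
        )
        jsonlite::write_json(summary_doc, p("summary.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
        )
        outputs$assignments <- p("assignments.csv")
        outputs$model <- p("model.json")
        outputs$summary <- p("summary.json")
        if (!is.null(pm)) {
          write_ploidy_map(pm, p("ploidy_map.tif"), p("ploidy_map.png"), p("palette.json"))
          outputs$map_raster <- p("ploidy_map.tif")
          outputs$map_png <- p("ploidy_map.png")
        }
      }
      list(
        scan = scan, model = model, class_map = cmap, assignment = assignment,
        class_summary = summary_cs, proportions = props, class_stats = stats,
        qc = qc, ploidy_map = pm, outputs = outputs
      )
    },
    error = function(e) {
      np_log_drain()
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  log <- np_log_drain()
  manifest <- list(
    package = "nucploidy",
    version = as.character(utils::packageVersion("nucploidy")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed %||% 0L,
    config = config,
    config_hash = digest::digest(config),
    warnings = Filter(function(r) r$level == "warning", log),
    log = log,
    outputs = result$outputs
  )
  if (!is.null(config$output_dir)) {
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null", force = TRUE
    )
  }
  result$manifest <- manifest
  invisible(result)
}

#' Re-run a pipeline from a written manifest
#'
#' The manifest embeds the full config (and seed), so a run can be
#' reproduced bit-identically from it alone.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param output_dir optional new output directory (defaults to the one
#'   recorded in the manifest).
#' @return see [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, output_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  if (!is.null(cfg$mixture$K_range)) cfg$mixture$K_range <- as.integer(cfg$mixture$K_range)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  run_pipeline(cfg)
}
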