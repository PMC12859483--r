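# Shared fixture builders: everything is generated in code at test time.

# tiny feature table built by hand
make_table <- function(n = 10, seed = 1) {
  set.seed(seed)
  feature_table(data.frame(
    object_id = seq_len(n),
    total_intensity = stats::runif(n, 100, 1000),
    size = sample(50:200, n, replace = TRUE),
    variance_of_intensity = stats::runif(n, 0, 600),
    user_label = rep_len(c("nucleus", "nucleus", "nucleus", "nucleus", "incomplete"), n),
    group = rep_len(c("g1", "g2"), n),
    stringsAsFactors = FALSE
  ))
}

# a hand-built mixture model (no fitting) for class-map tests
fake_model_1d <- function(means, weights = NULL, sd = 0.1) {
  K <- length(means)
  structure(
    list(
      K = K, family = "spherical",
      weights = weights %||% rep(1 / K, K),
      means = matrix(sort(means), ncol = 1),
      covariances = rep(sd^2, K),
      log_likelihood = 0, n = 100L, d = n_free_parameters(K, 1, "spherical"),
      aic = 0, bic = 0, converged = TRUE, n_iter = 1L, trace = 0,
      feature_names = "total_intensity",
      params = fit_params(1)
    ),
    class = "mixture_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ilastik-style CSV fixture on disk; returns the path
write_ilastik_csv <- function(path, n = 5, intensity_col = "Total Intensity_0",
                              seed = 2, extra = NULL) {
  set.seed(seed)
  df <- data.frame(
    check.names = FALSE,
    `object_id` = seq_len(n),
    `Size in pixels` = sample(50:150, n, replace = TRUE),
    `User Labels` = rep_len(c("nucleus", "incomplete"), n),
    stringsAsFactors = FALSE
  )
  df[[intensity_col]] <- round(stats::runif(n, 500, 5000), 3)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# quick fitted assignment on clearly separated synthetic data
make_assignment <- function(n = 60, K = 2, seed = 5) {
  cfg <- sim_config(
    classes = stats::setNames(rep(1 / K, K), ladder_k(K)),
    n = n, intensity_cv = 0.05, seed = seed
  )
  sim <- simulate_feature_table(cfg)
  X <- log2_features(sim$table, "total_intensity")
  m <- fit_mixture(X, K, "spherical", fit_params(1, n_init = 2, max_iter = 200))
  cmap <- map_components_to_classes(m, "2C")
  a <- classify(posteriors(m, X), cmap,
    object_ids = sim$table$records$object_id[attr(X, "index")],
    index = attr(X, "index")
  )
  list(table = sim$table, truth = sim$truth, model = m, map = cmap, assignment = a)
}

ladder_k <- function(K) paste0(2^(seq_len(K)), "C")
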