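test_that("K = 1 fits reduce to closed-form moments", {
  set.seed(2)
  X <- cbind(stats::rnorm(80, 3, 0.5), stats::rnorm(80, 7, 1.2))
  p <- fit_params(2, n_init = 1, max_iter = 50, tol = 1e-8)
  m <- fit_mixture(X, 1, "spherical", p)
  expect_equal(m$weights, 1)
  expect_equal(as.numeric(m$means), colMeans(X), tolerance = 1e-10)
  pop_var <- colMeans(sweep(X, 2, colMeans(X))^2)
  expect_equal(m$covariances, mean(pop_var) + p$reg_covar, tolerance = 1e-8)
  md <- fit_mixture(X, 1, "diagonal", p)
  expect_equal(as.numeric(md$covariances), pop_var + p$reg_covar, tolerance = 1e-8)
})

test_that("information criteria and d-counting follow the definitions", {
  ic <- information_criteria(0, 2, 1)
  expect_equal(ic[["aic"]], 4)
  expect_equal(ic[["bic"]], 0) # ln 1 = 0
  expect_equal(n_free_parameters(3, 2, "spherical"), 11)
  # bic - aic = (ln n - 2) d, so bic > aic iff n > e^2
  for (n in c(2, 7, 8, 100)) {
    ic <- information_criteria(-12.3, 5, n)
    expect_equal(ic[["bic"]] - ic[["aic"]], (log(n) - 2) * 5)
    expect_equal(ic[["bic"]] > ic[["aic"]], n > exp(2))
  }
})

test_that("1D parameter recovery at two components", {
  set.seed(17)
  X <- matrix(c(stats::rnorm(200, 1.0, 0.1), stats::rnorm(200, 2.0, 0.1)), ncol = 1)
  m <- fit_mixture(X, 2, "spherical", fit_params(1, n_init = 5, seed = 17))
  expect_equal(sort(as.numeric(m$means)), c(1.0, 2.0), tolerance = 0.05)
  expect_equal(sort(m$weights), c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(m$weights), 1, tolerance = 1e-8)
})

test_that("fits are bit-reproducible under a fixed seed", {
  set.seed(3)
  X <- matrix(c(stats::rnorm(60, 0, 1), stats::rnorm(60, 4, 1)), ncol = 1)
  p <- fit_params(1, n_init = 3, seed = 42, max_iter = 200)
  m1 <- fit_mixture(X, 2, "diagonal", p)
  m2 <- fit_mixture(X, 2, "diagonal", p)
  expect_identical(m1$means, m2$means)
  expect_identical(m1$covariances, m2$covariances)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$log_likelihood, m2$log_likelihood)
})

test_that("stored criteria always reproduce from (logL, d, n)", {
  set.seed(5)
  X <- cbind(stats::rnorm(50), stats::rnorm(50))
  for (fam in c("spherical", "diagonal", "full", "tied")) {
    m <- fit_mixture(X, 2, fam, fit_params(2, n_init = 1, max_iter = 100, tol = 1e-6))
    ic <- information_criteria(m$log_likelihood, m$d, m$n)
    expect_identical(m$aic, ic[["aic"]])
    expect_identical(m$bic, ic[["bic"]])
    expect_equal(m$d, n_free_parameters(2, 2, fam))
  }
})

test_that("posteriors match the naive density oracle", {
  set.seed(9)
  X <- cbind(stats::rnorm(100, 1, 0.6), stats::rnorm(100, 2, 0.8))
  m <- fit_mixture(X, 3, "diagonal", fit_params(2, n_init = 2, max_iter = 100, tol = 1e-6))
  P <- posteriors(m, X)
  expect_equal(rowSums(P), rep(1, 100), tolerance = 1e-8)
  # brute force: w_k * prod_d dnorm / sum_j ...
  naive <- matrix(0, 100, 3)
  for (i in 1:100) {
    for (k in 1:3) {
      dens <- prod(stats::dnorm(X[i, ], m$means[k, ], sqrt(m$covariances[k, ])))
      naive[i, k] <- m$weights[k] * dens
    }
    naive[i, ] <- naive[i, ] / sum(naive[i, ])
  }
  expect_equal(P, naive, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("posterior limit cases: separation and symmetry", {
  m <- fake_model_1d(c(0, 20), sd = 1) # 20 sd apart
  P <- posteriors(m, matrix(0))
  expect_gt(max(P), 1 - 1e-10)
  m2 <- fake_model_1d(c(1, 1), sd = 0.5)
  P2 <- posteriors(m2, matrix(stats::rnorm(10), ncol = 1))
  expect_equal(P2, matrix(0.5, 10, 2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(posteriors(m, matrix(0, 1, 2)), "dimension mismatch")
})

test_that("model_scan recovers the truth and handles edge grids", {
  set.seed(23)
  X <- cbind(
    c(stats::rnorm(300, 1, 0.12), stats::rnorm(300, 2, 0.12), stats::rnorm(300, 3, 0.12)),
    c(stats::rnorm(300, 1, 0.12), stats::rnorm(300, 2, 0.12), stats::rnorm(300, 3, 0.12))
  )
  p <- fit_params(2, n_init = 2, max_iter = 300, tol = 1e-5, seed = 1)
  sc <- suppressWarnings(model_scan(X, 1:6, c("spherical", "diagonal"), p))
  expect_equal(sc$best_by_aic$K, 3)
  expect_equal(sc$best_by_bic$K, 3)

  sc1 <- model_scan(X[1:50, ], 1, "spherical", p)
  expect_equal(sc1$best_by_aic$K, 1)
  expect_equal(sc1$best_by_bic$K, 1)
  expect_error(model_scan(X[1:5, ], 1:10, "spherical", p), "below the number")
})

test_that("row permutation leaves the best model invariant up to relabeling", {
  set.seed(33)
  X <- matrix(c(stats::rnorm(150, 0, 0.2), stats::rnorm(150, 3, 0.2)), ncol = 1)
  p <- fit_params(1, n_init = 3, seed = 7, max_iter = 300)
  m1 <- fit_mixture(X, 2, "spherical", p)
  m2 <- fit_mixture(X[sample(nrow(X)), , drop = FALSE], 2, "spherical", p)
  o1 <- order(m1$means[, 1])
  o2 <- order(m2$means[, 1])
  expect_equal(m1$means[o1, ], m2$means[o2, ], tolerance = 1e-6)
  expect_equal(m1$weights[o1], m2$weights[o2], tolerance = 1e-6)
})

test_that("degenerate inputs fail loudly", {
  X <- matrix(stats::rnorm(4), ncol = 1)
  expect_error(fit_mixture(X, 4, "spherical", fit_params(1, n_init = 1)), "more samples")
})

test_that("model serialization round-trips through JSON", {
  set.seed(13)
  X <- cbind(stats::rnorm(60, 1, 0.3), stats::rnorm(60, 2, 0.4))
  colnames(X) <- c("total_intensity", "size")
  for (fam in c("spherical", "full")) {
    m <- fit_mixture(X, 2, fam, fit_params(2, n_init = 1, max_iter = 100, tol = 1e-6))
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path)
    m2 <- read_model(path)
    expect_equal(m2$means, m$means, ignore_attr = TRUE)
    expect_equal(as.numeric(m2$covariances), as.numeric(m$covariances))
    expect_equal(m2$log_likelihood, m$log_likelihood)
    expect_equal(posteriors(m2, X), posteriors(m, X), tolerance = 1e-12)
  }
})
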