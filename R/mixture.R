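# Gaussian mixture fitting on log2 feature matrices.
#
# The expectation-maximization loop, the four covariance families
# (spherical, diagonal, full, tied), parameter counting and AIC/BIC are
# implemented here so that the log-likelihood trace and the free-parameter
# count are directly inspectable and testable.

FAMILIES <- c("spherical", "diagonal", "full", "tied")

#' Fitting hyperparameters for mixture estimation
#'
#' Defaults follow the feature dimensionality: 1D fits use a tolerance of
#' 1e-5 on the per-sample mean log-likelihood improvement, at most 10000
#' iterations and 20 random restarts; 2D (and higher) fits use 1e-7, 5000
#' and 500. Initialization is k-means++-style seeding of responsibilities.
#'
#' @param dims feature dimensionality the defaults should target.
#' @param tol convergence tolerance on the change of the per-sample mean
#'   log-likelihood between EM iterations.
#' @param max_iter EM iteration cap per restart.
#' @param n_init number of random restarts; the best final likelihood wins.
#' @param seed integer seed; fits are bit-reproducible given the same seed.
#' @param reg_covar small non-negative value added to covariance diagonals
#'   (log2 units squared) to prevent degeneracy.
#' @param init_method currently only `"kmeans++"`.
#' @return a `fit_params` list.
#' @export
fit_params <- function(dims = 1L, tol = NULL, max_iter = NULL, n_init = NULL,
                       seed = 0L, reg_covar = 1e-6, init_method = "kmeans++") {
  if (is.null(tol)) tol <- if (dims >= 2) 1e-7 else 1e-5
  if (is.null(max_iter)) max_iter <- if (dims >= 2) 5000L else 10000L
  if (is.null(n_init)) n_init <- if (dims >= 2) 500L else 20L
  stopifnot(tol > 0, max_iter >= 1, n_init >= 1, reg_covar >= 0)
  structure(
    list(
      tol = tol, max_iter = as.integer(max_iter), n_init = as.integer(n_init),
      seed = as.integer(seed), reg_covar = reg_covar, init_method = init_method
    ),
    class = "fit_params"
  )
}

#' Free-parameter count of a mixture model
#'
#' `(K - 1)` weights + `K * D` means + the covariance parameters of the
#' family: `K` (spherical), `K * D` (diagonal), `K * D * (D + 1) / 2`
#' (full) or `D * (D + 1) / 2` (tied).
#'
#' @param K component count.
#' @param D feature dimensionality.
#' @param family covariance family.
#' @return integer parameter count `d`.
#' @export
n_free_parameters <- function(K, D, family = FAMILIES) {
  family <- match.arg(family)
  cov_d <- switch(family,
    spherical = K,
    diagonal = K * D,
    full = K * D * (D + 1) / 2,
    tied = D * (D + 1) / 2
  )
  as.integer((K - 1) + K * D + cov_d)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 log(L) + 2 d` and `BIC = -2 log(L) + ln(n) d`, with `log(L)`
#' the maximized total log-likelihood (natural log), `d` the free-parameter
#' count and `n` the number of samples.
#'
#' @param log_likelihood maximized total log-likelihood.
#' @param d free-parameter count (>= 1).
#' @param n sample count (>= 1).
#' @return named numeric vector `c(aic = ..., bic = ...)`.
#' @export
information_criteria <- function(log_likelihood, d, n) {
  stopifnot(n >= 1, d >= 1)
  c(
    aic = -2 * log_likelihood + 2 * d,
    bic = -2 * log_likelihood + log(n) * d
  )
}

# per-component log density matrix (n x K)
component_log_density <- function(X, means, covariances, family) {
  n <- nrow(X)
  D <- ncol(X)
  K <- nrow(means)
  out <- matrix(0, n, K)
  cst <- D * log(2 * pi)
  for (k in seq_len(K)) {
    xc <- sweep(X, 2L, means[k, ], "-")
    if (family == "spherical") {
      v <- covariances[k]
      out[, k] <- -0.5 * (cst + D * log(v) + rowSums(xc^2) / v)
    } else if (family == "diagonal") {
      v <- covariances[k, ]
      out[, k] <- -0.5 * (cst + sum(log(v)) + rowSums(sweep(xc^2, 2L, v, "/")))
    } else {
      S <- if (family == "full") covariances[, , k] else covariances
      L <- chol(S) # upper triangular, S = t(L) %*% L
      logdet <- 2 * sum(log(diag(L)))
      w <- backsolve(L, t(xc), transpose = TRUE)
      out[, k] <- -0.5 * (cst + logdet + colSums(w^2))
    }
  }
  out
}

m_step <- function(X, R, family, reg_covar) {
  n <- nrow(X)
  D <- ncol(X)
  K <- ncol(R)
  Nk <- colSums(R)
  if (any(Nk < 1e-8)) {
    return(NULL) # collapsed component; caller restarts
  }
  weights <- Nk / n
  means <- (t(R) %*% X) / Nk
  covariances <- switch(family,
    spherical = {
      v <- vapply(seq_len(K), function(k) {
        xc <- sweep(X, 2L, means[k, ], "-")
        sum(R[, k] * rowSums(xc^2)) / (Nk[k] * D)
      }, numeric(1))
      v + reg_covar
    },
    diagonal = {
      v <- matrix(0, K, D)
      for (k in seq_len(K)) {
        xc <- sweep(X, 2L, means[k, ], "-")
        v[k, ] <- colSums(R[, k] * xc^2) / Nk[k]
      }
      v + reg_covar
    },
    full = {
      a <- array(0, dim = c(D, D, K))
      for (k in seq_len(K)) {
        xc <- sweep(X, 2L, means[k, ], "-")
        a[, , k] <- crossprod(xc * sqrt(R[, k])) / Nk[k] + diag(reg_covar, D)
      }
      a
    },
    tied = {
      S <- matrix(0, D, D)
      for (k in seq_len(K)) {
        xc <- sweep(X, 2L, means[k, ], "-")
        S <- S + crossprod(xc * sqrt(R[, k]))
      }
      S / n + diag(reg_covar, D)
    }
  )
  list(weights = weights, means = means, covariances = covariances)
}

# greedy k-means++ center seeding (Arthur & Vassilvitskii, with the
# customary 2 + log(k) local trials per step)
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (K > 1) {
    n_trials <- 2L + as.integer(floor(log(K)))
    d2 <- rowSums(sweep(X, 2L, centers[1, ], "-")^2)
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      cand <- sample.int(n, min(n_trials, n), prob = p)
      best_pot <- Inf
      best_d2 <- NULL
      best_i <- cand[1L]
      for (ci in cand) {
        nd2 <- pmin(d2, rowSums(sweep(X, 2L, X[ci, ], "-")^2))
        pot <- sum(nd2)
        if (pot < best_pot) {
          best_pot <- pot
          best_d2 <- nd2
          best_i <- ci
        }
      }
      centers[k, ] <- X[best_i, ]
      d2 <- best_d2
    }
  }
  centers
}

em_single_run <- function(X, K, family, params) {
  n <- nrow(X)
  centers <- kmeanspp_centers(X, K)
  # hard-assign to nearest center => one-hot responsibilities
  d2 <- vapply(
    seq_len(K), function(k) rowSums(sweep(X, 2L, centers[k, ], "-")^2),
    numeric(n)
  )
  if (n == 1L) d2 <- matrix(d2, nrow = 1L)
  assign0 <- max.col(-d2, ties.method = "first")
  R <- matrix(0, n, K)
  R[cbind(seq_len(n), assign0)] <- 1
  theta <- m_step(X, R, family, params$reg_covar)
  if (is.null(theta)) {
    return(NULL)
  }
  prev_avg <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    logphi <- component_log_density(X, theta$means, theta$covariances, family)
    wlog <- sweep(logphi, 2L, log(theta$weights), "+")
    lse <- logsumexp_rows(wlog)
    ll <- sum(lse)
    trace <- c(trace, ll)
    avg <- ll / n
    if (is.finite(prev_avg) && abs(avg - prev_avg) < params$tol) {
      converged <- TRUE
      break
    }
    if (iter >= params$max_iter) break
    prev_avg <- avg
    R <- exp(wlog - lse)
    theta <- m_step(X, R, family, params$reg_covar)
    if (is.null(theta)) {
      return(NULL)
    }
  }
  list(theta = theta, log_likelihood = ll, trace = trace, converged = converged, n_iter = iter)
}

#' Fit a K-component Gaussian mixture by expectation-maximization
#'
#' Runs `params$n_init` restarts (k-means++ seeding, hard initial
#' assignment, then EM) and keeps the restart with the highest final
#' log-likelihood. Within a restart the total log-likelihood is
#' non-decreasing over iterations; the trace of the winning restart is
#' stored in the returned model for inspection.
#'
#' @param X numeric matrix (n x D) of log2-scaled features; column names
#'   are recorded as `feature_names`.
#' @param K component count (`n > K` required).
#' @param family covariance family: `"spherical"`, `"diagonal"`, `"full"`
#'   or `"tied"`.
#' @param params a [fit_params()] list.
#' @return a `mixture_model` with weights, means (K x D), family-shaped
#'   covariances, `log_likelihood`, `d`, `n`, `aic`, `bic`, `converged`,
#'   `trace` and `params`.
#' @export
fit_mixture <- function(X, K, family = FAMILIES, params = fit_params(ncol(X))) {
  family <- match.arg(family)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  D <- ncol(X)
  if (n <= K) stop("need more samples (", n, ") than components (", K, ")", call. = FALSE)
  best <- NULL
  n_collapsed <- 0L
  with_private_seed(params$seed, {
    for (r in seq_len(params$n_init)) {
      run <- em_single_run(X, K, family, params)
      if (is.null(run)) {
        n_collapsed <- n_collapsed + 1L
        next
      }
      if (is.null(best) || run$log_likelihood > best$log_likelihood) best <- run
    }
  })
  if (is.null(best)) {
    stop(
      "all ", params$n_init, " restarts collapsed a component; ",
      "reduce K or increase reg_covar",
      call. = FALSE
    )
  }
  d <- n_free_parameters(K, D, family)
  ic <- information_criteria(best$log_likelihood, d, n)
  structure(
    list(
      K = as.integer(K), family = family,
      weights = as.numeric(best$theta$weights),
      means = best$theta$means,
      covariances = best$theta$covariances,
      log_likelihood = best$log_likelihood,
      n = n, d = d, aic = ic[["aic"]], bic = ic[["bic"]],
      converged = best$converged, n_iter = best$n_iter,
      trace = best$trace,
      n_collapsed_restarts = n_collapsed,
      feature_names = colnames(X),
      params = params
    ),
    class = "mixture_model"
  )
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf(
    "<mixture_model> K=%d, family=%s, D=%d, n=%d: logL=%.3f, AIC=%.2f, BIC=%.2f%s\n",
    x$K, x$family, ncol(x$means), x$n, x$log_likelihood, x$aic, x$bic,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Posterior responsibilities of a fitted mixture
#'
#' Row m holds the probability that sample m was generated by each
#' component, `w_k phi_k(x_m) / sum_j w_j phi_j(x_m)`; rows sum to 1.
#'
#' @param model a `mixture_model`.
#' @param X matrix whose columns match the model's `feature_names`.
#' @return n x K matrix of responsibilities.
#' @export
posteriors <- function(model, X) {
  stopifnot(inherits(model, "mixture_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$means)) {
    stop(
      "feature dimension mismatch: model has ", ncol(model$means),
      ", data has ", ncol(X),
      call. = FALSE
    )
  }
  if (!is.null(model$feature_names) && !is.null(colnames(X)) &&
    !identical(colnames(X), model$feature_names)) {
    stop(
      "feature names mismatch: model was fitted on (",
      paste(model$feature_names, collapse = ", "), ")",
      call. = FALSE
    )
  }
  logphi <- component_log_density(X, model$means, model$covariances, model$family)
  wlog <- sweep(logphi, 2L, log(model$weights), "+")
  exp(wlog - logsumexp_rows(wlog))
}

#' Scan component counts and covariance families
#'
#' Fits every (K, family) pair on the grid with identical parameters and
#' locates the AIC- and BIC-optimal cells. Ties break toward smaller K,
#' then family order spherical < diagonal < full < tied (parsimony first).
#' When a criterion decreases strictly across the whole scanned K range
#' (no interior minimum), its monotonic flag is set and a warning is
#' logged: the chosen K is then only a ceiling assumption.
#'
#' @param X log2 feature matrix.
#' @param K_range integer vector of component counts (all `< nrow(X)`).
#' @param families subset of the covariance families.
#' @param params shared [fit_params()].
#' @return a `model_scan` object: `grid` (data.frame of K, family, aic,
#'   bic, converged, failed), `fits` (list of `mixture_model`),
#'   `best_by_aic`, `best_by_bic` (rows of `grid`), `monotonic_aic`,
#'   `monotonic_bic`.
#' @export
model_scan <- function(X, K_range, families = c("spherical", "diagonal"),
                       params = fit_params(ncol(X))) {
  stopifnot(length(K_range) >= 1)
  families <- match.arg(families, FAMILIES, several.ok = TRUE)
  X <- as.matrix(X)
  if (max(K_range) >= nrow(X)) {
    stop("max(K_range) must be below the number of samples", call. = FALSE)
  }
  grid <- expand.grid(
    K = sort(unique(as.integer(K_range))),
    family = factor(families, levels = FAMILIES),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$K, as.integer(grid$family)), , drop = FALSE]
  rownames(grid) <- NULL
  fits <- vector("list", nrow(grid))
  grid$aic <- NA_real_
  grid$bic <- NA_real_
  grid$converged <- NA
  grid$failed <- FALSE
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      fit_mixture(X, grid$K[i], as.character(grid$family[i]), params),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      grid$failed[i] <- TRUE
      np_log("model_scan", "warning", sprintf(
        "fit K=%d family=%s failed: %s", grid$K[i], grid$family[i], conditionMessage(fit)
      ))
    } else {
      fits[[i]] <- fit
      grid$aic[i] <- fit$aic
      grid$bic[i] <- fit$bic
      grid$converged[i] <- fit$converged
    }
  }
  if (all(grid$failed)) stop("every (K, family) fit failed", call. = FALSE)
  pick <- function(crit) {
    ok <- which(!grid$failed)
    v <- grid[[crit]][ok]
    # ties: smaller K first, then family order (grid is sorted that way)
    ok[order(v, grid$K[ok], as.integer(grid$family[ok]))[1L]]
  }
  i_aic <- pick("aic")
  i_bic <- pick("bic")
  monotone <- function(crit) {
    ks <- sort(unique(grid$K))
    if (length(ks) < 2) {
      return(FALSE)
    }
    curve <- vapply(ks, function(k) {
      v <- grid[[crit]][grid$K == k & !grid$failed]
      if (length(v) == 0) NA_real_ else min(v)
    }, numeric(1))
    all(!is.na(curve)) && all(diff(curve) < 0)
  }
  mono_aic <- monotone("aic")
  mono_bic <- monotone("bic")
  if (mono_aic || mono_bic) {
    np_log("model_scan", "warning", paste0(
      "criterion decreases monotonically over the scanned K range (",
      paste(c("AIC", "BIC")[c(mono_aic, mono_bic)], collapse = ", "),
      "); the selected K is a ceiling assumption, not an interior optimum"
    ))
  }
  if (grid$K[i_aic] != grid$K[i_bic] || grid$family[i_aic] != grid$family[i_bic]) {
    np_log("model_scan", "warning", sprintf(
      "AIC and BIC disagree: AIC -> K=%d/%s, BIC -> K=%d/%s",
      grid$K[i_aic], grid$family[i_aic], grid$K[i_bic], grid$family[i_bic]
    ))
  }
  structure(
    list(
      grid = grid, fits = fits,
      best_by_aic = grid[i_aic, c("K", "family")],
      best_by_bic = grid[i_bic, c("K", "family")],
      best_fit_aic = fits[[i_aic]],
      best_fit_bic = fits[[i_bic]],
      monotonic_aic = mono_aic, monotonic_bic = mono_bic
    ),
    class = "model_scan"
  )
}

#' @export
print.model_scan <- function(x, ...) {
  cat(sprintf(
    "<model_scan> %d fits; best AIC: K=%d/%s; best BIC: K=%d/%s\n",
    sum(!x$grid$failed), x$best_by_aic$K, x$best_by_aic$family,
    x$best_by_bic$K, x$best_by_bic$family
  ))
  invisible(x)
}

#' Select the best fit from a scan
#' @param scan a `model_scan`.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return the winning `mixture_model`.
#' @export
best_model <- function(scan, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  if (criterion == "bic") scan$best_fit_bic else scan$best_fit_aic
}

#' Serialize a fitted mixture model to JSON
#'
#' @param model a `mixture_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mixture_model"))
  doc <- list(
    K = model$K, family = model$family, weights = model$weights,
    means = model$means,
    covariances = as.numeric(model$covariances),
    covariance_dim = dim(model$covariances) %||% length(model$covariances),
    log_likelihood = model$log_likelihood, n = model$n, d = model$d,
    aic = model$aic, bic = model$bic, converged = model$converged,
    n_iter = model$n_iter, feature_names = model$feature_names,
    params = unclass(model$params)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reload a mixture model written by [write_model()]
#' @param path JSON path.
#' @return a `mixture_model` (without the fitting trace).
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  D <- length(doc$feature_names %||% seq_len(ncol(as.matrix(doc$means))))
  means <- matrix(as.numeric(unlist(doc$means)), nrow = doc$K)
  covs <- as.numeric(doc$covariances)
  cd <- as.integer(doc$covariance_dim)
  if (length(cd) > 1) dim(covs) <- cd
  structure(
    list(
      K = as.integer(doc$K), family = doc$family, weights = as.numeric(doc$weights),
      means = means, covariances = covs,
      log_likelihood = doc$log_likelihood, n = as.integer(doc$n),
      d = as.integer(doc$d), aic = doc$aic, bic = doc$bic,
      converged = doc$converged, n_iter = doc$n_iter, trace = NULL,
      feature_names = doc$feature_names,
      params = structure(doc$params, class = "fit_params")
    ),
    class = "mixture_model"
  )
}
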