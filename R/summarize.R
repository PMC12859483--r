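# Per-group ploidy proportions, per-class feature means with fold
# increases, and the two-sample Cramer-von Mises comparison used to judge
# image-based ploidy distributions against flow cytometry.

#' Per-group ploidy class proportions
#'
#' @param assignment a [classify()] result.
#' @param groups character vector aligned with the assignment rows (e.g.
#'   the `group` column of the source records at the assignment's index).
#' @return data.frame with one row per (group, class): `count`,
#'   `proportion` (over non-filtered nuclei of the group).
#' @export
class_proportions <- function(assignment, groups) {
  stopifnot(inherits(assignment, "ploidy_assignment"))
  if (length(groups) != nrow(assignment$df)) {
    stop("groups must align with the assignment rows", call. = FALSE)
  }
  keep <- !assignment$df$filtered
  df <- assignment$df[keep, , drop = FALSE]
  groups <- as.character(groups)[keep]
  classes <- assignment$class_map$classes
  out <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    n_g <- sum(sel)
    if (n_g == 0) {
      np_log("class_proportions", "warning", sprintf("group '%s' empty after filtering", g))
      next
    }
    counts <- vapply(classes, function(cl) sum(df$class[sel] == cl), integer(1))
    out[[g]] <- data.frame(
      group = g, class = classes, count = counts,
      proportion = counts / n_g, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-class feature means and fold increases
#'
#' Means are computed per ploidy class on the linear scale for each
#' requested feature (arithmetic by default; the geometric mean, the
#' natural companion of log2-space fitting, is reported alongside).
#' `fold_to_next` divides the mean of each class by the mean of the
#' previous (lower) class; under perfect genome doubling the intensity
#' folds are 2.
#'
#' @param table the source [feature_table()].
#' @param assignment a [classify()] result (its `index` locates each
#'   posterior row in `table`).
#' @param features character vector of linear-scale record fields.
#' @return a `class_stats` list: `means` (class x feature, arithmetic),
#'   `geometric_means`, `folds` (data.frame feature/from/to/fold), `counts`.
#' @export
class_means_and_folds <- function(table, assignment, features) {
  stopifnot(inherits(table, "feature_table"), inherits(assignment, "ploidy_assignment"))
  idx <- assignment$index %||% seq_len(nrow(assignment$df))
  rec <- table$records[idx, , drop = FALSE]
  keep <- !assignment$df$filtered
  rec <- rec[keep, , drop = FALSE]
  cls <- assignment$df$class[keep]
  classes <- assignment$class_map$classes
  present <- classes[classes %in% cls]
  mean_mat <- matrix(NA_real_,
    nrow = length(classes), ncol = length(features),
    dimnames = list(classes, features)
  )
  gmean_mat <- mean_mat
  counts <- stats::setNames(integer(length(classes)), classes)
  for (cl in classes) {
    sel <- cls == cl
    counts[cl] <- sum(sel)
    if (!any(sel)) next
    for (f in features) {
      v <- rec[[f]][sel]
      mean_mat[cl, f] <- mean(v)
      gmean_mat[cl, f] <- 2^mean(log2(v))
    }
  }
  folds <- NULL
  if (length(classes) >= 2) {
    folds <- do.call(rbind, lapply(features, function(f) {
      data.frame(
        feature = f,
        from = classes[-length(classes)],
        to = classes[-1],
        fold = as.numeric(mean_mat[classes[-1], f] / mean_mat[classes[-length(classes)], f]),
        stringsAsFactors = FALSE
      )
    }))
    rownames(folds) <- NULL
  }
  missing_cls <- classes[counts == 0]
  if (length(missing_cls) > 0) {
    np_log("class_stats", "warning", sprintf(
      "class(es) with zero members: %s; folds involving them are missing",
      paste(missing_cls, collapse = ", ")
    ))
  }
  structure(
    list(
      means = mean_mat, geometric_means = gmean_mat, folds = folds,
      counts = counts
    ),
    class = "class_stats"
  )
}

#' @export
print.class_stats <- function(x, ...) {
  cat("<class_stats>\n")
  print(round(x$means, 3))
  if (!is.null(x$folds)) {
    cat("folds:\n")
    print(x$folds)
  }
  invisible(x)
}

# asymptotic limiting CDF of the Cramer-von Mises statistic
# (Anderson-Darling 1952 series with Bessel K_{1/4} terms)
cvm_limiting_cdf <- function(x, n_terms = 12L) {
  if (x <= 0) {
    return(0)
  }
  total <- 0
  for (j in seq_len(n_terms) - 1L) {
    a <- (4 * j + 1)^2 / (16 * x)
    term <- exp(lgamma(j + 0.5) - lgamma(0.5) - lgamma(j + 1)) *
      sqrt(4 * j + 1) * exp(-a) * besselK(a, 0.25)
    if (!is.finite(term)) term <- 0
    total <- total + term
  }
  min(1, max(0, total / (pi * sqrt(x))))
}

#' Two-sample Cramer-von Mises test
#'
#' Computes the two-sample statistic T from the pooled empirical
#' distribution functions (rank form, midranks for ties) and a p-value
#' from the asymptotic limiting distribution of T. Used to compare
#' image-derived ploidy distributions with flow cytometry; the class-label
#' encoding (numeric C-levels 2, 4, 8, ...) is the default input.
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2).
#' @return a `cvm_result`: `T`, `p`, `n1`, `n2`.
#' @export
cvm_two_sample <- function(sample_a, sample_b) {
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 values", call. = FALSE)
  N <- n1 + n2
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled, ties.method = "average")
  r1 <- sort(r[seq_len(n1)])
  r2 <- sort(r[n1 + seq_len(n2)])
  u <- n1 * sum((r1 - seq_len(n1))^2) + n2 * sum((r2 - seq_len(n2))^2)
  k <- n1 * n2
  T_stat <- u / (k * N) - (4 * k - 1) / (6 * N)
  # normalize with the exact finite-N mean/variance of T under H0
  # (Anderson 1962, eqs. 11-15), then use the limiting distribution
  et <- (1 + 1 / N) / 6
  vt <- (N + 1) * (4 * k * N - 3 * (n1^2 + n2^2) - 2 * k) / (45 * N^2 * 4 * k)
  tn <- 1 / 6 + (T_stat - et) / sqrt(45 * vt)
  p <- if (tn < 0.003) 1 else 1 - cvm_limiting_cdf(tn)
  p <- min(1, max(p, .Machine$double.xmin))
  structure(
    list(T = T_stat, p = p, n1 = n1, n2 = n2),
    class = "cvm_result"
  )
}

#' @export
print.cvm_result <- function(x, ...) {
  cat(sprintf(
    "<cvm_result> T = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
    x$T, x$p, x$n1, x$n2
  ))
  invisible(x)
}
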