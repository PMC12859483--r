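test_that("variance_of_intensity is the population variance", {
  expect_equal(variance_of_intensity(c(5, 5, 5, 5)), 0)
  expect_equal(variance_of_intensity(c(1, 3)), 1.0)
  expect_error(variance_of_intensity(numeric(0)), "at least one")

  # brute-force two-pass oracle on random vectors
  set.seed(11)
  for (i in 1:100) {
    v <- stats::rnorm(sample(1:50, 1), mean = 100, sd = 30)
    mu <- sum(v) / length(v)
    acc <- 0
    for (x in v) acc <- acc + (x - mu)^2 # explicit loop, no var()/mean()
    expect_equal(variance_of_intensity(v), acc / length(v), tolerance = 1e-12)
  }
})

test_that("select_by_label keeps and drops by user label", {
  tbl <- make_table(10)
  suppressMessages({
    out <- select_by_label(tbl, exclude = "incomplete")
    expect_equal(n_records(out), 8)
    expect_equal(n_records(select_by_label(tbl, exclude = character(0))), 10)
    only <- select_by_label(tbl, include = "incomplete")
  })
  expect_equal(unique(only$records$user_label), "incomplete")
  expect_error(
    select_by_label(tbl, exclude = "a", include = c("a", "b")),
    "both included and excluded"
  )
})

test_that("threshold_filter keeps the stated side, ties inclusive", {
  rec <- data.frame(
    object_id = 1:5, total_intensity = c(10, 20, 30, 40, 50), size = rep(1, 5),
    variance_of_intensity = c(100, 200, 300, 300, 500)
  )
  tbl <- feature_table(rec)
  suppressMessages({
    hi <- threshold_filter(tbl, "variance_of_intensity", 300, "above")
    lo <- threshold_filter(tbl, "variance_of_intensity", 300, "below")
  })
  expect_equal(hi$records$object_id, 3:5) # ties at 300 kept
  expect_equal(lo$records$object_id, 1:4)
  expect_equal(n_records(hi) + sum(!rec$variance_of_intensity >= 300), 5)
  expect_error(
    suppressMessages(threshold_filter(tbl, "nope", 1, "above")),
    "'nope'"
  )
  empty <- feature_table(data.frame(
    object_id = integer(0), total_intensity = numeric(0), size = numeric(0)
  ))
  expect_equal(n_records(threshold_filter(empty, "total_intensity", 1, "above")), 0)
})

test_that("filters are pure subset operations", {
  tbl <- make_table(25, seed = 4)
  suppressMessages({
    for (out in list(
      select_by_label(tbl, exclude = "incomplete"),
      threshold_filter(tbl, "variance_of_intensity", 2^8.3, "above"),
      threshold_filter(tbl, "total_intensity", 2^9, "below")
    )) {
      expect_true(all(out$records$object_id %in% tbl$records$object_id))
      kept <- n_records(out)
      expect_true(kept <= n_records(tbl))
    }
  })
})

test_that("reference QC gates flip independently", {
  # all three gates pass
  rep_ok <- reference_qc(rep(3000, 12))
  expect_true(rep_ok$passed)
  expect_equal(rep_ok$fraction_in_band, 1.0)

  # count gate: 9 values fail regardless of their values
  rep_n <- reference_qc(rep(3000, 9))
  expect_false(rep_n$passed)
  expect_true("count" %in% rep_n$reasons)

  # median gate: 15 values with median 7000
  rep_med <- reference_qc(rep(7000, 15))
  expect_false(rep_med$passed)
  expect_equal(rep_med$reasons, "median")

  # band gate: median in range but 40% of values far out of band
  vals <- c(rep(3000, 12), rep(9000, 8))
  rep_band <- reference_qc(vals)
  expect_false(rep_band$passed)
  expect_equal(rep_band$reasons, "band")
  expect_equal(rep_band$fraction_in_band, 12 / 20)
})

test_that("normalize_by_reference builds the C-value ladder", {
  tbl <- make_table(6)
  med <- tbl$records$total_intensity[2]
  out <- normalize_by_reference(tbl, med)
  expect_equal(out$records$normalized_intensity[2], 1.0) # sits at 1C
  expect_equal(out$records$total_intensity, tbl$records$total_intensity)
  ident <- normalize_by_reference(tbl, 1)
  expect_equal(ident$records$normalized_intensity, tbl$records$total_intensity)
  # multiplying back is the identity
  expect_equal(
    out$records$normalized_intensity * med, tbl$records$total_intensity,
    tolerance = 1e-12
  )
  # odd-length reference lists have median ratio exactly 1
  set.seed(8)
  ref <- stats::runif(11, 2000, 6000)
  expect_equal(stats::median(ref / stats::median(ref)), 1.0)
  expect_error(normalize_by_reference(tbl, 0), "positive")
  expect_error(normalize_by_reference(tbl, -3), "positive")
})

test_that("log2_features transforms, drops non-positives, maps indices", {
  rec <- data.frame(
    object_id = 1:4, total_intensity = c(8, 1024, 2048, -5), size = c(2, 4, 8, 16)
  )
  tbl <- feature_table(rec)
  expect_warning(X <- log2_features(tbl, "total_intensity"), "non-positive")
  expect_equal(as.numeric(X), c(3, 10, 11))
  expect_equal(attr(X, "index"), 1:3)

  # doubling becomes +1 in log2 space
  expect_equal(diff(X[2:3, 1]), 1)

  # inverse-function round trip
  set.seed(21)
  xs <- stats::runif(50, 0.01, 20)
  t2 <- feature_table(data.frame(
    object_id = seq_along(xs), total_intensity = 2^xs, size = rep(1, 50)
  ))
  expect_equal(as.numeric(log2_features(t2, "total_intensity")), xs, tolerance = 1e-12)

  t3 <- feature_table(data.frame(object_id = 1, total_intensity = -1, size = 1))
  expect_error(suppressWarnings(log2_features(t3, "total_intensity")), "no records")
  expect_error(log2_features(tbl, "bogus"), "bogus")
})
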