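test_that("class ladders are laid out from the component means", {
  # six components, drop the lowest
  m6 <- fake_model_1d(1:6)
  cm6 <- map_components_to_classes(m6, "2C", drop_lowest = TRUE)
  expect_equal(
    cm6$class_names[cm6$order],
    c("<2C/Unclassified", "2C", "4C", "8C", "16C", "32C")
  )
  expect_equal(cm6$drop_classes, "<2C/Unclassified")

  # five components, drop lowest, open top
  m5 <- fake_model_1d(1:5)
  cm5 <- map_components_to_classes(m5, "2C", drop_lowest = TRUE, open_top = TRUE)
  expect_equal(
    cm5$class_names[cm5$order],
    c("<2C/Unclassified", "2C", "4C", "8C", "≥16C")
  )

  # relative ladder for an unknown base ploidy
  m3 <- fake_model_1d(1:3)
  cm3 <- map_components_to_classes(m3, "2αC")
  expect_equal(cm3$class_names[cm3$order], c("2αC", "4αC", "8αC"))
  expect_length(cm3$drop_classes, 0)
})

test_that("anchors pin the ladder and merge lower components", {
  # three components at means 1, 1.5, 3; anchors sit in the middle one
  m <- fake_model_1d(c(1, 1.5, 3), sd = 0.1)
  anchors <- list(X = matrix(c(1.5, 1.52, 1.49)), class = "2C")
  suppressMessages(cm <- map_components_to_classes(m, anchors = anchors))
  # the two lowest-mean components both carry the anchor class
  expect_equal(cm$class_names[cm$order], c("2C", "2C", "4C"))
  expect_equal(cm$classes, c("2C", "4C"))

  # anchors spread over non-adjacent components are refused
  bad <- list(X = matrix(c(1, 3, 1.01, 3.02)), class = "2C")
  expect_error(map_components_to_classes(m, anchors = bad), "non-adjacent")
})

test_that("classify takes the argmax with the documented tie-break", {
  cm <- map_components_to_classes(fake_model_1d(1:3), "2C")
  a <- classify(matrix(c(0, 1, 0), 1), cm)
  expect_equal(a$df$component, 2L)
  expect_equal(a$df$class, "4C")

  # exact tie goes to the lower-mean component
  cm2 <- map_components_to_classes(fake_model_1d(1:2), "2C")
  tie <- classify(matrix(c(0.5, 0.5), 1), cm2)
  expect_equal(tie$df$component, 1L)
  expect_equal(tie$df$class, "2C")

  expect_error(classify(matrix(numeric(0), 0, 2), cm2), "empty")
  expect_error(classify(matrix(c(0.7, 0.1), 1), cm2), "sum to 1")

  # argmax agrees with a linear scan oracle
  set.seed(41)
  P <- matrix(stats::rexp(3000), ncol = 3)
  P <- P / rowSums(P)
  cm3 <- map_components_to_classes(fake_model_1d(1:3), "2C")
  got <- classify(P, cm3)$df$component
  want <- integer(nrow(P))
  for (i in seq_len(nrow(P))) {
    best <- 1L
    for (k in 2:3) if (P[i, k] > P[i, best]) best <- k
    want[i] <- best
  }
  expect_equal(got, want)
})

test_that("classification is invariant to order-preserving posterior rescaling", {
  set.seed(6)
  P <- matrix(stats::rexp(400), ncol = 4)
  P <- P / rowSums(P)
  cm <- map_components_to_classes(fake_model_1d(1:4), "2C")
  base <- classify(P, cm)$df$component
  # squaring preserves the row-wise order; renormalize
  P2 <- P^2 / rowSums(P^2)
  expect_equal(classify(P2, cm)$df$component, base)
})

test_that("uncertainty intervals reproduce the hand-worked example", {
  cm <- map_components_to_classes(fake_model_1d(1:2), "2C")
  P <- rbind(c(0.9, 0.1), c(0.7, 0.3), c(0.6, 0.4), c(0.15, 0.85))
  cs <- uncertainty_intervals(classify(P, cm))
  expect_equal(cs$V, c(0.75, 0.25))
  expect_equal(cs$C_out, c(0.5, 0))
  expect_equal(cs$C_in, c(0, 0.5))
  expect_equal(cs$lower, c(0.25, 0.25))
  expect_equal(cs$upper, c(0.75, 0.75))
  expect_equal(sum(cs$V), 1)

  # one-hot posteriors give zero-width intervals
  hot <- diag(2)[c(1, 1, 2, 2, 1), ]
  cs0 <- uncertainty_intervals(classify(hot, cm))
  expect_equal(cs0$C_out, c(0, 0))
  expect_equal(cs0$C_in, c(0, 0))
  expect_equal(cs0$lower, cs0$V)
  expect_equal(cs0$upper, cs0$V)
})

test_that("interval terms respect their bounds and threshold monotonicity", {
  set.seed(14)
  cm <- map_components_to_classes(fake_model_1d(1:3), "2C")
  for (rep in 1:20) {
    P <- matrix(stats::rexp(60), ncol = 3)
    P <- P / rowSums(P)
    a <- classify(P, cm)
    cs <- uncertainty_intervals(a)
    expect_equal(sum(cs$V), 1)
    expect_true(all(cs$C_out <= cs$V + 1e-12))
    expect_true(all(cs$lower >= -1e-12))
    expect_true(all(cs$V + cs$C_in <= 1 + 1e-12))
    # raising conf_threshold can only grow C_out
    hi <- uncertainty_intervals(a, conf_threshold = 0.95)
    expect_true(all(hi$C_out >= cs$C_out - 1e-12))
    # raising second_threshold can only shrink C_in
    hi2 <- uncertainty_intervals(a, second_threshold = 0.4)
    expect_true(all(hi2$C_in <= cs$C_in + 1e-12))
  }
})

test_that("dropped classes leave the summary denominator", {
  m <- fake_model_1d(1:3)
  cm <- map_components_to_classes(m, "2C", drop_lowest = TRUE)
  P <- rbind(
    c(0.97, 0.02, 0.01), # lowest component -> dropped
    c(0.01, 0.98, 0.01),
    c(0.01, 0.01, 0.98),
    c(0.02, 0.96, 0.02)
  )
  a <- classify(P, cm)
  expect_equal(sum(a$df$filtered), 1)
  cs <- uncertainty_intervals(a)
  expect_equal(attr(cs, "n"), 3)
  expect_equal(cs$V, c(2 / 3, 1 / 3))
})
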