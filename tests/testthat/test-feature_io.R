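test_that("read_feature_table resolves both intensity column spellings", {
  for (col in c("Total Intensity", "Total Intensity_0")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_ilastik_csv(path, n = 4, intensity_col = col)
    tbl <- read_feature_table(path)
    expect_equal(n_records(tbl), 4)
    expect_true(all(tbl$records$total_intensity > 0))
  }
})

test_that("reader handles empty files, column order, and label fallback", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("object_id,Total Intensity,Size in pixels", path)
  expect_equal(n_records(read_feature_table(path)), 0)

  # column order is irrelevant
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_ilastik_csv(p1, n = 6, seed = 9)
  df <- utils::read.csv(p1, check.names = FALSE)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, rev(names(df))], p2, row.names = FALSE)
  t1 <- read_feature_table(p1)
  t2 <- read_feature_table(p2)
  expect_equal(t1$records$total_intensity, t2$records$total_intensity)
  expect_equal(t1$records$object_id, t2$records$object_id)

  # "Predicted Class" is the fallback for user labels
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    check.names = FALSE, object_id = 1:2, `Total Intensity` = c(10, 20),
    `Size in pixels` = c(5, 5), `Predicted Class` = c("a", "b")
  ), p3, row.names = FALSE)
  expect_equal(read_feature_table(p3)$records$user_label, c("a", "b"))
})

test_that("reader errors name the offending column or row", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(object_id = 1:2, `Size in pixels` = c(5, 5),
    check.names = FALSE
  ), p, row.names = FALSE)
  expect_error(read_feature_table(p), "total intensity")

  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    check.names = FALSE, object_id = 1:2,
    `Total Intensity` = c("12", "oops"), `Size in pixels` = c(5, 5)
  ), p2, row.names = FALSE)
  expect_error(read_feature_table(p2), "non-numeric.*2")
})

test_that("feature table invariants are enforced", {
  expect_error(
    feature_table(data.frame(
      object_id = c(1, 1), total_intensity = c(1, 2), size = c(1, 1)
    )),
    "unique"
  )
  expect_error(
    feature_table(data.frame(
      object_id = 1, total_intensity = 100, size = 10, mean_intensity = 50
    )),
    "0.1%"
  )
  expect_error(
    feature_table(data.frame(
      object_id = 1, total_intensity = 1, size = 1, variance_of_intensity = -2
    )),
    ">= 0"
  )
})

test_that("label image round-trips exactly through TIFF and HDF5", {
  set.seed(31)
  arr <- matrix(0L, 20, 25)
  arr[3:6, 4:8] <- 1L
  arr[10:13, 10:14] <- 2L
  arr[15:18, 20:24] <- 7L
  arr[1, 1] <- 65535L
  img <- label_image(arr)
  for (ext in c(".tif", ".h5")) {
    if (ext == ".h5") skip_if_not_installed("rhdf5")
    path <- withr::local_tempfile(fileext = ext)
    write_label_image(img, path)
    back <- read_label_image(path)
    expect_identical(back$array, img$array)
  }
  # 3D stack round-trip
  vol <- array(sample(0:9, 4 * 5 * 3, TRUE), dim = c(4, 5, 3))
  p3 <- withr::local_tempfile(fileext = ".tif")
  write_label_image(label_image(vol), p3)
  expect_identical(read_label_image(p3)$array, label_image(vol)$array)
})

test_that("floating-point rasters are rejected with an actionable message", {
  p <- withr::local_tempfile(fileext = ".tif")
  nucploidy:::write_tiff_gray(matrix(c(0.2, 0.8, 0.5, 1), 2, 2), p,
    sample_format = "float"
  )
  expect_error(read_label_image(p), "probabilit")
})

test_that("write_assignments emits one row per record with filtered markers", {
  fx <- make_assignment(n = 40, K = 2)
  # knock one record out of the assignment to force a "filtered" row
  tbl <- fx$table
  a <- fx$assignment
  keep <- a$index != 3L
  a$df <- a$df[a$index != 3L, , drop = FALSE]
  a$posteriors <- a$posteriors[keep, , drop = FALSE]
  a$index <- a$index[keep]
  path <- withr::local_tempfile(fileext = ".csv")
  write_assignments(tbl, a, path)
  out <- read_assignments(path)
  expect_equal(nrow(out), n_records(tbl))
  expect_equal(out$class[3], "filtered")
  expect_true(is.na(out$posterior_1[3]))
  # class counts survive the round trip
  expect_equal(
    sort(table(out$class[out$class != "filtered"])),
    sort(table(a$df$class))
  )
  # intensities survive at full precision
  expect_equal(out$total_intensity, tbl$records$total_intensity, tolerance = 1e-12)

  # zero-record table -> header-only file
  empty <- feature_table(data.frame(
    object_id = integer(0), total_intensity = numeric(0), size = numeric(0)
  ))
  a0 <- a
  a0$df <- a0$df[0, , drop = FALSE]
  a0$posteriors <- a0$posteriors[0, , drop = FALSE]
  a0$index <- integer(0)
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_assignments(empty, a0, p0)
  expect_equal(nrow(read_assignments(p0)), 0)

  # misaligned assignment is refused
  bad <- fx$assignment
  bad$index <- seq_len(nrow(bad$df)) + 100L
  expect_error(write_assignments(tbl, bad, path), "align")
})
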