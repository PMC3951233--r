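test_that("descriptor CSV reading preserves shape, order and flags missing cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,alpha,beta",
               "drug_a,1.5,2",
               "drug_b,NA,4",
               "drug_c,2.5,6"), f)
  raw <- read_descriptor_table(f)
  expect_s3_class(raw, "qspkr_raw")
  expect_identical(dim(raw$values), c(3L, 2L))
  expect_identical(raw$compound_ids, c("drug_a", "drug_b", "drug_c"))
  expect_identical(raw$column_names, c("alpha", "beta"))
  expect_true(is.na(raw$values["drug_b", "alpha"]))
  expect_identical(raw$values[, "beta"], c(drug_a = 2, drug_b = 4, drug_c = 6))
})

test_that("malformed tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,alpha", "drug_a,1", "drug_a,2"), f)
  expect_error(read_descriptor_table(f), "drug_a")
  writeLines(c("compound,alpha", "drug_a,1", "drug_b,oops"), f)
  expect_error(read_descriptor_table(f), "drug_b.*alpha")
  expect_error(read_descriptor_table(tempfile()), "not found")
})

test_that("missing-value handling is explicit and logged", {
  raw <- new_qspkr_raw(c("a", "b", "c"), c("x", "y"),
                       cbind(c(1, NA, 3), c(4, 5, 6)))
  expect_message(dropped <- handle_missing(raw), "dropping 1 column")
  expect_identical(dropped$column_names, "y")
  expect_message(imputed <- handle_missing(raw, "impute_mean"), "mean-imputed")
  expect_equal(imputed$values[2, "x"], 2)
  # clean tables pass through silently
  expect_silent(handle_missing(dropped))
  # normalization refuses tables with unresolved missing values
  pk <- new_qspkr_raw(c("a", "b", "c"), "pk", matrix(1:3))
  expect_error(minmax_normalize(raw, pk), "handle_missing")
})

test_that("min-max normalization maps each column onto [0, 1] and keeps scale info", {
  raw <- new_qspkr_raw(c("a", "b", "c"), c("x", "const"),
                       cbind(c(2, 4, 6), c(7, 7, 7)))
  pk <- new_qspkr_raw(c("a", "b", "c"), "CL", matrix(c(10, 20, 55)))
  d <- minmax_normalize(raw, pk)
  expect_equal(unname(d$X[, 1]), c(0, 0.5, 1))
  expect_equal(unname(d$X[, 2]), c(0, 0, 0))   # constant column: zeroed + flagged
  expect_identical(d$constant, c(FALSE, TRUE))
  expect_equal(d$dp, c(0, 2 / 9, 1))
  expect_equal(c(d$scale_pk$min, d$scale_pk$max), c(10, 55))
  expect_error(
    minmax_normalize(new_qspkr_raw(c("a", "z", "c"), "x", matrix(1:3)), pk),
    "identical compound ids")
})

test_that("denormalization inverts normalization on the training range", {
  expect_equal(denormalize(0.5, c(10, 55)), 32.5)
  expect_equal(denormalize(0, c(10, 55)), 10)
  expect_error(denormalize(0.5, c(3, 3)), "constant")
  set.seed(42)
  for (rep in 1:20) {
    y <- rnorm(sample(3:20, 1), sd = 10^sample(-2:3, 1))
    if (max(y) == min(y)) next
    v <- (y - min(y)) / (max(y) - min(y))
    expect_equal(denormalize(v, c(min(y), max(y))), y, tolerance = 1e-10)
  }
})

test_that("normalization is order-preserving and attains both extremes", {
  set.seed(7)
  raw <- new_qspkr_raw(sprintf("c%d", 1:12), sprintf("d%d", 1:5),
                       matrix(rnorm(60, sd = 50), 12, 5))
  pk <- new_qspkr_raw(sprintf("c%d", 1:12), "pk", matrix(runif(12)))
  d <- minmax_normalize(raw, pk)
  expect_true(all(d$X >= 0 & d$X <= 1))
  for (j in 1:5) {
    expect_equal(min(d$X[, j]), 0, tolerance = 1e-12)
    expect_equal(max(d$X[, j]), 1, tolerance = 1e-12)
    expect_identical(order(d$X[, j]), order(raw$values[, j]))
  }
})

test_that("training-fold-only normalization uses only the requested rows", {
  raw <- new_qspkr_raw(c("a", "b", "c", "d"), "x", matrix(c(0, 1, 2, 10)))
  pk <- new_qspkr_raw(c("a", "b", "c", "d"), "pk", matrix(c(1, 2, 3, 4)))
  d <- minmax_normalize(raw, pk, scope_rows = 1:3)
  expect_equal(unname(d$X[, 1]), c(0, 0.5, 1, 5))  # row 4 extrapolates
  expect_equal(c(d$scale_x$min, d$scale_x$max), c(0, 2))
})
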