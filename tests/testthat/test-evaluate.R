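test_that("the R statistic is the printed 1 - SSE/SST form", {
  y <- c(0.2, 0.5, 0.9, 0.4)
  expect_identical(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(0, 1), c(0, 0.5)), 0.5)
  # can go negative; no square root is taken
  expect_lt(r_squared(c(0, 1, 0, 1), c(1, 0, 1, 0)), 0)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  # agrees with an independent two-pass computation on random data
  set.seed(1)
  for (i in 1:10) {
    obs <- rnorm(12); pred <- obs + rnorm(12, sd = 0.3)
    expect_equal(r_squared(obs, pred),
                 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
                 tolerance = 1e-12)
  }
})

test_that("RMSE and NRMSE follow their definitions and identities", {
  expect_identical(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(c(3, 4), c(0, 0)), rmse(c(0, 0), c(3, 4)))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_equal(nrmse(0.5, c(0, 1)), 0.5)
  expect_identical(nrmse(0, c(10, 55)), 0)
  expect_equal(nrmse(3, c(10, 55)), 3 / 45)
  expect_error(nrmse(1, c(5, 5)), "constant")
  set.seed(2)
  for (i in 1:10) {
    obs <- rnorm(10); pred <- rnorm(10)
    sc <- range(obs)
    expect_equal(nrmse(rmse(obs, pred), sc) * (sc[2] - sc[1]),
                 rmse(obs, pred), tolerance = 1e-10)
    # NRMSE is invariant under affine rescaling of the measurement scale
    a <- runif(1, 0.5, 20); b <- rnorm(1)
    expect_equal(nrmse(rmse(a * obs + b, a * pred + b), a * sc + b),
                 nrmse(rmse(obs, pred), sc), tolerance = 1e-10)
  }
})

test_that("random splitting produces the 33/6 protocol partition", {
  s <- split_train_test(39, 33, seed = 1)
  expect_length(s$train, 33)
  expect_length(s$test, 6)
  expect_identical(sort(c(s$train, s$test)), 1:39)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(split_train_test(39, 33, seed = 1)$train, s$train)
  expect_false(identical(split_train_test(39, 33, seed = 2)$train, s$train))
  expect_error(split_train_test(10, 0), "strictly between")
  expect_error(split_train_test(10, 10), "strictly between")
})

test_that("homogeneity tests behave like the reference split check", {
  g <- c(1, 2, 3, 4, 5)
  h <- homogeneity_tests(g, g)
  expect_equal(h$t_statistic, 0)
  expect_equal(h$ttest_p, 1)
  set.seed(3)
  for (i in 1:10) {
    r <- homogeneity_tests(rnorm(33), rnorm(6))
    expect_true(r$levene_p >= 0 && r$levene_p <= 1)
    expect_true(r$ttest_p >= 0 && r$ttest_p <= 1)
  }
  # a planted 5-sd location shift is flagged
  set.seed(1)
  r <- homogeneity_tests(rnorm(33), rnorm(6, mean = 5))
  expect_lt(r$ttest_p, 0.001)
  expect_error(homogeneity_tests(1, c(1, 2)), "at least two")
})

test_that("repeated sub-sampling validation recovers a noiseless planted model", {
  synth <- generate_dataset(synthetic_spec(
    n_compounds = 30, n_descriptors = 40, n_informative = 5,
    noise_sd = 0, seed = 5))
  val <- repeated_subsampling_validation(synth$data, synth$truth$informative,
                                         n_repeats = 5, seed = 5)
  expect_s3_class(val, "qspkr_validation")
  expect_gt(mean(val$per_repeat$R), 0.9)
  # NRMSE * range = RMSE for every repeat
  rng <- synth$data$scale_pk$max - synth$data$scale_pk$min
  expect_equal(val$per_repeat$NRMSE * rng, val$per_repeat$RMSE,
               tolerance = 1e-10)
  # 33:39 proportion of 30 compounds
  expect_identical(val$n_train, 25L)
  expect_identical(val$n_test, 5L)
})

test_that("a single repeat reproduces one split evaluation end to end", {
  synth <- generate_dataset(synthetic_spec(
    n_compounds = 24, n_descriptors = 30, n_informative = 4,
    noise_sd = 0.02, seed = 6))
  val <- repeated_subsampling_validation(synth$data, synth$truth$informative,
                                         n_repeats = 1, seed = 9)
  expect_identical(nrow(val$per_repeat), 1L)
  expect_identical(nrow(val$predictions), val$n_test)
  # aggregate over one repeat equals that repeat
  expect_equal(val$aggregate$R, val$per_repeat$R[1])
  expect_equal(val$aggregate$RMSE, val$per_repeat$RMSE[1])
  # determinism
  val2 <- repeated_subsampling_validation(synth$data, synth$truth$informative,
                                          n_repeats = 1, seed = 9)
  expect_identical(val$predictions$predicted, val2$predictions$predicted)
  expect_error(
    repeated_subsampling_validation(synth$data, c(1L, 999L), n_repeats = 1),
    "out of range")
})
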