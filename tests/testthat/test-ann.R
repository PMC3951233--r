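test_that("network initialization has the right shapes and is seed-reproducible", {
  m <- init_network(15, ann_control(seed = 1))
  expect_identical(dim(m$W1), c(4L, 15L))
  expect_length(m$b1, 4)
  expect_length(m$w2, 4)
  # 15 inputs x 4 hidden + 4 biases + 4 output weights + 1 output bias
  expect_identical(qspkr:::n_params(m), 69L)
  m2 <- init_network(15, ann_control(seed = 1))
  expect_identical(m$W1, m2$W1)
  expect_identical(m$b2, m2$b2)
  z <- init_network(3, ann_control(weight_init_scale = 0))
  expect_true(all(c(z$W1, z$b1, z$w2, z$b2) == 0))
  expect_error(init_network(0), "at least 1")
})

test_that("the forward pass matches hand computation and is row-independent", {
  # all-zero weights with a logistic output always predict 0.5
  z <- init_network(2, ann_control(weight_init_scale = 0))
  expect_equal(ann_forward(z, matrix(runif(10), 5, 2)), rep(0.5, 5))
  # hand-set 1-input / 1-hidden network
  m <- init_network(1, ann_control(n_hidden = 1, seed = 1))
  m$W1[1, 1] <- 0.7; m$b1 <- -0.2; m$w2 <- 1.3; m$b2 <- 0.4
  x <- 0.6
  hand <- 1 / (1 + exp(-(1.3 * tanh(0.7 * x - 0.2) + 0.4)))
  expect_equal(ann_forward(m, matrix(x)), hand, tolerance = 1e-12)
  # row order does not change per-row predictions
  mm <- init_network(3, ann_control(seed = 2))
  X <- matrix(runif(30), 10, 3)
  p <- ann_forward(mm, X)
  expect_equal(ann_forward(mm, X[10:1, ]), p[10:1])
  expect_error(ann_forward(mm, matrix(1, 2, 2)), "expects 3")
})

test_that("analytic derivatives agree with central finite differences", {
  set.seed(3)
  X <- matrix(runif(24), 8, 3)
  m <- init_network(3, ann_control(seed = 4))
  expect_lt(analytic_gradient_check(m, X), 1e-6)
  z <- init_network(3, ann_control(weight_init_scale = 0))
  expect_lt(analytic_gradient_check(z, X), 1e-6)
  expect_gte(analytic_gradient_check(m, X), 0)
  lin <- init_network(2, ann_control(activation_output = "linear", seed = 5))
  expect_lt(analytic_gradient_check(lin, matrix(runif(10), 5, 2)), 1e-6)
})

test_that("Levenberg-Marquardt training reduces error monotonically and converges", {
  x <- matrix(seq(0, 1, length.out = 30))
  y <- 1 / (1 + exp(-(2 * x[, 1] - 1)))
  m <- train_ann(init_network(1, ann_control(seed = 3)), x, y)
  expect_lt(sqrt(mean((y - ann_forward(m, x))^2)), 1e-3)
  expect_true(all(diff(m$trace$sse) <= 1e-12))
  expect_lte(nrow(m$trace), 50)
})

test_that("training is a no-op for zero epochs and deterministic for a fixed seed", {
  set.seed(9)
  X <- matrix(runif(20), 10, 2); y <- runif(10)
  m0 <- init_network(2, ann_control(seed = 6))
  expect_identical(train_ann(m0, X, y, ann_control(epochs = 0, seed = 6))$W1,
                   m0$W1)
  a <- train_ann(init_network(2, ann_control(seed = 7)), X, y)
  b <- train_ann(init_network(2, ann_control(seed = 7)), X, y)
  expect_identical(qspkr:::pack_params(a), qspkr:::pack_params(b))
  expect_error(train_ann(m0, X, y[-1]), "differ")
})

test_that("with huge damping the LM step turns into a small gradient step", {
  set.seed(10)
  X <- matrix(runif(30), 15, 2); y <- runif(15)
  m <- init_network(2, ann_control(seed = 11))
  fwd <- qspkr:::ann_jacobian(m, X)
  r <- y - fwd$yhat
  grad_dir <- as.numeric(crossprod(fwd$J, r))
  mu <- 1e8
  step <- solve(crossprod(fwd$J) + diag(mu, length(grad_dir)),
                grad_dir)
  cosine <- sum(step * grad_dir) / sqrt(sum(step^2) * sum(grad_dir^2))
  expect_gt(cosine, 0.9999)
})

test_that("the gradient-descent fallback also reduces the error", {
  x <- matrix(seq(0, 1, length.out = 25))
  y <- 0.2 + 0.5 * x[, 1]
  ctl <- ann_control(optimizer = "gd", epochs = 200, learning_rate = 0.5,
                     seed = 12)
  m <- train_ann(init_network(1, ctl), x, y, ctl)
  expect_lt(m$trace$sse[200], m$trace$sse[1])
})

test_that("a trained network survives JSON serialization unchanged", {
  set.seed(13)
  X <- matrix(runif(24), 12, 2); y <- runif(12)
  m <- train_ann(init_network(2, ann_control(seed = 14)), X, y)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(ann_to_list(m), f, auto_unbox = TRUE, digits = NA)
  m2 <- ann_from_list(jsonlite::read_json(f, simplifyVector = TRUE))
  expect_equal(ann_forward(m2, X), ann_forward(m, X), tolerance = 1e-12)
})
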