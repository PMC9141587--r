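test_that("threshold update follows the moving-average law", {
  # gamma = 0: theta is the batch mean of z^2
  ts <- update_threshold(threshold_state(1, gamma = 0), matrix(c(1, 2, 3), 1))
  expect_equal(ts$theta, 14 / 3)

  # gamma = 1: full memory, theta unchanged
  ts1 <- frozen_threshold(5, gamma = 1)
  ts1 <- update_threshold(ts1, matrix(c(10, 20), 1))
  expect_equal(ts1$theta, 5)

  # gamma = 0.5, theta_prev = 2, batch mean z^2 = 4 -> 3
  ts2 <- frozen_threshold(2, gamma = 0.5)
  ts2 <- update_threshold(ts2, matrix(2, 1, 3))
  expect_equal(ts2$theta, 3)

  expect_error(update_threshold(threshold_state(1), matrix(numeric(0), 1, 0)),
               "empty")
})

test_that("an uninitialised threshold bootstraps from its first batch", {
  for (gamma in c(0, 0.5, 0.9, 1)) {
    ts <- update_threshold(threshold_state(2, gamma = gamma),
                           matrix(c(1, 2, 3, 4), 2))
    expect_equal(ts$theta, rowMeans(matrix(c(1, 2, 3, 4), 2)^2))
  }
})

test_that("theta is clamped at its floor", {
  ts <- update_threshold(threshold_state(1, gamma = 0, floor = 1e-8),
                         matrix(0, 1, 4))
  expect_equal(ts$theta, 1e-8)
  expect_equal(ts$step, 1L)
})

test_that("the Law-Cooper update matches a scalar brute-force oracle", {
  # hand-worked single-synapse case: z = 1, theta = 2, x = (1, 0)
  ts <- frozen_threshold(2)
  dW <- bcm_update(matrix(1, 1, 1), matrix(c(1, 0), 2, 1), ts)
  expect_equal(dW, matrix(c(-0.5, 0), 1, 2))

  set.seed(99)
  for (rep in 1:5) {
    N <- sample(1:4, 1); nf <- sample(1:5, 1); b <- sample(1:6, 1)
    Z <- matrix(abs(rnorm(N * b)), N, b)
    X <- matrix(abs(rnorm(nf * b)), nf, b)
    theta <- runif(N, 0.5, 2)
    expect_equal(bcm_update(Z, X, frozen_threshold(theta)),
                 bcm_update_oracle(Z, X, theta), tolerance = 1e-12)
  }
})

test_that("silent neurons and at-threshold responses produce zero update", {
  ts <- frozen_threshold(c(1, 2))
  Z <- rbind(c(0, 0, 0), c(1, 2, 0.5))
  X <- matrix(abs(rnorm(9)), 3)
  dW <- bcm_update(Z, X, ts)
  expect_equal(dW[1, ], rep(0, 3))

  # z = theta exactly is the fixed-point condition
  dW2 <- bcm_update(matrix(2, 1, 1), matrix(1, 1, 1), frozen_threshold(2))
  expect_equal(dW2, matrix(0, 1, 1))

  expect_error(bcm_update(Z, X, threshold_state(2)), "uninitialised")
})

test_that("the selective state on orthogonal patterns is an exact fixed point", {
  # K orthogonal patterns with probabilities p: responding 1/p[k] to
  # pattern k and 0 elsewhere gives theta = E[z^2] = p (1/p)^2 p = 1/p,
  # so z = theta at the selected pattern and the update vanishes.
  for (K in c(2, 4)) {
    p <- rep(1 / K, K)
    ps <- orthogonal_patterns(K, probabilities = p)
    W <- selective_weights(K, k = 1L, p = p)
    net <- network_state(W, "linear")
    Z <- forward(net, ps)
    expect_equal(as.vector(Z), c(1 / p[1], rep(0, K - 1)))
    # gamma = 0, full batch: theta equals the environment mean of z^2
    ts <- update_threshold(threshold_state(1, gamma = 0), Z)
    expect_equal(ts$theta, 1 / p[1] * p[1] * (1 / p[1]))  # p (1/p)^2 = 1/p
    dW <- bcm_update(Z, ps$X, ts)
    expect_equal(dW, matrix(0, 1, K))
    # per-pattern updates vanish individually at the certified theta
    for (k in seq_len(K)) {
      dWk <- bcm_update(Z[, k, drop = FALSE], ps$X[, k, drop = FALSE], ts)
      expect_equal(dWk, matrix(0, 1, K))
    }
  }
})

test_that("non-uniform probabilities shift the fixed point to 1/p", {
  p <- c(0.8, 0.2)
  ps <- orthogonal_patterns(2, probabilities = p)
  W <- selective_weights(2, k = 2L, p = p)  # responds 5 to pattern 2
  Z <- forward(network_state(W, "linear"), ps)
  theta <- sum(p * Z^2)  # population (weighted) mean of z^2 = 1/p[2]
  expect_equal(theta, 1 / p[2])
  dW <- bcm_update_oracle(Z, ps$X, theta) # oracle on the weighted certificate
  # weighted combination of per-pattern updates is zero
  upd <- p[1] * bcm_update(Z[, 1, drop = FALSE], ps$X[, 1, drop = FALSE],
                           frozen_threshold(theta)) +
         p[2] * bcm_update(Z[, 2, drop = FALSE], ps$X[, 2, drop = FALSE],
                           frozen_threshold(theta))
  expect_equal(upd, matrix(0, 1, 2))
})

test_that("with frozen weights theta converges geometrically at rate gamma", {
  set.seed(3)
  W <- matrix(abs(rnorm(2 * 4)), 2, 4)
  ps <- orthogonal_patterns(4)
  Z <- forward(network_state(W, "relu"), ps)
  mu <- rowMeans(Z^2)  # full-batch population mean
  gamma <- 0.8
  ts <- frozen_threshold(c(5, 0.1), gamma = gamma)
  err0 <- ts$theta - mu
  for (t in 1:20) {
    ts <- update_threshold(ts, Z)
    expect_equal(ts$theta - mu, gamma^t * err0, tolerance = 1e-12)
  }
})

test_that("gamma = 0 with a full batch equals the environment average in one step", {
  set.seed(4)
  W <- matrix(rnorm(3 * 5), 3, 5)
  X <- matrix(abs(rnorm(5 * 12)), 5, 12)
  Z <- forward(network_state(W, "relu"), X)
  ts <- update_threshold(threshold_state(3, gamma = 0), Z)
  expect_identical(ts$theta, pmax(1e-8, rowMeans(Z^2)))
})

test_that("epoch threshold averages are plain means over steps", {
  expect_equal(epoch_threshold_average(c(2, 4)), 3)
  expect_equal(epoch_threshold_average(rep(7, 5)), 7)
  expect_equal(epoch_threshold_average(c(1, 2, 3, 4)), 2.5)
  m <- cbind(c(1, 3), c(10, 20))
  expect_equal(epoch_threshold_average(m), c(2, 15))
  expect_error(epoch_threshold_average(numeric(0)), "empty")
})
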