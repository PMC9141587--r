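test_that("weight initialization is seeded, scaled, and optionally positive", {
  W1 <- init_weights(3, 10, seed = 5)
  W2 <- init_weights(3, 10, seed = 5)
  expect_identical(W1, W2)

  # law of large numbers: empirical sd ~ scale / sqrt(n_features)
  W <- init_weights(100, 100, scale = 1, seed = 1)
  expect_equal(stats::sd(W), 0.1, tolerance = 0.2)

  expect_true(all(init_weights(2, 50, seed = 2, positive = TRUE) >= 0))
  expect_warning(W0 <- init_weights(2, 3, scale = 0), "dead")
  expect_equal(W0, matrix(0, 2, 3))
})

test_that("zero-epoch runs return the initial state with empty history", {
  ps <- orthogonal_patterns(3)
  fit <- bcm_train(ps, epochs = 0, n_neurons = 2, seed_weights = 9)
  expect_equal(fit$epochs_run, 0L)
  expect_equal(nrow(fit$history$theta_epoch), 0L)
  expect_equal(fit$network$W,
               init_weights(2, 3, scale = 0.01, seed = 9, positive = TRUE))
  expect_false(any(fit$converged))
  expect_equal(nrow(tidy(fit)), 0L)
})

test_that("training is bitwise deterministic from its seeds", {
  ps <- clustered_patterns(3, 6, 12, noise_sd = 0.05, seed = 2)
  cfg <- bcm_config(n_neurons = 2, xi = -0.1, epochs = 15, batch_size = 5,
                    seed_weights = 4, seed_batches = 8,
                    stop_on_convergence = FALSE)
  f1 <- bcm_train(ps, cfg)
  f2 <- bcm_train(ps, cfg)
  expect_identical(f1$network$W, f2$network$W)
  expect_identical(f1$history$theta_step, f2$history$theta_step)
  expect_identical(f1$history$mean_abs_dw, f2$history$mean_abs_dw)
})

# narrow helper: same config restricted to neuron i
modify_config_for_test <- function(cfg, i, W0) {
  bcm_config(n_neurons = 1, xi = 0, epochs = cfg$epochs,
             batch_size = cfg$batch_size, seed_batches = cfg$seed_batches,
             stop_on_convergence = FALSE, W0 = W0[i, , drop = FALSE],
             gamma = cfg$gamma, activation = cfg$activation,
             optimizer = cfg$optimizer)
}

test_that("a decoupled network trains identically to independent single neurons", {
  ps <- clustered_patterns(4, 5, 16, noise_sd = 0.1, seed = 6)
  N <- 3
  W0 <- init_weights(N, 16, seed = 11, positive = TRUE)
  cfg <- bcm_config(n_neurons = N, xi = 0, epochs = 12, batch_size = 10,
                    seed_batches = 21, stop_on_convergence = FALSE, W0 = W0)
  joint <- bcm_train(ps, cfg)
  for (i in seq_len(N)) {
    single <- bcm_train(ps, modify_config_for_test(cfg, i, W0))
    expect_equal(joint$network$W[i, ], single$network$W[1, ],
                 tolerance = 1e-12)
    expect_equal(joint$history$theta_step[, i],
                 single$history$theta_step[, 1], tolerance = 1e-12)
  }
})

test_that("stored epoch averages equal recomputed means of the step trace", {
  ps <- orthogonal_patterns(6)
  fit <- bcm_train(ps, n_neurons = 2, epochs = 9, batch_size = 4,
                   stop_on_convergence = FALSE)
  B <- fit$history$B
  expect_equal(B, 2)  # ceiling(6 / 4)
  for (e in seq_len(fit$epochs_run)) {
    rows <- ((e - 1) * B + 1):(e * B)
    expect_identical(
      epoch_threshold_average(fit$history$theta_step[rows, , drop = FALSE]),
      fit$history$theta_epoch[e, ])
  }
})

test_that("convergence flags react to the trailing threshold trace", {
  flat <- matrix(1, 20, 1)
  expect_true(check_convergence(flat, rel_tol = 0.01, window = 10))

  doubling <- matrix(2^(1:20), 20, 1)
  expect_false(check_convergence(doubling, rel_tol = 0.5, window = 10))

  # last three relative changes 0.001, 0.002, 0.0005 under rel_tol 0.01
  trace <- c(10, 5, 1)  # wild early history is irrelevant
  trace <- c(trace, trace[3] * cumprod(1 + c(0.001, 0.002, 0.0005)))
  expect_true(check_convergence(matrix(trace, ncol = 1),
                                rel_tol = 0.01, window = 3))
  expect_false(check_convergence(matrix(trace, ncol = 1),
                                 rel_tol = 0.001, window = 3))

  expect_error(check_convergence(matrix(1, 5, 1), window = 10), "exceeds")
})

test_that("training on orthogonal patterns reaches the analytic 1/p response", {
  # single neuron, 2 equiprobable orthogonal patterns, linear activation,
  # gamma = 0, full batch, plain stepping: attractor response is 1/p = 2
  ps <- orthogonal_patterns(2)
  fit <- bcm_train(ps, n_neurons = 1, activation = "linear", gamma = 0,
                   batch_size = 2, epochs = 4000, optimizer = "sgd",
                   positive_init = FALSE, seed_weights = 3,
                   stop_on_convergence = FALSE)
  z <- forward(fit$network, ps)
  expect_equal(max(z), 2, tolerance = 0.05)
  expect_equal(min(abs(z)), 0, tolerance = 0.05)
})

test_that("the trained endpoint matches a fine-step ODE integration oracle", {
  skip_if_not_installed("deSolve")
  # continuous-time Law-Cooper flow on 2 orthogonal equiprobable patterns:
  # dw/dt = sum_k p_k z_k (z_k - theta) e_k / theta, theta = sum_k p_k z_k^2
  flow <- function(t, w, parms) {
    z <- w  # identity patterns of unit scale
    theta <- max(mean(z^2), 1e-12)
    list(0.5 * z * (z - theta) / theta)
  }
  sol <- deSolve::ode(y = c(0.3, 0.1), times = c(0, 400), func = flow,
                      parms = NULL, method = "ode45")
  w_inf <- sol[nrow(sol), -1]
  expect_equal(sort(unname(w_inf)), c(0, 2), tolerance = 1e-3)

  fit <- bcm_train(orthogonal_patterns(2), n_neurons = 1,
                   activation = "linear", gamma = 0, batch_size = 2,
                   epochs = 4000, optimizer = "sgd",
                   W0 = matrix(c(0.3, 0.1), 1), stop_on_convergence = FALSE)
  expect_equal(sort(as.vector(fit$network$W)), sort(unname(w_inf)),
               tolerance = 0.02)
})

test_that("diverging weights abort with an error naming the epoch", {
  ps <- orthogonal_patterns(2)
  expect_error(
    bcm_train(ps, n_neurons = 1, activation = "linear", gamma = 0,
              batch_size = 2, epochs = 500, optimizer = "sgd",
              learning_rate = 1e5, positive_init = FALSE,
              stop_on_convergence = FALSE),
    "diverged at epoch")
})

test_that("fits tidy and summarise into well-formed tibbles", {
  ps <- orthogonal_patterns(4)
  fit <- bcm_train(ps, n_neurons = 2, epochs = 8, batch_size = 4,
                   stop_on_convergence = FALSE)
  td <- tidy(fit)
  expect_equal(nrow(td), 8 * 2)
  expect_named(td, c("epoch", "neuron", "theta_bar", "mean_abs_dw",
                     "converged"))
  gl <- glance(fit)
  expect_equal(gl$epochs_run, 8L)
  expect_equal(gl$n_neurons, 2L)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
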