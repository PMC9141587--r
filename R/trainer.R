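#' Random initial synaptic weights
#'
#' I.i.d. zero-mean Gaussian entries with standard deviation
#' `scale / sqrt(n_features)`, so the typical initial drive is of order
#' `scale` regardless of dimensionality. With `positive = TRUE` the
#' absolute value is taken (half-normal entries): under a ReLU activation
#' a fully zero-mean start leaves a neuron silent on every pattern with
#' probability `2^-K` on `K` orthogonal patterns, and a silent ReLU neuron
#' has identically zero plasticity, so ReLU runs default to the positive
#' variant (see [bcm_config()]).
#'
#' The default scale keeps initial weights small relative to unit-scale
#' inputs so that receptive fields are shaped by the data rather than by
#' the random start.
#'
#' @param n_neurons,n_features Weight matrix dimensions.
#' @param scale Magnitude scale; `0` gives all-zero weights (warned: dead
#'   under ReLU).
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @param positive If `TRUE`, take absolute values (half-normal init).
#' @return A `n_neurons x n_features` weight matrix.
#' @export
init_weights <- function(n_neurons, n_features, scale = 0.01, seed = NULL,
                         positive = FALSE) {
  N <- assert_count(n_neurons, "n_neurons")
  d <- assert_count(n_features, "n_features")
  scale <- assert_number(scale, "scale", min = 0)
  if (scale == 0) {
    warning("scale = 0 gives all-zero weights: dead under ReLU activation")
    return(matrix(0, N, d))
  }
  draw <- function() {
    W <- matrix(stats::rnorm(N * d, sd = scale / sqrt(d)), N, d)
    if (positive) abs(W) else W
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Training run configuration
#'
#' Collects every knob of a training run. Unset fields fall back to
#' defaults chosen for the package's synthetic fixtures: ReLU activation,
#' decoupled neurons (`xi = 0`), memory factor `gamma = 0.9`, batch size
#' 20 (or the full set if smaller), Adam with its reference defaults, and
#' a convergence criterion on the epoch-averaged threshold (relative
#' change below `rel_tol` across a `window` of epochs).
#'
#' @param n_neurons Number of neurons.
#' @param xi Uniform lateral interaction strength.
#' @param activation `"relu"`, `"linear"` or `"logistic"`.
#' @param gamma Threshold memory factor in `[0, 1]`.
#' @param batch_size Patterns per batch (`NULL`: min(20, n_patterns)).
#' @param epochs Maximum number of epochs.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Step size (`NULL`: optimizer default).
#' @param beta1,beta2,eps Adam hyperparameters.
#' @param weight_scale Initial weight scale (see [init_weights()]).
#' @param positive_init Half-normal initial weights (`NULL`: `TRUE` iff
#'   the activation is ReLU).
#' @param theta_floor Lower clamp for the modification threshold.
#' @param seed_weights,seed_batches Independent seeds for the two sources
#'   of randomness, so either can be held fixed.
#' @param rel_tol,window Convergence criterion: a neuron has converged
#'   when the relative change of its epoch-averaged threshold stays below
#'   `rel_tol` over the last `window` epoch-to-epoch changes.
#' @param stop_on_convergence Stop early once every neuron has converged.
#' @param max_abs_weight Divergence guard: abort if any weight magnitude
#'   exceeds this.
#' @param record_steps Keep the per-step threshold trace (set `FALSE` to
#'   save memory on long runs; epoch averages are always kept).
#' @param W0 Optional explicit initial weight matrix (overrides
#'   `weight_scale`/`seed_weights`/`positive_init`).
#' @return An object of class `bcm_config` (a named list).
#' @export
bcm_config <- function(n_neurons = 1, xi = 0,
                       activation = c("relu", "linear", "logistic"),
                       gamma = 0.9, batch_size = NULL, epochs = 100,
                       optimizer = c("adam", "sgd"), learning_rate = NULL,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_scale = 0.01, positive_init = NULL,
                       theta_floor = 1e-8,
                       seed_weights = 1, seed_batches = 2,
                       rel_tol = 0.01, window = 10,
                       stop_on_convergence = TRUE, max_abs_weight = 1e6,
                       record_steps = TRUE, W0 = NULL) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  if (is.null(positive_init)) positive_init <- activation == "relu"
  cfg <- list(
    n_neurons = assert_count(n_neurons, "n_neurons"),
    xi = assert_number(xi, "xi"),
    activation = activation,
    gamma = assert_number(gamma, "gamma", min = 0),
    batch_size = if (!is.null(batch_size)) assert_count(batch_size, "batch_size"),
    epochs = assert_count(epochs, "epochs", min = 0L),
    optimizer = optimizer,
    learning_rate = if (!is.null(learning_rate)) {
      assert_number(learning_rate, "learning_rate", min = 0)
    },
    beta1 = beta1, beta2 = beta2, eps = eps,
    weight_scale = assert_number(weight_scale, "weight_scale", min = 0),
    positive_init = isTRUE(positive_init),
    theta_floor = assert_number(theta_floor, "theta_floor"),
    seed_weights = assert_count(seed_weights, "seed_weights",
                                min = -.Machine$integer.max),
    seed_batches = assert_count(seed_batches, "seed_batches",
                                min = -.Machine$integer.max),
    rel_tol = assert_number(rel_tol, "rel_tol"),
    window = assert_count(window, "window"),
    stop_on_convergence = isTRUE(stop_on_convergence),
    max_abs_weight = assert_number(max_abs_weight, "max_abs_weight"),
    record_steps = isTRUE(record_steps),
    W0 = if (!is.null(W0)) assert_matrix(W0, "W0")
  )
  if (cfg$gamma > 1) stop("`gamma` must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "bcm_config")
}

#' @export
print.bcm_config <- function(x, ...) {
  cat(sprintf(
    "<bcm_config: %d neuron(s), xi = %g, %s, gamma = %g, %s, %d epochs>\n",
    x$n_neurons, x$xi, x$activation, x$gamma, x$optimizer, x$epochs))
  invisible(x)
}

# Merge `...` overrides into a config, revalidating.
modify_config <- function(config, ...) {
  dots <- list(...)
  if (length(dots) == 0L) return(config)
  bad <- setdiff(names(dots), names(formals(bcm_config)))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- unclass(config)
  args[names(dots)] <- dots
  do.call(bcm_config, args)
}

#' Train a BCM network on a pattern set
#'
#' Runs the full step loop: draw a batch, forward pass through the
#' laterally mixed network, advance the modification threshold on the
#' batch, compute the Law-Cooper update with the freshly advanced
#' threshold, and step the weights with the configured optimizer. One
#' parameter update per batch; `B = ceiling(n_patterns / batch_size)`
#' steps per epoch. Training stops at the epoch cap, earlier if every
#' neuron's epoch-averaged threshold has stabilised (see
#' [check_convergence()]), or aborts with an error if weights diverge.
#'
#' All randomness derives from `seed_weights` (initial `W`) and
#' `seed_batches` (batch schedule); identical configurations reproduce
#' identical histories bitwise.
#'
#' @param patterns A [pattern_set()] (or a data frame coercible via
#'   [as_pattern_set()]).
#' @param config A [bcm_config()].
#' @param ... Config overrides, e.g. `bcm_train(ps, n_neurons = 5,
#'   xi = -0.1)`.
#' @return An object of class `bcm_fit`: list with the trained `network`
#'   ([network_state()]), `threshold` ([threshold_state()]), `optimizer`,
#'   `history` (per-step and per-epoch threshold traces, per-epoch mean
#'   `|dW|`, steps per epoch `B`), `converged` (per-neuron flags),
#'   `epochs_run`, and the `config`. Explore it with [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' ps <- orthogonal_patterns(2)
#' fit <- bcm_train(ps, n_neurons = 1, activation = "linear", gamma = 0,
#'                  batch_size = 2, epochs = 200, optimizer = "sgd",
#'                  learning_rate = 0.1)
#' forward(fit$network, ps)
bcm_train <- function(patterns, config = bcm_config(), ...) {
  ps <- as_pattern_set(patterns)
  config <- modify_config(config, ...)
  X <- ps$X
  n_pat <- ncol(X)
  n_feat <- nrow(X)
  N <- config$n_neurons
  batch_size <- config$batch_size
  if (is.null(batch_size)) batch_size <- min(20L, n_pat)

  lateral <- build_lateral(N, config$xi)
  W <- config$W0
  if (is.null(W)) {
    W <- init_weights(N, n_feat, scale = config$weight_scale,
                      seed = config$seed_weights,
                      positive = config$positive_init)
  } else if (!identical(dim(W), c(N, n_feat))) {
    stop("W0 has the wrong shape", call. = FALSE)
  }
  ts <- threshold_state(N, gamma = config$gamma, floor = config$theta_floor)
  opt <- optimizer_state(config$optimizer, config$learning_rate,
                         config$beta1, config$beta2, config$eps)

  B <- ceiling(n_pat / batch_size)
  empty_history <- list(
    theta_step = matrix(numeric(0), 0L, N),
    theta_epoch = matrix(numeric(0), 0L, N),
    mean_abs_dw = numeric(0), B = B
  )
  make_fit <- function(history, converged, epochs_run) {
    structure(
      list(network = network_state(W, config$activation, lateral),
           threshold = ts, optimizer = opt, history = history,
           converged = converged, epochs_run = epochs_run,
           config = config, patterns_seed = ps$seed),
      class = "bcm_fit")
  }
  if (config$epochs == 0L) {
    return(make_fit(empty_history, rep(FALSE, N), 0L))
  }

  schedule <- sample_batches(ps, batch_size, config$epochs,
                             seed = config$seed_batches)
  theta_step <- if (config$record_steps) {
    matrix(NA_real_, config$epochs * B, N)
  }
  theta_epoch <- matrix(NA_real_, config$epochs, N)
  mean_abs_dw <- numeric(config$epochs)
  step <- 0L
  epochs_run <- 0L
  converged <- rep(FALSE, N)

  for (e in seq_len(config$epochs)) {
    theta_this_epoch <- matrix(NA_real_, B, N)
    dw_acc <- 0
    for (bi in seq_along(schedule[[e]])) {
      idx <- schedule[[e]][[bi]]
      Xb <- X[, idx, drop = FALSE]
      Z <- forward_raw(W, Xb, lateral, config$activation)
      ts <- update_threshold(ts, Z)
      dW <- bcm_update(Z, Xb, ts)
      res <- optimizer_step(opt, W, dW)
      W <- res$weights
      opt <- res$state
      step <- step + 1L
      theta_this_epoch[bi, ] <- ts$theta
      dw_acc <- dw_acc + mean(abs(dW))
      if (config$record_steps) theta_step[step, ] <- ts$theta
    }
    if (!all(is.finite(W)) || max(abs(W)) > config$max_abs_weight) {
      stop(sprintf("training diverged at epoch %d (weights exceeded %g)",
                   e, config$max_abs_weight), call. = FALSE)
    }
    theta_epoch[e, ] <- epoch_threshold_average(theta_this_epoch)
    mean_abs_dw[e] <- dw_acc / length(schedule[[e]])
    epochs_run <- e
    if (e > config$window) {
      converged <- check_convergence(theta_epoch[seq_len(e), , drop = FALSE],
                                     rel_tol = config$rel_tol,
                                     window = config$window)
      if (config$stop_on_convergence && all(converged)) break
    }
  }

  history <- list(
    theta_step = if (config$record_steps) {
      theta_step[seq_len(step), , drop = FALSE]
    } else {
      matrix(numeric(0), 0L, N)
    },
    theta_epoch = theta_epoch[seq_len(epochs_run), , drop = FALSE],
    mean_abs_dw = mean_abs_dw[seq_len(epochs_run)],
    B = B
  )
  make_fit(history, converged, epochs_run)
}

# Forward pass without constructing a bcm_network (hot loop).
forward_raw <- function(W, Xb, lateral, activation) {
  drive <- W %*% Xb
  if (lateral$xi != 0) drive <- lateral$mixing %*% drive
  activation_apply(activation, drive)
}

#' Per-neuron convergence of the epoch-averaged threshold
#'
#' A neuron is converged when the relative epoch-to-epoch change of its
#' epoch-averaged threshold stayed below `rel_tol` for the last `window`
#' changes.
#'
#' @param history A `bcm_fit`, or a matrix of epoch-averaged thresholds
#'   (`epochs x n_neurons`).
#' @param rel_tol Relative tolerance on the change.
#' @param window Number of trailing epoch-to-epoch changes examined.
#' @return Logical vector, one flag per neuron.
#' @export
check_convergence <- function(history, rel_tol = 0.01, window = 10) {
  if (inherits(history, "bcm_fit")) history <- history$history$theta_epoch
  history <- as.matrix(history)
  rel_tol <- assert_number(rel_tol, "rel_tol")
  window <- assert_count(window, "window")
  n_e <- nrow(history)
  if (n_e < window + 1L) {
    stop(sprintf("window (%d) exceeds the epochs run (%d)", window, n_e),
         call. = FALSE)
  }
  tail_theta <- history[(n_e - window):n_e, , drop = FALSE]
  prev <- tail_theta[-nrow(tail_theta), , drop = FALSE]
  curr <- tail_theta[-1L, , drop = FALSE]
  rel <- abs(curr - prev) / pmax(abs(prev), .Machine$double.eps)
  apply(rel < rel_tol, 2L, all)
}

#' @export
print.bcm_fit <- function(x, ...) {
  cat(sprintf(
    "<bcm_fit: %d neuron(s) x %d features, %s, xi = %g, %d epoch(s), %d/%d converged>\n",
    nrow(x$network$W), ncol(x$network$W), x$network$activation,
    x$network$lateral$xi, x$epochs_run, sum(x$converged), length(x$converged)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a BCM fit
#'
#' @param x A `bcm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch and neuron: `epoch`, `neuron`,
#'   `theta_bar` (epoch-averaged modification threshold), `mean_abs_dw`
#'   (epoch mean of `|dW|`, shared across neurons), `converged`.
#' @export
tidy.bcm_fit <- function(x, ...) {
  te <- x$history$theta_epoch
  if (nrow(te) == 0L) {
    return(tibble::tibble(epoch = integer(), neuron = integer(),
                          theta_bar = numeric(), mean_abs_dw = numeric(),
                          converged = logical()))
  }
  N <- ncol(te)
  tibble::tibble(
    epoch = rep(seq_len(nrow(te)), times = N),
    neuron = rep(seq_len(N), each = nrow(te)),
    theta_bar = as.vector(te),
    mean_abs_dw = rep(x$history$mean_abs_dw, times = N),
    converged = rep(x$converged, each = nrow(te))
  )
}

#' One-row summary of a BCM fit
#'
#' @param x A `bcm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, coupling, epochs run, steps per
#'   epoch, converged count, final mean `|dW|` and final mean threshold.
#' @export
glance.bcm_fit <- function(x, ...) {
  tibble::tibble(
    n_neurons = nrow(x$network$W),
    n_features = ncol(x$network$W),
    activation = x$network$activation,
    xi = x$network$lateral$xi,
    gamma = x$threshold$gamma,
    optimizer = x$optimizer$kind,
    epochs_run = x$epochs_run,
    steps_per_epoch = x$history$B,
    n_converged = sum(x$converged),
    final_mean_abs_dw = if (x$epochs_run > 0)
      x$history$mean_abs_dw[x$epochs_run] else NA_real_,
    final_theta_mean = if (!is.null(x$threshold$theta))
      mean(x$threshold$theta) else NA_real_
  )
}

#' Plot the epoch-averaged threshold traces of a fit
#'
#' @param object A `bcm_fit`.
#' @param ... Unused.
#' @return A ggplot: `<theta>` per epoch, one line per neuron.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.bcm_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$epoch, y = .data$theta_bar,
    colour = factor(.data$neuron))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = expression(bar(theta)),
                  colour = "neuron") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
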