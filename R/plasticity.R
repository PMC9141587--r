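#' Sliding modification threshold state
#'
#' The BCM modification threshold `theta` separates potentiation from
#' depression: responses above `theta` strengthen the active synapses,
#' responses below weaken them. Here `theta` is tracked per neuron as a
#' moving average of batch-averaged squared postsynaptic activity,
#'
#'   `theta_t = gamma * theta_{t-1} + (1 - gamma) * <z^2>_batch`,
#'
#' where `gamma` in `[0, 1]` is the memory factor. The superlinearity in
#' `z` (squaring) is what makes selective states attractors. `theta` is
#' clamped below at a small positive floor because the Law-Cooper update
#' divides by it; an uninitialised state bootstraps `theta_0` from the
#' first batch it sees rather than from an arbitrary constant.
#'
#' @param n_neurons Number of neurons tracked.
#' @param gamma Memory factor in `[0, 1]`; values near 1 give long memory
#'   and enforce high selectivity.
#' @param floor Positive lower clamp for `theta` (division safety).
#' @return An object of class `bcm_threshold`: list with `theta` (NULL
#'   until the first update), `gamma`, `floor`, `step`.
#' @export
threshold_state <- function(n_neurons, gamma = 0.9, floor = 1e-8) {
  N <- assert_count(n_neurons, "n_neurons")
  gamma <- assert_number(gamma, "gamma", min = 0)
  if (gamma > 1) stop("`gamma` must lie in [0, 1]", call. = FALSE)
  floor <- assert_number(floor, "floor")
  if (floor <= 0) stop("`floor` must be positive", call. = FALSE)
  structure(list(n_neurons = N, theta = NULL, gamma = gamma, floor = floor,
                 step = 0L),
            class = "bcm_threshold")
}

#' @export
print.bcm_threshold <- function(x, ...) {
  cat(sprintf("<bcm_threshold: %d neurons, gamma = %g, step %d%s>\n",
              x$n_neurons, x$gamma, x$step,
              if (is.null(x$theta)) ", uninitialised" else ""))
  invisible(x)
}

#' Advance the modification threshold on one batch of responses
#'
#' Per neuron `i`, `theta_i <- gamma * theta_i + (1 - gamma) * mean(z_i^2)`
#' with the mean taken over the batch, then clamped below at the floor.
#' On the first call `theta` is bootstrapped to the batch mean of `z^2`
#' before the update, so `theta_1` equals the first batch average for any
#' `gamma`.
#'
#' @param ts A [threshold_state()].
#' @param Z Activity matrix, `n_neurons x batch_size` (non-empty).
#' @return The updated `bcm_threshold`.
#' @export
#' @examples
#' ts <- threshold_state(1, gamma = 0)
#' update_threshold(ts, matrix(c(1, 2, 3), 1))$theta  # mean(z^2) = 14/3
update_threshold <- function(ts, Z) {
  stopifnot(inherits(ts, "bcm_threshold"))
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = ts$n_neurons)
  if (ncol(Z) < 1L) stop("empty activity batch", call. = FALSE)
  if (nrow(Z) != ts$n_neurons) {
    stop("Z has the wrong number of neurons", call. = FALSE)
  }
  mz2 <- rowMeans(Z^2)
  prev <- if (is.null(ts$theta)) pmax(ts$floor, mz2) else ts$theta
  ts$theta <- pmax(ts$floor, ts$gamma * prev + (1 - ts$gamma) * mz2)
  ts$step <- ts$step + 1L
  ts
}

#' Law-Cooper BCM weight update for one batch
#'
#' The raw plasticity direction, averaged over the batch:
#'
#'   `dW[i, j] = mean_b( z_i (z_i - theta_i) x_j / theta_i )`.
#'
#' Responses above the threshold potentiate the synapses that drove them,
#' responses below depress them, and the division by `theta` (the
#' Law-Cooper form) rescales plasticity so that strongly active neurons
#' stabilise. No learning rate is applied here; optimizers consume the
#' direction. The batch aggregate is the arithmetic mean, so the learning
#' rate is batch-size invariant. The ordering contract is that `ts` has
#' already been advanced on this batch (the update at step `t` uses
#' `theta_t`).
#'
#' @param Z Activity matrix for the batch, `n_neurons x batch_size`.
#' @param X_batch Pattern matrix for the same batch,
#'   `n_features x batch_size`.
#' @param ts The [threshold_state()] already updated on this batch.
#' @return Matrix of proposed weight changes, `n_neurons x n_features`.
#' @export
bcm_update <- function(Z, X_batch, ts) {
  stopifnot(inherits(ts, "bcm_threshold"))
  if (is.null(ts$theta)) {
    stop("threshold is uninitialised; call update_threshold() first",
         call. = FALSE)
  }
  if (any(ts$theta < ts$floor)) {
    stop("internal error: theta fell below its floor", call. = FALSE)
  }
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = ts$n_neurons)
  if (!is.matrix(X_batch)) X_batch <- matrix(X_batch, ncol = ncol(Z))
  if (ncol(Z) != ncol(X_batch)) {
    stop("Z and X_batch disagree on batch size", call. = FALSE)
  }
  # (Z - theta) and /theta recycle per-row down the columns of Z
  phi <- Z * (Z - ts$theta) / ts$theta
  dW <- phi %*% t(X_batch) / ncol(Z)
  if (!all(is.finite(dW))) {
    stop("non-finite plasticity update", call. = FALSE)
  }
  dW
}

#' Epoch average of the modification threshold
#'
#' The per-step threshold trace can be noisy (small batches, small
#' `gamma`); convergence is therefore monitored on its epoch average
#' `<theta> = mean_t(theta_t)` over the `B` steps of one epoch.
#'
#' @param theta_trace Numeric matrix of per-step thresholds
#'   (`steps x n_neurons`) or a numeric vector for a single neuron.
#' @return Per-neuron mean, numeric of length `n_neurons`.
#' @export
#' @examples
#' epoch_threshold_average(c(2, 4))  # 3
epoch_threshold_average <- function(theta_trace) {
  if (is.null(theta_trace) || length(theta_trace) == 0L) {
    stop("empty threshold trace", call. = FALSE)
  }
  if (!is.matrix(theta_trace)) theta_trace <- matrix(theta_trace, ncol = 1L)
  colMeans(theta_trace)
}
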