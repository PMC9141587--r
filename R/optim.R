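#' Optimizer state for stepping weights along the plasticity direction
#'
#' The BCM update is a plasticity *direction*, not the gradient of a loss.
#' Plain stepping adds `lr * dW` directly (positive `dW` is potentiation).
#' Adam is fed `g = -dW` so that the standard descent-form recursion
#' performs ascent along the plasticity direction; its moment estimates
#' adapt the per-synapse step size and give markedly faster convergence at
#' equal selectivity.
#'
#' Defaults are `lr = 0.01` for `sgd` and the Adam reference defaults
#' (`lr = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`).
#'
#' @param kind `"adam"` or `"sgd"`.
#' @param learning_rate Step size; default depends on `kind`.
#' @param beta1,beta2 Adam moment decay rates, in (0, 1).
#' @param eps Adam denominator offset.
#' @return An object of class `bcm_optimizer`. Adam moment matrices are
#'   allocated lazily at the first step.
#' @export
optimizer_state <- function(kind = c("adam", "sgd"), learning_rate = NULL,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  if (is.null(learning_rate)) {
    learning_rate <- if (kind == "adam") 0.001 else 0.01
  }
  learning_rate <- assert_number(learning_rate, "learning_rate", min = 0)
  stopifnot(beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, eps > 0)
  structure(
    list(kind = kind, learning_rate = learning_rate, beta1 = beta1,
         beta2 = beta2, eps = eps, m = NULL, v = NULL, t = 0L),
    class = "bcm_optimizer"
  )
}

#' @export
print.bcm_optimizer <- function(x, ...) {
  cat(sprintf("<bcm_optimizer: %s, lr = %g, step %d>\n",
              x$kind, x$learning_rate, x$t))
  invisible(x)
}

#' Plain fixed-rate step
#'
#' `W' = W + lr * dW`: the plasticity direction scaled by a constant
#' learning rate.
#'
#' @param W Weight matrix.
#' @param dW Plasticity direction from [bcm_update()].
#' @param lr Positive learning rate.
#' @return The updated weight matrix.
#' @export
sgd_step <- function(W, dW, lr = 0.01) {
  if (!all(is.finite(dW))) stop("non-finite update", call. = FALSE)
  if (!identical(dim(W), dim(dW))) {
    stop("W and dW shapes differ", call. = FALSE)
  }
  W + lr * dW
}

#' Adam step along the plasticity direction
#'
#' Standard bias-corrected Adam applied to the pseudo-gradient `g = -dW`:
#' `m <- beta1 m + (1 - beta1) g`, `v <- beta2 v + (1 - beta2) g^2`,
#' `W' = W - lr * m_hat / (sqrt(v_hat) + eps)`. Under a constant update
#' direction the first step has magnitude approximately `lr` per synapse.
#'
#' @param state A [optimizer_state()] with `kind = "adam"`.
#' @param W Weight matrix.
#' @param dW Plasticity direction from [bcm_update()].
#' @return List with elements `weights` (updated `W`) and `state` (updated
#'   optimizer state).
#' @export
adam_step <- function(state, W, dW) {
  stopifnot(inherits(state, "bcm_optimizer"), state$kind == "adam")
  if (!all(is.finite(dW))) stop("non-finite update", call. = FALSE)
  if (!identical(dim(W), dim(dW))) {
    stop("W and dW shapes differ", call. = FALSE)
  }
  if (is.null(state$m)) {
    state$m <- array(0, dim(W))
    state$v <- array(0, dim(W))
  }
  g <- -dW
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * g
  state$v <- state$beta2 * state$v + (1 - state$beta2) * g^2
  m_hat <- state$m / (1 - state$beta1^state$t)
  v_hat <- state$v / (1 - state$beta2^state$t)
  W <- W - state$learning_rate * m_hat / (sqrt(v_hat) + state$eps)
  if (!all(is.finite(W))) stop("non-finite weights after Adam step", call. = FALSE)
  list(weights = W, state = state)
}

# Dispatch one optimizer step; returns list(weights, state).
optimizer_step <- function(state, W, dW) {
  if (state$kind == "sgd") {
    list(weights = sgd_step(W, dW, state$learning_rate), state = state)
  } else {
    adam_step(state, W, dW)
  }
}
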