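#' Uniform lateral (cortico-cortical) coupling between neurons
#'
#' Neurons of one BCM layer interact through a coupling matrix `L` with
#' `xi` everywhere off the diagonal and 0 on the diagonal (no
#' self-interaction). Positive `xi` is cooperation (excitation), negative
#' `xi` competition (inhibition). The laterally mixed response uses the
#' operator `(I - L)^-1`, which is precomputed here and cached because `L`
#' is constant during a run.
#'
#' `I - L` has eigenvalues `1 - (N-1) xi` (the common mode, multiplicity 1)
#' and `1 + xi` (the differential modes, multiplicity `N - 1`). The
#' coupling is rejected as singular when either factor vanishes, i.e. at
#' `xi = 1/(N-1)` or `xi = -1`.
#'
#' @param n_neurons Number of neurons `N`.
#' @param xi Interaction strength (sign encodes excitatory/inhibitory).
#' @param tol Singularity tolerance on the eigenvalue magnitudes.
#' @return An object of class `bcm_lateral`: list with `n_neurons`, `xi`,
#'   `L`, and the cached `mixing` operator `(I - L)^-1`.
#' @export
#' @examples
#' build_lateral(3, -0.1)$L
build_lateral <- function(n_neurons, xi = 0, tol = 1e-8) {
  N <- assert_count(n_neurons, "n_neurons")
  xi <- assert_number(xi, "xi")
  if (N >= 2) {
    common <- 1 - (N - 1) * xi
    if (abs(common) <= tol) {
      stop(sprintf(
        "singular lateral coupling: xi = %g is at the critical value 1/(N-1) = %g",
        xi, 1 / (N - 1)
      ), call. = FALSE)
    }
    if (abs(1 + xi) <= tol) {
      stop(sprintf(
        "singular lateral coupling: xi = %g is at the critical value -1", xi
      ), call. = FALSE)
    }
  }
  L <- matrix(xi, N, N)
  diag(L) <- 0
  mixing <- if (xi == 0) diag(N) else solve(diag(N) - L)
  structure(list(n_neurons = N, xi = xi, L = L, mixing = mixing),
            class = "bcm_lateral")
}

#' @export
print.bcm_lateral <- function(x, ...) {
  cat(sprintf("<bcm_lateral: %d neurons, xi = %g>\n", x$n_neurons, x$xi))
  invisible(x)
}

#' Network state: weights, activation, lateral coupling
#'
#' Everything needed for a forward pass: the synaptic weight matrix `W`
#' (`n_neurons x n_features`), the activation function, and the lateral
#' coupling.
#'
#' @param W Numeric weight matrix, `n_neurons x n_features`.
#' @param activation One of `"relu"`, `"linear"`, `"logistic"`.
#' @param lateral A [build_lateral()] coupling (default: decoupled,
#'   `xi = 0`).
#' @return An object of class `bcm_network`.
#' @export
network_state <- function(W, activation = c("relu", "linear", "logistic"),
                          lateral = NULL) {
  W <- assert_matrix(W, "W")
  activation <- match.arg(activation)
  if (is.null(lateral)) lateral <- build_lateral(nrow(W), 0)
  stopifnot(inherits(lateral, "bcm_lateral"))
  if (lateral$n_neurons != nrow(W)) {
    stop("lateral coupling and W disagree on the number of neurons",
         call. = FALSE)
  }
  structure(list(W = W, activation = activation, lateral = lateral),
            class = "bcm_network")
}

#' @export
print.bcm_network <- function(x, ...) {
  cat(sprintf("<bcm_network: %d neurons x %d features, %s activation, xi = %g>\n",
              nrow(x$W), ncol(x$W), x$activation, x$lateral$xi))
  invisible(x)
}

#' Apply an activation function elementwise
#'
#' ReLU (`max(0, .)`) is the package default: it preserves the positivity
#' a rate interpretation requires while keeping responses unbounded.
#' `linear` is the identity and `logistic` is `1/(1 + exp(-x))`, the
#' classical choice.
#'
#' @param kind One of `"relu"`, `"linear"`, `"logistic"`.
#' @param x Numeric vector or matrix of pre-activations.
#' @return The activated values, same shape as `x`.
#' @export
activation_apply <- function(kind = c("relu", "linear", "logistic"), x) {
  kind <- match.arg(kind)
  switch(kind,
    relu = pmax(x, 0),
    linear = x,
    logistic = 1 / (1 + exp(-x))
  )
}

#' Forward pass: laterally mixed postsynaptic responses
#'
#' Computes `Z = sigma((I - L)^-1 W X)`: the linear drive `W X` is mixed
#' through the lateral operator and the activation is applied elementwise
#' afterwards, exactly as the model's response equation parenthesises it.
#' With `xi = 0` this reduces to independent single-neuron responses
#' `sigma(w_i . x)`.
#'
#' @param network A [network_state()].
#' @param X A [pattern_set()] or a `n_features x n_patterns` matrix.
#' @return Matrix of postsynaptic activities, `n_neurons x n_patterns`.
#' @export
forward <- function(network, X) {
  stopifnot(inherits(network, "bcm_network"))
  if (inherits(X, "bcm_pattern_set")) X <- X$X
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (nrow(X) != ncol(network$W)) {
    stop(sprintf("feature dimension mismatch: W has %d features, X has %d",
                 ncol(network$W), nrow(X)), call. = FALSE)
  }
  drive <- network$W %*% X
  if (network$lateral$xi != 0) {
    drive <- network$lateral$mixing %*% drive
  }
  Z <- activation_apply(network$activation, drive)
  if (!all(is.finite(Z))) {
    stop("non-finite postsynaptic activity in forward pass", call. = FALSE)
  }
  Z
}
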