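# Shared fixtures, built in code.

# Analytic selective weight vector for K orthogonal unit patterns with
# probabilities p: responds 1/p[k] to pattern k, 0 elsewhere.
selective_weights <- function(K, k = 1L, p = rep(1 / K, K)) {
  w <- matrix(0, 1L, K)
  w[1L, k] <- 1 / p[k]
  w
}

# Threshold state frozen at an explicit theta (bypasses bootstrapping).
frozen_threshold <- function(theta, gamma = 0) {
  ts <- threshold_state(length(theta), gamma = gamma)
  ts$theta <- theta
  ts
}

# Scalar brute-force oracle for the Law-Cooper batch update: loops over
# batch elements and synapses, independent of the vectorised path.
bcm_update_oracle <- function(Z, X, theta) {
  N <- nrow(Z); nf <- nrow(X); b <- ncol(Z)
  dW <- matrix(0, N, nf)
  for (i in seq_len(N)) for (j in seq_len(nf)) {
    acc <- 0
    for (t in seq_len(b)) {
      acc <- acc + Z[i, t] * (Z[i, t] - theta[i]) * X[j, t] / theta[i]
    }
    dW[i, j] <- acc / b
  }
  dW
}
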