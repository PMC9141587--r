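#' Construct a pattern set (the training "environment")
#'
#' A pattern set holds the presynaptic input matrix `X` together with
#' optional class labels and per-pattern sampling probabilities. It is the
#' environment a BCM network is exposed to during training: column `k` of
#' `X` is the presynaptic rate vector of pattern `k`, and `probabilities[k]`
#' is the probability that pattern `k` is presented at any one draw.
#'
#' Presynaptic rates must be nonnegative (biological positivity) and finite.
#' Probabilities must be nonnegative and sum to one; they are renormalised
#' to machine precision on construction.
#'
#' @param X Numeric matrix, `n_features x n_patterns`, entries `>= 0`.
#' @param labels Optional integer class label per pattern.
#' @param probabilities Optional per-pattern sampling probabilities
#'   (default: uniform).
#' @param seed Integer seed recorded for provenance (`NA` if the set was
#'   not produced by a seeded generator).
#'
#' @return An object of class `bcm_pattern_set`: a list with elements `X`,
#'   `labels`, `probabilities`, `seed`.
#' @seealso [orthogonal_patterns()], [clustered_patterns()],
#'   [sample_batches()], [as_pattern_set()]
#' @export
#' @examples
#' ps <- pattern_set(diag(3))
#' ps$probabilities
pattern_set <- function(X, labels = NULL, probabilities = NULL, seed = NA_integer_) {
  X <- assert_matrix(X, "X")
  if (any(X < 0)) {
    stop("presynaptic activities must be nonnegative", call. = FALSE)
  }
  n <- ncol(X)
  if (n < 1L) stop("a pattern set needs at least one pattern", call. = FALSE)
  if (is.null(probabilities)) {
    probabilities <- rep(1 / n, n)
  }
  if (length(probabilities) != n || any(!is.finite(probabilities)) ||
      any(probabilities < 0)) {
    stop("`probabilities` must be nonnegative, one per pattern", call. = FALSE)
  }
  s <- sum(probabilities)
  if (abs(s - 1) > 1e-8) {
    stop("`probabilities` must sum to 1", call. = FALSE)
  }
  probabilities <- probabilities / s
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop("`labels` must have one entry per pattern", call. = FALSE)
    }
    labels <- as.integer(labels)
  }
  structure(
    list(X = X, labels = labels, probabilities = probabilities,
         seed = as.integer(seed)),
    class = "bcm_pattern_set"
  )
}

#' @export
print.bcm_pattern_set <- function(x, ...) {
  unif <- max(abs(x$probabilities - 1 / ncol(x$X))) < 1e-12
  cat(sprintf(
    "<bcm_pattern_set: %d patterns x %d features%s, %s probabilities%s>\n",
    ncol(x$X), nrow(x$X),
    if (is.null(x$labels)) "" else sprintf(", %d classes", length(unique(x$labels))),
    if (unif) "uniform" else "weighted",
    if (is.na(x$seed)) "" else sprintf(", seed %d", x$seed)
  ))
  invisible(x)
}

#' Number of patterns / features in a pattern set
#' @param ps A [pattern_set()].
#' @return An integer count.
#' @export
n_patterns <- function(ps) ncol(ps$X)

#' @rdname n_patterns
#' @export
n_features <- function(ps) nrow(ps$X)

#' @importFrom tibble as_tibble
#' @export
as_tibble.bcm_pattern_set <- function(x, ...) {
  ft <- tibble::as_tibble(t(x$X), .name_repair = ~ sprintf("f%d", seq_along(.x)))
  out <- tibble::tibble(
    pattern = seq_len(ncol(x$X)),
    label = if (is.null(x$labels)) NA_integer_ else x$labels,
    probability = x$probabilities
  )
  dplyr::bind_cols(out, ft)
}

#' Coerce tabular data to a pattern set
#'
#' Rows are patterns; every numeric column except `label` and `probability`
#' is treated as a feature.
#'
#' @param x A data frame (or a `bcm_pattern_set`, returned unchanged).
#' @param ... Unused.
#' @return A [pattern_set()].
#' @export
as_pattern_set <- function(x, ...) UseMethod("as_pattern_set")

#' @export
as_pattern_set.bcm_pattern_set <- function(x, ...) x

#' @export
as_pattern_set.data.frame <- function(x, ...) {
  labels <- if ("label" %in% names(x) && !all(is.na(x$label))) x$label
  probabilities <- if ("probability" %in% names(x)) x$probability
  feats <- setdiff(names(x), c("pattern", "label", "probability"))
  X <- t(as.matrix(x[feats]))
  pattern_set(X, labels = labels, probabilities = probabilities)
}

#' Mutually orthogonal patterns with chosen presentation probabilities
#'
#' Builds `n_patterns` axis-aligned patterns of magnitude `scale` in a
#' `n_features`-dimensional space. Because the patterns are orthogonal, the
#' BCM fixed points of a single neuron are known analytically: the stable
#' selective states respond with `1 / p_k` to exactly one pattern `k` and
#' with 0 to all others. This makes the set the canonical fixture for
#' convergence and selectivity checks.
#'
#' @param n_patterns Number of patterns `K`.
#' @param n_features Input dimensionality (`>= n_patterns`, default equal).
#' @param probabilities Per-pattern presentation probabilities (default
#'   uniform).
#' @param scale Pattern magnitude (default 1).
#' @return A [pattern_set()].
#' @export
#' @examples
#' orthogonal_patterns(2)$X
orthogonal_patterns <- function(n_patterns, n_features = n_patterns,
                                probabilities = NULL, scale = 1) {
  K <- assert_count(n_patterns, "n_patterns")
  d <- assert_count(n_features, "n_features")
  scale <- assert_number(scale, "scale")
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (K > d) {
    stop(sprintf(
      "cannot place %d mutually orthogonal patterns in %d dimensions", K, d
    ), call. = FALSE)
  }
  X <- matrix(0, d, K)
  X[cbind(seq_len(K), seq_len(K))] <- scale
  pattern_set(X, probabilities = probabilities)
}

#' Clustered nonnegative patterns (noisy class prototypes)
#'
#' Emulates the class structure of image benchmarks: each class gets a
#' random nonnegative prototype whose dominant support is a distinct
#' contiguous block of `floor(n_features / n_classes)` features with
#' uniform(0.5, 1) magnitudes, and each pattern is a noisy copy of its
#' class prototype (additive Gaussian noise, clipped at 0 to preserve
#' positivity). Zero-noise patterns of different classes are therefore
#' exactly orthogonal. Defaults give the 10-class, 200-pattern,
#' 64-dimensional fixture used throughout the package's competitiveness
#' experiments.
#'
#' @param n_classes Number of classes.
#' @param per_class Patterns per class.
#' @param n_features Input dimensionality (`>= n_classes`).
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed RNG seed (recorded in the result).
#' @return A [pattern_set()] with labels `1..n_classes` and uniform
#'   probabilities.
#' @export
clustered_patterns <- function(n_classes = 10, per_class = 20, n_features = 64,
                               noise_sd = 0.1, seed = 1) {
  n_classes <- assert_count(n_classes, "n_classes")
  per_class <- assert_count(per_class, "per_class")
  n_features <- assert_count(n_features, "n_features")
  noise_sd <- assert_number(noise_sd, "noise_sd", min = 0)
  seed <- assert_count(seed, "seed", min = -.Machine$integer.max)
  if (n_features < n_classes) {
    stop("`n_features` must be at least `n_classes`", call. = FALSE)
  }
  block <- n_features %/% n_classes
  local_seed(seed, {
    protos <- matrix(0, n_features, n_classes)
    for (k in seq_len(n_classes)) {
      idx <- ((k - 1L) * block + 1L):(k * block)
      protos[idx, k] <- stats::runif(block, 0.5, 1.0)
    }
    X <- protos[, rep(seq_len(n_classes), each = per_class), drop = FALSE]
    if (noise_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X))
    }
    X <- pmax(X, 0)
    pattern_set(X, labels = rep(seq_len(n_classes), each = per_class),
                seed = seed)
  })
}

#' Random batch schedule over a pattern set
#'
#' Training presents patterns in random batches, one parameter update per
#' batch. With uniform probabilities each epoch is a random permutation of
#' all patterns split into `ceiling(n / batch_size)` batches (the last
#' batch may be short), so every pattern is visited exactly once per epoch.
#' With non-uniform probabilities an epoch is `n_patterns` independent
#' probability-weighted draws with replacement, split the same way; this
#' mode exists to exercise the `1/p` fixed-point structure of the model.
#'
#' @param ps A [pattern_set()].
#' @param batch_size Patterns per batch, `1 <= batch_size <= n_patterns`.
#' @param epochs Number of epochs to schedule.
#' @param seed RNG seed for the schedule.
#' @return A list of length `epochs`; each element is a list of integer
#'   vectors of pattern indices (the batches of that epoch).
#' @export
#' @examples
#' ps <- orthogonal_patterns(4)
#' sample_batches(ps, batch_size = 3, epochs = 1, seed = 1)
sample_batches <- function(ps, batch_size, epochs = 1, seed = 1) {
  stopifnot(inherits(ps, "bcm_pattern_set"))
  n <- n_patterns(ps)
  batch_size <- assert_count(batch_size, "batch_size")
  epochs <- assert_count(epochs, "epochs", min = 0L)
  if (batch_size > n) {
    stop(sprintf("`batch_size` (%d) exceeds the number of patterns (%d)",
                 batch_size, n), call. = FALSE)
  }
  uniform <- max(abs(ps$probabilities - 1 / n)) < 1e-12
  grouping <- ceiling(seq_len(n) / batch_size)
  local_seed(seed, {
    lapply(seq_len(epochs), function(e) {
      idx <- if (uniform) {
        sample.int(n)
      } else {
        sample.int(n, n, replace = TRUE, prob = ps$probabilities)
      }
      unname(split(idx, grouping))
    })
  })
}
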