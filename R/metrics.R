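#' Selection set of one neuron
#'
#' A neuron has *selected* a pattern when its response to it strictly
#' exceeds its expected response over the whole environment:
#' `z(x) - E[z] > 0`. The expectation is the unweighted empirical mean
#' over the training patterns, or the probability-weighted mean when
#' presentation probabilities are non-uniform. Patterns exactly at the
#' mean are not selected (strict inequality), so a constant-response
#' neuron selects nothing.
#'
#' @param z Numeric vector: the neuron's response to every training
#'   pattern.
#' @param probabilities Optional per-pattern probabilities used to weight
#'   the expectation.
#' @return Integer vector of selected pattern indices.
#' @export
#' @examples
#' selection_set(c(3, 2, 1, 0))  # mean 1.5 -> patterns 1, 2
selection_set <- function(z, probabilities = NULL) {
  if (length(z) == 0L) stop("empty response vector", call. = FALSE)
  mu <- if (is.null(probabilities)) {
    mean(z)
  } else {
    stopifnot(length(probabilities) == length(z))
    sum(z * probabilities) / sum(probabilities)
  }
  which(z - mu > 0)
}

#' Selectivity: size of a selection set
#'
#' `alpha = |A|`, the number of training patterns a neuron responds to
#' above its mean response. Low alpha means a highly oriented receptive
#' field.
#'
#' @param A A selection set (integer vector).
#' @return Integer count.
#' @export
selectivity <- function(A) length(A)

#' Overlap index of a population of selection sets
#'
#' `beta = S / alpha_bar`, where `S` is the number of distinct patterns
#' selected by the whole network and `alpha_bar` the mean per-neuron
#' selectivity. For non-empty sets `beta` ranges in `[1, N]`: 1 means all
#' neurons selected the same patterns (total overlap), `N` means pairwise
#' disjoint selections (maximal competitiveness).
#'
#' @param sets List of per-neuron selection sets.
#' @return The overlap index, a number in `[1, N]`.
#' @export
#' @examples
#' overlap_index(list(c(1, 2, 3), c(3, 4)))  # 4 / 2.5 = 1.6
overlap_index <- function(sets) {
  stopifnot(is.list(sets), length(sets) > 0L)
  alphas <- lengths(sets)
  if (mean(alphas) == 0) {
    stop("overlap index undefined: every selection set is empty",
         call. = FALSE)
  }
  length(unique(unlist(sets))) / mean(alphas)
}

#' Memorization capacity
#'
#' `C = sum(alpha_i)`: the maximum number of (not necessarily distinct)
#' pattern selections the population can hold, also reported in the
#' approximate form `alpha_bar * N` for display. The exact sum is used
#' everywhere.
#'
#' @param alphas Per-neuron selectivities.
#' @return The capacity (numeric).
#' @export
capacity <- function(alphas) sum(alphas)

#' Classify the memorization regime
#'
#' Compares the number of training patterns `T` to the capacity `C`:
#' `T << C` (redundant: perfect memorization with redundancy is possible),
#' `T ~ C` (critical: perfect memorization only without redundancy, so
#' competition matters most), `T >> C` (ill-posed: perfect memorization is
#' impossible). The asymptotic symbols are operationalised by ratio
#' thresholds on `T / C`.
#'
#' @param n_patterns Number of training patterns `T`.
#' @param C Capacity from [capacity()]. `C = 0` is ill-posed by
#'   convention.
#' @param ratio_lo `T/C` below this is redundant.
#' @param ratio_hi `T/C` above this is ill-posed.
#' @return One of `"redundant"`, `"critical"`, `"ill_posed"`.
#' @export
classify_regime <- function(n_patterns, C, ratio_lo = 0.5, ratio_hi = 2) {
  T_ <- assert_count(n_patterns, "n_patterns")
  C <- assert_number(C, "C", min = 0)
  stopifnot(ratio_lo > 0, ratio_hi > ratio_lo)
  if (C == 0) return("ill_posed")
  r <- T_ / C
  if (r < ratio_lo) "redundant" else if (r > ratio_hi) "ill_posed" else "critical"
}

#' Class composition of a selection set
#'
#' Splits a neuron's selected patterns by class label: the per-class
#' histogram, the majority class, and the purity (majority count over
#' selectivity). For an empty selection set the majority class and purity
#' are undefined (`NA`).
#'
#' @param A Selection set (integer pattern indices).
#' @param labels Integer class label per pattern.
#' @return A list of class `bcm_class_profile`: `profile` (tibble with
#'   `class`, `n_selected`), `majority_class`, `purity`, `alpha`.
#' @export
#' @examples
#' # 201 of 250 selected patterns share one class -> purity 0.804
#' labels <- rep(c(3L, 9L), c(201, 49))
#' class_response_profile(seq_len(250), labels)$purity
class_response_profile <- function(A, labels) {
  if (is.null(labels)) {
    stop("pattern labels are required for a class profile", call. = FALSE)
  }
  if (length(A) == 0L) {
    return(structure(
      list(profile = tibble::tibble(class = integer(), n_selected = integer()),
           majority_class = NA_integer_, purity = NA_real_, alpha = 0L),
      class = "bcm_class_profile"))
  }
  sel <- labels[A]
  tab <- sort(table(sel), decreasing = TRUE)
  profile <- tibble::tibble(
    class = as.integer(names(tab)),
    n_selected = as.integer(tab)
  )
  structure(
    list(profile = profile,
         majority_class = profile$class[1L],
         purity = profile$n_selected[1L] / length(A),
         alpha = length(A)),
    class = "bcm_class_profile")
}

#' @export
print.bcm_class_profile <- function(x, ...) {
  cat(sprintf("<bcm_class_profile: alpha = %d, majority class %s, purity %s>\n",
              x$alpha,
              ifelse(is.na(x$majority_class), "NA", x$majority_class),
              ifelse(is.na(x$purity), "NA", sprintf("%.3f", x$purity))))
  invisible(x)
}

#' Competition report for a trained network
#'
#' Evaluates the trained network on every training pattern and assembles
#' the population metrics: per-neuron selection sets and selectivities,
#' the number of distinct selected patterns `S`, mean selectivity, the
#' overlap index `beta`, the capacity `C`, and the memorization regime of
#' `T` patterns against `C`.
#'
#' Selectivity is always computed from the network's own forward pass.
#' For competitiveness (beta) experiments the trained lateral coupling is
#' kept on; for pure selectivity experiments set `use_lateral = FALSE`
#' to evaluate the neurons independently (coupling turned off).
#'
#' @param fit A `bcm_fit` from [bcm_train()] (or a [network_state()]).
#' @param patterns The [pattern_set()] the network was trained on.
#' @param use_lateral Evaluate with the trained lateral coupling (`TRUE`)
#'   or with the coupling turned off (`FALSE`).
#' @return An object of class `bcm_competition`: list with
#'   `selection_sets`, `alphas`, `alpha_bar`, `S`, `beta` (`NA` when every
#'   set is empty), `capacity`, `regime`, `n_neurons`, `n_patterns`.
#'   Explore with [tidy()] and [glance()].
#' @export
competition_report <- function(fit, patterns, use_lateral = TRUE) {
  network <- if (inherits(fit, "bcm_fit")) fit$network else fit
  stopifnot(inherits(network, "bcm_network"))
  ps <- as_pattern_set(patterns)
  if (!use_lateral && network$lateral$xi != 0) {
    network <- network_state(network$W, network$activation,
                             build_lateral(nrow(network$W), 0))
  }
  Z <- forward(network, ps)
  uniform <- max(abs(ps$probabilities - 1 / ncol(ps$X))) < 1e-12
  probs <- if (uniform) NULL else ps$probabilities
  sets <- lapply(seq_len(nrow(Z)), function(i) selection_set(Z[i, ], probs))
  alphas <- vapply(sets, selectivity, integer(1))
  alpha_bar <- mean(alphas)
  S <- length(unique(unlist(sets)))
  C <- capacity(alphas)
  structure(
    list(selection_sets = sets, alphas = alphas, alpha_bar = alpha_bar,
         S = S,
         beta = if (alpha_bar > 0) S / alpha_bar else NA_real_,
         capacity = C,
         regime = classify_regime(ncol(ps$X), C),
         n_neurons = nrow(Z), n_patterns = ncol(ps$X),
         labels = ps$labels),
    class = "bcm_competition")
}

#' @export
print.bcm_competition <- function(x, ...) {
  cat(sprintf(
    "<bcm_competition: N = %d, T = %d, alpha_bar = %.2f, S = %d, beta = %s, C = %g (%s)>\n",
    x$n_neurons, x$n_patterns, x$alpha_bar, x$S,
    ifelse(is.na(x$beta), "NA", sprintf("%.3f", x$beta)),
    x$capacity, x$regime))
  invisible(x)
}

#' @rdname competition_report
#' @param x A `bcm_competition`.
#' @param ... Unused.
#' @export
tidy.bcm_competition <- function(x, ...) {
  out <- tibble::tibble(neuron = seq_len(x$n_neurons), alpha = x$alphas)
  if (!is.null(x$labels)) {
    profs <- lapply(x$selection_sets, class_response_profile, labels = x$labels)
    out$majority_class <- vapply(profs, function(p) p$majority_class, integer(1))
    out$purity <- vapply(profs, function(p) p$purity, numeric(1))
  }
  out
}

#' @rdname competition_report
#' @export
glance.bcm_competition <- function(x, ...) {
  tibble::tibble(
    n_neurons = x$n_neurons, n_patterns = x$n_patterns,
    alpha_bar = x$alpha_bar, S = x$S, beta = x$beta,
    capacity = x$capacity, regime = x$regime
  )
}
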