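#' Overlap index as a function of lateral connection strength
#'
#' Retrains the network for every requested interaction strength `xi`,
#' holding the initial weights fixed (same `seed_weights`) so that beta
#' differences are attributable to `xi` alone, and replicating each
#' training over several batch-order seeds. Inhibitory (negative) `xi`
#' discourages neurons from memorizing the same patterns, so beta grows
#' towards `N`; small excitatory `xi` pulls neurons onto the same
#' attractor and beta drops to 1.
#'
#' A `xi` at a singular coupling value is recorded as an error row and the
#' sweep continues.
#'
#' @param patterns A [pattern_set()].
#' @param xi Vector of lateral strengths to sweep.
#' @param seeds Batch-order seeds to replicate each training over.
#' @param config Base [bcm_config()] (its `xi` and `seed_batches` are
#'   overridden per run).
#' @param use_lateral Evaluate selection sets with the trained coupling
#'   (default) or decoupled.
#' @param ... Further config overrides applied before sweeping.
#' @return A tibble of class `bcm_sweep`: one row per (`xi`, `seed`) with
#'   `beta`, `alpha_bar`, `S`, `capacity`, `epochs_run`, `n_converged`,
#'   `error` (`NA` for successful runs). Plot with
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' \donttest{
#' ps <- clustered_patterns(seed = 42)
#' sw <- beta_sweep(ps, xi = c(0.05, -0.1), seeds = 1:2,
#'                  config = bcm_config(n_neurons = 5, epochs = 60))
#' dplyr::summarise(dplyr::group_by(sw, xi), median_beta = median(beta))
#' }
beta_sweep <- function(patterns, xi = c(0.05, 0, -0.05, -0.1, -0.2),
                       seeds = 1:5, config = bcm_config(n_neurons = 5),
                       use_lateral = TRUE, ...) {
  ps <- as_pattern_set(patterns)
  config <- modify_config(config, ...)
  grid <- tidyr::expand_grid(xi = xi, seed = as.integer(seeds))
  rows <- purrr::pmap(grid, function(xi, seed) {
    res <- tryCatch({
      fit <- bcm_train(ps, config, xi = xi, seed_batches = seed)
      rep_ <- competition_report(fit, ps, use_lateral = use_lateral)
      tibble::tibble(
        beta = rep_$beta, alpha_bar = rep_$alpha_bar, S = rep_$S,
        capacity = rep_$capacity, epochs_run = fit$epochs_run,
        n_converged = sum(fit$converged), error = NA_character_)
    }, error = function(e) {
      tibble::tibble(beta = NA_real_, alpha_bar = NA_real_, S = NA_integer_,
                     capacity = NA_real_, epochs_run = NA_integer_,
                     n_converged = NA_integer_, error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(xi = xi, seed = seed), res)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bcm_sweep", class(out))
  out
}

#' Plot a beta-vs-xi sweep
#'
#' @param object A `bcm_sweep` tibble from [beta_sweep()].
#' @param ... Unused.
#' @return A ggplot: per-run beta (points) and median beta per `xi`
#'   (line), against the lateral strength.
#' @export
autoplot.bcm_sweep <- function(object, ...) {
  ok <- dplyr::filter(object, is.na(.data$error))
  med <- dplyr::summarise(dplyr::group_by(ok, .data$xi),
                          beta = stats::median(.data$beta), .groups = "drop")
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$xi, y = .data$beta)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = med, colour = "steelblue") +
    ggplot2::geom_point(data = med, colour = "steelblue", size = 2) +
    ggplot2::labs(x = expression(xi~"(lateral strength)"),
                  y = expression(beta~"(overlap index)")) +
    ggplot2::theme_minimal()
}
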