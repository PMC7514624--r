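#' Sweep the neighborhood radius
#'
#' Runs the reduct search over a grid of radii (by default `0.05, 0.10, ...,
#' 1`, the usual protocol for choosing delta) and, optionally, cross-validates
#' each reduct. Radius 1 on min-max-normalized data whose pairwise distances
#' never exceed 1 saturates every neighborhood, NRH collapses to 0, and the
#' reduct degenerates to the empty set — expected behavior at the coarse end
#' of the sweep.
#'
#' @param data A decision table or data frame.
#' @param deltas Numeric grid of radii in `[0, 1]`.
#' @param epsilon Equality tolerance passed to [arnrje()].
#' @param classifier Optional: `"knn3"` or `"linear_svm"` to cross-validate
#'   each reduct. `NULL` (default) skips evaluation.
#' @param folds,seed Cross-validation settings (see [cross_validate()]).
#' @param decision Decision column name.
#' @return A tibble of class `delta_sweep`, one row per radius: `delta`,
#'   `n_reduct`, `reduction_rate`, `reduct` (list column), and
#'   `mean_accuracy`, `recall` when a classifier was requested.
#' @export
sweep_delta <- function(data, deltas = seq(0.05, 1, by = 0.05),
                        epsilon = 1e-10, classifier = NULL,
                        folds = 10L, seed = 0L, decision = NULL) {
  if (length(deltas) == 0L) stop("empty delta grid", call. = FALSE)
  if (any(deltas < 0 | deltas > 1)) stop("deltas must lie in [0, 1]", call. = FALSE)
  rows <- purrr::map(deltas, function(d) {
    tr <- arnrje(data, delta = d, epsilon = epsilon, decision = decision)
    row <- tibble::tibble(
      delta = d,
      n_reduct = length(tr$reduct),
      reduction_rate = reduction_rate(tr$n_attributes, length(tr$reduct)),
      reduct = list(tr$reduct)
    )
    if (!is.null(classifier) && length(tr$reduct) > 0L) {
      cv <- cross_validate(data, tr$reduct, classifier = classifier,
                           folds = folds, seed = seed, decision = decision)
      row$mean_accuracy <- cv$mean_accuracy
      row$recall <- cv$recall
    } else if (!is.null(classifier)) {
      row$mean_accuracy <- NA_real_
      row$recall <- NA_real_
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("delta_sweep", class(out))
  out
}

#' @describeIn sweep_delta Reduction rate (and accuracy, when present)
#'   against the radius.
#' @param object A `delta_sweep` tibble.
#' @param ... Unused.
#' @method autoplot delta_sweep
#' @export
autoplot.delta_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("delta", "reduction_rate",
                                intersect("mean_accuracy", names(object)))],
    -"delta", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delta, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "neighborhood radius delta", y = NULL,
                  title = "Reduct size and classification quality across radii") +
    ggplot2::theme_minimal()
}
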