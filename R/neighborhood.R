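#' Pairwise Euclidean distances on an attribute subset
#'
#' Distance between samples i and j restricted to the attribute subset `B`:
#' `sqrt(sum_k (x_ik - x_jk)^2)` over `k` in `B`. The empty subset is not
#' accepted here; the neighborhood convention for `B = {}` (every sample is a
#' neighbor of every other) is handled by [neighborhoods()].
#'
#' @param data A decision table or data frame.
#' @param attributes Attribute names or indices (default: all attributes).
#' @param decision Decision column name, if `data` is a plain data frame.
#' @return An n x n symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(data, attributes = NULL, decision = NULL) {
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  if (length(B) == 0L) stop("attribute subset must be non-empty", call. = FALSE)
  D <- as.matrix(stats::dist(ctx$X[, B, drop = FALSE], method = "euclidean"))
  dimnames(D) <- NULL
  D
}

#' Neighborhood classes under a distance threshold
#'
#' For each sample `x`, its neighborhood class on attribute subset `B` with
#' radius `delta` is the set of samples at Euclidean distance at most `delta`
#' (inclusive comparison, so a pair at exactly `delta` are neighbors). Sets
#' are measured with the counting measure, the finite-sample specialization
#' of the Lebesgue measure. The empty subset follows the convention that all
#' distances are zero, so every neighborhood is the whole sample set.
#'
#' @inheritParams pairwise_distances
#' @param delta Neighborhood radius in `[0, 1]`.
#' @return An object of class `neighborhood_model`: a list with `neighbors`
#'   (list of integer vectors, one per sample), `attributes`, `delta`, `n`.
#' @examples
#' dt <- simulate_decision_table(10, 2, seed = 1)
#' nb <- neighborhoods(dt, delta = 0.3)
#' lengths(nb$neighbors)
#' @export
neighborhoods <- function(data, attributes = NULL, delta, decision = NULL) {
  stopifnot(is.numeric(delta), length(delta) == 1L)
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  neighbors <- if (length(B) == 0L) {
    rep(list(seq_len(ctx$n)), ctx$n)
  } else {
    D <- as.matrix(stats::dist(ctx$X[, B, drop = FALSE]))
    dimnames(D) <- NULL
    lapply(seq_len(ctx$n), function(i) which(D[i, ] <= delta))
  }
  structure(
    list(neighbors = neighbors,
         attributes = ctx$attrs[B],
         delta = delta,
         n = ctx$n),
    class = "neighborhood_model"
  )
}

#' @export
print.neighborhood_model <- function(x, ...) {
  cat("# Neighborhood model: n = ", x$n, ", delta = ", x$delta,
      ", B = {", paste(x$attributes, collapse = ", "), "}\n", sep = "")
  cat("# neighborhood sizes: ", paste(lengths(x$neighbors), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy neighborhood_model
#' @export
tidy.neighborhood_model <- function(x, ...) {
  tibble::tibble(
    sample = seq_len(x$n),
    size = lengths(x$neighbors),
    neighbors = x$neighbors
  )
}

#' Lower/upper approximations, precision and roughness per decision class
#'
#' For each decision class `d_j`, the lower approximation collects samples
#' whose whole neighborhood lies inside the class, the upper approximation
#' those whose neighborhood meets it. Precision `rho` is the ratio of the
#' two counting measures and roughness `gamma = 1 - rho`.
#'
#' @param data A decision table or data frame.
#' @param attributes Attribute subset (default all).
#' @param delta Neighborhood radius in `[0, 1]`.
#' @param decision Decision column name.
#' @param model Optionally a precomputed [neighborhoods()] model for the same
#'   data (saves recomputation).
#' @return A tibble with one row per decision class: `class`, `n_class`,
#'   `lower`, `upper` (list columns of sample indices), `n_lower`, `n_upper`,
#'   `precision`, `roughness`.
#' @export
class_approximations <- function(data, attributes = NULL, delta,
                                 decision = NULL, model = NULL) {
  ctx <- dt_context(data, decision)
  if (is.null(model)) model <- neighborhoods(data, attributes, delta, decision)
  stopifnot(model$n == ctx$n)
  if (any(lengths(ctx$classes) == 0L)) stop("empty decision class", call. = FALSE)
  approx_one <- function(dj) {
    in_class <- logical(ctx$n)
    in_class[dj] <- TRUE
    lower <- which(vapply(model$neighbors, function(nb) all(in_class[nb]), logical(1)))
    upper <- which(vapply(model$neighbors, function(nb) any(in_class[nb]), logical(1)))
    list(lower = lower, upper = upper)
  }
  res <- lapply(ctx$classes, approx_one)
  tibble::tibble(
    class = names(ctx$classes),
    n_class = lengths(ctx$classes),
    lower = lapply(res, `[[`, "lower"),
    upper = lapply(res, `[[`, "upper"),
    n_lower = vapply(res, function(r) length(r$lower), integer(1)),
    n_upper = vapply(res, function(r) length(r$upper), integer(1)),
    precision = .data_precision(res),
    roughness = 1 - .data_precision(res)
  )
}

.data_precision <- function(res) {
  vapply(unname(res), function(r) {
    if (length(r$upper) == 0L) return(1)  # empty upper forces empty lower; vacuous class
    length(r$lower) / length(r$upper)
  }, numeric(1))
}

#' Positive region of the decision
#'
#' Union of the lower approximations of all decision classes: the samples
#' whose neighborhood is decision-consistent.
#'
#' @inheritParams class_approximations
#' @return Integer vector of sample indices.
#' @export
positive_region <- function(data, attributes = NULL, delta, decision = NULL) {
  ap <- class_approximations(data, attributes, delta, decision)
  sort(unique(unlist(ap$lower)))
}
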